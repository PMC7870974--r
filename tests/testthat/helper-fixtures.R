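# Shared fixtures, built in code at load time. Tables use width 5 (1,536
# changes) unless a test needs the default width-7 scale.

toy_table <- function(motif_consensus = "TAAT", width = 5L, seed = 1L,
                      name = "toy", ...) {
  synth_qbic_table(synth_motif(motif_consensus, seed = seed + 100L),
                   name = name, width = width, seed = seed, ...)
}

ct_signature <- function() synth_signature(c("C>T" = 0.95, "C>A" = 0.05),
                                           name = "ct_dominated")
tc_signature <- function() synth_signature(c("T>C" = 0.9, "T>G" = 0.1),
                                           name = "tc_dominated")
flat_signature <- function() {
  synth_signature(stats::setNames(rep(1 / 6, 6), sigbind:::SUBSTITUTION_TYPES),
                  name = "flat")
}

# Independent brute-force oracle for GR/LR: per-change loops, hand-rolled
# BH step-up, no shared code with the vectorised implementation.
oracle_bh_threshold <- function(score, pvalue, fdr) {
  n <- length(pvalue)
  ord <- order(pvalue)
  p_sorted <- pvalue[ord]
  k <- which(p_sorted <= fdr * seq_len(n) / n)
  if (length(k) == 0) return(NA_real_)
  p_star <- p_sorted[max(k)]
  min(abs(score[pvalue <= p_star]))
}

oracle_gain_loss <- function(table, sig, fdr = 0.1) {
  thr <- oracle_bh_threshold(table$score, table$pvalue, fdr)
  per_class <- 4^(nchar(table$kmer[1]) - 3)
  n <- nrow(table)
  wpos <- 0; wneg <- 0; upos <- 0; uneg <- 0
  for (i in seq_len(n)) {
    m_sig <- sig[[table$class[i]]] / per_class
    m_uni <- 1 / n
    if (table$score[i] >= thr) { wpos <- wpos + m_sig; upos <- upos + m_uni }
    if (table$score[i] <= -thr) { wneg <- wneg + m_sig; uneg <- uneg + m_uni }
  }
  list(threshold = thr, gr = wpos / upos, lr = wneg / uneg,
       area_pos = wpos, area_neg = wneg, base_pos = upos, base_neg = uneg)
}
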