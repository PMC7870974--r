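# The central statistic: signature-weighted score distributions, the
# FDR-induced tail threshold, Gain and Loss Ratios, and their resampling
# significance test.
#
# For a score table D and signature sigma, the weighted distribution puts
# mass sigma_mu / 4^(width-3) on each change of class mu (the uniform
# baseline puts 1 / (96 * 4^(width-3)) on every change). GR is the ratio of
# weighted to baseline mass in the significant positive tail, LR in the
# negative tail; both tails are cut at the same |score| threshold T induced
# by Benjamini-Hochberg FDR on the per-change p-values.

sig_input <- function(signatures) {
  if (is.numeric(signatures)) {
    stopifnot(!is.null(names(signatures)))
    return(tibble::tibble(signature = "signature",
                          class = names(signatures),
                          prob = unname(signatures)))
  }
  signatures
}

#' Signature-weighted score distribution
#'
#' Reweights a score table by a signature: every change of class `mu` gets
#' mass `sigma_mu / 4^(width-3)`, so the 96 per-class distributions are
#' scaled by the class probabilities and summed. With the uniform signature
#' this reduces to the equal-frequency baseline (mass
#' `1 / (96 * 4^(width-3))` per change). Total mass is 1.
#'
#' @param table A `qbic_tbl`.
#' @param signatures Signature catalog tibble (one signature, or pass
#'   `name`) or a named 96-vector.
#' @param name Signature to use when the catalog has several.
#' @return Tibble `kmer`, `alt`, `class`, `score`, `pvalue`, `mass`.
#' @export
weighted_distribution <- function(table, signatures, name = NULL) {
  sig <- sig_vector(sig_input(signatures), name)
  per_class <- 4^(attr(table, "width") - 3)
  out <- tibble::as_tibble(table)
  out$mass <- unname(sig[out$class]) / per_class
  out
}

#' Tail threshold induced by Benjamini-Hochberg FDR
#'
#' Applies BH jointly to all p-values of a table and returns the smallest
#' `|score|` among changes passing `FDR < fdr`. Because the p-value is a
#' decreasing function of `|score|`, the passing set is exactly
#' `{|score| >= T}`, a symmetric two-tail cut. When no change passes, the
#' table has no significant tail and `NA` is returned with a message;
#' ratios are undefined (reported as missing) downstream.
#'
#' @param table A `qbic_tbl`.
#' @param fdr FDR level in (0, 1); default 0.1.
#' @return The threshold `T` (numeric scalar), or `NA_real_` when no change
#'   passes.
#' @export
fdr_threshold <- function(table, fdr = 0.1) {
  stopifnot(fdr > 0, fdr < 1)
  q <- stats::p.adjust(table$pvalue, method = "BH")
  pass <- q < fdr
  if (!any(pass)) {
    rlang::inform(sprintf(
      "no change passes BH FDR < %g in experiment %s; tail undefined",
      fdr, attr(table, "experiment_id")
    ))
    return(NA_real_)
  }
  min(abs(table$score[pass]))
}

#' Tail areas of a weighted distribution
#'
#' Mass of the distribution above `T` (positive tail) and below `-T`
#' (negative tail). The cut is inclusive so that, with `T` from
#' [fdr_threshold()], the two tails together are exactly the set of changes
#' passing the FDR cut; the same changes make up the tails under every
#' signature, only their masses differ. Areas are exact weighted sums over
#' changes, not histogram-bin sums.
#'
#' @param dist A weighted distribution from [weighted_distribution()] (needs
#'   `score` and `mass` columns).
#' @param threshold The score-magnitude threshold `T`.
#' @return Tibble with columns `area_pos`, `area_neg`.
#' @export
tail_areas <- function(dist, threshold) {
  if (is.na(threshold)) {
    return(tibble::tibble(area_pos = NA_real_, area_neg = NA_real_))
  }
  tibble::tibble(
    area_pos = sum(dist$mass[dist$score >= threshold]),
    area_neg = sum(dist$mass[dist$score <= -threshold])
  )
}

class_tail_counts <- function(table, threshold) {
  cls <- factor(table$class, levels = mutation_classes())
  pos <- tapply(table$score >= threshold, cls, sum, default = 0L)
  neg <- tapply(table$score <= -threshold, cls, sum, default = 0L)
  list(pos = as.numeric(pos), neg = as.numeric(neg))
}

#' Gain and Loss Ratios of signatures against one score table
#'
#' For each signature, `GR = area'_pos / area_pos` and
#' `LR = area'_neg / area_neg`, where the primed areas are tail masses under
#' the signature-weighted distribution and the unprimed ones under the
#' equal-frequency baseline, both cut at the same BH threshold `T`.
#' `GR > 1` means the mutational process preferentially creates binding
#' sites for the assayed TF; `LR > 1` that it preferentially destroys them.
#' The uniform signature gives `GR = LR = 1` exactly. A table with no
#' significant tail, or an empty baseline tail on one side, yields `NA`
#' ratios (flagged, never silently 0).
#'
#' @param table A `qbic_tbl`.
#' @param signatures Signature catalog tibble (any number of signatures) or
#'   named 96-vector.
#' @param fdr BH FDR level defining the tails (default 0.1).
#' @return Tibble with one row per signature: `experiment`, `tf`,
#'   `signature`, `threshold`, `area_pos`, `area_neg`, `base_pos`,
#'   `base_neg`, `gr`, `lr`.
#' @export
gain_loss_ratios <- function(table, signatures, fdr = 0.1) {
  signatures <- sig_input(signatures)
  sig_names <- unique(signatures$signature)
  thr <- fdr_threshold(table, fdr)
  n <- nrow(table)
  per_class <- 4^(attr(table, "width") - 3)
  base <- function(len) rep(NA_real_, len)
  out <- tibble::tibble(
    experiment = attr(table, "experiment_id"),
    tf = attr(table, "tf_name"),
    signature = sig_names,
    threshold = thr,
    area_pos = base(length(sig_names)), area_neg = base(length(sig_names)),
    base_pos = NA_real_, base_neg = NA_real_,
    gr = base(length(sig_names)), lr = base(length(sig_names))
  )
  if (is.na(thr)) return(out)
  counts <- class_tail_counts(table, thr)
  # baseline areas through the same weighted path (with the flat signature)
  # so the uniform-signature identity GR = LR = 1 holds exactly, not just to
  # rounding; algebraically these equal sum(counts)/n
  sig_mat <- vapply(sig_names, function(nm) sig_vector(signatures, nm),
                    numeric(96))
  sig_mat <- cbind(sig_mat, .baseline = rep(1 / 96, 96))
  pos <- as.numeric(crossprod(sig_mat, counts$pos / per_class))
  neg <- as.numeric(crossprod(sig_mat, counts$neg / per_class))
  k <- length(sig_names)
  area_pos <- pos[seq_len(k)]; base_pos <- pos[k + 1]
  area_neg <- neg[seq_len(k)]; base_neg <- neg[k + 1]
  out$area_pos <- area_pos
  out$area_neg <- area_neg
  out$base_pos <- base_pos
  out$base_neg <- base_neg
  out$gr <- if (base_pos > 0) area_pos / base_pos else NA_real_
  out$lr <- if (base_neg > 0) area_neg / base_neg else NA_real_
  if (base_pos == 0 || base_neg == 0) {
    rlang::inform(sprintf(
      "experiment %s: empty baseline %s tail; ratio reported as missing",
      attr(table, "experiment_id"),
      paste(c("positive", "negative")[c(base_pos == 0, base_neg == 0)],
            collapse = " and ")
    ))
  }
  out
}

#' Resampling significance of tail-area excess
#'
#' Tests, for each signature, the null hypothesis that
#' `area'_pos - area_pos` (gain side; loss side analogous) is no greater
#' than expected for random mutations drawn with equal class frequencies.
#' Each replicate draws `n_mutations` class labels from the uniform
#' multinomial over the 96 classes, normalises the counts to a
#' pseudo-signature and recomputes the tail-area difference; the one-sided
#' p-value uses the add-one estimator
#' `(1 + #{replicate >= observed}) / (n_reps + 1)`. The same seeded
#' replicate set is shared across signatures.
#'
#' @param table A `qbic_tbl`.
#' @param signatures Signature catalog or named 96-vector.
#' @param n_mutations Mutations drawn per replicate (default 10,000).
#' @param n_reps Number of replicates (default 1,000).
#' @param seed Integer seed (required; the test is Monte Carlo).
#' @param fdr BH FDR level defining the tails.
#' @return Tibble with one row per signature: `experiment`, `signature`,
#'   `p_gain`, `p_loss`, `n_resamples`, `seed`.
#' @export
resample_significance <- function(table, signatures, n_mutations = 10000,
                                  n_reps = 1000, seed, fdr = 0.1) {
  stopifnot(n_mutations >= 1, n_reps >= 1)
  if (missing(seed) || is.null(seed)) rlang::abort("`seed` is required")
  signatures <- sig_input(signatures)
  sig_names <- unique(signatures$signature)
  thr <- fdr_threshold(table, fdr)
  out <- tibble::tibble(
    experiment = attr(table, "experiment_id"), signature = sig_names,
    p_gain = NA_real_, p_loss = NA_real_,
    n_resamples = as.integer(n_reps), seed = as.integer(seed)
  )
  if (is.na(thr)) return(out)
  per_class <- 4^(attr(table, "width") - 3)
  counts <- class_tail_counts(table, thr)
  a_pos <- counts$pos / per_class
  a_neg <- counts$neg / per_class
  # baseline through the same dot-product form as the observed statistic
  base_pos <- sum(rep(1 / 96, 96) * a_pos)
  base_neg <- sum(rep(1 / 96, 96) * a_neg)
  set.seed(as.integer(seed))
  reps <- stats::rmultinom(n_reps, n_mutations, rep(1 / 96, 96)) / n_mutations
  null_pos <- as.numeric(crossprod(reps, a_pos)) - base_pos
  null_neg <- as.numeric(crossprod(reps, a_neg)) - base_neg
  for (i in seq_along(sig_names)) {
    sig <- sig_vector(signatures, sig_names[i])
    obs_pos <- sum(sig * a_pos) - base_pos
    obs_neg <- sum(sig * a_neg) - base_neg
    out$p_gain[i] <- (1 + sum(null_pos >= obs_pos)) / (n_reps + 1)
    out$p_loss[i] <- (1 + sum(null_neg >= obs_neg)) / (n_reps + 1)
  }
  out
}

#' Aggregate per-experiment ratios to the TF level
#'
#' A TF assayed in several PBM experiments is summarised by the median GR
#' and LR over its experiments (standard median: mean of the middle two for
#' even counts). Resampling p-values, when present, are aggregated the same
#' way.
#'
#' @param results Tibble of per-experiment results (from
#'   [gain_loss_ratios()], optionally joined with resampling p-values); must
#'   have columns `tf`, `signature`, `gr`, `lr`.
#' @param experiment_map Optional tibble `(experiment, tf)` overriding the
#'   `tf` column.
#' @return Tibble with one row per (tf, signature): `tf`, `signature`,
#'   `n_experiments`, `gr`, `lr` and median `p_gain`/`p_loss` when present.
#' @export
aggregate_tf <- function(results, experiment_map = NULL) {
  if (!is.null(experiment_map)) {
    results <- results |>
      dplyr::select(-dplyr::any_of("tf")) |>
      dplyr::left_join(experiment_map, by = "experiment")
  }
  if (any(is.na(results$tf))) {
    rlang::abort("some experiments have no TF assignment")
  }
  med <- function(x) stats::median(x, na.rm = FALSE)
  results |>
    dplyr::group_by(.data$tf, .data$signature) |>
    dplyr::summarise(
      n_experiments = dplyr::n(),
      dplyr::across(dplyr::any_of(c("gr", "lr", "p_gain", "p_loss")), med),
      .groups = "drop"
    )
}

#' Classify (TF, signature) pairs as gain- or loss-of-binding
#'
#' A pair is gain-of-binding when the signature-weighted positive tail
#' significantly exceeds the baseline (`p_gain < alpha`), loss-of-binding
#' when the negative tail does (`p_loss < alpha`); a pair may be neither.
#'
#' @param results Tibble with `p_gain` and `p_loss` columns (per experiment
#'   or per TF).
#' @param alpha Significance level (default 0.05).
#' @return `results` with logical columns `gain` and `loss` added.
#' @export
classify_gain_loss <- function(results, alpha = 0.05) {
  dplyr::mutate(
    results,
    gain = !is.na(.data$p_gain) & .data$p_gain < alpha,
    loss = !is.na(.data$p_loss) & .data$p_loss < alpha
  )
}

#' Wide GR or LR matrix
#'
#' @param results Per-TF results tibble (`tf`, `signature`, `gr`, `lr`).
#' @param value `"gr"` or `"lr"`.
#' @return Tibble with one row per signature and one column per TF.
#' @export
grlr_matrix <- function(results, value = c("gr", "lr")) {
  value <- rlang::arg_match(value)
  results |>
    dplyr::select("signature", "tf", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "tf", values_from = dplyr::all_of(value)) |>
    dplyr::arrange(.data$signature)
}

#' Hierarchically cluster the GR/LR matrix
#'
#' Clusters signatures (rows) and TFs (columns) by complete-linkage
#' agglomeration on Euclidean distance, each axis described by the
#' concatenated GR and LR profiles. Missing ratios are imputed as 1 (no
#' effect) for clustering only, with a message. Deterministic given the
#' input order; a degenerate axis (single row or column) keeps identity
#' order.
#'
#' @param results Per-TF results tibble (`tf`, `signature`, `gr`, `lr`).
#' @return List with `signature_order`, `tf_order` (character vectors),
#'   `signature_hclust`, `tf_hclust` (`hclust` objects or `NULL` when
#'   degenerate) and `signature_newick`, `tf_newick` (Newick strings).
#' @export
cluster_gr_lr <- function(results) {
  gr <- grlr_matrix(results, "gr")
  lr <- grlr_matrix(results, "lr")
  sigs <- gr$signature
  m <- cbind(as.matrix(gr[, -1]), as.matrix(lr[, -1]))
  rownames(m) <- sigs
  if (anyNA(m)) {
    rlang::inform(sprintf(
      "imputing %d missing ratio(s) as 1 for clustering", sum(is.na(m))
    ))
    m[is.na(m)] <- 1
  }
  tfs <- colnames(gr)[-1]
  tf_m <- rbind(as.matrix(gr[, -1]), as.matrix(lr[, -1]))
  tf_m[is.na(tf_m)] <- 1
  cluster_axis <- function(x, labels) {
    if (nrow(x) < 2) {
      return(list(order = labels, hclust = NULL,
                  newick = if (length(labels) == 1) paste0(labels, ";") else NA))
    }
    hc <- stats::hclust(stats::dist(x), method = "complete")
    list(order = labels[hc$order], hclust = hc,
         newick = ape::write.tree(ape::as.phylo(hc)))
  }
  row_cl <- cluster_axis(m, sigs)
  col_cl <- cluster_axis(t(tf_m), tfs)
  list(
    signature_order = row_cl$order, tf_order = col_cl$order,
    signature_hclust = row_cl$hclust, tf_hclust = col_cl$hclust,
    signature_newick = row_cl$newick, tf_newick = col_cl$newick
  )
}
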