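# AT/GC classification of TF position weight matrices and the expected
# change in sequence (base-composition) entropy under signature-weighted
# mutations. "+AT" mutations convert C/G to A/T (central C>A or C>T) and
# push AT-rich k-mers toward lower composition entropy; "-AT" mutations
# (T>C, T>G) do the converse.

PLUS_AT_TYPES <- c("C>A", "C>T")
MINUS_AT_TYPES <- c("T>C", "T>G")

validate_pwm <- function(pwm, tol = 1e-6) {
  need <- c("position", "A", "C", "G", "T")
  if (!all(need %in% names(pwm))) {
    rlang::abort("PWM needs columns position, A, C, G, T")
  }
  rows <- as.matrix(pwm[, DNA_BASES_])
  if (any(rows < 0)) rlang::abort("negative PWM probability")
  s <- rowSums(rows)
  if (any(abs(s - 1) > tol)) {
    rlang::warn("PWM positions do not sum to 1; renormalizing")
    pwm[, DNA_BASES_] <- rows / s
  }
  if (nrow(pwm) < 4) rlang::abort("PWM width must be >= 4")
  pwm
}

#' Read a CIS-BP-style PWM
#'
#' Tab-separated, one row per motif position, columns for A, C, G, T
#' probabilities (an optional leading position column is accepted).
#'
#' @param path Path to the TSV.
#' @param tf TF name (defaults to the file name).
#' @return Tibble `tf`, `pwm`, `position`, `A`, `C`, `G`, `T`.
#' @export
read_pwm_cisbp <- function(path, tf = sub("\\.[^.]*$", "", basename(path))) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(d) <- sub("^Pos.*", "position", names(d), ignore.case = TRUE)
  if (!"position" %in% names(d)) d$position <- seq_len(nrow(d))
  d <- validate_pwm(d[, c("position", DNA_BASES_)])
  tibble::tibble(tf = tf, pwm = basename(path), d)
}

#' Read PWMs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with their letter-probability matrices (alphabet
#' ACGT).
#'
#' @param path Path to the MEME file.
#' @return Tibble `tf`, `pwm`, `position`, `A`, `C`, `G`, `T` (one block of
#'   rows per motif).
#' @export
read_pwm_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) rlang::abort("no MOTIF blocks found")
  out <- purrr::map(starts, function(s) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    i <- s + 1
    while (i <= length(lines) && !grepl("^letter-probability", lines[i])) i <- i + 1
    if (i > length(lines)) rlang::abort(sprintf("motif %s has no matrix", name))
    rows <- list()
    j <- i + 1
    while (j <= length(lines) &&
             grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[j])) {
      rows[[length(rows) + 1]] <- as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]])
      j <- j + 1
    }
    m <- do.call(rbind, rows)
    colnames(m) <- DNA_BASES_
    d <- validate_pwm(tibble::tibble(position = seq_len(nrow(m)),
                                     tibble::as_tibble(m)))
    tibble::tibble(tf = name, pwm = name, d)
  })
  dplyr::bind_rows(out)
}

#' Average AT content of each TF's PWM
#'
#' The AT percent of a PWM is the mean over positions of P(A) + P(T); a TF
#' assayed with several PWMs is summarised by the median AT percent. TFs
#' are labelled `AT-PWM` when AT percent exceeds `at_threshold` (default
#' 0.6), `GC-PWM` below `gc_threshold` (default 0.4), `neither` otherwise
#' (strict inequalities).
#'
#' @param pwms Tibble of PWMs (`tf`, `pwm`, `position`, `A`, `C`, `G`, `T`).
#' @param at_threshold,gc_threshold Classification cut-offs.
#' @return Tibble `tf`, `at_percent`, `label`.
#' @export
at_percent <- function(pwms, at_threshold = 0.6, gc_threshold = 0.4) {
  per_pwm <- pwms |>
    dplyr::group_by(.data$tf, .data$pwm) |>
    dplyr::summarise(at = mean(.data$A + .data$T), .groups = "drop")
  per_pwm |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(at_percent = stats::median(.data$at), .groups = "drop") |>
    dplyr::mutate(label = dplyr::case_when(
      .data$at_percent > at_threshold ~ "AT-PWM",
      .data$at_percent < gc_threshold ~ "GC-PWM",
      TRUE ~ "neither"
    ))
}

base_counts <- function(kmer) {
  out <- vapply(DNA_BASES_, function(b) {
    nchar(kmer) - nchar(gsub(b, "", kmer, fixed = TRUE))
  }, numeric(length(kmer)))
  if (length(kmer) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, DNA_BASES_))
  out
}

shannon <- function(counts, base = 2) {
  w <- rowSums(counts)
  p <- counts / w
  h <- -rowSums(ifelse(p > 0, p * log(p), 0))
  h / log(base)
}

#' Change in base-composition entropy of a k-mer change
#'
#' Shannon entropy of the mutated k-mer's base-composition frequency vector
#' minus that of the reference k-mer, computed on the given strand (not
#' canonicalised). Depends only on the composition multisets, so permuting
#' positions leaves it unchanged; mutations that swap between two bases of
#' equal count (e.g. C>G with equal C and G counts) give exactly 0.
#'
#' @param kmer Character vector of reference k-mers.
#' @param alt Alternate central base(s).
#' @param base Logarithm base for the entropy (default 2, bits).
#' @return Numeric vector of entropy changes.
#' @export
#' @examples
#' entropy_change("AAAAACAAAAA", "A") # negative: composition gets purer
entropy_change <- function(kmer, alt, base = 2) {
  n <- max(length(kmer), length(alt))
  kmer <- rep_len(kmer, n)
  alt <- rep_len(alt, n)
  check_dna(kmer, "kmer")
  check_dna(alt, "alt")
  w <- nchar(kmer)
  c0 <- (w + 1L) %/% 2L
  center <- substr(kmer, c0, c0)
  if (any(center == alt)) rlang::abort("alt must differ from the central base")
  ref_counts <- base_counts(kmer)
  mut_counts <- ref_counts
  idx <- cbind(seq_len(n), match(center, DNA_BASES_))
  mut_counts[idx] <- mut_counts[idx] - 1
  idx2 <- cbind(seq_len(n), match(alt, DNA_BASES_))
  mut_counts[idx2] <- mut_counts[idx2] + 1
  shannon(mut_counts, base) - shannon(ref_counts, base)
}

# Enumerate flank base compositions with multiplicities: all ways to fill
# the 2*flank non-central-trinucleotide positions, collapsed by composition.
flank_compositions <- function(n_flank) {
  grid <- expand.grid(A = 0:n_flank, C = 0:n_flank, G = 0:n_flank)
  grid$T <- n_flank - grid$A - grid$C - grid$G
  grid <- grid[grid$T >= 0, , drop = FALSE]
  grid$mult <- exp(lgamma(n_flank + 1) - lgamma(grid$A + 1) - lgamma(grid$C + 1) -
                     lgamma(grid$G + 1) - lgamma(grid$T + 1))
  grid
}

class_entropy_summary <- function(width, sequence_filter, base = 2) {
  n_flank <- width - 3L
  comps <- flank_compositions(n_flank)
  classes <- mutation_classes()
  out <- tibble::tibble(class = classes, mean_dh = NA_real_, n_eligible = 0)
  for (i in seq_along(classes)) {
    tri <- substr(classes[i], 1, 3)
    alt <- substr(classes[i], 6, 6)
    tri_counts <- base_counts(tri)[1, ]
    ref <- cbind(comps$A + tri_counts["A"], comps$C + tri_counts["C"],
                 comps$G + tri_counts["G"], comps$T + tri_counts["T"])
    colnames(ref) <- DNA_BASES_
    at_frac <- (ref[, "A"] + ref[, "T"]) / width
    keep <- switch(sequence_filter,
      "all" = rep(TRUE, nrow(ref)),
      "AT-rich" = at_frac > 0.6,
      "GC-rich" = at_frac < 0.4
    )
    if (!any(keep)) next
    mut <- ref[keep, , drop = FALSE]
    center <- substr(tri, 2, 2)
    mut[, center] <- mut[, center] - 1
    mut[, alt] <- mut[, alt] + 1
    dh <- shannon(mut, base) - shannon(ref[keep, , drop = FALSE], base)
    mult <- comps$mult[keep]
    out$mean_dh[i] <- sum(mult * dh) / sum(mult)
    out$n_eligible[i] <- sum(mult)
  }
  out
}

#' Expected entropy change under a signature
#'
#' The signature-weighted mean entropy change over all canonical k-mer
#' changes, optionally restricted to AT-rich (reference AT fraction > 0.6)
#' or GC-rich (< 0.4) k-mers. Each class's mass is spread uniformly over
#' its eligible changes and masses are renormalised over the filtered set;
#' classes with no eligible change are skipped with a message. Computed
#' exactly by enumerating flank base compositions, so the full width-11
#' space is summed without materialising 6.3 million changes.
#'
#' @param signatures Signature catalog tibble or named 96-vector.
#' @param sequence_filter `"all"`, `"AT-rich"` or `"GC-rich"`.
#' @param width Odd k-mer width (default 11).
#' @param base Entropy logarithm base (default 2, bits).
#' @return Tibble `signature`, `sequence_filter`, `expected_dh`.
#' @export
expected_entropy_change <- function(signatures,
                                    sequence_filter = c("all", "AT-rich", "GC-rich"),
                                    width = 11L, base = 2) {
  sequence_filter <- rlang::arg_match(sequence_filter)
  signatures <- sig_input(signatures)
  summ <- class_entropy_summary(width, sequence_filter, base)
  purrr::map_dfr(unique(signatures$signature), function(nm) {
    sig <- sig_vector(signatures, nm)
    eligible <- !is.na(summ$mean_dh)
    skipped <- sum(sig[!eligible])
    if (skipped > 0) {
      rlang::inform(sprintf(
        "signature %s: %.3g mass on classes with no %s k-mers; skipped",
        nm, skipped, sequence_filter
      ))
    }
    mass <- sig[eligible]
    tibble::tibble(
      signature = nm, sequence_filter = sequence_filter,
      expected_dh = sum(mass * summ$mean_dh[eligible]) / sum(mass)
    )
  })
}

#' Entropy and score summaries over filtered change sets
#'
#' Median and median absolute deviation (MAD, `constant = 1` by default) of
#' the entropy change and of the binding-change score over the subset of a
#' table selected by a mutation filter (`"+AT"` = central C>A or C>T,
#' `"-AT"` = T>C or T>G) and a sequence filter on the reference k-mer's AT
#' fraction.
#'
#' @param table A `qbic_tbl`.
#' @param mutation_filter `"all"`, `"+AT"` or `"-AT"`.
#' @param sequence_filter `"all"`, `"AT-rich"` or `"GC-rich"`.
#' @param base Entropy logarithm base.
#' @param mad_constant Scale constant passed to [stats::mad()].
#' @return One-row tibble: `n`, `median_dh`, `mad_dh`, `median_score`,
#'   `mad_score`.
#' @export
tail_stats_by_filter <- function(table,
                                 mutation_filter = c("all", "+AT", "-AT"),
                                 sequence_filter = c("all", "AT-rich", "GC-rich"),
                                 base = 2, mad_constant = 1) {
  mutation_filter <- rlang::arg_match(mutation_filter)
  sequence_filter <- rlang::arg_match(sequence_filter)
  d <- tibble::as_tibble(table)
  type <- substitution_type(d$class)
  keep <- switch(mutation_filter,
    "all" = rep(TRUE, nrow(d)),
    "+AT" = type %in% PLUS_AT_TYPES,
    "-AT" = type %in% MINUS_AT_TYPES
  )
  counts <- base_counts(d$kmer)
  at_frac <- (counts[, "A"] + counts[, "T"]) / nchar(d$kmer)
  keep <- keep & switch(sequence_filter,
    "all" = TRUE, "AT-rich" = at_frac > 0.6, "GC-rich" = at_frac < 0.4
  )
  if (!any(keep)) rlang::abort("empty selection under the given filters")
  d <- d[keep, , drop = FALSE]
  dh <- entropy_change(d$kmer, d$alt, base = base)
  tibble::tibble(
    n = nrow(d),
    median_dh = stats::median(dh),
    mad_dh = stats::mad(dh, constant = mad_constant),
    median_score = stats::median(d$score),
    mad_score = stats::mad(d$score, constant = mad_constant)
  )
}
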