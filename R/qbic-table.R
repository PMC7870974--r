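# Per-experiment binding-change prediction tables: a score and a p-value for
# every single-nucleotide change at the centre of every k-mer (11-mers in
# the published assay tables). Tables are tibbles keyed by canonical
# (kmer, alt), one row per change, carrying experiment metadata as
# attributes; class slicing is a grouped filter.

#' Construct a binding-change score table
#'
#' Validates and canonicalises a per-change score/p-value table. Keys are
#' collapsed to pyrimidine-centred form via [canonical_change()]; the table
#' must cover every canonical change at its width exactly once (the
#' `96 * 4^(width-3)` change space, 6,291,456 rows at width 11). Exact
#' duplicate rows arising from files that carry both strand representations
#' are merged; duplicates with conflicting values are an error. P-values
#' must lie in (0, 1] and be a decreasing function of `|score|`; violations
#' beyond `mono_tol` trigger a warning and an empirical monotonization
#' (running minimum of p over increasing `|score|`).
#'
#' @param kmer,alt,score,pvalue Parallel vectors of changes and predictions.
#' @param experiment_id Experiment identifier (one PBM assay).
#' @param tf_name Assayed transcription factor.
#' @param mono_tol Tolerance on p-vs-|score| monotonicity violations.
#' @return A `qbic_tbl`: tibble with columns `kmer`, `alt`, `class`,
#'   `score`, `pvalue` and attributes `experiment_id`, `tf_name`, `width`.
#' @export
qbic_table <- function(kmer, alt, score, pvalue, experiment_id = "exp1",
                       tf_name = experiment_id, mono_tol = 1e-9) {
  ch <- canonical_change(kmer, alt)
  d <- tibble::tibble(kmer = ch$kmer, alt = ch$alt, class = ch$class,
                      score = as.numeric(score), pvalue = as.numeric(pvalue))
  key <- paste(d$kmer, d$alt)
  if (anyDuplicated(key)) {
    d <- d |>
      dplyr::group_by(.data$kmer, .data$alt, .data$class) |>
      dplyr::summarise(
        conflict = max(.data$score) - min(.data$score) > 1e-12 |
          max(.data$pvalue) - min(.data$pvalue) > 1e-12,
        score = .data$score[1], pvalue = .data$pvalue[1],
        .groups = "drop"
      )
    if (any(d$conflict)) {
      bad <- d[d$conflict, ][1, ]
      rlang::abort(sprintf(
        "conflicting duplicate entries for change %s>%s", bad$kmer, bad$alt
      ))
    }
    d$conflict <- NULL
  }
  width <- nchar(d$kmer[1])
  per_class <- 4^(width - 3)
  counts <- table(factor(d$class, levels = mutation_classes()))
  short <- names(counts)[counts < per_class]
  if (length(short) > 0) {
    rlang::abort(sprintf(
      "table is incomplete: class %s has %d of %d changes",
      short[1], counts[[short[1]]], per_class
    ))
  }
  if (any(d$pvalue <= 0 | d$pvalue > 1)) {
    rlang::abort("p-values must lie in (0, 1]")
  }
  ord <- order(abs(d$score))
  p_sorted <- d$pvalue[ord]
  # smallest nonincreasing-in-|score| majorant of the observed p-values
  mono <- rev(cummax(rev(p_sorted)))
  if (any(mono - p_sorted > mono_tol)) {
    rlang::warn(sprintf(
      "p-values are not a decreasing function of |score| (max violation %.3g); monotonizing",
      max(mono - p_sorted)
    ))
    d$pvalue[ord] <- mono
  }
  d <- d[order(factor(d$class, levels = mutation_classes()), d$kmer), ]
  structure(
    tibble::as_tibble(d),
    experiment_id = experiment_id, tf_name = tf_name, width = width,
    class = c("qbic_tbl", class(tibble::tibble()))
  )
}

#' @export
print.qbic_tbl <- function(x, ...) {
  cat(sprintf("<qbic_tbl> experiment %s (TF %s), width %d, %d changes\n",
              attr(x, "experiment_id"), attr(x, "tf_name"),
              attr(x, "width"), nrow(x)))
  NextMethod()
}

#' Read a binding-change table from aligned prediction and p-value files
#'
#' The default dialect is two TSVs with columns `(kmer, alt, score)` and
#' `(kmer, alt, pvalue)` (header names configurable via `columns` for other
#' download layouts). Rows are matched positionally after checking the keys
#' agree; keys are canonicalised on load.
#'
#' @param prediction_path,pvalue_path Paths to the two aligned tables.
#' @param experiment_id,tf_name Experiment metadata.
#' @param columns Named character vector mapping the roles `kmer`, `alt`,
#'   `score`, `pvalue` to the column names used in the files.
#' @return A `qbic_tbl`.
#' @export
read_qbic_table <- function(prediction_path, pvalue_path,
                            experiment_id = basename(prediction_path),
                            tf_name = experiment_id,
                            columns = c(kmer = "kmer", alt = "alt",
                                        score = "score", pvalue = "pvalue")) {
  # value columns come in as text and go through strtod (correctly rounded),
  # so written tables round-trip bit-exactly
  pred <- readr::read_tsv(prediction_path, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  pval <- readr::read_tsv(pvalue_path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  pred[[unname(columns["score"])]] <- as.numeric(pred[[unname(columns["score"])]])
  pval[[unname(columns["pvalue"])]] <- as.numeric(pval[[unname(columns["pvalue"])]])
  if (nrow(pred) != nrow(pval)) {
    rlang::abort(sprintf(
      "row count mismatch: %d predictions vs %d p-values", nrow(pred), nrow(pval)
    ))
  }
  k <- unname(columns["kmer"]); a <- unname(columns["alt"])
  if (!identical(paste(pred[[k]], pred[[a]]), paste(pval[[k]], pval[[a]]))) {
    rlang::abort("prediction and p-value files are not keyed identically")
  }
  qbic_table(pred[[k]], pred[[a]],
             pred[[unname(columns["score"])]], pval[[unname(columns["pvalue"])]],
             experiment_id = experiment_id, tf_name = tf_name)
}

#' Write a binding-change table as aligned prediction and p-value TSVs
#'
#' @param table A `qbic_tbl`.
#' @param prediction_path,pvalue_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_qbic_table <- function(table, prediction_path, pvalue_path) {
  # %.17g guarantees binary64 values survive the text round trip exactly
  readr::write_tsv(
    tibble::tibble(kmer = table$kmer, alt = table$alt,
                   score = sprintf("%.17g", table$score)),
    prediction_path, progress = FALSE
  )
  readr::write_tsv(
    tibble::tibble(kmer = table$kmer, alt = table$alt,
                   pvalue = sprintf("%.17g", table$pvalue)),
    pvalue_path, progress = FALSE
  )
  invisible(c(prediction_path, pvalue_path))
}

#' Look up changes in a table (strand-insensitively)
#'
#' Queries with purine-centred k-mers are canonicalised before lookup, so
#' both strand representations of a change return the stored value.
#'
#' @param table A `qbic_tbl`.
#' @param kmer,alt The queried change(s).
#' @return Tibble of the matching rows, in query order.
#' @export
lookup_change <- function(table, kmer, alt) {
  ch <- canonical_change(kmer, alt)
  dplyr::left_join(ch, table, by = c("kmer", "alt", "class"))
}

#' Per-class score distribution
#'
#' Slices one mutation class out of a table: the `4^(width-3)` changes whose
#' central trinucleotide change equals `class` (65,536 at width 11). The 96
#' slices partition the table.
#'
#' @param table A `qbic_tbl`.
#' @param class A canonical class label.
#' @return Tibble of the class's rows.
#' @export
class_distribution <- function(table, class) {
  if (!class %in% mutation_classes()) {
    rlang::abort(sprintf("unknown mutation class '%s'", class))
  }
  cl <- class
  dplyr::filter(tibble::as_tibble(table), .data$class == cl)
}
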