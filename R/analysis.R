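# One-call analysis over a set of experiments: ratios, resampling
# significance, TF-level aggregation, gain/loss classification and
# clustering, wrapped in a fitted-object class with broom-style accessors.

#' Run the full signature x TF binding-change analysis
#'
#' Computes, for every experiment and signature, the Gain and Loss Ratios
#' at the BH tail threshold, their resampling p-values, the per-TF medians,
#' the gain-/loss-of-binding classification, and the clustering of the
#' resulting TF x signature matrix.
#'
#' @param tables A `qbic_tbl` or list of them (one per experiment).
#' @param signatures Signature catalog tibble.
#' @param fdr BH FDR level defining the tails (default 0.1).
#' @param alpha Significance level for gain/loss calls (default 0.05).
#' @param n_mutations,n_reps Resampling-test parameters.
#' @param seed Integer seed for the resampling test.
#' @return A `grlr_fit` object: list with `results` (per experiment x
#'   signature), `by_tf` (per TF x signature, classified), `clustering`,
#'   and `params`.
#' @export
#' @examples
#' sigs <- dplyr::bind_rows(
#'   uniform_signature(),
#'   synth_signature(c("C>T" = 1), name = "ct")
#' )
#' tab <- synth_qbic_table(synth_motif("TAAT"), width = 5, seed = 1)
#' fit <- gain_loss_analysis(tab, sigs, n_reps = 99, seed = 1)
#' tidy(fit)
gain_loss_analysis <- function(tables, signatures, fdr = 0.1, alpha = 0.05,
                               n_mutations = 10000, n_reps = 1000, seed) {
  if (inherits(tables, "qbic_tbl")) tables <- list(tables)
  per_exp <- purrr::map2(tables, seq_along(tables), function(tab, i) {
    ratios <- gain_loss_ratios(tab, signatures, fdr = fdr)
    pvals <- resample_significance(tab, signatures, n_mutations = n_mutations,
                                   n_reps = n_reps,
                                   seed = as.integer(seed) + i - 1L, fdr = fdr)
    dplyr::left_join(ratios, dplyr::select(pvals, -"seed"),
                     by = c("experiment", "signature"))
  })
  results <- dplyr::bind_rows(per_exp)
  by_tf <- classify_gain_loss(aggregate_tf(results), alpha = alpha)
  clustering <- if (dplyr::n_distinct(by_tf$tf) >= 1 &&
                      !all(is.na(by_tf$gr))) cluster_gr_lr(by_tf) else NULL
  structure(
    list(
      results = classify_gain_loss(results, alpha = alpha),
      by_tf = by_tf,
      clustering = clustering,
      params = list(fdr = fdr, alpha = alpha, n_mutations = n_mutations,
                    n_reps = n_reps, seed = as.integer(seed))
    ),
    class = "grlr_fit"
  )
}

#' @export
print.grlr_fit <- function(x, ...) {
  cat(sprintf(
    "<grlr_fit> %d experiment(s), %d TF(s), %d signature(s); FDR %g, alpha %g\n",
    dplyr::n_distinct(x$results$experiment), dplyr::n_distinct(x$by_tf$tf),
    dplyr::n_distinct(x$results$signature), x$params$fdr, x$params$alpha
  ))
  cat(sprintf("gain-of-binding pairs: %d; loss-of-binding pairs: %d\n",
              sum(x$by_tf$gain), sum(x$by_tf$loss)))
  invisible(x)
}

#' Tidy a fitted gain/loss analysis
#'
#' @param x A `grlr_fit`.
#' @param level `"tf"` (default: per TF x signature medians) or
#'   `"experiment"`.
#' @param ... Unused.
#' @return A tibble, one row per (TF or experiment) x signature.
#' @export
tidy.grlr_fit <- function(x, level = c("tf", "experiment"), ...) {
  level <- rlang::arg_match(level)
  if (level == "tf") x$by_tf else x$results
}

#' One-row summary of a fitted gain/loss analysis
#'
#' @param x A `grlr_fit`.
#' @param ... Unused.
#' @return Tibble with counts of experiments, TFs, signatures, gain and
#'   loss pairs, and the analysis parameters.
#' @export
glance.grlr_fit <- function(x, ...) {
  tibble::tibble(
    n_experiments = dplyr::n_distinct(x$results$experiment),
    n_tfs = dplyr::n_distinct(x$by_tf$tf),
    n_signatures = dplyr::n_distinct(x$results$signature),
    n_gain_pairs = sum(x$by_tf$gain),
    n_loss_pairs = sum(x$by_tf$loss),
    median_gr = stats::median(x$by_tf$gr, na.rm = TRUE),
    median_lr = stats::median(x$by_tf$lr, na.rm = TRUE),
    fdr = x$params$fdr, alpha = x$params$alpha,
    n_resamples = x$params$n_reps, seed = x$params$seed
  )
}

#' Heatmap of Gain and Loss Ratios
#'
#' Plots the per-TF GR and LR matrices as tiles, signatures x TFs, with
#' axes in clustered order when clustering is available.
#'
#' @param object A `grlr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grlr_fit <- function(object, ...) {
  d <- object$by_tf |>
    tidyr::pivot_longer(c("gr", "lr"), names_to = "ratio", values_to = "value") |>
    dplyr::mutate(ratio = toupper(.data$ratio))
  if (!is.null(object$clustering)) {
    d$tf <- factor(d$tf, levels = object$clustering$tf_order)
    d$signature <- factor(d$signature, levels = object$clustering$signature_order)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tf, y = .data$signature,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~ratio) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "#2166ac",
                                  mid = "white", high = "#b2182b",
                                  name = "ratio") +
    ggplot2::labs(x = "TF", y = "signature") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
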