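# Gene-set enrichment of gain-/loss-of-binding TF sets: one-sided Fisher
# exact tests against a GMT collection with Benjamini-Hochberg q-values.

#' Read a GMT gene-set collection
#'
#' Standard GMT layout: set name, description, tab-separated gene symbols.
#' Symbols are upper-cased and deduplicated; empty sets are dropped.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(g) unique(toupper(g[nzchar(g)])))
  sets[lengths(sets) > 0]
}

#' Gene-set enrichment of a TF set
#'
#' For each gene set, a one-sided Fisher exact test on the 2x2 table
#' (query and set, query not set, set not query, rest of background), with
#' BH q-values across all sets. The background defaults to the union of
#' the collection's sets; when the query is a subset of an assayed-TF
#' universe, pass that universe explicitly.
#'
#' @param query Character vector of gene symbols (case-folded on use).
#' @param collection Named list from [read_gmt()].
#' @param background Optional character vector of background symbols.
#' @param q_threshold Significance threshold on the BH q-value
#'   (default 0.005).
#' @return Tibble, one row per set: `set_name`, `n_set`, `overlap`, `p`,
#'   `q`, `significant`, `overlapping_genes` (comma-separated), sorted by
#'   `p`.
#' @export
enrich <- function(query, collection, background = NULL, q_threshold = 0.005) {
  query <- unique(toupper(query))
  if (length(query) == 0) rlang::abort("empty query")
  if (is.null(background)) {
    background <- unique(unlist(collection, use.names = FALSE))
  }
  background <- unique(toupper(background))
  missing <- setdiff(query, background)
  if (length(missing) == length(query)) {
    rlang::abort(sprintf(
      "query is disjoint from the background; missing symbols: %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  if (length(missing) > 0) {
    rlang::warn(sprintf(
      "%d query symbol(s) absent from the background dropped: %s",
      length(missing), paste(utils::head(missing, 5), collapse = ", ")
    ))
    query <- setdiff(query, missing)
  }
  rows <- purrr::imap(collection, function(genes, nm) {
    genes <- intersect(unique(toupper(genes)), background)
    a <- length(intersect(query, genes))
    b <- length(query) - a
    cc <- length(genes) - a
    d <- length(background) - a - b - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2),
                            alternative = "greater")$p.value
    tibble::tibble(
      set_name = nm, n_set = length(genes), overlap = a, p = p,
      overlapping_genes = paste(sort(intersect(query, genes)), collapse = ",")
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_threshold
  dplyr::arrange(
    dplyr::select(out, "set_name", "n_set", "overlap", "p", "q",
                  "significant", "overlapping_genes"),
    .data$p
  )
}
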