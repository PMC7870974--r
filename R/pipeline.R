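# End-to-end orchestration: ratios -> significance -> classification ->
# clustering -> enrichment, with all artefacts written as plain-text files
# and a JSON provenance manifest.

#' Run the full workflow and write its outputs
#'
#' Runs [gain_loss_analysis()] over a set of score tables, writes the
#' long-format result TSV, the wide GR and LR matrices, cluster orderings
#' with Newick dendrograms, the gain/loss classification, optional gene-set
#' enrichment of the gain- and loss-of-binding TF sets per signature, and a
#' JSON manifest recording parameters, seed, package version and output
#' checksums.
#'
#' @param tables A `qbic_tbl` or list of them.
#' @param signatures Signature catalog tibble.
#' @param out_dir Output directory (created).
#' @param gmt Optional named list from [read_gmt()]; enables enrichment.
#' @param background Optional enrichment background (defaults to the set of
#'   assayed TFs).
#' @param fdr,alpha,n_mutations,n_reps,seed Analysis parameters (see
#'   [gain_loss_analysis()]).
#' @param q_threshold Enrichment significance threshold.
#' @return The `grlr_fit`, invisibly, with `out_dir` and `manifest`
#'   attached.
#' @export
run_analysis <- function(tables, signatures, out_dir, gmt = NULL,
                         background = NULL, fdr = 0.1, alpha = 0.05,
                         n_mutations = 10000, n_reps = 1000, seed,
                         q_threshold = 0.005) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- gain_loss_analysis(tables, signatures, fdr = fdr, alpha = alpha,
                            n_mutations = n_mutations, n_reps = n_reps,
                            seed = seed)
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p, progress = FALSE)
    paths[[name]] <<- p
    p
  }
  wr(fit$results, "results_long.tsv")
  wr(fit$by_tf, "results_by_tf.tsv")
  wr(grlr_matrix(fit$by_tf, "gr"), "gr_matrix.tsv")
  wr(grlr_matrix(fit$by_tf, "lr"), "lr_matrix.tsv")
  if (!is.null(fit$clustering)) {
    wr(tibble::tibble(signature = fit$clustering$signature_order),
       "signature_order.tsv")
    wr(tibble::tibble(tf = fit$clustering$tf_order), "tf_order.tsv")
    for (axis in c("signature", "tf")) {
      nwk <- fit$clustering[[paste0(axis, "_newick")]]
      if (!is.null(nwk) && !is.na(nwk)) {
        p <- file.path(out_dir, paste0(axis, "_dendrogram.nwk"))
        writeLines(nwk, p)
        paths[[basename(p)]] <- p
      }
    }
  }
  if (!is.null(gmt)) {
    if (is.null(background)) background <- unique(fit$by_tf$tf)
    for (side in c("gain", "loss")) {
      called <- dplyr::filter(fit$by_tf, .data[[side]])
      empty <- tibble::tibble(
        signature = character(), set_name = character(), n_set = integer(),
        overlap = integer(), p = double(), q = double(),
        significant = logical(), overlapping_genes = character()
      )
      enr <- purrr::map_dfr(unique(called$signature), function(sg) {
        tfs <- called$tf[called$signature == sg]
        dplyr::bind_cols(
          tibble::tibble(signature = sg),
          enrich(tfs, gmt, background = background, q_threshold = q_threshold)
        )
      })
      if (nrow(enr) == 0) enr <- empty
      wr(enr, sprintf("enrichment_%s.tsv", side))
    }
  }
  manifest <- list(
    package = "sigbind",
    version = as.character(utils::packageVersion("sigbind")),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = list(fdr = fdr, alpha = alpha, n_mutations = n_mutations,
                  n_reps = n_reps, seed = as.integer(seed),
                  q_threshold = q_threshold),
    inputs = list(
      n_experiments = dplyr::n_distinct(fit$results$experiment),
      n_signatures = dplyr::n_distinct(fit$results$signature),
      gene_sets = if (is.null(gmt)) 0L else length(gmt)
    ),
    outputs = as.list(tools::md5sum(unlist(paths)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  attr(fit, "out_dir") <- out_dir
  attr(fit, "manifest") <- manifest
  invisible(fit)
}

#' Self-contained demonstration run on synthetic data
#'
#' Generates toy score tables (AT-rich and GC-rich motifs), a small
#' signature panel (C>T-dominated, T>C-dominated, flat, uniform), a
#' synthetic gene-set collection, and runs [run_analysis()] end to end.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_reps Resampling replicates (default 200, demo scale).
#' @return The `grlr_fit`, invisibly.
#' @export
run_demo <- function(out_dir, seed, n_reps = 200) {
  seed <- as.integer(seed)
  motifs <- list(
    HOMEO1 = synth_motif("TAAT"), HOMEO2 = synth_motif("TTAAT"),
    GCBOX1 = synth_motif("GCCGC"), GCBOX2 = synth_motif("GGCGG")
  )
  tables <- purrr::imap(motifs, function(m, nm) {
    synth_qbic_table(m, name = paste0(nm, "_pbm1"), tf = nm,
                     seed = seed + match(nm, names(motifs)))
  })
  sigs <- dplyr::bind_rows(
    synth_signature(c("C>T" = 0.95, "C>A" = 0.05), name = "CT_dominated"),
    synth_signature(c("T>C" = 0.9, "T>G" = 0.1), name = "TC_dominated"),
    synth_signature(stats::setNames(rep(1 / 6, 6), SUBSTITUTION_TYPES),
                    name = "flat"),
    uniform_signature()
  )
  gmt <- list(
    HOMEOBOX_SET = c("HOMEO1", "HOMEO2"),
    GC_SET = c("GCBOX1", "GCBOX2"),
    MIXED_SET = c("HOMEO1", "GCBOX1")
  )
  run_analysis(tables, sigs, out_dir, gmt = gmt, n_mutations = 10000,
               n_reps = n_reps, seed = seed)
}

#' Consistency checks against published reference values
#'
#' When pointed at locally downloaded reference inputs (a COSMIC v3 SBS
#' catalog and score/p-value tables for the FOXL1 experiments), verifies
#' the published anchor values: the TCA>TTA probability of SBS7a (0.238),
#' the C>T mass of SBS2 (99.24%), and the FOXL1 x SBS1 per-TF median
#' ratios (GR 1.22, LR 0.18). These inputs are not redistributable with
#' the package and must be supplied by the caller.
#'
#' @param catalog_path Path to the COSMIC v3 SBS catalog (TSV/CSV).
#' @param foxl1_tables Optional list of `qbic_tbl` for the FOXL1
#'   experiments.
#' @param fdr BH FDR level.
#' @return Tibble with columns `check`, `value`, `expected`.
#' @export
external_data_checks <- function(catalog_path, foxl1_tables = NULL,
                                 fdr = 0.1) {
  catalog <- read_signature_catalog(catalog_path)
  sbs7a <- sig_vector(catalog, "SBS7a")
  ct_mass <- catalog |>
    dplyr::filter(.data$signature == "SBS2",
                  substitution_type(.data$class) == "C>T") |>
    dplyr::summarise(m = sum(.data$prob)) |>
    dplyr::pull("m")
  out <- tibble::tibble(
    check = c("SBS7a TCA>TTA probability", "SBS2 C>T percent"),
    value = c(unname(sbs7a["TCA>TTA"]), 100 * ct_mass),
    expected = c(0.238, 99.24)
  )
  if (!is.null(foxl1_tables)) {
    res <- dplyr::bind_rows(lapply(foxl1_tables, gain_loss_ratios,
                                   signatures = catalog, fdr = fdr))
    med <- aggregate_tf(dplyr::filter(res, .data$signature == "SBS1"))
    out <- dplyr::bind_rows(out, tibble::tibble(
      check = c("FOXL1 x SBS1 GR", "FOXL1 x SBS1 LR"),
      value = c(med$gr[1], med$lr[1]),
      expected = c(1.22, 0.18)
    ))
  }
  out
}
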