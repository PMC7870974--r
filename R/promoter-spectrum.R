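# Promoter-restricted 96-class mutation spectra: TSS +/- 2000 bp regions
# from a GTF, class assignment of VCF-like SNV calls against a genome, and
# comparison of spectrum-derived with signature-derived ratios.

norm_chrom <- function(x) sub("^chr", "", as.character(x))

load_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet")) {
    rlang::abort("genome must be a FASTA path or a DNAStringSet")
  }
  # FASTA headers may carry descriptions after the sequence name
  names(genome) <- norm_chrom(sub("\\s.*$", "", names(genome)))
  genome
}

#' Proximal-promoter regions around transcription start sites
#'
#' One region per gene: 2000 bp 5' to 2000 bp 3' of the TSS (4001 reference
#' bases). The TSS of a plus-strand gene is its annotated start coordinate;
#' of a minus-strand gene, its annotated end. Regions are implemented
#' strand-agnostically as TSS +/- `flank` on the reference, since mutation
#' classes are strand-collapsed anyway. Overlapping regions are retained.
#'
#' @param gtf Path to a GTF file (gene features used when present,
#'   transcripts otherwise).
#' @param flank Bases on each side of the TSS (default 2000).
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `gene_id`, `tss` (1-based).
#' @export
tss_regions <- function(gtf, flank = 2000L) {
  gr <- rtracklayer::import(gtf)
  types <- as.character(gr$type)
  keep <- if (any(types == "gene")) types == "gene" else types == "transcript"
  gr <- gr[keep]
  if (length(gr) == 0) rlang::abort("no gene or transcript features in GTF")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) rlang::abort("GTF features must be stranded")
  tss <- ifelse(strand == "+", GenomicRanges::start(gr), GenomicRanges::end(gr))
  ids <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else
    paste0("gene", seq_along(gr))
  tibble::tibble(
    chrom = norm_chrom(GenomicRanges::seqnames(gr)),
    start = pmax(tss - flank - 1L, 0L),
    end = tss + flank,
    strand = strand,
    gene_id = ids,
    tss = as.integer(tss)
  )
}

#' Write regions as BED
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `gene_id`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  bed <- tibble::tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = if ("gene_id" %in% names(regions)) regions$gene_id else ".",
    score = 0L,
    strand = if ("strand" %in% names(regions)) regions$strand else "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a VCF-like simple mutation table
#'
#' Tab-separated with header columns `sample`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, as in PCAWG "vcf-like simple" files.
#'
#' @param path Path to the TSV.
#' @return Tibble of mutation records.
#' @export
read_mutations <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(d)[1:5] <- c("sample", "chrom", "pos", "ref", "alt")
  dplyr::mutate(d, chrom = norm_chrom(.data$chrom), pos = as.integer(.data$pos))
}

#' Samples dominated by one signature
#'
#' Samples in which at least `min_fraction` of mutations (genome-wide, per
#' the exposure table) are attributed to the named signature. The bound is
#' inclusive.
#'
#' @param exposures Exposure tibble from [read_exposures()] (`sample`,
#'   `signature`, `fraction`).
#' @param signature Signature name.
#' @param min_fraction Minimum exposure fraction (default 0.4).
#' @return Character vector of sample ids.
#' @export
select_dominant_tumors <- function(exposures, signature, min_fraction = 0.4) {
  if (!signature %in% exposures$signature) {
    rlang::abort(sprintf("unknown signature '%s' in exposure table", signature))
  }
  d <- dplyr::filter(exposures, .data$signature == !!signature,
                     .data$fraction >= min_fraction)
  unique(d$sample)
}

#' Build a 96-class mutation spectrum restricted to regions
#'
#' Assigns every single-nucleotide substitution falling inside a region its
#' canonical mutation class from the +/- 1 bp reference context, and counts
#' per sample. Mutations whose stated reference allele mismatches the
#' genome, or that fall outside every region, are dropped (with a message
#' for mismatches). A mutation inside several overlapping regions is
#' counted once. With `type_filter`, only substitutions of the given
#' pyrimidine types are counted (the major-class filter).
#'
#' @param mutations Tibble from [read_mutations()].
#' @param regions Tibble from [tss_regions()]; `NULL` to use all mutations.
#' @param genome FASTA path or `DNAStringSet`.
#' @param type_filter Optional character vector of substitution types
#'   (e.g. `"C>T"`).
#' @param samples Optional sample subset.
#' @return Tibble `sample`, `class`, `count`, complete over the 96 classes
#'   for every retained sample.
#' @export
build_spectrum <- function(mutations, regions, genome, type_filter = NULL,
                           samples = NULL) {
  genome <- load_genome(genome)
  d <- dplyr::mutate(mutations, chrom = norm_chrom(.data$chrom))
  if (!is.null(samples)) d <- dplyr::filter(d, .data$sample %in% samples)
  snv <- nchar(d$ref) == 1 & nchar(d$alt) == 1 &
    !grepl("[^ACGT]", d$ref) & !grepl("[^ACGT]", d$alt) & d$ref != d$alt
  d <- d[snv, , drop = FALSE]
  known <- d$chrom %in% names(genome)
  if (!all(known)) {
    missing <- unique(d$chrom[!known])[1]
    rlang::abort(sprintf(
      "chromosome '%s' (also tried 'chr%s') not found in the genome",
      missing, missing
    ))
  }
  lens <- Biostrings::width(genome)[match(d$chrom, names(genome))]
  inside <- d$pos >= 2L & d$pos <= lens - 1L
  d <- d[inside, , drop = FALSE]
  if (!is.null(regions)) {
    reg <- GenomicRanges::GRanges(
      norm_chrom(regions$chrom),
      IRanges::IRanges(start = regions$start + 1L, end = regions$end)
    )
    qry <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, d$pos))
    hit <- IRanges::overlapsAny(qry, reg)
    d <- d[hit, , drop = FALSE]
  }
  if (nrow(d) > 0) {
    ctx <- as.character(Biostrings::subseq(
      genome[d$chrom], start = d$pos - 1L, end = d$pos + 1L
    ))
    match_ref <- substr(ctx, 2, 2) == d$ref
    if (any(!match_ref)) {
      rlang::inform(sprintf(
        "dropping %d mutation(s) whose ref allele mismatches the genome",
        sum(!match_ref)
      ))
    }
    d <- d[match_ref, , drop = FALSE]
    ctx <- ctx[match_ref]
    d$class <- if (nrow(d) > 0) canonical_class(ctx, d$alt) else character(0)
  } else {
    d$class <- character(0)
  }
  if (!is.null(type_filter)) {
    d <- dplyr::filter(d, substitution_type(.data$class) %in% type_filter)
  }
  d |>
    dplyr::count(.data$sample, .data$class, name = "count") |>
    tidyr::complete(
      sample = unique(d$sample),
      class = mutation_classes(),
      fill = list(count = 0L)
    ) |>
    dplyr::arrange(.data$sample,
                   factor(.data$class, levels = mutation_classes()))
}

#' Aggregate spectrum over samples
#'
#' @param spectrum Tibble from [build_spectrum()].
#' @return Tibble `class`, `count` over the 96 classes.
#' @export
aggregate_spectrum <- function(spectrum) {
  spectrum |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(factor(.data$class, levels = mutation_classes()))
}

#' Normalise an aggregate spectrum into a signature
#'
#' @param spectrum Tibble from [build_spectrum()] or [aggregate_spectrum()].
#' @param name Name for the resulting signature.
#' @return One-signature catalog tibble.
#' @export
spectrum_to_signature <- function(spectrum, name = "spectrum") {
  agg <- if ("sample" %in% names(spectrum)) aggregate_spectrum(spectrum) else spectrum
  if (sum(agg$count) == 0) rlang::abort("empty spectrum")
  new_sig_catalog(tibble::tibble(
    signature = name, class = agg$class, prob = agg$count / sum(agg$count)
  ))
}

#' Agreement between spectrum-based and signature-based ratios
#'
#' Pairs per-experiment GRs and LRs computed from an observed-spectrum
#' signature with those computed from the signature profile alone, pools GR
#' and LR per signature, and reports the coefficient of determination
#' (squared Pearson correlation) per signature and its mean.
#'
#' @param spectrum_based,signature_based Result tibbles with columns
#'   `experiment`, `signature`, `gr`, `lr`, paired on `experiment` (the
#'   `signature` column of `spectrum_based` names the generating signature).
#' @return List with `per_signature` (tibble `signature`, `n_pairs`,
#'   `r_squared`) and `mean_r_squared`.
#' @export
compare_gr_lr <- function(spectrum_based, signature_based) {
  paired <- dplyr::inner_join(
    dplyr::select(spectrum_based, "experiment", "signature",
                  spec_gr = "gr", spec_lr = "lr"),
    dplyr::select(signature_based, "experiment", "signature",
                  sig_gr = "gr", sig_lr = "lr"),
    by = c("experiment", "signature")
  )
  if (nrow(paired) == 0) rlang::abort("no paired (experiment, signature) rows")
  per_sig <- paired |>
    tidyr::pivot_longer(-c("experiment", "signature"),
                        names_to = c("basis", "ratio"), names_sep = "_") |>
    tidyr::pivot_wider(names_from = "basis", values_from = "value") |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(
      n_pairs = sum(stats::complete.cases(.data$spec, .data$sig)),
      r_squared = {
        ok <- stats::complete.cases(.data$spec, .data$sig)
        if (sum(ok) < 3) rlang::abort("fewer than 3 paired values for a signature")
        stats::cor(.data$spec[ok], .data$sig[ok])^2
      },
      .groups = "drop"
    )
  list(per_signature = per_sig, mean_r_squared = mean(per_sig$r_squared))
}
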