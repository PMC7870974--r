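# Seeded generators for every input the analyses consume: energy-model
# binding-change tables with valid score/p-value structure, signatures with
# chosen substitution-type masses, and toy genomes with annotated TSSs and
# signature-driven mutation cohorts. Defaults are sized so the whole
# pipeline runs end-to-end in seconds (7-mer change space, 24,576 changes);
# the assay-scale width of 11 is available through the same arguments.

#' Log-odds motif matrix from a consensus sequence
#'
#' Consensus bases get weight `match`, others `mismatch`; with `jitter > 0`
#' every cell is perturbed by a seeded uniform draw so that binding-energy
#' differences take a continuum of values rather than a few lattice steps
#' (real regression-derived score tables are likewise graded).
#'
#' @param consensus A/C/G/T string, width <= 11.
#' @param match,mismatch Log-odds values for matching and non-matching
#'   bases.
#' @param jitter Half-width of the uniform perturbation added to each cell.
#' @param seed Seed for the jitter.
#' @return 4 x width numeric matrix, rows A, C, G, T.
#' @export
synth_motif <- function(consensus, match = 2, mismatch = -6, jitter = 1.5,
                        seed = 1L) {
  check_dna(consensus, "consensus")
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix(mismatch, nrow = 4, ncol = length(bases),
              dimnames = list(DNA_BASES_, NULL))
  m[cbind(match(bases, DNA_BASES_), seq_along(bases))] <- match
  if (jitter > 0) {
    set.seed(as.integer(seed))
    m <- m + matrix(stats::runif(length(m), -jitter, jitter), nrow = 4)
  }
  m
}

kmer_base_matrix <- function(kmers) {
  w <- nchar(kmers[1])
  matrix(match(unlist(strsplit(kmers, "")), DNA_BASES_),
         ncol = w, byrow = TRUE)
}

#' Motif binding energy of k-mers
#'
#' Best log-odds sum of the motif over all offsets and both strands.
#'
#' @param kmers Character vector of equal-width k-mers.
#' @param motif 4 x m log-odds matrix (rows A, C, G, T).
#' @return Numeric vector of binding scores.
#' @export
motif_binding <- function(kmers, motif) {
  w <- nchar(kmers[1])
  m <- ncol(motif)
  if (m > w) rlang::abort("motif is wider than the k-mers")
  idx <- kmer_base_matrix(kmers)
  rc <- motif[4:1, m:1, drop = FALSE]  # reverse-complement strand
  best <- rep(-Inf, length(kmers))
  for (mat in list(motif, rc)) {
    for (off in 0:(w - m)) {
      s <- rep(0, length(kmers))
      for (j in seq_len(m)) {
        s <- s + mat[cbind(idx[, off + j], j)]
      }
      best <- pmax(best, s)
    }
  }
  best
}

#' Synthesise a binding-change score table from an energy model
#'
#' Enumerates all canonical k-mer changes at the given width and scores
#' each as the motif binding energy of the mutated k-mer minus that of the
#' reference, plus seeded Gaussian noise. Binding energies are floored at
#' `baseline` (nonspecific binding), so only changes that create or
#' destroy near-consensus sites move the score appreciably. P-values are
#' the two-sided standard-normal tail of `score / p_scale`, hence strictly
#' decreasing in `|score|` as the table contract requires. With the
#' defaults a few percent of changes pass BH FDR < 0.1, keeping both tails
#' non-degenerate.
#'
#' @param motif 4 x m log-odds matrix from [synth_motif()].
#' @param name Experiment id; `tf` defaults to it.
#' @param tf TF name.
#' @param width Odd k-mer width (default 7: 24,576 changes; use 11 for the
#'   assay-scale space of 6,291,456).
#' @param noise_sd Gaussian noise SD added to the energy difference.
#' @param p_scale Scale of the normal tail used for p-values (noise-only
#'   changes get roughly uniform p-values when `p_scale >= noise_sd`).
#' @param baseline Nonspecific-binding floor on the energy.
#' @param seed Integer seed; the table is bit-identical given the seed.
#' @return A `qbic_tbl`.
#' @export
synth_qbic_table <- function(motif, name = "toyTF", tf = name, width = 7L,
                             noise_sd = 1, p_scale = 2, baseline = 0,
                             seed = 1L) {
  changes <- enumerate_all_changes(width)
  c0 <- (width + 1L) %/% 2L
  mut <- paste0(substr(changes$kmer, 1, c0 - 1L), changes$alt,
                substr(changes$kmer, c0 + 1L, width))
  ref_binding <- pmax(motif_binding(changes$kmer, motif), baseline)
  mut_binding <- pmax(motif_binding(mut, motif), baseline)
  set.seed(as.integer(seed))
  noise <- if (noise_sd > 0) stats::rnorm(nrow(changes), 0, noise_sd) else 0
  score <- mut_binding - ref_binding + noise
  pvalue <- pmax(2 * stats::pnorm(-abs(score) / p_scale), .Machine$double.xmin)
  qbic_table(changes$kmer, changes$alt, score, pvalue,
             experiment_id = name, tf_name = tf)
}

#' Synthesise a signature from substitution-type masses
#'
#' @param type_masses Named numeric vector over the six pyrimidine types
#'   (missing types get mass 0), e.g. `c("C>T" = 0.99, "C>A" = 0.01)`.
#' @param within `"uniform"` spreads each type's mass equally over its 16
#'   classes; `"random"` draws seeded random within-type proportions.
#' @param seed Seed for `within = "random"`.
#' @param name Signature name.
#' @return One-signature catalog tibble.
#' @export
synth_signature <- function(type_masses, within = c("uniform", "random"),
                            seed = 1L, name = "synthetic") {
  within <- rlang::arg_match(within)
  if (any(type_masses < 0)) rlang::abort("type masses must be >= 0")
  if (sum(type_masses) <= 0) rlang::abort("all type masses are zero")
  bad <- setdiff(names(type_masses), SUBSTITUTION_TYPES)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown substitution type '%s'", bad[1]))
  }
  masses <- stats::setNames(rep(0, 6), SUBSTITUTION_TYPES)
  masses[names(type_masses)] <- type_masses
  masses <- masses / sum(masses)
  classes <- mutation_classes()
  types <- substitution_type(classes)
  if (within == "uniform") {
    prob <- masses[types] / 16
  } else {
    set.seed(as.integer(seed))
    prob <- numeric(96)
    for (ty in SUBSTITUTION_TYPES) {
      u <- stats::runif(16)
      prob[types == ty] <- masses[ty] * u / sum(u)
    }
  }
  new_sig_catalog(tibble::tibble(signature = name, class = classes,
                                 prob = unname(prob)))
}

#' Synthesise a genome, annotation and signature-driven mutation cohort
#'
#' Generates a random uniform-composition genome with `n_genes` genes whose
#' TSS +/- `flank` promoters tile the sequence end to end (by default:
#' genome length `n_genes * (2*flank + 1) + 1`), then draws mutations by
#' sampling a mutation class from the signature and a uniformly random
#' genomic position whose strand-collapsed trinucleotide context matches
#' the class. Reference alleles therefore always match the genome, and the
#' promoter-restricted spectrum of the cohort is multinomial in the
#' generating signature. Exposures record the generating fraction (1) for
#' every sample.
#'
#' @param signatures One-signature catalog tibble (the generating process).
#' @param n_genes Number of genes/TSSs (default 5).
#' @param n_samples Number of tumour samples (default 10).
#' @param mutations_per_sample SNVs per sample (default 200).
#' @param flank Promoter half-width (default 2000).
#' @param genome_size Genome length; default tiles promoters exactly.
#' @param seed Integer seed.
#' @return List with `genome` (`DNAStringSet`), `genes` (tibble), `gtf`
#'   (character lines), `mutations`, `exposures`, `signature_name`.
#' @export
synth_cohort <- function(signatures, n_genes = 5L, n_samples = 10L,
                         mutations_per_sample = 200L, flank = 2000L,
                         genome_size = NULL, seed = 1L) {
  sig <- sig_vector(signatures)
  sig_name <- unique(signatures$signature)
  span <- 2L * flank + 1L
  if (is.null(genome_size)) genome_size <- n_genes * span + 1L
  if (genome_size < n_genes * span) {
    rlang::abort("genome_size too small to host the promoters")
  }
  set.seed(as.integer(seed))
  genome_chars <- sample(DNA_BASES_, genome_size, replace = TRUE)
  genome_str <- paste(genome_chars, collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_str, "chr1"))

  tss <- as.integer(flank + 1L + (seq_len(n_genes) - 1L) * span)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gene_len <- 1000L
  genes <- tibble::tibble(
    gene_id = paste0("g", seq_len(n_genes)),
    chrom = "chr1", strand = strand, tss = tss,
    start = ifelse(strand == "+", tss, pmax(tss - gene_len, 1L)),
    end = ifelse(strand == "+", pmin(tss + gene_len, genome_size), tss)
  )
  gtf <- sprintf(
    'chr1\tsigbind\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    genes$start, genes$end, genes$strand, genes$gene_id
  )

  # strand-collapsed trinucleotide context of every internal position
  pos <- 2:(genome_size - 1L)
  tri <- substring(genome_str, pos - 1L, pos + 1L)
  center <- substr(tri, 2, 2)
  purine <- center %in% c("A", "G")
  canon_tri <- tri
  canon_tri[purine] <- revcomp(tri[purine])
  pos_by_tri <- split(pos, canon_tri)

  classes <- mutation_classes()
  needed <- unique(substr(classes[sig > 0], 1, 3))
  unrealizable <- setdiff(needed, names(pos_by_tri))
  if (length(unrealizable) > 0) {
    rlang::abort(sprintf(
      "context %s has no genomic occurrence; genome too small", unrealizable[1]
    ))
  }
  n_mut <- n_samples * mutations_per_sample
  mut_class <- sample(classes, n_mut, replace = TRUE, prob = sig)
  mut_tri <- substr(mut_class, 1, 3)
  mut_pos <- vapply(mut_tri, function(tr) {
    cand <- pos_by_tri[[tr]]
    cand[sample.int(length(cand), 1L)]
  }, integer(1))
  ref <- genome_chars[mut_pos]
  alt_canon <- substr(mut_class, 6, 6)
  alt <- ifelse(ref %in% c("C", "T"), alt_canon, comp_base(alt_canon))
  mutations <- tibble::tibble(
    sample = rep(paste0("s", seq_len(n_samples)), each = mutations_per_sample),
    chrom = "chr1", pos = unname(mut_pos), ref = ref, alt = alt,
    class = mut_class
  )
  exposures <- tibble::tibble(
    sample = paste0("s", seq_len(n_samples)),
    signature = sig_name, fraction = 1
  )
  list(genome = genome, genes = genes, gtf = gtf, mutations = mutations,
       exposures = exposures, signature_name = sig_name)
}

#' Write a synthetic cohort to disk
#'
#' Writes the FASTA, GTF, mutation TSV (`sample`, `chrom`, `pos`, `ref`,
#' `alt`) and exposure TSV dialects the readers consume.
#'
#' @param cohort List from [synth_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "genes.gtf"),
    mutations = file.path(dir, "mutations.tsv"),
    exposures = file.path(dir, "exposures.tsv")
  )
  Biostrings::writeXStringSet(cohort$genome, paths["genome"])
  writeLines(cohort$gtf, paths["gtf"])
  readr::write_tsv(
    dplyr::select(cohort$mutations, "sample", "chrom", "pos", "ref", "alt"),
    paths["mutations"], progress = FALSE
  )
  readr::write_tsv(cohort$exposures, paths["exposures"], progress = FALSE)
  invisible(paths)
}
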