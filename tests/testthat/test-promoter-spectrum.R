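write_toy_gtf <- function(path) {
  writeLines(c(
    'chr1\ttest\tgene\t10000\t12000\t.\t+\t.\tgene_id "gplus";',
    'chr1\ttest\tgene\t8000\t10000\t.\t-\t.\tgene_id "gminus";',
    'chr2\ttest\tgene\t3000\t5000\t.\t+\t.\tgene_id "gother";'
  ), path)
}

test_that("promoter regions span TSS +/- 2000 with strand-aware TSS choice", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_toy_gtf(gtf)
  reg <- tss_regions(gtf)
  expect_equal(nrow(reg), 3L)
  plus <- reg[reg$gene_id == "gplus", ]
  minus <- reg[reg$gene_id == "gminus", ]
  # + strand gene starting at 10,000 and - strand gene ending at 10,000
  # cover the same 1-based 8,000..12,000 window (4,001 bases)
  expect_equal(plus$tss, 10000L)
  expect_equal(minus$tss, 10000L)
  expect_equal(plus$start, 7999)   # 0-based half-open
  expect_equal(plus$end, 12000)
  expect_equal(minus$start, plus$start)
  expect_true(all(reg$end - reg$start == 4001))

  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(reg, bed)
  expect_equal(length(readLines(bed)), 3L)
})

test_that("mutations are classified from genomic context, reverse-complemented when needed", {
  #                 123456789012345
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAACATTTCGTAAAA"))
  regions <- tibble::tibble(chrom = "chr1", start = 0, end = 15,
                            strand = "+", gene_id = "g")
  muts <- tibble::tibble(
    sample = "s1",
    chrom = "chr1",
    pos = c(4L, 10L, 7L),
    ref = c("C", "G", "T"),
    alt = c("A", "A", "G")
  )
  # pos 4: context ACA, C>A -> ACA>AAA
  # pos 10: context CGT, G>A -> purine centre, revcomp -> ACG>ATG
  # pos 7: context TTT, T>G -> TTT>TGT
  spec <- build_spectrum(muts, regions, genome)
  counts <- setNames(spec$count, spec$class)
  expect_equal(unname(counts["ACA>AAA"]), 1L)
  expect_equal(unname(counts["ACG>ATG"]), 1L)
  expect_equal(unname(counts["TTT>TGT"]), 1L)
  expect_equal(sum(spec$count), 3L)

  # type filter keeps only the requested substitution types
  filt <- build_spectrum(muts, regions, genome, type_filter = "C>A")
  expect_equal(sum(filt$count), 1L)

  # ref mismatching the genome is dropped with a message
  bad <- dplyr::mutate(muts, ref = c("T", "G", "T"))
  expect_message(spec2 <- build_spectrum(bad, regions, genome), "mismatches")
  expect_equal(sum(spec2$count), 2L)

  # unknown chromosome is a naming error mentioning both styles
  expect_error(
    build_spectrum(dplyr::mutate(muts, chrom = "chr9"), regions, genome),
    "chr9"
  )
})

test_that("region boundaries are inclusive and outside mutations are excluded", {
  set.seed(1)
  seq <- paste(sample(c("A", "C", "G", "T"), 9000, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\ttest\tgene\t4000\t5000\t.\t+\t.\tgene_id "g";', gtf)
  reg <- tss_regions(gtf)  # TSS 4000: 1-based 2000..6000
  at <- function(p) tibble::tibble(sample = "s", chrom = "chr1", pos = p,
                                   ref = substr(seq, p, p),
                                   alt = chartr("ACGT", "CATG",
                                                substr(seq, p, p)))
  expect_equal(sum(build_spectrum(at(2000L), reg, genome)$count), 1L)
  expect_equal(sum(build_spectrum(at(6000L), reg, genome)$count), 1L)
  expect_equal(sum(build_spectrum(at(1999L), reg, genome)$count), 0L)
  expect_equal(sum(build_spectrum(at(6001L), reg, genome)$count), 0L)
  expect_equal(sum(build_spectrum(at(8500L), reg, genome)$count), 0L)
})

test_that("spectra are invariant under reverse-complementing the genome", {
  sig <- synth_signature(c("C>T" = 0.6, "T>A" = 0.4), within = "random",
                         seed = 2, name = "gen")
  coh <- synth_cohort(sig, n_samples = 2, mutations_per_sample = 300,
                      seed = 9)
  fwd <- build_spectrum(coh$mutations, NULL, coh$genome)

  L <- length(coh$genome[[1]])
  rc_genome <- Biostrings::reverseComplement(coh$genome)
  names(rc_genome) <- names(coh$genome)
  rc_muts <- dplyr::mutate(coh$mutations,
                           pos = L + 1L - pos,
                           ref = chartr("ACGT", "TGCA", ref),
                           alt = chartr("ACGT", "TGCA", alt))
  rev <- build_spectrum(rc_muts, NULL, rc_genome)
  expect_equal(fwd, rev)
})

test_that("dominant-tumour selection is inclusive at the threshold", {
  expo <- tibble::tibble(
    sample = c("a", "b", "c", "d", "e"),
    signature = "SBSx",
    fraction = c(0.40, 0.399, 0.8, 0.1, 0.5)
  )
  expect_setequal(select_dominant_tumors(expo, "SBSx"), c("a", "c", "e"))
  expect_error(select_dominant_tumors(expo, "SBSy"), "unknown signature")
})

test_that("identical ratio sets give R squared of 1 and small sets error", {
  res <- tibble::tibble(experiment = paste0("e", 1:4), signature = "s",
                        gr = c(1, 2, 3, 4), lr = c(0.5, 0.4, 0.3, 0.2))
  cmp <- compare_gr_lr(res, res)
  expect_equal(cmp$per_signature$r_squared, 1)
  expect_equal(cmp$mean_r_squared, 1)
  expect_equal(cmp$per_signature$n_pairs, 8L)
  expect_error(compare_gr_lr(res[1, ], res[1, ]), "fewer than 3")
})
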