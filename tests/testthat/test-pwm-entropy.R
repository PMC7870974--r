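test_that("AT percent averages A+T cells, medians over PWMs, strict labels", {
  uniform <- tibble::tibble(tf = "U", pwm = "u1",
                            position = 1:5, A = 0.25, C = 0.25,
                            G = 0.25, T = 0.25)
  res <- at_percent(uniform)
  expect_equal(res$at_percent, 0.5)
  expect_equal(res$label, "neither")

  at_rich <- tibble::tibble(tf = "H", pwm = "h1", position = 1:4,
                            A = 0.5, C = 0.1, G = 0.1, T = 0.3)
  expect_equal(at_percent(at_rich)$label, "AT-PWM")
  expect_equal(at_percent(at_rich)$at_percent, 0.8)

  gc_rich <- tibble::tibble(tf = "G", pwm = "g1", position = 1:4,
                            A = 0.1, C = 0.4, G = 0.4, T = 0.1)
  expect_equal(at_percent(gc_rich)$label, "GC-PWM")

  # a TF assayed three times: the median of 0.2, 0.5, 0.8 is 0.5
  multi <- dplyr::bind_rows(
    dplyr::mutate(at_rich, tf = "M", pwm = "m1"),
    dplyr::mutate(uniform[1:4, ], tf = "M", pwm = "m2"),
    dplyr::mutate(gc_rich, tf = "M", pwm = "m3")
  )
  expect_equal(at_percent(multi)$at_percent, 0.5)

  # thresholds are strict: exactly 0.6 is "neither"
  edge <- tibble::tibble(tf = "E", pwm = "e1", position = 1:4,
                         A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  expect_equal(at_percent(edge)$label, "neither")
})

test_that("CIS-BP and MEME PWM files parse to the same matrix", {
  m <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.1, 0.1, 0.1, 0.7,
                0.1, 0.7, 0.1, 0.1,
                0.25, 0.25, 0.25, 0.25), nrow = 4, byrow = TRUE)
  cisbp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT",
               paste(1:4, m[, 1], m[, 2], m[, 3], m[, 4], sep = "\t")), cisbp)
  p1 <- read_pwm_cisbp(cisbp, tf = "TFX")

  meme <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF TFX", "letter-probability matrix: alength= 4 w= 4",
               apply(m, 1, paste, collapse = " ")), meme)
  p2 <- read_pwm_meme(meme)
  expect_equal(p1[, c("A", "C", "G", "T")], p2[, c("A", "C", "G", "T")])

  # rows not summing to 1 are renormalized with a warning
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT",
               paste(1:4, 0.5, 0.5, 0.5, 0.5, sep = "\t")), bad)
  expect_warning(read_pwm_cisbp(bad), "renormalizing")
})

test_that("entropy change follows the base-composition multiset", {
  # C>G leaving the count multiset unchanged (C:2,G:1 -> C:1,G:2) gives 0
  expect_equal(entropy_change("GCCAA", "G"), 0)
  # near-homopolymer: mutating the lone C to A removes all entropy
  h <- -(10 / 11 * log2(10 / 11) + 1 / 11 * log2(1 / 11))
  expect_equal(entropy_change("AAAAACAAAAA", "A"), 0 - h)
  # permuting flank positions (same multiset, same centre) changes nothing
  expect_equal(entropy_change("AAGGGCTTTTT", "T"),
               entropy_change("GGGAACTTTTT", "T"))
  # entropy base is configurable
  expect_equal(entropy_change("AAAAACAAAAA", "A", base = exp(1)),
               -h * log(2))
})

test_that("the +AT/AT-rich and -AT/GC-rich change sets mirror each other", {
  ch <- enumerate_all_changes(5)
  dh <- entropy_change(ch$kmer, ch$alt)
  type <- substitution_type(ch$class)
  at_frac <- (nchar(gsub("[CG]", "", ch$kmer))) / 5
  plus <- type %in% c("C>A", "C>T") & at_frac > 0.6
  minus <- type %in% c("T>C", "T>G") & at_frac < 0.4
  expect_equal(sum(plus), sum(minus))
  expect_equal(sort(dh[plus]), sort(dh[minus]))
  # +AT mutations in AT-rich sequences reduce composition entropy
  expect_lt(median(dh[plus]), 0)
  # and over all canonical changes the median change is zero
  expect_equal(median(dh), 0)
})

test_that("expected entropy change matches brute-force enumeration", {
  # composition-enumeration path vs direct per-change summation at width 5
  ch <- enumerate_all_changes(5)
  dh <- entropy_change(ch$kmer, ch$alt)
  at_frac <- (nchar(gsub("[CG]", "", ch$kmer))) / 5

  brute <- function(sig, keep) {
    w <- rep(0, nrow(ch))
    for (mc in mutation_classes()) {
      sel <- keep & ch$class == mc
      if (any(sel)) w[sel] <- sig[[mc]] / sum(sel)
    }
    sum(w * dh) / sum(w)
  }
  sigs <- list(
    uniform = sig_vector(uniform_signature()),
    ct = sig_vector(ct_signature()),
    skew = sig_vector(synth_signature(c("T>C" = 0.7, "C>G" = 0.3),
                                      within = "random", seed = 4))
  )
  for (nm in names(sigs)) {
    expect_equal(
      expected_entropy_change(tibble::tibble(signature = nm,
                                             class = mutation_classes(),
                                             prob = unname(sigs[[nm]])),
                              "all", width = 5)$expected_dh,
      brute(sigs[[nm]], rep(TRUE, nrow(ch))),
      tolerance = 1e-12
    )
    expect_equal(
      suppressMessages(expected_entropy_change(
        tibble::tibble(signature = nm, class = mutation_classes(),
                       prob = unname(sigs[[nm]])), "AT-rich", width = 5
      ))$expected_dh,
      brute(sigs[[nm]], at_frac > 0.6),
      tolerance = 1e-12
    )
  }

  # directional expectations
  expect_equal(expected_entropy_change(uniform_signature(), "all",
                                       width = 5)$expected_dh, 0,
               tolerance = 1e-9)
  ct <- suppressMessages(expected_entropy_change(
    synth_signature(c("C>T" = 1), name = "ct_only"), "AT-rich", width = 7
  ))
  expect_lt(ct$expected_dh, 0)
  tc <- expected_entropy_change(
    synth_signature(c("T>C" = 1), name = "tc_only"), "AT-rich", width = 7
  )
  expect_gt(tc$expected_dh, 0)
})

test_that("filtered tail statistics are deterministic with the expected signs", {
  tab <- toy_table(seed = 12)
  all_all <- tail_stats_by_filter(tab, "all", "all")
  expect_equal(all_all$median_dh, 0)
  expect_equal(all_all, tail_stats_by_filter(tab, "all", "all"))

  plus_at <- tail_stats_by_filter(tab, "+AT", "AT-rich")
  expect_lt(plus_at$median_dh, 0)
  expect_gt(plus_at$n, 0)
  expect_error(tail_stats_by_filter(tab, mutation_filter = "oops"),
               "must be one of")
})
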