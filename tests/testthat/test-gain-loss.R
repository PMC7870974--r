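test_that("the BH threshold matches a hand-applied step-up on printed p-values", {
  # 10 changes, p-values {0.001 x2, 0.5 x8}: the step-up keeps the two
  # smallest (0.001 <= 0.1 * 2/10 * ... via adjusted p 0.005 < 0.1), so T is
  # the smaller |score| of those two, here 4.
  p10 <- c(0.001, 0.001, rep(0.5, 8))
  s10 <- c(4, -6, seq(0.1, 0.8, by = 0.1))
  expect_equal(oracle_bh_threshold(s10, p10, 0.1), 4)
  # at FDR 0.0005 nothing passes
  expect_true(is.na(oracle_bh_threshold(s10, p10, 5e-4)))

  # on a complete table, the implementation agrees with the hand rule
  tab <- toy_table(seed = 77)
  expect_equal(fdr_threshold(tab, 0.1),
               oracle_bh_threshold(tab$score, tab$pvalue, 0.1))

  # all p = 1: no significant tail
  ch <- enumerate_all_changes(5)
  tab1 <- qbic_table(ch$kmer, ch$alt, rep(0, nrow(ch)), rep(1, nrow(ch)))
  expect_message(thr <- fdr_threshold(tab1), "no change passes")
  expect_true(is.na(thr))
})

test_that("lowering the FDR level never lowers the threshold", {
  tab <- toy_table(seed = 8)
  thrs <- vapply(c(0.2, 0.1, 0.05, 0.01), function(f) fdr_threshold(tab, f),
                 numeric(1))
  expect_true(all(diff(thrs) >= 0))
})

test_that("weighted distributions have the stated per-change masses", {
  tab <- toy_table(seed = 9)
  n <- nrow(tab)
  uni <- weighted_distribution(tab, uniform_signature())
  expect_true(all(abs(uni$mass - 1 / n) < 1e-15))
  expect_equal(sum(uni$mass), 1, tolerance = 1e-9)

  point <- tibble::tibble(signature = "pt", class = mutation_classes(),
                          prob = as.numeric(mutation_classes() == "TCA>TTA"))
  w <- weighted_distribution(tab, point)
  expect_equal(sum(w$mass), 1, tolerance = 1e-9)
  expect_true(all(w$mass[w$class == "TCA>TTA"] == 1 / 16))
  expect_true(all(w$mass[w$class != "TCA>TTA"] == 0))
})

test_that("tail areas count weighted mass above the threshold", {
  tab <- toy_table(seed = 10)
  thr <- fdr_threshold(tab)
  uni <- weighted_distribution(tab, uniform_signature())
  areas <- tail_areas(uni, thr)
  expect_equal(areas$area_pos, sum(tab$score >= thr) / nrow(tab))
  expect_equal(areas$area_neg, sum(tab$score <= -thr) / nrow(tab))

  # a signature with zero mass on every positive-tail class has empty
  # positive tail; the AT-motif table leaves many classes out of that tail
  tail_classes <- unique(tab$class[tab$score >= thr])
  off <- setdiff(mutation_classes(), tail_classes)
  expect_gt(length(off), 0)
  sig0 <- tibble::tibble(signature = "off", class = mutation_classes(),
                         prob = as.numeric(mutation_classes() %in% off) /
                           length(off))
  w0 <- weighted_distribution(tab, sig0)
  expect_equal(tail_areas(w0, thr)$area_pos, 0)
})

test_that("the uniform signature gives GR = LR = 1 exactly, for every table", {
  for (seed in 1:3) {
    tab <- toy_table(motif_consensus = c("TAAT", "GCGC", "ATTA")[seed],
                     seed = c(1, 2, 3)[seed])
    res <- gain_loss_ratios(tab, uniform_signature())
    expect_identical(res$gr, 1)
    expect_identical(res$lr, 1)
  }
})

test_that("vectorised ratios equal the brute-force per-change oracle", {
  sigs <- dplyr::bind_rows(ct_signature(), tc_signature())
  for (seed in 1:2) {
    tab <- toy_table(seed = c(1, 21)[seed])
    res <- gain_loss_ratios(tab, sigs)
    for (nm in unique(sigs$signature)) {
      oracle <- oracle_gain_loss(tab, sig_vector(sigs, nm))
      row <- res[res$signature == nm, ]
      expect_equal(row$threshold, oracle$threshold, tolerance = 1e-12)
      expect_equal(row$gr, oracle$gr, tolerance = 1e-12)
      expect_equal(row$lr, oracle$lr, tolerance = 1e-12)
    }
  }
})

test_that("ratios are linear in signature mixtures", {
  tab <- toy_table(seed = 31)
  s1 <- ct_signature()
  s2 <- tc_signature()
  for (lambda in c(0.25, 0.5, 0.9)) {
    mix <- tibble::tibble(
      signature = "mix", class = mutation_classes(),
      prob = lambda * sig_vector(s1) + (1 - lambda) * sig_vector(s2)
    )
    res <- gain_loss_ratios(tab, dplyr::bind_rows(s1, s2, mix))
    grs <- setNames(res$gr, res$signature)
    lrs <- setNames(res$lr, res$signature)
    expect_equal(grs[["mix"]],
                 lambda * grs[["ct_dominated"]] + (1 - lambda) * grs[["tc_dominated"]],
                 tolerance = 1e-9)
    expect_equal(lrs[["mix"]],
                 lambda * lrs[["ct_dominated"]] + (1 - lambda) * lrs[["tc_dominated"]],
                 tolerance = 1e-9)
  }
})

test_that("a table with no significant tail yields flagged missing ratios", {
  ch <- enumerate_all_changes(5)
  tab <- qbic_table(ch$kmer, ch$alt, rnorm(nrow(ch)), rep(1, nrow(ch)))
  expect_message(res <- gain_loss_ratios(tab, uniform_signature()), "no change")
  expect_true(is.na(res$gr))
  expect_true(is.na(res$lr))
})

test_that("resampling p-values are seeded, centred for the uniform signature,
           and minimal for the strongest point-mass", {
  tab <- toy_table(seed = 31)
  u <- uniform_signature()
  p1 <- resample_significance(tab, u, n_reps = 200, seed = 5)
  p2 <- resample_significance(tab, u, n_reps = 200, seed = 5)
  expect_identical(p1, p2)
  # the uniform signature sits at the null's centre
  expect_gte(p1$p_gain, 0.2)
  expect_gte(p1$p_loss, 0.2)

  # point mass on the class with the largest positive-tail count
  thr <- fdr_threshold(tab)
  pos_counts <- tapply(tab$score >= thr, tab$class, sum)
  best <- names(which.max(pos_counts))
  point <- tibble::tibble(signature = "pt", class = mutation_classes(),
                          prob = as.numeric(mutation_classes() == best))
  pp <- resample_significance(tab, point, n_mutations = 10000, n_reps = 200,
                              seed = 6)
  expect_equal(pp$p_gain, 1 / 201)
})

test_that("TF aggregation uses the standard median over experiments", {
  res <- tibble::tibble(
    experiment = c("e1", "e2", "e3", "f1", "f2"),
    tf = c("TF1", "TF1", "TF1", "TF2", "TF2"),
    signature = "s",
    gr = c(1, 2, 4, 1, 3), lr = c(0.1, 0.2, 0.3, 1, 1)
  )
  agg <- aggregate_tf(res)
  expect_equal(agg$gr[agg$tf == "TF1"], 2)
  expect_equal(agg$gr[agg$tf == "TF2"], 2)  # even count: mean of middle two
  expect_equal(agg$n_experiments, c(3L, 2L))

  single <- aggregate_tf(res[1, ])
  expect_equal(single$gr, 1)

  expect_error(
    aggregate_tf(dplyr::mutate(res, tf = NA_character_)),
    "no TF assignment"
  )
})

test_that("gain/loss calls require significance and can both be empty", {
  res <- tibble::tibble(tf = c("a", "b"), signature = "s",
                        p_gain = c(1, 1), p_loss = c(1, 1))
  cl <- classify_gain_loss(res)
  expect_false(any(cl$gain))
  expect_false(any(cl$loss))
  cl2 <- classify_gain_loss(dplyr::mutate(res, p_gain = c(0.01, 0.2)))
  expect_equal(cl2$gain, c(TRUE, FALSE))
})

test_that("complete-linkage clustering keeps separated blocks contiguous", {
  # two well-separated blocks of signatures
  res <- tidyr::expand_grid(tf = paste0("tf", 1:4),
                            signature = paste0("s", 1:6)) |>
    dplyr::mutate(
      gr = ifelse(signature %in% c("s1", "s3", "s5"), 5, 1) +
        0.01 * as.integer(factor(tf)),
      lr = 1
    )
  cl <- cluster_gr_lr(res)
  ord <- cl$signature_order
  block_a <- match(c("s1", "s3", "s5"), ord)
  expect_equal(diff(sort(block_a)), c(1, 1))
  expect_true(grepl(";$", cl$signature_newick))

  # identical rows merge at height zero
  same <- dplyr::mutate(res, gr = 1, lr = 1)
  cl0 <- cluster_gr_lr(same)
  expect_true(all(cl0$signature_hclust$height == 0))

  # degenerate single signature keeps identity order
  one <- dplyr::filter(res, signature == "s1")
  expect_equal(cluster_gr_lr(one)$signature_order, "s1")

  # missing ratios are imputed as 1 with a message
  holey <- res
  holey$gr[1] <- NA
  expect_message(cluster_gr_lr(holey), "imputing")
})
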