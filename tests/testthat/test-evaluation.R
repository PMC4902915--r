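test_that("precision/recall/F closed forms and degenerate conventions", {
  m <- matrix(0L, 20, 20); m[3:12, 3:12] <- 1L           # 100 px
  s <- precision_recall_f(m, m)
  expect_equal(c(s$precision, s$recall, s$f_value), c(1, 1, 1))

  inner <- matrix(0L, 20, 20); inner[3:12, 3:7] <- 1L    # 50 px inside
  s <- precision_recall_f(inner, m)
  expect_equal(s$precision, 1)
  expect_equal(s$recall, 0.5)
  expect_equal(s$f_value, 2 / 3)

  other <- matrix(0L, 20, 20); other[15:18, 15:18] <- 1L
  s <- precision_recall_f(other, m)
  expect_equal(c(s$precision, s$recall, s$f_value), c(0, 0, 0))

  empty <- matrix(0L, 20, 20)
  expect_equal(precision_recall_f(empty, m)$f_value, 0)
  expect_equal(precision_recall_f(m, empty)$f_value, 0)
  expect_equal(precision_recall_f(empty, empty)$f_value, 0)
  expect_error(precision_recall_f(m, matrix(0L, 5, 5)), "shape")
})

test_that("P/R swap under exchange and F is symmetric (vs pixel oracle)", {
  set.seed(41)
  for (i in 1:20) {
    a <- random_mask(32, 32, runif(1, 0.2, 0.8))
    b <- random_mask(32, 32, runif(1, 0.2, 0.8))
    ab <- precision_recall_f(a, b)
    ba <- precision_recall_f(b, a)
    o <- prf_oracle(a, b)
    expect_equal(ab$precision, o[["p"]])
    expect_equal(ab$recall, o[["r"]])
    expect_equal(ab$f_value, o[["f"]])
    expect_equal(ab$precision, ba$recall)
    expect_equal(ab$recall, ba$precision)
    expect_equal(ab$f_value, ba$f_value)
    # harmonic mean never exceeds the arithmetic mean
    expect_lte(ab$f_value, (ab$precision + ab$recall) / 2 + 1e-12)
    if (abs(ab$precision - ab$recall) < 1e-12 && ab$precision > 0)
      expect_equal(ab$f_value, ab$precision)
    expect_true(ab$f_value >= min(ab$precision, ab$recall) - 1e-12)
    expect_true(ab$f_value <= max(ab$precision, ab$recall) + 1e-12)
  }
})

rand_set <- function(id, p = 0.5, nr = 16) {
  methods <- c("C1", "C2", "T1", "T2", "E1", "E2", "E3", "E4")
  mask_set(setNames(replicate(8, random_mask(nr, nr, p), simplify = FALSE),
                    methods), id)
}

test_that("the agreement matrix has 28 informative symmetric cells", {
  m <- disk_mask(16, 5)
  same <- mask_set(setNames(replicate(8, m, simplify = FALSE),
                            c("C1", "C2", "T1", "T2",
                              "E1", "E2", "E3", "E4")), "same")
  am <- pairwise_f_matrix(list(same))
  expect_equal(sum(am$mean_f[upper.tri(am$mean_f)] == 1), 28)
  expect_equal(nrow(tidy(am)), 28)
  expect_equal(glance(am)$n_pairs, 28)
  expect_true(isSymmetric(am$mean_f))
  expect_equal(diag(am$mean_f), rep(1, 8), ignore_attr = TRUE)

  # full-frame vs empty: agreement 0
  masks <- setNames(replicate(8, matrix(1L, 8, 8), simplify = FALSE),
                    c("C1", "C2", "T1", "T2", "E1", "E2", "E3", "E4"))
  masks$C2 <- matrix(0L, 8, 8)
  am2 <- pairwise_f_matrix(list(mask_set(masks, "x")))
  expect_equal(am2$mean_f["C1", "C2"], 0)
  expect_equal(am2$mean_f["C1", "T1"], 1)
  expect_error(pairwise_f_matrix(list()), "at least one")
})

test_that("the matrix equals brute-force recomputation with swapped roles", {
  set.seed(42)
  sets <- lapply(1:10, function(i) rand_set(paste0("img", i)))
  am <- pairwise_f_matrix(sets)
  methods <- am$methods
  for (i in 1:7) for (j in (i + 1):8) {
    f_ab <- mean(vapply(sets, function(s) precision_recall_f(
      s$masks[[methods[i]]], s$masks[[methods[j]]])$f_value, numeric(1)))
    f_ba <- mean(vapply(sets, function(s) precision_recall_f(
      s$masks[[methods[j]]], s$masks[[methods[i]]])$f_value, numeric(1)))
    expect_equal(am$mean_f[i, j], f_ab)
    expect_equal(am$mean_f[i, j], f_ba)     # reference choice is irrelevant
  }
})

test_that("methods_vs_reference aggregates mean and SE per method", {
  set.seed(43)
  sets <- lapply(1:20, function(i) rand_set(paste0("img", i)))
  refs <- lapply(1:20, function(i) random_mask(16, 16, 0.5))
  tab <- methods_vs_reference(sets, refs)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$n, rep(20, 8))

  # independent recomputation for one method
  f_c1 <- vapply(seq_along(sets), function(i) precision_recall_f(
    sets[[i]]$masks$C1, refs[[i]])$f_value, numeric(1))
  row <- tab[tab$method == "C1", ]
  expect_equal(row$f_value_mean, mean(f_c1))
  expect_equal(row$f_value_se, sd(f_c1) / sqrt(20))

  # identical masks: all means 1, SEs 0
  m <- disk_mask(16, 5)
  one <- mask_set(setNames(replicate(8, m, simplify = FALSE),
                           c("C1", "C2", "T1", "T2",
                             "E1", "E2", "E3", "E4")), "s")
  perfect <- methods_vs_reference(list(one, one), list(m, m))
  expect_true(all(perfect$f_value_mean == 1))
  expect_true(all(perfect$f_value_se == 0))

  # a method that is always empty scores 0 everywhere
  broken <- one; broken$masks$E2 <- matrix(0L, 16, 16)
  tab2 <- methods_vs_reference(list(broken), list(m))
  expect_equal(tab2$f_value_mean[tab2$method == "E2"], 0)

  # images with an empty reference are never scored
  tab3 <- methods_vs_reference(list(one, one), list(m, matrix(0L, 16, 16)))
  expect_equal(tab3$n, rep(1, 8))
  expect_error(methods_vs_reference(list(one), list(m, m)), "equal length")

  # stratification keeps groups separate
  tab4 <- methods_vs_reference(list(one, broken), list(m, m),
                               strata = c("W0", "W1"))
  expect_equal(nrow(tab4), 16)
  expect_equal(tab4$f_value_mean[tab4$method == "E2" & tab4$stratum == "W1"], 0)
  expect_equal(tab4$f_value_mean[tab4$method == "E2" & tab4$stratum == "W0"], 1)
})

test_that("the empty-prediction convention can exclude instead of count", {
  m <- disk_mask(16, 5)
  one <- mask_set(setNames(replicate(8, m, simplify = FALSE),
                           c("C1", "C2", "T1", "T2",
                             "E1", "E2", "E3", "E4")), "s")
  broken <- one; broken$masks$E2 <- matrix(0L, 16, 16)
  cfg <- seg_config(score_empty_as_zero = FALSE)
  tab <- methods_vs_reference(list(one, broken), list(m, m), cfg = cfg)
  expect_equal(tab$n[tab$method == "E2"], 1)      # empty image dropped
  expect_equal(tab$n[tab$method == "C1"], 2)
  expect_equal(tab$f_value_mean[tab$method == "E2"], 1)
})
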