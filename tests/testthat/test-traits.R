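test_that("pixel counts convert to areas by the squared scale", {
  expect_equal(pixels_to_area(10000, 100), 1.0)
  expect_equal(pixels_to_area(0, 74.36), 0)
  expect_equal(pixels_to_area(5531, 74.36), 5531 / 74.36^2)
  expect_equal(round(pixels_to_area(5531, 74.36), 4), 1.0003)
  # scale equivariance: doubling the scale quarters the area
  expect_equal(pixels_to_area(500, 40), 4 * pixels_to_area(500, 80))
  expect_error(pixels_to_area(10, 0), "positive")
})

test_that("thermal time accumulates clipped daily means above the base", {
  d5 <- tibble::tibble(tmin = rep(10, 5), tmax = rep(10, 5))
  expect_equal(thermal_time(d5), 50)
  expect_equal(thermal_time(tibble::tibble(tmin = -4, tmax = 2)), 0)
  expect_equal(thermal_time(tibble::tibble(tmin = c(4, 4), tmax = c(10, 10))), 14)
  # base temperature shifts the contribution
  expect_equal(thermal_time(d5, t_base = 4), 30)
  # additivity over consecutive ranges; non-negativity
  set.seed(51)
  tt <- generate_temperature_series(60, seed = 9)
  expect_equal(thermal_time(tt),
               thermal_time(tt[1:25, ]) + thermal_time(tt[26:60, ]))
  expect_gte(thermal_time(tt), 0)
  expect_error(thermal_time(tibble::tibble(tmin = 5, tmax = 2)), "tmin")
  expect_error(thermal_time(tibble::tibble()), "empty")
  gc <- gdd_cumulative(tt)
  expect_equal(gc$gdd_cum, cumsum(gc$gdd_day))
})

obs_row <- function(g, r, tp, wk, area, valid = TRUE) {
  tibble::tibble(genotype_id = g, replicate = r, timepoint = tp,
                 week = wk, area_cm2 = area, valid = valid)
}

test_that("regrowth pairs W0/W1 and converts to a thermal-time rate", {
  obs <- dplyr::bind_rows(
    obs_row("G1", 1, "Y1C2", "W0", 12), obs_row("G1", 1, "Y1C2", "W1", 30),
    obs_row("G1", 1, "Y1C3", "W0", 20), obs_row("G1", 1, "Y1C3", "W1", 26))
  out <- regrowth(obs, gdd_week = c(Y1C2 = 90, Y1C3 = 120))
  expect_equal(out$regrowth_cm2, c(18, 6))
  expect_equal(out$regrowth_rate, c(0.2, 0.05))
  expect_true(all(out$valid))

  # invalid W0 invalidates the pair
  obs$valid[1] <- FALSE
  out2 <- regrowth(obs)
  expect_false(out2$valid[out2$timepoint == "Y1C2"])
  expect_true(is.na(out2$regrowth_cm2[out2$timepoint == "Y1C2"]))

  # negative regrowth is retained but reported
  obs3 <- dplyr::bind_rows(obs_row("G1", 1, "Y1C2", "W0", 30),
                           obs_row("G1", 1, "Y1C2", "W1", 25))
  expect_message(out3 <- regrowth(obs3), "negative regrowth")
  expect_equal(out3$regrowth_cm2, -5)
})

test_that("lateral expansion is the OLS slope with an n >= 3 rule", {
  gdd <- c(Y1C2 = 0, Y1C3 = 100, Y1C4 = 200, Y1C5 = 300)
  obs <- dplyr::bind_rows(lapply(1:4, function(i)
    obs_row("G1", 1, names(gdd)[i], "W0", c(10, 20, 30, 40)[i])))
  fit <- lateral_expansion(obs, gdd)
  expect_equal(fit$slope, 0.100, tolerance = 1e-12)
  expect_equal(fit$n_obs, 4)

  # adding a constant to all areas leaves the slope unchanged
  obs_c <- obs; obs_c$area_cm2 <- obs_c$area_cm2 + 7.3
  expect_equal(lateral_expansion(obs_c, gdd)$slope, 0.100, tolerance = 1e-12)

  # fewer than three valid points: no estimate, not an error
  obs2 <- obs; obs2$valid[3:4] <- FALSE
  fit2 <- lateral_expansion(obs2, gdd)
  expect_true(is.na(fit2$slope))
  expect_equal(fit2$n_obs, 2)

  # noisy simulation oracle: the OLS estimator is unbiased
  set.seed(52)
  slopes <- replicate(500, {
    y <- 5 + 0.06 * c(0, 150, 300, 450) + rnorm(4, 0, 2)
    obs_n <- dplyr::bind_rows(lapply(1:4, function(i)
      obs_row("G", 1, names(gdd)[i], "W0", y[i])))
    lateral_expansion(obs_n, setNames(c(0, 150, 300, 450), names(gdd)))$slope
  })
  expect_lt(abs(mean(slopes) - 0.06), 0.005)
})

test_that("leaf growth divides height by the window's thermal time", {
  expect_equal(leaf_growth(30, 150), 0.2)
  expect_equal(leaf_growth(0, 150), 0)
  expect_equal(leaf_growth(21, 140), 0.15)
  expect_error(leaf_growth(30, 0), "positive")
})

test_that("genotype means average valid clonal replicates", {
  rec <- tibble::tibble(
    genotype_id = rep(c("G1", "G2"), each = 3),
    replicate = rep(1:3, 2),
    tiller_number = c(10, 20, 30, 10, 15, 20),
    valid = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  gm <- genotype_means(rec)
  expect_equal(gm$tiller_number[gm$genotype_id == "G1"], 20)
  expect_equal(gm$tiller_number[gm$genotype_id == "G2"], 15)  # mean of 10, 20
  expect_equal(gm$n_reps, c(3, 2))

  # all replicates invalid: genotype excluded with a message
  rec$valid[4:6] <- FALSE
  expect_message(gm2 <- genotype_means(rec), "excluded")
  expect_equal(gm2$genotype_id, "G1")
})

test_that("pearson_correlation matches closed forms and errors", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(1:2, 2:3), "3 complete pairs")
  expect_error(pearson_correlation(rep(1, 5), x), "variance")
  expect_error(pearson_correlation(1:4, 1:5), "lengths")

  # missing genotypes removed pairwise
  out <- pearson_correlation(c(x, NA), c(2 * x, 4))
  expect_equal(out$n, 5)
  expect_equal(out$r, 1)

  # sampling oracle at true rho = 0.8
  set.seed(53)
  n <- 500
  z <- rnorm(n)
  x1 <- z
  y1 <- 0.8 * z + sqrt(1 - 0.8^2) * rnorm(n)
  est <- pearson_correlation(x1, y1)
  expect_lt(abs(est$r - 0.8), 0.05)
  expect_lt(est$p_value, 1e-6)
})

test_that("correlation_table reproduces the per-cut layout", {
  set.seed(54)
  df <- tibble::tibble(
    timepoint = rep(c("Y1C2", "Y1C3"), each = 30),
    leaf_growth = rnorm(60),
    regrowth_rate = NA_real_)
  df$regrowth_rate <- 0.7 * df$leaf_growth + rnorm(60, 0, 0.5)
  tab <- correlation_table(df, "leaf_growth", "regrowth_rate",
                           by = "timepoint")
  expect_equal(nrow(tab), 2)
  expect_true(all(c("r", "p_value", "n") %in% names(tab)))
  one <- df[df$timepoint == "Y1C2", ]
  expect_equal(tab$r[tab$timepoint == "Y1C2"],
               unname(cor.test(one$leaf_growth, one$regrowth_rate)$estimate))
})
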