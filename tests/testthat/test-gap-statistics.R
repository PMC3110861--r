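test_that("gap accessibilities are emitted residue-wise, in column order", {
  # three consecutive target residues aligned against a template gap
  aln <- reference_alignment("AC---W", "ACDEFW")
  tb <- c(0.1, 0.5, 0.9)
  ta <- c(0.2, 0.2, 0.2)
  # track_b covers the target's 6 residues
  out <- gap_accessibilities(aln, track_b = c(0.3, 0.3, tb, 0.3))
  expect_equal(out, tb)
  # no gap columns -> empty
  expect_equal(gap_accessibilities(reference_alignment("ACD", "ACD"),
                                   track_a = c(1, 1, 1) / 2,
                                   track_b = c(1, 1, 1) / 2),
               numeric(0))
  # two separate gaps, lengths 2 and 1, values by hand-read columns
  aln2 <- reference_alignment("A--CDW", "AEFC-W")
  track_a <- c(0.1, 0.2, 0.3, 0.4)   # template AC DW
  track_b <- c(0.5, 0.6, 0.7, 0.8, 0.9) # target AEFCW
  out2 <- gap_accessibilities(aln2, track_a, track_b)
  expect_length(out2, 3)
  expect_setequal(out2, c(0.3, 0.6, 0.7)) # template D deleted; E,F inserted
  # length mismatch errors
  expect_error(gap_accessibilities(aln2, track_a = c(0.1, 0.2)), "length")
})

test_that("binned odds are 1 when gaps and residues share a distribution", {
  set.seed(1)
  v <- runif(200)
  bt <- bin_gap_odds(v, v, w = 0.05)
  expect_true(all(abs(bt$odds[!is.na(bt$odds)] - 1) < 1e-12))
  # frequencies are normalised
  expect_equal(sum(bt$g), 1, tolerance = 1e-12)
  expect_equal(sum(bt$f), 1, tolerance = 1e-12)
})

test_that("bin counts and odds match a hand count", {
  bt <- bin_gap_odds(c(0.02, 0.07), c(0.02, 0.02, 0.07, 0.07), w = 0.05)
  expect_equal(bt$n_gap[1:2], c(1L, 1L))
  expect_equal(bt$n_res[1:2], c(2L, 2L))
  expect_equal(bt$g[1:2], c(0.5, 0.5))
  expect_equal(bt$f[1:2], c(0.5, 0.5))
  expect_equal(bt$odds[1:2], c(1, 1))
  # value exactly 1.0 lands in the final (closed) bin
  bt2 <- bin_gap_odds(1.0, c(1.0, 0.5), w = 0.05)
  expect_equal(bt2$n_gap[20], 1L)
  # odds flagged NA where the bin holds no residues
  expect_true(is.na(bt$odds[20]))
  # empty residue list errors
  expect_error(bin_gap_odds(0.5, numeric(0)), "empty")
  # bin width must divide 1
  expect_error(bin_gap_odds(0.5, 0.5, w = 0.07), "divide")
})

test_that("pooling datasets equals binning concatenated values", {
  set.seed(2)
  g1 <- runif(40); r1 <- runif(120)
  g2 <- runif(25); r2 <- runif(90)
  pooled <- bin_gap_odds(c(g1, g2), c(r1, r2))
  sep1 <- bin_gap_odds(g1, r1); sep2 <- bin_gap_odds(g2, r2)
  expect_equal(pooled$n_gap, sep1$n_gap + sep2$n_gap)
  expect_equal(pooled$n_res, sep1$n_res + sep2$n_res)
})

make_stat_pair <- function(seed) {
  p <- simulate_pair(n = 80, seed = seed)
  list(alignment = p$reference, track_a = p$track, track_b = NULL)
}

test_that("bootstrap SDs are zero for identical pairs and reproducible", {
  one <- make_stat_pair(5)
  same <- list(one, one, one, one)
  sd0 <- bootstrap_odds_sd(same, B = 50, seed = 9)
  expect_true(all(sd0$odds_sd[!is.na(sd0$odds_sd)] == 0))
  two <- list(make_stat_pair(11), make_stat_pair(12), make_stat_pair(13))
  s1 <- bootstrap_odds_sd(two, B = 200, seed = 42)
  s2 <- bootstrap_odds_sd(two, B = 200, seed = 42)
  expect_identical(s1, s2)
  expect_true(any(s1$odds_sd > 0, na.rm = TRUE))
})

test_that("regression recovers an exact exponential with zero residual", {
  mids <- (1:20 - 0.5) * 0.05
  odds <- exp(1.55 * mids - 0.50)
  bt <- structure(tibble::tibble(bin = 1:20, lo = (0:19) * 0.05,
                                 hi = (1:20) * 0.05, mid = mids,
                                 n_gap = 1L, n_res = 1L, g = 0.05, f = 0.05,
                                 odds = odds),
                  class = c("gap_bin_table", class(tibble::tibble())))
  fit <- fit_odds_regression(bt, "log-linear")
  expect_equal(fit$slope, 1.55, tolerance = 1e-9)
  expect_equal(fit$intercept, -0.50, tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
  # constant odds = 1: linear fit is flat with zero residual
  bt$odds <- rep(1, 20)
  lin <- fit_odds_regression(bt, "linear")
  expect_equal(lin$slope, 0, tolerance = 1e-9)
  expect_equal(lin$intercept, 1, tolerance = 1e-9)
  expect_equal(lin$rmse, 0, tolerance = 1e-9)
  # zero odds break the log-linear form, naming the bin
  bt$odds[3] <- 0
  expect_error(fit_odds_regression(bt, "log-linear"), "bin 3")
})

test_that("noisy exponential slope is recovered, matching the normal equations", {
  set.seed(33)
  mids <- (1:20 - 0.5) * 0.05
  odds <- exp(1.55 * mids - 0.50 + rnorm(20, sd = 0.08))
  bt <- structure(tibble::tibble(bin = 1:20, lo = (0:19) * 0.05,
                                 hi = (1:20) * 0.05, mid = mids,
                                 n_gap = 1L, n_res = 1L, g = 0.05, f = 0.05,
                                 odds = odds),
                  class = c("gap_bin_table", class(tibble::tibble())))
  fit <- fit_odds_regression(bt, "log-linear")
  expect_equal(fit$slope, 1.55, tolerance = 0.15)
  # closed-form least squares oracle
  y <- log(odds)
  slope_oracle <- sum((mids - mean(mids)) * (y - mean(y))) /
    sum((mids - mean(mids))^2)
  intercept_oracle <- mean(y) - slope_oracle * mean(mids)
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-9)
  expect_equal(fit$intercept, intercept_oracle, tolerance = 1e-9)
  # on exponential data the log-linear residual beats the linear residual
  steep <- exp(3 * mids - 1 + rnorm(20, sd = 0.05))
  bt$odds <- steep
  expect_lt(fit_odds_regression(bt, "log-linear")$rmse,
            fit_odds_regression(bt, "linear")$rmse)
})

test_that("tidy and glance summarise a regression fit", {
  mids <- (1:20 - 0.5) * 0.05
  bt <- bin_gap_odds(runif(100), runif(400))
  fit <- fit_odds_regression(bt, "linear")
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- glance(fit)
  expect_equal(gl$form, "linear")
  expect_gte(gl$rmse, 0)
})
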