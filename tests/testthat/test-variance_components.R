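const_draws <- function(n = 50L, ...) {
  vals <- list(...)
  as.data.frame(lapply(vals, rep, length.out = n), check.names = FALSE)
}

base_cols <- function(n = 50L) {
  cols <- list()
  for (h in c("summer", "winter")) {
    for (p in c("alpha", "b", "alpha_T", "b_T")) {
      cols[[sprintf("%s[%s]", p, h)]] <- rep(0, n)
    }
    for (lv in c("cave", "year", "caveyear")) {
      cols[[sprintf("V_alpha_%s[%s]", lv, h)]] <- rep(0, n)
      cols[[sprintf("V_b_%s[%s]", lv, h)]] <- rep(0, n)
      cols[[sprintf("cov_ab_%s[%s]", lv, h)]] <- rep(0, n)
    }
    cols[[sprintf("V_e[%s]", h)]] <- rep(1, n)
    cols[[sprintf("T_mean[%s]", h)]] <- rep(5, n)
    cols[[sprintf("T_V_cave[%s]", h)]] <- rep(0, n)
    cols[[sprintf("T_V_year[%s]", h)]] <- rep(0, n)
    cols[[sprintf("T_V_resid[%s]", h)]] <- rep(0, n)
  }
  as.data.frame(cols, check.names = FALSE)
}

test_that("temperature-associated variance applies V(a+bx) = b^2 V(x)", {
  d <- base_cols()
  d[["T_V_year[summer]"]] <- 0.15
  d[["alpha_T[summer]"]] <- 0.40
  fit <- make_fake_fit(d)
  # 0.15 * 0.40^2 = 0.024 per month^2
  expect_equal(unique(temperature_associated_variance(fit, "time", "summer")),
               0.024)
  # zero effect -> zero associated variance
  expect_equal(unique(temperature_associated_variance(fit, "time", "winter")),
               0)
  # season scale multiplies by months^2
  expect_equal(unique(temperature_associated_variance(fit, "time", "summer",
                                                      scale = "season")),
               0.024 * 4)
  expect_error(temperature_associated_variance(fit, "galaxy", "summer"),
               "unknown level")
  fit_nt <- make_fake_fit(d, ablation = "no_temperature")
  expect_error(temperature_associated_variance(fit_nt, "time", "summer"),
               "no_temperature")
})

test_that("the rule matches a brute-force variance of effect x covariate", {
  set.seed(31)
  d <- base_cols(20L)
  d[["T_V_year[summer]"]] <- runif(20L, 0.05, 0.5)
  d[["alpha_T[summer]"]] <- rnorm(20L, 0.4, 0.2)
  fit <- make_fake_fit(d)
  got <- temperature_associated_variance(fit, "time", "summer")
  for (k in c(1L, 7L, 20L)) {
    x <- rnorm(2e5, 0, sqrt(d[["T_V_year[summer]"]][k]))
    brute <- var(d[["alpha_T[summer]"]][k] * x)
    expect_lt(abs(got[k] - brute), 0.05 * brute + 1e-4)
  }
})

test_that("slope-variance conversion is exact and linear", {
  vb <- c(0, 0.001, 0.002, 0.01)
  expect_equal(convert_slope_variance(vb, 24), vb * 24)
  # the printed pairing: V_b = 0.001 with sigma_fl^2 = 24 -> 0.024
  expect_equal(convert_slope_variance(0.001, 24), 0.024)
  expect_equal(convert_slope_variance(vb, 48), 2 * convert_slope_variance(vb, 24))
  expect_error(convert_slope_variance(vb, -1))
})

test_that("fork-length variance recovers a known spread", {
  # 500 fish measured once at one August occasion, lengths ~ N(92, 25)
  set.seed(12)
  L <- matrix(round(rnorm(500L, 92, 5), 1), 500L, 1L)
  caps <- make_captures(L, 2013, "August")
  panel <- build_panel(validate_captures(caps), full_temp_grid("C01", 2013))
  fv <- fork_length_variance(panel, "summer")
  se <- 25 * sqrt(2 / 499)
  expect_lt(abs(fv$sigma_fl_sq - 25), 3 * se + 25 / 12 / 10)
  # identical lengths -> zero variance
  Lc <- matrix(rep(90, 40L), 40L, 1L)
  panel_c <- build_panel(validate_captures(make_captures(Lc, 2013, "August")),
                         full_temp_grid("C01", 2013))
  expect_equal(fork_length_variance(panel_c, "summer")$sigma_fl_sq, 0)
  expect_error(fork_length_variance(panel, "winter"), "post-winter")
})

test_that("fork-length variance uses post-season occasions with grouping", {
  sim <- small_sim(); panel <- small_panel()
  fs <- fork_length_variance(panel, "summer")
  fw <- fork_length_variance(panel, "winter")
  expect_gt(fs$sigma_fl_sq, 0); expect_gt(fw$sigma_fl_sq, 0)
  expect_named(fs$components, c("cave", "year", "residual"))
  # totals are in the ballpark of the plain spread of those lengths
  aug <- panel$occasions$occasion[panel$occasions$month == "August"]
  plain <- var(panel$obs[, aug][!is.na(panel$obs[, aug])])
  expect_lt(abs(fs$sigma_fl_sq - plain) / plain, 0.5)
})

test_that("repeatability components sum to one per draw", {
  set.seed(77)
  n <- 200L
  d <- base_cols(n)
  for (h in c("summer", "winter")) {
    for (lv in c("cave", "year", "caveyear")) {
      d[[sprintf("V_alpha_%s[%s]", lv, h)]] <- rexp(n, 2)
      d[[sprintf("V_b_%s[%s]", lv, h)]] <- rexp(n, 500)
    }
    d[[sprintf("T_V_cave[%s]", h)]] <- rexp(n, 5)
    d[[sprintf("T_V_year[%s]", h)]] <- rexp(n, 5)
    d[[sprintf("T_V_resid[%s]", h)]] <- rexp(n, 3)
    d[[sprintf("alpha_T[%s]", h)]] <- rnorm(n, 0.3, 0.1)
  }
  fit <- make_fake_fit(d)
  vr <- repeatability(fit, c(summer = 24, winter = 30))
  for (h in c("summer", "winter")) {
    dr <- vr$draws[[h]]
    rsum <- Reduce(`+`, dr[grep("^R", names(dr))])
    expect_equal(rsum, rep(1, n))
    # every derived variance is non-negative in every draw
    for (v in grep("^V", names(dr), value = TRUE)) {
      expect_true(all(dr[[v]] >= 0))
    }
    # V_g excludes the residual; the labelled alternative includes it
    expect_equal(dr$V_g_with_residual, dr$V_g + dr$V_e)
  }
})

test_that("summaries are computed per draw, not from summarised inputs", {
  # skewed draws where mean(a/b) differs markedly from mean(a)/mean(b)
  n <- 400L
  set.seed(5)
  d <- base_cols(n)
  d[["V_alpha_year[summer]"]] <- rexp(n, 1 / 5)
  d[["V_alpha_cave[summer]"]] <- rexp(n, 1)
  fit <- make_fake_fit(d)
  vr <- repeatability(fit, c(summer = 24, winter = 30))
  per_draw <- mean(d[["V_alpha_year[summer]"]] /
                     (d[["V_alpha_year[summer]"]] +
                        d[["V_alpha_cave[summer]"]]))
  of_means <- mean(d[["V_alpha_year[summer]"]]) /
    mean(d[["V_alpha_year[summer]"]] + d[["V_alpha_cave[summer]"]])
  got <- vr$table$mean[vr$table$season == "summer" &
                         vr$table$quantity == "R_alpha_year"]
  expect_equal(got, per_draw)
  expect_gt(abs(per_draw - of_means), 0.02)  # the orders genuinely disagree
})

test_that("a single nonzero component takes the whole share", {
  d <- base_cols(30L)
  d[["V_alpha_year[summer]"]] <- 2
  d[["V_alpha_year[winter]"]] <- 3
  fit <- make_fake_fit(d)
  vr <- repeatability(fit, c(summer = 24, winter = 30))
  tab <- vr$table[vr$table$season == "summer", ]
  expect_equal(tab$mean[tab$quantity == "R_alpha_year"], 1)
  expect_equal(tab$mean[tab$quantity == "R_alpha_cave"], 0)
  expect_equal(tab$mean[tab$quantity == "R_temp_caveyear"], 0)
})

test_that("draws with zero total variance are flagged, not divided", {
  d <- base_cols(10L)
  d[["V_alpha_year[summer]"]][1:4] <- 1   # 6 draws have V_g = 0 in summer
  fit <- make_fake_fit(d)
  vr <- repeatability(fit, c(summer = 24, winter = 30))
  expect_equal(unname(vr$n_undefined["summer"]), 6L)
  expect_equal(unname(vr$n_undefined["winter"]), 10L)
  expect_equal(vr$table$mean[vr$table$season == "summer" &
                               vr$table$quantity == "R_alpha_year"], 1)
})
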