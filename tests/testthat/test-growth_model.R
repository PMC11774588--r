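no_re <- list(V_alpha_cave = 0, V_b_cave = 0, V_alpha_year = 0,
              V_b_year = 0, V_alpha_caveyear = 0, V_b_caveyear = 0)

test_that("a single noiseless 100->110 summer forces alpha", {
  caps <- make_captures(matrix(c(100, 110), 1L, 2L), c(2013, 2013),
                        c("June", "August"))
  panel <- build_panel(validate_captures(caps), full_temp_grid("C01", 2013))
  fit <- fit_growth(panel, eta_sq = 0, ablation = "no_temperature",
                    fixed = c(no_re, list(b = 0, V_e = 1e-6)),
                    mcmc = quick_mcmc(), seed = 1L)
  # 10 mm over one 2-month summer: 5 mm/month, i.e. 10/67 mm/day
  al <- fit$draws[, "alpha[summer]"]
  expect_lt(abs(mean(al) - 5), 0.02)
  expect_lt(sd(al), 0.02)
  expect_equal(mean(al) / (67 / 2), 10 / 67, tolerance = 0.005)
})

test_that("eta_sq is required and must come from the measurement module", {
  expect_error(fit_growth(small_panel()), "estimate_measurement_error")
  # a measurement_error_estimate object is accepted directly
  reps <- small_sim()$repeats
  est <- estimate_measurement_error(reps, method = "mom")
  expect_gt(est$eta_sq, 0)
})

test_that("variance components need replication unless fixed to zero", {
  caps <- make_captures(matrix(c(100, 110), 1L, 2L),
                        c(2013, 2013), c("June", "August"))
  panel <- build_panel(validate_captures(caps), full_temp_grid("C01", 2013))
  expect_error(fit_growth(panel, eta_sq = 0.6, mcmc = quick_mcmc()),
               ">= 2 caves")
})

test_that("measured occasions with tiny noise reproduce the measurement", {
  fit <- small_fit()
  panel <- small_panel()
  i <- which(rowSums(!is.na(panel$obs)) >= 3L)[1L]
  occ <- which(!is.na(panel$obs[i, ]))[1L]
  pr <- predict_size(fit, panel$fish$fish_id[i], occ)
  # eta^2 = 0.6: the latent size tracks the measurement to ~sqrt(0.6) mm
  expect_lt(abs(pr$mean - panel$obs[i, occ]), 3 * sqrt(0.6))
  expect_error(predict_size(fit, panel$fish$fish_id[i], 999L),
               "outside the latent support")
})

test_that("an interior unmeasured occasion is bracketed by its neighbours", {
  years <- c(2013, 2013, 2014); months <- c("June", "August", "June")
  L <- matrix(NA_real_, 24L, 3L)
  set.seed(42)
  L[, 1L] <- round(rnorm(24L, 100, 8))
  L[, 2L] <- round(L[, 1L] + rnorm(24L, 5, 1.5))
  L[, 3L] <- round(L[, 2L] + rnorm(24L, 6, 1.5))
  L[1L, ] <- c(100, NA, 110)   # the probe fish
  caps <- make_captures(L, years, months)
  panel <- build_panel(validate_captures(caps),
                       full_temp_grid("C01", 2013:2014))
  fit <- fit_growth(panel, eta_sq = 0.6, ablation = "no_temperature",
                    fixed = no_re, mcmc = quick_mcmc(), seed = 3L)
  pr <- predict_size(fit, "F001", 2L)
  expect_gt(pr$mean, 95); expect_lt(pr$mean, 115)
  expect_gt(pr$lwr, 80); expect_lt(pr$upr, 130)
})

test_that("latent-size augmentation leaves fixed effects stable", {
  panel <- small_panel()
  fit_full <- small_fit()
  # mask ~10% of interior observations and refit
  set.seed(8)
  interior <- do.call(rbind, lapply(seq_len(nrow(panel$fish)), function(i) {
    occ <- which(!is.na(panel$obs[i, ]))
    occ <- occ[occ > panel$fish$first_occasion[i] &
                 occ < panel$fish$last_occasion[i]]
    if (length(occ)) data.frame(fish_id = panel$fish$fish_id[i],
                                occasion = occ) else NULL
  }))
  pick <- interior[sample(nrow(interior), ceiling(0.5 * nrow(interior))), ]
  p2 <- remove_observations(panel, pick)
  fit_masked <- fit_growth(p2, eta_sq = 0.6, mcmc = quick_mcmc(), seed = 99L)
  for (p in c("alpha[summer]", "alpha[winter]", "b[summer]", "b[winter]")) {
    psd <- sd(fit_full$draws[, p])
    expect_lt(abs(mean(fit_full$draws[, p]) - mean(fit_masked$draws[, p])),
              3 * psd)
  }
})

test_that("relabelling fish and caves permutes nothing but labels", {
  sim <- simulate_scenario(modify_config(preset("paper-small"), n_caves = 3L,
                                         end_year = 2014L,
                                         n_initial_per_cave = 10L,
                                         n_recruits_per_cave = 2L), 17)
  caps <- sim$captures
  # order-preserving relabel: F..... -> G....., C.. -> D..
  caps2 <- caps
  caps2$fish_id <- sub("^F", "G", caps2$fish_id)
  caps2$cave_id <- sub("^C", "D", caps2$cave_id)
  temps2 <- sim$temperatures
  temps2$cave_id <- sub("^C", "D", temps2$cave_id)
  p1 <- build_panel(validate_captures(caps), sim$temperatures)
  p2 <- build_panel(validate_captures(caps2), temps2)
  f1 <- fit_growth(p1, 0.6, mcmc = quick_mcmc(n_iter = 500L,
                                              n_warmup = 200L), seed = 5L)
  f2 <- fit_growth(p2, 0.6, mcmc = quick_mcmc(n_iter = 500L,
                                              n_warmup = 200L), seed = 5L)
  expect_equal(f1$draws, f2$draws)
})

test_that("growth-function curves reflect the fitted distributions", {
  nd <- 400L
  draws <- data.frame(
    `alpha[summer]` = rep(3, nd), `b[summer]` = rep(-0.05, nd),
    `V_alpha_cave[summer]` = rep(1, nd), `V_b_cave[summer]` = rep(4e-4, nd),
    `cov_ab_cave[summer]` = rep(0, nd),
    `V_alpha_year[summer]` = rep(0, nd), `V_b_year[summer]` = rep(0, nd),
    `cov_ab_year[summer]` = rep(0, nd),
    `V_alpha_caveyear[summer]` = rep(0, nd),
    `V_b_caveyear[summer]` = rep(0, nd),
    `cov_ab_caveyear[summer]` = rep(0, nd), check.names = FALSE)
  fit <- make_fake_fit(draws, seasons = "summer")
  cur <- simulate_growth_functions(fit, c(70, 120), n_curves = 300L,
                                   seed = 2L)
  # slopes at the spatial level spread like sqrt(V_b); time level is exact
  sl <- vapply(split(cur[cur$level == "space", ],
                     cur$curve[cur$level == "space"]), function(d) {
    coef(lm(growth_mm_month ~ size_mm, data = d))[2L]
  }, numeric(1L))
  expect_lt(abs(sd(sl) - sqrt(4e-4)), 0.2 * sqrt(4e-4) + 3e-3)
  expect_lt(abs(mean(sl) - (-0.05)), 3 * sd(sl) / sqrt(length(sl)))
  tl <- cur[cur$level == "time", ]
  # zero time-level variance: every curve is the fixed-effect line
  expect_equal(tl$growth_mm_month,
               3 - 0.05 * (tl$size_mm - fit$zbar))
  # zero slope everywhere -> horizontal lines
  draws0 <- draws; draws0[["b[summer]"]] <- 0
  draws0[["V_b_cave[summer]"]] <- 0
  cur0 <- simulate_growth_functions(make_fake_fit(draws0, seasons = "summer"),
                                    c(70, 120), n_curves = 20L, seed = 3L)
  spread <- tapply(cur0$growth_mm_month,
                   paste(cur0$level, cur0$curve), function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
  expect_error(simulate_growth_functions(fit, c(10, 120)), "support")
  expect_error(simulate_growth_functions(fit, levels = "galaxy"),
               "unknown level")
})

test_that("asymptotic size solves the linear growth function", {
  # alpha = 1 mm/day, b = -0.01 per day, centring at 92 mm -> 192 mm
  expect_equal(asymptotic_size_point(1, -0.01, 92), 192)
  expect_equal(asymptotic_size_point(0, -0.01, 92), 92)
  expect_true(is.na(asymptotic_size_point(1, 0, 92)))
  nd <- 10L
  draws <- data.frame(
    `alpha[summer]` = rep(3.4, nd), `alpha[winter]` = rep(0.82, nd),
    `b[summer]` = c(rep(-0.025, 8L), 0, 0.01),
    `b[winter]` = c(rep(-0.002, 8L), 0, 0.01), check.names = FALSE)
  fit <- make_fake_fit(draws, zbar = 92)
  as <- asymptotic_size(fit)
  # annualized: alpha = 2*3.4 + 10*0.82 = 15; b = 2*(-0.025) + 10*(-0.002)
  expect_equal(as$alpha_annual, rep(15, nd))
  expect_equal(as$b_annual[1L], -0.07)
  expect_equal(as$asymptotic_mm[1L], 92 + 15 / 0.07)
  # non-negative slopes reported as undefined, not dropped
  expect_equal(sum(!as$defined), 2L)
  expect_equal(nrow(as), nd)
})

test_that("ablations drop the flagged terms", {
  panel <- small_panel()
  fit_nt <- cached("fit_no_temp",
                   fit_growth(panel, 0.6, ablation = "no_temperature",
                              mcmc = quick_mcmc(), seed = 21L))
  expect_false(any(grepl("alpha_T|T_mean", colnames(fit_nt$draws))))
  fit_ns <- cached("fit_no_season",
                   fit_growth(panel, 0.6, ablation = "no_season",
                              mcmc = quick_mcmc(n_iter = 600L,
                                                n_warmup = 250L), seed = 22L))
  expect_true("alpha[all]" %in% colnames(fit_ns$draws))
  expect_false(any(grepl("\\[summer\\]",
                         grep("^alpha|^b\\[|^V_", colnames(fit_ns$draws),
                              value = TRUE))))
})
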