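SEASONS <- c("summer", "winter")

sw <- function(summer, winter) c(summer = summer, winter = winter)

#' Scenario configuration for the synthetic cave system
#'
#' Describes a simulated world with exactly the statistical structure the
#' state-space model assumes: a seasonal cave-by-year temperature field with
#' varying intercepts, linear size-dependent growth with season-specific fixed
#' effects, temperature effects on intercept and slope, bivariate
#' intercept-slope random effects over cave, year and cave-by-year, a normal
#' initial-size distribution, Gaussian measurement error, and a
#' capture-mark-recapture observation scheme (per-occasion capture
#' probability, steady recruitment, geometric residence via a per-occasion
#' survival probability).
#'
#' Growth parameters are on the per-month growth scale (mm/month for
#' intercept-level quantities, per month per mm for slopes); a season's total
#' growth is the monthly rate times 2 (summer) or 10 (winter). All `sw()`
#' style arguments are length-2 vectors `c(summer=, winter=)`.
#'
#' @param n_caves Number of caves.
#' @param start_year,end_year Study years; occasions run from
#'   `start_month` of `start_year` to August of `end_year`.
#' @param start_month First occasion month (`"August"` mirrors a study that
#'   began late in its first summer).
#' @param temp_mean Seasonal mean water temperature, degrees C.
#' @param temp_V_cave,temp_V_year,temp_V_resid Temperature variance
#'   components (among caves, among years, residual cave-by-year), per season.
#' @param alpha Size-independent growth of the reference-size fish, mm/month.
#' @param b Size-dependence slope, growth change per mm of size, per month.
#' @param alpha_T,b_T Effects of centred temperature on intercept and slope
#'   (per degree C).
#' @param V_alpha_cave,V_alpha_year,V_alpha_caveyear Variances of the random
#'   intercept deviations, (mm/month)^2.
#' @param V_b_cave,V_b_year,V_b_caveyear Variances of the random slope
#'   deviations, (per month)^2.
#' @param cor_cave,cor_year,cor_caveyear Intercept-slope correlation at each
#'   level (shared across seasons).
#' @param V_e Residual growth variance, (mm/month)^2, per season.
#' @param mu0,sigma0_sq Mean and variance of size at first capture, mm, mm^2.
#' @param eta_sq Measurement-error variance, mm^2.
#' @param capture_prob Per-occasion capture probability of an alive fish.
#' @param survival Per-occasion probability an alive fish remains in the
#'   sampled pool (death and permanent emigration are indistinguishable here,
#'   matching a design that never models death versus non-capture).
#' @param n_initial_per_cave,n_recruits_per_cave Fish present at the first
#'   occasion and new fish entering at each later occasion, per cave.
#' @param n_repeat_fish Number of fish receiving duplicate measurements at the
#'   last June occasion (measurement-error design).
#' @param missing_frac Fraction of temperature cells masked missing,
#'   uniformly at random.
#' @return A `scenario_config` list, validated.
#' @export
scenario_config <- function(
    n_caves = 20L,
    start_year = 2012L, end_year = 2019L, start_month = "August",
    temp_mean = sw(6.33, 4.32),
    temp_V_cave = sw(0.22, 0.21),
    temp_V_year = sw(0.15, 0.03),
    temp_V_resid = sw(0.35, 1.03),
    alpha = sw(3.4, 0.82),
    b = sw(-0.05, -0.02),
    alpha_T = sw(0.40, -9.85e-4),
    b_T = sw(4.99e-3, 7.81e-4),
    V_alpha_cave = sw(1.986, 5.032) / c(4, 100),
    V_alpha_year = sw(4.721, 16.593) / c(4, 100),
    V_alpha_caveyear = sw(1.233, 5.901) / c(4, 100),
    V_b_cave = sw(0.001, 0.001) / c(4, 100),
    V_b_year = sw(0.001, 0.001) / c(4, 100),
    V_b_caveyear = sw(0.001, 0.002) / c(4, 100),
    cor_cave = 0, cor_year = 0, cor_caveyear = 0,
    V_e = sw(9.403, 17.539) / c(4, 100),
    mu0 = 75, sigma0_sq = 225,
    eta_sq = 0.6,
    capture_prob = 0.5,
    survival = 0.8,
    n_initial_per_cave = 90L,
    n_recruits_per_cave = 10L,
    n_repeat_fish = 76L,
    missing_frac = 0.22) {
  cfg <- list(
    n_caves = as.integer(n_caves), start_year = as.integer(start_year),
    end_year = as.integer(end_year), start_month = start_month,
    temp_mean = temp_mean, temp_V_cave = temp_V_cave,
    temp_V_year = temp_V_year, temp_V_resid = temp_V_resid,
    alpha = alpha, b = b, alpha_T = alpha_T, b_T = b_T,
    V_alpha_cave = V_alpha_cave, V_alpha_year = V_alpha_year,
    V_alpha_caveyear = V_alpha_caveyear,
    V_b_cave = V_b_cave, V_b_year = V_b_year,
    V_b_caveyear = V_b_caveyear,
    cor_cave = cor_cave, cor_year = cor_year, cor_caveyear = cor_caveyear,
    V_e = V_e, mu0 = mu0, sigma0_sq = sigma0_sq, eta_sq = eta_sq,
    capture_prob = capture_prob, survival = survival,
    n_initial_per_cave = as.integer(n_initial_per_cave),
    n_recruits_per_cave = as.integer(n_recruits_per_cave),
    n_repeat_fish = as.integer(n_repeat_fish),
    missing_frac = missing_frac)
  validate_config(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

validate_config <- function(cfg) {
  vs <- c("temp_V_cave", "temp_V_year", "temp_V_resid", "V_alpha_cave",
          "V_alpha_year", "V_alpha_caveyear", "V_b_cave", "V_b_year",
          "V_b_caveyear", "V_e", "sigma0_sq", "eta_sq")
  for (v in vs) if (any(cfg[[v]] < 0)) stop("variance ", v, " must be >= 0")
  for (v in c("cor_cave", "cor_year", "cor_caveyear")) {
    if (any(abs(cfg[[v]]) > 1)) stop(v, " must lie in [-1, 1]")
  }
  if (cfg$capture_prob <= 0 || cfg$capture_prob > 1) {
    stop("capture_prob must be in (0, 1]")
  }
  if (cfg$survival <= 0 || cfg$survival > 1) stop("survival must be in (0, 1]")
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1) {
    stop("missing_frac must be in [0, 1)")
  }
  if (cfg$end_year <= cfg$start_year) stop("end_year must exceed start_year")
  if (!cfg$start_month %in% MONTH_TAGS) stop("unknown start_month")
  if (cfg$n_caves < 1L || cfg$n_initial_per_cave < 0L ||
      cfg$n_recruits_per_cave < 0L) stop("counts must be non-negative")
  if (cfg$n_initial_per_cave + cfg$n_recruits_per_cave == 0L) {
    stop("config recruits no fish at all")
  }
  invisible(cfg)
}

#' Modify a scenario configuration
#'
#' @param config A `scenario_config`.
#' @param ... Named fields to replace.
#' @export
modify_config <- function(config, ...) {
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(config)) stop("unknown config field: ", nm)
    config[[nm]] <- if (is.numeric(config[[nm]]) &&
                        length(config[[nm]]) == 2L &&
                        length(dots[[nm]]) == 1L) {
      sw(dots[[nm]], dots[[nm]])
    } else dots[[nm]]
  }
  validate_config(config)
  class(config) <- "scenario_config"
  config
}

#' Named scenario presets
#'
#' `"paper-like"` reproduces the scale of the motivating cave system: 20
#' caves, 15 semi-annual occasions (August of year 1 through August of year
#' 8), roughly 3,800 observed fish and 9,200 size observations, 22% of
#' temperature cells missing, measurement-error variance 0.6 mm^2, and growth
#' and temperature parameters at the fitted posterior means for that system.
#' `"paper-small"` keeps the same parameters but scales the design down
#' roughly tenfold (5 caves, 9 occasions) for desk-scale recovery runs.
#' `"null-model"` zeroes every growth and temperature variance component, the
#' size-dependence slope and the temperature effects, with perfect capture
#' and no measurement noise, so trajectories follow the fixed effects
#' exactly.
#'
#' @param name One of `"paper-like"`, `"paper-small"`, `"null-model"`.
#' @return A `scenario_config`.
#' @export
preset <- function(name) {
  switch(name,
    "paper-like" = scenario_config(),
    "paper-small" = scenario_config(
      n_caves = 5L, end_year = 2016L,
      n_initial_per_cave = 30L, n_recruits_per_cave = 4L,
      n_repeat_fish = 30L),
    "null-model" = scenario_config(
      n_caves = 5L, end_year = 2016L,
      n_initial_per_cave = 30L, n_recruits_per_cave = 4L,
      n_repeat_fish = 0L,
      temp_V_cave = sw(0, 0), temp_V_year = sw(0, 0),
      temp_V_resid = sw(0, 0),
      b = sw(0, 0), alpha_T = sw(0, 0), b_T = sw(0, 0),
      V_alpha_cave = sw(0, 0), V_alpha_year = sw(0, 0),
      V_alpha_caveyear = sw(0, 0), V_b_cave = sw(0, 0),
      V_b_year = sw(0, 0), V_b_caveyear = sw(0, 0),
      V_e = sw(0, 0), eta_sq = 0, capture_prob = 1, survival = 1,
      missing_frac = 0),
    stop("unknown preset: ", name))
}

config_occasions <- function(cfg) {
  years <- rep(cfg$start_year:cfg$end_year, each = 2L)
  months <- rep(c("June", "August"), cfg$end_year - cfg$start_year + 1L)
  if (cfg$start_month == "August") {
    years <- years[-1L]; months <- months[-1L]
  }
  occasion_grid(years, months)
}

cave_ids <- function(n) sprintf("C%02d", seq_len(n))

#' Simulate the seasonal temperature field
#'
#' Draws the true cave-by-year-by-season temperature surface
#' `T = a_h + a_hj + a_ht + eps` (seasonal mean plus independent cave and
#' year intercepts plus a cave-by-year residual, all season-specific) over
#' every study year, then masks cells missing uniformly at random at the
#' configured fraction. The mask is independent of the values, matching the
#' missing-at-random assumption the fit relies on.
#'
#' @param config A `scenario_config`.
#' @param seed Integer seed.
#' @return List with `records` (tibble, `NA` = missing) and `truth` (full
#'   values plus the realized effects).
#' @export
simulate_temperature_field <- function(config, seed) {
  set.seed(seed)
  years <- config$start_year:config$end_year
  J <- config$n_caves; Y <- length(years)
  caves <- cave_ids(J)
  a_cave <- sapply(SEASONS, function(h)
    rnorm(J, 0, sqrt(config$temp_V_cave[h])))
  a_year <- sapply(SEASONS, function(h)
    rnorm(Y, 0, sqrt(config$temp_V_year[h])))
  vals <- array(NA_real_, c(J, Y, 2L), dimnames = list(caves, years, SEASONS))
  for (h in SEASONS) {
    eps <- matrix(rnorm(J * Y, 0, sqrt(config$temp_V_resid[h])), J, Y)
    vals[, , h] <- config$temp_mean[h] + outer(a_cave[, h], a_year[, h], "+") +
      eps
  }
  rec <- expand.grid(cave_id = caves, year = years, season = SEASONS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec <- rec[order(rec$cave_id, rec$year, rec$season), ]
  rec$mean_temp_C <- vals[cbind(match(rec$cave_id, caves),
                                match(rec$year, years),
                                match(rec$season, SEASONS))]
  miss <- runif(nrow(rec)) < config$missing_frac
  rec$mean_temp_C[miss] <- NA_real_
  list(records = tibble::as_tibble(rec),
       truth = list(values = vals, a_cave = a_cave, a_year = a_year,
                    years = years, missing = miss))
}

draw_pairs <- function(n, v_a, v_b, rho) {
  # bivariate normal intercept-slope deviations, possibly degenerate
  a <- rnorm(n, 0, sqrt(v_a))
  if (v_a > 0 && v_b > 0 && rho != 0) {
    b <- rho * sqrt(v_b / v_a) * a + rnorm(n, 0, sqrt(v_b * (1 - rho^2)))
  } else {
    b <- rnorm(n, 0, sqrt(v_b))
  }
  cbind(a = a, b = b)
}

#' Simulate the fish population and its capture records
#'
#' Propagates latent fork lengths through the seasonal growth process: a
#' fish's size at the next occasion is its current size plus its per-month
#' growth rate times the months in the season, where the growth rate is the
#' season's fixed intercept and slope, the cave/year/cave-by-year random
#' deviations, the temperature effects evaluated at the cave's true (centred)
#' seasonal temperature, and a residual. Fish enter at the first occasion and
#' by steady recruitment afterwards with initial sizes drawn from the
#' configured normal; each fish stays with the per-occasion survival
#' probability; each alive fish is captured independently with the configured
#' capture probability; observed lengths add Gaussian measurement noise. Fish
#' never captured are not emitted. A configured number of fish captured at the
#' last June occasion receive a duplicate measurement (two independent noisy
#' readings) for the measurement-error design.
#'
#' A propagated size that would fall at or below zero has its residual
#' resampled (the event count is reported in the truth manifest); at realistic
#' parameters this is vanishingly rare.
#'
#' @param config A `scenario_config`.
#' @param temperature_truth `truth` element from
#'   [simulate_temperature_field()] (must cover all study years).
#' @param seed Integer seed.
#' @return List with `captures`, `repeats` (tibbles) and `truth` (a manifest
#'   holding every realized random-effect draw, all true latent sizes, the
#'   alive/captured masks and the config; dimensions match the emitted data).
#' @export
simulate_population <- function(config, temperature_truth, seed) {
  set.seed(seed + 1L)
  occ <- config_occasions(config)
  ints <- season_intervals(occ)
  T <- nrow(occ)
  years <- temperature_truth$years
  if (!all(ints$season_year %in% years)) {
    stop("temperature truth does not cover all interval years")
  }
  J <- config$n_caves
  caves <- cave_ids(J)
  zbar_sim <- config$mu0
  tbar_sim <- mean(config$temp_mean)

  re <- list()
  for (h in SEASONS) {
    re[[h]] <- list(
      cave = draw_pairs(J, config$V_alpha_cave[h], config$V_b_cave[h],
                        config$cor_cave),
      year = draw_pairs(length(years), config$V_alpha_year[h],
                        config$V_b_year[h], config$cor_year),
      caveyear = array(draw_pairs(J * length(years),
                                  config$V_alpha_caveyear[h],
                                  config$V_b_caveyear[h],
                                  config$cor_caveyear),
                       c(J, length(years), 2L)))
  }

  # recruitment: fish enter at occasion 1 (n_initial_per_cave each) and at
  # every later occasion (n_recruits_per_cave each)
  recruit_occ <- c(rep(1L, J * config$n_initial_per_cave),
                   rep(2:T, each = J * config$n_recruits_per_cave))
  recruit_cave <- c(rep(seq_len(J), config$n_initial_per_cave),
                    rep(rep(seq_len(J), each = config$n_recruits_per_cave),
                        T - 1L))
  N <- length(recruit_occ)
  ord <- order(recruit_occ, recruit_cave)
  recruit_occ <- recruit_occ[ord]; recruit_cave <- recruit_cave[ord]
  fish_id <- sprintf("F%05d", seq_len(N))

  # geometric residence: alive from recruitment occasion onwards
  alive <- matrix(FALSE, N, T)
  alive[cbind(seq_len(N), recruit_occ)] <- TRUE
  for (t in seq_len(T - 1L)) {
    cur <- alive[, t]
    stay <- cur & (runif(N) < config$survival)
    alive[, t + 1L] <- alive[, t + 1L] | stay
  }

  Z <- matrix(NA_real_, N, T)
  Z[cbind(seq_len(N), recruit_occ)] <- rnorm(N, config$mu0,
                                             sqrt(config$sigma0_sq))
  n_resampled <- 0L
  for (s in seq_len(T - 1L)) {
    act <- which(alive[, s] & alive[, s + 1L])
    if (!length(act)) next
    h <- ints$season[s]; yi <- match(ints$season_year[s], years)
    jv <- recruit_cave[act]
    Tc <- temperature_truth$values[cbind(jv, yi, match(h, SEASONS))] - tbar_sim
    zc <- Z[act, s] - zbar_sim
    aa <- config$alpha[h] + re[[h]]$cave[jv, 1L] + re[[h]]$year[yi, 1L] +
      re[[h]]$caveyear[cbind(jv, yi, 1L)] + config$alpha_T[h] * Tc
    bb <- config$b[h] + re[[h]]$cave[jv, 2L] + re[[h]]$year[yi, 2L] +
      re[[h]]$caveyear[cbind(jv, yi, 2L)] + config$b_T[h] * Tc
    mu <- aa + bb * zc
    e <- rnorm(length(act), 0, sqrt(config$V_e[h]))
    znew <- Z[act, s] + (mu + e) * ints$n_months[s]
    bad <- which(znew <= 0)
    while (length(bad)) {
      n_resampled <- n_resampled + length(bad)
      e[bad] <- rnorm(length(bad), 0, sqrt(config$V_e[h]))
      znew[bad] <- Z[act[bad], s] + (mu[bad] + e[bad]) * ints$n_months[s]
      bad <- which(znew <= 0)
    }
    Z[act, s + 1L] <- znew
  }

  captured <- alive & matrix(runif(N * T) < config$capture_prob, N, T)
  obs_noise <- matrix(rnorm(N * T, 0, sqrt(config$eta_sq)), N, T)
  Zobs <- Z + obs_noise

  idx <- which(captured, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  captures <- tibble::tibble(
    fish_id = fish_id[idx[, 1L]],
    cave_id = caves[recruit_cave[idx[, 1L]]],
    year = occ$year[idx[, 2L]],
    month = occ$month[idx[, 2L]],
    fork_length_mm = round(Zobs[idx]),
    capture_date = as.Date(NA))
  # fish below the tagging threshold are not marked or measured
  keep <- captures$fork_length_mm >= 45
  captures <- captures[keep, ]

  # duplicate measurements at the last June occasion
  junes <- which(occ$month == "June")
  repeats <- tibble::tibble(fish_id = character(), replicate_index = integer(),
                            fork_length_mm = numeric())
  if (config$n_repeat_fish > 0L && length(junes)) {
    ro <- max(junes)
    cand <- which(captured[, ro])
    cand <- cand[seq_len(min(length(cand), config$n_repeat_fish))]
    if (length(cand)) {
      m1 <- Z[cand, ro] + rnorm(length(cand), 0, sqrt(config$eta_sq))
      m2 <- Z[cand, ro] + rnorm(length(cand), 0, sqrt(config$eta_sq))
      repeats <- tibble::tibble(
        fish_id = rep(fish_id[cand], 2L),
        replicate_index = rep(1:2, each = length(cand)),
        fork_length_mm = round(c(m1, m2), 1))
      repeats <- repeats[order(repeats$fish_id, repeats$replicate_index), ]
    }
  }

  truth <- list(
    config = config, occasions = occ, fish_id = fish_id,
    cave = caves[recruit_cave], recruit_occasion = recruit_occ,
    latent_size = Z, alive = alive, captured = captured,
    random_effects = re, temperature = temperature_truth,
    zbar_sim = zbar_sim, tbar_sim = tbar_sim,
    n_resampled = n_resampled)
  list(captures = captures, repeats = repeats, truth = truth)
}

#' Simulate a complete scenario
#'
#' Temperature field plus population in one call.
#' @inheritParams simulate_population
#' @param seed Integer seed controlling everything.
#' @return List with `captures`, `temperatures`, `repeats`, `truth`.
#' @export
simulate_scenario <- function(config, seed) {
  tf <- simulate_temperature_field(config, seed)
  pop <- simulate_population(config, tf$truth, seed)
  list(captures = pop$captures, temperatures = tf$records,
       repeats = pop$repeats, truth = pop$truth)
}

#' Write a simulated scenario to disk
#'
#' Emits `captures.csv`, `temperatures.csv`, `repeats.csv` and `truth.json`
#' (the truth manifest, for parameter-recovery tests). Output is
#' byte-identical for identical seeds.
#'
#' @param sim Output of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_captures(sim$captures, file.path(dir, "captures.csv"))
  write_temperatures(sim$temperatures, file.path(dir, "temperatures.csv"))
  write_repeats(sim$repeats, file.path(dir, "repeats.csv"))
  tr <- sim$truth
  out <- list(
    config = unclass(tr$config),
    n_fish_total = length(tr$fish_id),
    n_resampled = tr$n_resampled,
    zbar_sim = tr$zbar_sim, tbar_sim = tr$tbar_sim,
    latent_size = tr$latent_size,
    random_effects = tr$random_effects,
    temperature_values = tr$temperature$values)
  jsonlite::write_json(out, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = FALSE)
  invisible(dir)
}
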