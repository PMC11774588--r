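# Joint Bayesian state-space fit of size-dependent seasonal growth.
#
# Process model: z[i,t+1] = z[i,t] + g(z[i,t]) * D, with the growth function
# g linear in centred size, season-specific fixed effects, centred-temperature
# effects on intercept and slope, and bivariate intercept-slope random effects
# over cave, year and cave-by-year (all season-specific). Observation model:
# measured fork length = latent size + N(0, eta^2). The seasonal temperature
# model is embedded so missing covariate cells are integrated over. All full
# conditionals are Gaussian or inverse-gamma/inverse-Wishart, so the sampler
# is a pure Gibbs scheme; latent sizes are updated in a red-black sweep over
# occasion parity (cells of equal parity are conditionally independent).
#
# Internal growth scale is mm per month, where one month is the season's
# nominal day span divided by its month count (summer 67/2, winter 298/10
# days); an interval of D days contributes D / month_days "months".

SEASON_MONTH_DAYS <- c(summer = 67 / 2, winter = 298 / 10)

#' Nominal days per month within each season
#'
#' Summer (16 June to 22 August) spans 67 days over 2 months; winter spans
#' 298 days over 10 months. Monthly growth rates times the season's month
#' count give seasonal totals exactly.
#' @export
season_month_days <- function() SEASON_MONTH_DAYS

gsum <- function(x, g, ng) {
  out <- numeric(ng)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# Assemble interval rows and index maps from a panel
prep_growth_data <- function(panel, no_season = FALSE) {
  occ <- panel$occasions; T <- nrow(occ); ints <- panel$intervals
  fish <- panel$fish; n <- nrow(fish)
  J <- length(panel$caves)
  jfish <- match(fish$cave_id, panel$caves)
  month_days_step <- ints$n_days / ints$n_months

  syk <- paste(ints$season, ints$season_year)
  sy_levels <- unique(syk)
  sy_step <- match(syk, sy_levels)
  n_sy <- length(sy_levels)
  sy_season <- match(ints$season[match(sy_levels, syk)], SEASONS)

  tg <- panel$temperatures
  cell_step_cave <- function(step, cave_chr) {
    match(paste(cave_chr, ints$season[step], ints$season_year[step]),
          paste(tg$cave_id, tg$season, tg$year))
  }

  # interval rows
  steps <- fish$last_occasion - fish$first_occasion
  rf <- rep(seq_len(n), steps)
  rs <- unlist(lapply(seq_len(n), function(i) {
    if (steps[i] > 0L) fish$first_occasion[i]:(fish$last_occasion[i] - 1L)
    else integer()
  }), use.names = FALSE)
  R <- length(rf)
  h_true <- match(ints$season[rs], SEASONS)
  row <- list(
    fish = rf, step = rs,
    h = if (no_season) rep(1L, R) else h_true,
    months = panel$days[cbind(rf, rs)] / month_days_step[rs],
    cave = jfish[rf],
    sy = sy_step[rs],
    cell = cell_step_cave(rs, fish$cave_id[rf]))
  if (anyNA(row$cell)) {
    stop("temperature grid lacks a cave x season-year cell required by the ",
         "capture records (missing values are allowed, missing rows are not)")
  }
  n_seas <- if (no_season) 1L else 2L
  row$gc <- (row$h - 1L) * J + row$cave
  row$gy <- row$sy
  row$gcy <- (row$sy - 1L) * J + row$cave
  gc_season <- rep(seq_len(n_seas), each = J)
  gy_season <- if (no_season) rep(1L, n_sy) else sy_season
  gcy_season <- rep(gy_season, each = J)

  # latent support cells
  ci <- rep(seq_len(n), fish$last_occasion - fish$first_occasion + 1L)
  ct <- unlist(lapply(seq_len(n), function(i) {
    fish$first_occasion[i]:fish$last_occasion[i]
  }), use.names = FALSE)
  ncell <- length(ci)
  cell_id <- matrix(NA_integer_, n, T)
  cell_id[cbind(ci, ct)] <- seq_len(ncell)
  row_id <- matrix(NA_integer_, n, max(T - 1L, 1L))
  row_id[cbind(rf, rs)] <- seq_len(R)

  list(row = row, R = R, n_seasons = n_seas, J = J, n_sy = n_sy,
       sy_levels = sy_levels, gc_season = gc_season, gy_season = gy_season,
       gcy_season = gcy_season, n_gc = n_seas * J, n_gcy = n_sy * J,
       cells = list(fish = ci, occ = ct), n_cells = ncell,
       cell_id = cell_id, row_id = row_id, jfish = jfish, T = T,
       month_days_step = month_days_step)
}

resolve_fixed <- function(fixed, n_seasons) {
  # user-fixed parameters: values recycled over seasons; NULL = free
  get2 <- function(nm) {
    v <- fixed[[nm]]
    if (is.null(v)) NULL else rep(as.numeric(v), length.out = n_seasons)
  }
  list(b = get2("b"), alpha_T = get2("alpha_T"), b_T = get2("b_T"),
       V_e = get2("V_e"),
       drop_level = vapply(c("cave", "year", "caveyear"), function(lv) {
         is_zero <- function(v) !is.null(v) && is.numeric(v) && all(v == 0)
         va <- fixed[[paste0("V_alpha_", lv)]]
         vb <- fixed[[paste0("V_b_", lv)]]
         if ((!is.null(va) && !is_zero(va)) || (!is.null(vb) && !is_zero(vb))) {
           stop("random-effect variances can only be fixed at 0")
         }
         c(int = is_zero(va), slo = is_zero(vb))
       }, logical(2L)))
}

#' Fit the joint state-space growth model
#'
#' Runs the Gibbs sampler for the integrated model: latent fork-length
#' trajectories over each fish's support (first to last capture), the linear
#' size-dependent growth process with season-specific fixed effects and
#' temperature effects, bivariate intercept-slope random effects over cave,
#' year and cave-by-year, the initial-size distribution, the measurement
#' model with known error variance, and the embedded seasonal temperature
#' model with augmentation of missing covariate cells.
#'
#' @param panel A `growth_panel` from [build_panel()].
#' @param eta_sq Measurement-error variance (mm^2), either a number or a
#'   `measurement_error_estimate`; it is treated as known (estimated
#'   separately from repeat measures, not jointly).
#' @param priors A [priors_config()].
#' @param mcmc An [mcmc_config()].
#' @param seed Integer seed.
#' @param ablation Character subset of `c("no_temperature", "no_season")`:
#'   drop the temperature terms (and the embedded temperature model), or
#'   collapse the two seasons into one shared set of effects.
#' @param fixed Named list of parameters to hold fixed rather than sample:
#'   `b`, `alpha_T`, `b_T`, `V_e` at given values, and random-effect
#'   variances `V_alpha_cave`, `V_b_cave`, `V_alpha_year`, `V_b_year`,
#'   `V_alpha_caveyear`, `V_b_caveyear` at exactly 0 (dropping that
#'   deviation). Mainly for degenerate-design checks.
#' @param rhat_threshold Convergence threshold on the split-chain statistic.
#' @return A `growth_fit` with scalar parameter draws (growth and
#'   temperature), latent-size draws per supported fish-occasion, augmented
#'   temperature draws per missing cell, posterior-mean random effects,
#'   convergence diagnostics and a `converged` flag.
#' @export
fit_growth <- function(panel, eta_sq, priors = priors_config(),
                       mcmc = mcmc_config(), seed = 1L,
                       ablation = character(), fixed = list(),
                       rhat_threshold = 1.05) {
  if (missing(eta_sq) || is.null(eta_sq)) {
    stop("eta_sq is required; estimate it from repeat measures with ",
         "estimate_measurement_error()")
  }
  if (inherits(eta_sq, "measurement_error_estimate")) eta_sq <- eta_sq$eta_sq
  stopifnot(eta_sq >= 0)
  stopifnot(all(ablation %in% c("no_temperature", "no_season")))
  no_temp <- "no_temperature" %in% ablation
  no_season <- "no_season" %in% ablation

  gd <- prep_growth_data(panel, no_season)
  fx <- resolve_fixed(fixed, gd$n_seasons)
  seasons_out <- if (no_season) "all" else SEASONS

  lv_active <- c(cave = !all(fx$drop_level[, "cave"]),
                 year = !all(fx$drop_level[, "year"]),
                 caveyear = !all(fx$drop_level[, "caveyear"]))
  if (lv_active["cave"] && gd$J < 2L) {
    stop("need >= 2 caves for cave-level variance components ",
         "(or fix them to 0)")
  }
  n_years <- length(unique(panel$intervals$season_year))
  if (lv_active["year"] && n_years < 2L) {
    stop("need >= 2 years for year-level variance components ",
         "(or fix them to 0)")
  }

  row <- gd$row; R <- gd$R
  if (R == 0L) stop("panel contains no growth intervals")
  obs <- panel$obs
  zbar <- panel$zbar; tbar <- panel$tbar
  pin_obs <- eta_sq < 1e-12

  # temperature cells
  tc_prep <- prep_temp_cells(panel$temperatures)
  if (!no_temp) {
    for (h in seq_along(SEASONS)) {
      if (!any(tc_prep$season == h & tc_prep$observed)) {
        stop("season ", SEASONS[h], " has no observed temperature cells")
      }
    }
  }

  free_b <- is.null(fx$b); free_at <- is.null(fx$alpha_T) && !no_temp
  free_bt <- is.null(fx$b_T) && !no_temp
  bval_fix <- if (free_b) NULL else fx$b
  atval_fix <- if (no_temp) rep(0, gd$n_seasons) else fx$alpha_T
  btval_fix <- if (no_temp) rep(0, gd$n_seasons) else fx$b_T

  par_names <- c(
    paste0("alpha[", seasons_out, "]"), paste0("b[", seasons_out, "]"),
    if (!no_temp) c(paste0("alpha_T[", seasons_out, "]"),
                    paste0("b_T[", seasons_out, "]")),
    paste0("V_alpha_cave[", seasons_out, "]"),
    paste0("V_b_cave[", seasons_out, "]"),
    paste0("cov_ab_cave[", seasons_out, "]"),
    paste0("V_alpha_year[", seasons_out, "]"),
    paste0("V_b_year[", seasons_out, "]"),
    paste0("cov_ab_year[", seasons_out, "]"),
    paste0("V_alpha_caveyear[", seasons_out, "]"),
    paste0("V_b_caveyear[", seasons_out, "]"),
    paste0("cov_ab_caveyear[", seasons_out, "]"),
    paste0("V_e[", seasons_out, "]"), "mu0", "sigma0_sq",
    if (!no_temp) c(paste0("T_mean[", SEASONS, "]"),
                    paste0("T_V_cave[", SEASONS, "]"),
                    paste0("T_V_year[", SEASONS, "]"),
                    paste0("T_V_resid[", SEASONS, "]")))

  n_keep <- (mcmc$n_iter - mcmc$n_warmup) %/% mcmc$thin
  total_keep <- n_keep * mcmc$n_chains
  draws <- matrix(NA_real_, total_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  chain_id <- integer(total_keep)
  z_draws <- if (mcmc$save_latent) {
    matrix(NA_real_, total_keep, gd$n_cells)
  } else NULL
  miss_cells <- which(!tc_prep$observed)
  aug_names <- if (length(miss_cells)) {
    sprintf("T_aug[%s,%d,%s]", tc_prep$caves[tc_prep$cave[miss_cells]],
            tc_prep$years[tc_prep$year[miss_cells]],
            SEASONS[tc_prep$season[miss_cells]])
  } else character()
  aug_draws <- if (!no_temp) {
    matrix(NA_real_, total_keep, length(miss_cells),
           dimnames = list(NULL, aug_names))
  } else NULL
  ranef_sum <- list(cave = matrix(0, gd$n_gc, 2L),
                    year = matrix(0, gd$n_sy, 2L),
                    caveyear = matrix(0, gd$n_gcy, 2L))

  fish <- panel$fish; n <- nrow(fish)
  first_occ <- fish$first_occasion
  ci <- gd$cells$fish; ct <- gd$cells$occ
  cell_obs <- obs[cbind(ci, ct)]
  cell_has_obs <- !is.na(cell_obs)
  cell_is_first <- ct == first_occ[ci]
  rb_of_cell <- ifelse(ct > first_occ[ci],
                       gd$row_id[cbind(ci, pmax(ct - 1L, 1L))], NA_integer_)
  rf_of_cell <- ifelse(ct < fish$last_occasion[ci],
                       gd$row_id[cbind(ci, pmin(ct, ncol(gd$row_id)))],
                       NA_integer_)
  sample_cell <- if (pin_obs) !cell_has_obs else rep(TRUE, gd$n_cells)
  parity_sets <- lapply(0:1, function(p) {
    which(ct %% 2L == p & sample_cell)
  })

  w_row_of <- function(Ve) 1 / Ve[row$h]

  old <- save_rng_state(); on.exit(restore_rng_state(old))
  krow <- 0L
  for (chn in seq_len(mcmc$n_chains)) {
    set.seed(seed + 7907L * (chn - 1L))
    # --- initial state ---
    z <- obs
    for (i in which(fish$last_occasion - first_occ + 1L >
                    rowSums(!is.na(obs)))) {
      sup <- first_occ[i]:fish$last_occasion[i]
      zi <- obs[i, sup]
      ok <- which(!is.na(zi))
      z[i, sup] <- stats::approx(ok, zi[ok], xout = seq_along(sup))$y
    }
    tvals <- tc_prep$value
    tstates <- NULL
    if (!no_temp) {
      tstates <- lapply(seq_along(SEASONS), function(h) {
        init_temp_state(tc_prep$value[tc_prep$season == h & tc_prep$observed],
                        length(tc_prep$caves), length(tc_prep$years))
      })
      for (h in seq_along(SEASONS)) {
        sel <- tc_prep$season == h & !tc_prep$observed
        tvals[sel] <- tstates[[h]]$a
      }
    }
    tc_row <- if (no_temp) numeric(R) else tvals[row$cell] - tbar

    y <- (z[cbind(row$fish, row$step + 1L)] - z[cbind(row$fish, row$step)]) /
      row$months
    alpha <- as.numeric(tapply(y, row$h, mean))[seq_len(gd$n_seasons)]
    alpha[is.na(alpha)] <- 0
    bvalv <- if (free_b) rep(0, gd$n_seasons) else bval_fix
    atv <- if (free_at) rep(0, gd$n_seasons) else
      (if (is.null(atval_fix)) rep(0, gd$n_seasons) else atval_fix)
    btv <- if (free_bt) rep(0, gd$n_seasons) else
      (if (is.null(btval_fix)) rep(0, gd$n_seasons) else btval_fix)
    Ac <- matrix(0, gd$n_gc, 2L)
    Ay <- matrix(0, gd$n_sy, 2L)
    Acy <- matrix(0, gd$n_gcy, 2L)
    Sig <- replicate(3L, replicate(gd$n_seasons,
                                   diag(c(1, 1e-3)), simplify = FALSE),
                     simplify = FALSE)
    names(Sig) <- c("cave", "year", "caveyear")
    aux_S <- lapply(1:3, function(i)
      replicate(gd$n_seasons, c(1, 1), simplify = FALSE))
    names(aux_S) <- names(Sig)
    Ve <- if (is.null(fx$V_e)) {
      v <- as.numeric(tapply(y, row$h, var))[seq_len(gd$n_seasons)]
      pmax(ifelse(is.na(v), 1, v), 1e-3)
    } else fx$V_e
    aux_e <- rep(1, gd$n_seasons)
    zfirst <- z[cbind(seq_len(n), first_occ)]
    mu0 <- mean(zfirst); sig0 <- max(var(zfirst), 1)
    if (is.na(sig0)) sig0 <- 100
    aux_s0 <- 1

    drop <- fx$drop_level
    lvl_free <- function(lv) c(int = !drop["int", lv], slo = !drop["slo", lv])

    kept <- 0L
    for (it in seq_len(mcmc$n_iter)) {
      w <- w_row_of(Ve)

      # per-row intercept/slope totals (centred-temperature effects included)
      arow <- alpha[row$h] + Ac[row$gc, 1L] + Ay[row$gy, 1L] +
        Acy[row$gcy, 1L] + atv[row$h] * tc_row
      brow <- bvalv[row$h] + Ac[row$gc, 2L] + Ay[row$gy, 2L] +
        Acy[row$gcy, 2L] + btv[row$h] * tc_row

      # --- latent sizes, red-black over occasion parity ---
      if (length(parity_sets[[1L]]) || length(parity_sets[[2L]])) {
        for (pp in 1:2) {
          cs <- parity_sets[[pp]]
          if (!length(cs)) next
          prec <- numeric(length(cs)); num <- numeric(length(cs))
          if (!pin_obs) {
            hob <- cell_has_obs[cs]
            prec[hob] <- prec[hob] + 1 / eta_sq
            num[hob] <- num[hob] + cell_obs[cs][hob] / eta_sq
          }
          isf <- cell_is_first[cs]
          prec[isf] <- prec[isf] + 1 / sig0
          num[isf] <- num[isf] + mu0 / sig0
          rb <- rb_of_cell[cs]; hasb <- !is.na(rb)
          if (any(hasb)) {
            r <- rb[hasb]
            zprev <- z[cbind(row$fish[r], row$step[r])]
            mn <- zprev + (arow[r] + brow[r] * (zprev - zbar)) * row$months[r]
            vr <- Ve[row$h[r]] * row$months[r]^2
            prec[hasb] <- prec[hasb] + 1 / vr
            num[hasb] <- num[hasb] + mn / vr
          }
          rfv <- rf_of_cell[cs]; hasf <- !is.na(rfv)
          if (any(hasf)) {
            r <- rfv[hasf]
            znext <- z[cbind(row$fish[r], row$step[r] + 1L)]
            cc <- 1 + brow[r] * row$months[r]
            dd <- znext - (arow[r] - brow[r] * zbar) * row$months[r]
            vr <- Ve[row$h[r]] * row$months[r]^2
            prec[hasf] <- prec[hasf] + cc^2 / vr
            num[hasf] <- num[hasf] + cc * dd / vr
          }
          z[cbind(ci[cs], ct[cs])] <- rnorm(length(cs), num / prec,
                                            sqrt(1 / prec))
        }
      }

      zc <- z[cbind(row$fish, row$step)] - zbar
      y <- (z[cbind(row$fish, row$step + 1L)] -
              z[cbind(row$fish, row$step)]) / row$months

      # --- fixed effects (joint weighted-normal update) ---
      re_part <- Ac[row$gc, 1L] + Ay[row$gy, 1L] + Acy[row$gcy, 1L] +
        (Ac[row$gc, 2L] + Ay[row$gy, 2L] + Acy[row$gcy, 2L]) * zc
      cols <- list()
      for (h in seq_len(gd$n_seasons)) {
        ind <- as.numeric(row$h == h)
        cols[[paste0("a", h)]] <- ind
        if (free_b) cols[[paste0("b", h)]] <- ind * zc
        if (free_at) cols[[paste0("at", h)]] <- ind * tc_row
        if (free_bt) cols[[paste0("bt", h)]] <- ind * zc * tc_row
      }
      X <- do.call(cbind, cols)
      offset <- re_part
      if (!free_b) offset <- offset + bval_fix[row$h] * zc
      if (!free_at && !is.null(atval_fix)) {
        offset <- offset + atval_fix[row$h] * tc_row
      }
      if (!free_bt && !is.null(btval_fix)) {
        offset <- offset + btval_fix[row$h] * zc * tc_row
      }
      yr <- y - offset
      sw_ <- sqrt(w)
      XtWX <- crossprod(X * sw_)
      XtWy <- crossprod(X, w * yr)
      Vpost <- solve(XtWX + diag(1 / priors$sd_fixed^2, ncol(X)))
      Vpost <- (Vpost + t(Vpost)) / 2
      beta <- rmvnorm1(Vpost %*% XtWy, Vpost)
      k <- 0L
      for (h in seq_len(gd$n_seasons)) {
        alpha[h] <- beta[k + 1L]; k <- k + 1L
        if (free_b) { bvalv[h] <- beta[k + 1L]; k <- k + 1L }
        if (free_at) { atv[h] <- beta[k + 1L]; k <- k + 1L }
        if (free_bt) { btv[h] <- beta[k + 1L]; k <- k + 1L }
      }

      # --- random effects per level ---
      fit_tot <- alpha[row$h] + atv[row$h] * tc_row +
        (bvalv[row$h] + btv[row$h] * tc_row) * zc +
        Ac[row$gc, 1L] + Ay[row$gy, 1L] + Acy[row$gcy, 1L] +
        (Ac[row$gc, 2L] + Ay[row$gy, 2L] + Acy[row$gcy, 2L]) * zc

      update_level <- function(U, g, ng, g_season, lv) {
        free <- lvl_free(lv)
        if (!any(free)) return(U)
        r <- y - fit_tot + U[g, 1L] + U[g, 2L] * zc
        sw_g <- gsum(w, g, ng); swx <- gsum(w * zc, g, ng)
        swxx <- gsum(w * zc^2, g, ng)
        swy <- gsum(w * r, g, ng); swxy <- gsum(w * zc * r, g, ng)
        for (h in seq_len(gd$n_seasons)) {
          sel <- which(g_season == h)
          if (!length(sel)) next
          if (all(free)) {
            Om <- solve(Sig[[lv]][[h]])
            U[sel, ] <- draw_pairs_posterior(sw_g[sel], swx[sel], swxx[sel],
                                             swy[sel], swxy[sel], Om)
          } else if (free["int"]) {
            pv <- 1 / Sig[[lv]][[h]][1L, 1L] + sw_g[sel]
            U[sel, 1L] <- rnorm(length(sel), swy[sel] / pv, sqrt(1 / pv))
          } else {
            pv <- 1 / Sig[[lv]][[h]][2L, 2L] + swxx[sel]
            U[sel, 2L] <- rnorm(length(sel), swxy[sel] / pv, sqrt(1 / pv))
          }
        }
        U
      }

      if (lv_active["cave"]) {
        Ac <- update_level(Ac, row$gc, gd$n_gc, gd$gc_season, "cave")
        fit_tot <- alpha[row$h] + atv[row$h] * tc_row +
          (bvalv[row$h] + btv[row$h] * tc_row) * zc +
          Ac[row$gc, 1L] + Ay[row$gy, 1L] + Acy[row$gcy, 1L] +
          (Ac[row$gc, 2L] + Ay[row$gy, 2L] + Acy[row$gcy, 2L]) * zc
      }
      if (lv_active["year"]) {
        Ay <- update_level(Ay, row$gy, gd$n_sy, gd$gy_season, "year")
        fit_tot <- alpha[row$h] + atv[row$h] * tc_row +
          (bvalv[row$h] + btv[row$h] * tc_row) * zc +
          Ac[row$gc, 1L] + Ay[row$gy, 1L] + Acy[row$gcy, 1L] +
          (Ac[row$gc, 2L] + Ay[row$gy, 2L] + Acy[row$gcy, 2L]) * zc
      }
      if (lv_active["caveyear"]) {
        Acy <- update_level(Acy, row$gcy, gd$n_gcy, gd$gcy_season, "caveyear")
        fit_tot <- alpha[row$h] + atv[row$h] * tc_row +
          (bvalv[row$h] + btv[row$h] * tc_row) * zc +
          Ac[row$gc, 1L] + Ay[row$gy, 1L] + Acy[row$gcy, 1L] +
          (Ac[row$gc, 2L] + Ay[row$gy, 2L] + Acy[row$gcy, 2L]) * zc
      }

      # --- recentring translation moves ---
      # fixed intercepts/slopes trade off against the mean of each level's
      # deviations; sampling the shift from its full conditional (likelihood
      # is invariant, only the priors constrain it) removes the ridge
      for (lvnm in c("cave", "year", "caveyear")) {
        if (!lv_active[lvnm]) next
        U <- switch(lvnm, cave = Ac, year = Ay, caveyear = Acy)
        gs <- switch(lvnm, cave = gd$gc_season, year = gd$gy_season,
                     caveyear = gd$gcy_season)
        free <- lvl_free(lvnm)
        for (h in seq_len(gd$n_seasons)) {
          sel <- which(gs == h)
          if (!length(sel)) next
          Om <- solve(Sig[[lvnm]][[h]])
          ng <- length(sel)
          S1 <- sum(U[sel, 1L]); S2 <- sum(U[sel, 2L])
          if (free["int"]) {
            pv <- ng * Om[1L, 1L] + 1 / priors$sd_fixed^2
            dd <- rnorm(1L, (Om[1L, 1L] * S1 + Om[1L, 2L] * S2 -
                               alpha[h] / priors$sd_fixed^2) / pv,
                        sqrt(1 / pv))
            alpha[h] <- alpha[h] + dd
            U[sel, 1L] <- U[sel, 1L] - dd
            S1 <- S1 - ng * dd
          }
          if (free["slo"] && free_b) {
            pv <- ng * Om[2L, 2L] + 1 / priors$sd_fixed^2
            dd <- rnorm(1L, (Om[2L, 2L] * S2 + Om[1L, 2L] * S1 -
                               bvalv[h] / priors$sd_fixed^2) / pv,
                        sqrt(1 / pv))
            bvalv[h] <- bvalv[h] + dd
            U[sel, 2L] <- U[sel, 2L] - dd
          }
        }
        switch(lvnm, cave = Ac <- U, year = Ay <- U, caveyear = Acy <- U)
      }

      # --- level covariances (Huang-Wand inverse-Wishart) ---
      upd_cov <- function(U, g_season, lv) {
        free <- lvl_free(lv)
        for (h in seq_len(gd$n_seasons)) {
          sel <- which(g_season == h)
          if (!length(sel)) next
          if (all(free)) {
            S <- crossprod(U[sel, , drop = FALSE])
            hw <- update_hw_cov(S, length(sel), aux_S[[lv]][[h]], 2,
                                c(priors$scale_alpha, priors$scale_b))
            Sig[[lv]][[h]] <<- hw$Sigma
            aux_S[[lv]][[h]] <<- hw$aux
          } else if (any(free)) {
            k2 <- if (free["int"]) 1L else 2L
            sc <- if (free["int"]) priors$scale_alpha else priors$scale_b
            up <- update_halft_var(sum(U[sel, k2]^2), length(sel),
                                   aux_S[[lv]][[h]][k2], priors$halft_df, sc)
            Sig[[lv]][[h]][k2, k2] <<- up$var
            aux_S[[lv]][[h]][k2] <<- up$aux
          }
        }
      }
      if (lv_active["cave"]) upd_cov(Ac, gd$gc_season, "cave")
      if (lv_active["year"]) upd_cov(Ay, gd$gy_season, "year")
      if (lv_active["caveyear"]) upd_cov(Acy, gd$gcy_season, "caveyear")

      # --- residual growth variance per season ---
      if (is.null(fx$V_e)) {
        res <- y - fit_tot
        for (h in seq_len(gd$n_seasons)) {
          sel <- row$h == h
          up <- update_halft_var(sum(res[sel]^2), sum(sel), aux_e[h],
                                 priors$halft_df, priors$scale_e)
          Ve[h] <- up$var; aux_e[h] <- up$aux
        }
      }

      # --- initial-size distribution ---
      zfirst <- z[cbind(seq_len(n), first_occ)]
      pr <- 1 / priors$sd_mu0^2 + n / sig0
      mu0 <- rnorm(1L, (sum(zfirst) / sig0) / pr, sqrt(1 / pr))
      up <- update_halft_var(sum((zfirst - mu0)^2), n, aux_s0,
                             priors$halft_df, priors$scale_sigma0)
      sig0 <- up$var; aux_s0 <- up$aux

      # --- embedded temperature model ---
      if (!no_temp) {
        # growth-side information about each cell: y = (base) + k * Tc + e
        krowv <- atv[row$h] + btv[row$h] * zc
        base <- fit_tot - krowv * tc_row
        rT <- y - base
        prec_g <- gsum(krowv^2 * w, row$cell, tc_prep$n)
        num_g <- gsum(krowv * rT * w, row$cell, tc_prep$n) + tbar * prec_g
        for (h in seq_along(SEASONS)) {
          sel <- which(tc_prep$season == h)
          st <- tstates[[h]]
          mu_cells <- st$a + st$u_cave[tc_prep$cave[sel]] +
            st$u_year[tc_prep$year[sel]]
          obs_h <- tc_prep$observed[sel]
          prec <- 1 / st$V_resid + prec_g[sel] +
            ifelse(obs_h, 1 / priors$temp_obs_var, 0)
          num <- mu_cells / st$V_resid + num_g[sel] +
            ifelse(obs_h, tc_prep$value[sel] / priors$temp_obs_var, 0)
          tvals[sel] <- rnorm(length(sel), num / prec, sqrt(1 / prec))
          tstates[[h]] <- update_temp_params(st, tvals[sel],
                                             tc_prep$cave[sel],
                                             tc_prep$year[sel], priors)
        }
        tc_row <- tvals[row$cell] - tbar
      }

      # --- store ---
      if (it > mcmc$n_warmup && (it - mcmc$n_warmup) %% mcmc$thin == 0L) {
        kept <- kept + 1L
        rr2 <- krow + kept
        covs <- unlist(lapply(c("cave", "year", "caveyear"), function(lv) {
          m <- vapply(seq_len(gd$n_seasons), function(h) {
            s <- Sig[[lv]][[h]]
            c(s[1L, 1L], s[2L, 2L], s[1L, 2L])
          }, numeric(3L))
          m <- matrix(m, nrow = 3L)
          # components fixed at zero report zero, not their placeholder init
          if (drop["int", lv]) m[c(1L, 3L), ] <- 0
          if (drop["slo", lv]) m[c(2L, 3L), ] <- 0
          c(m[1L, ], m[2L, ], m[3L, ])
        }))
        vals <- c(alpha, bvalv,
                  if (!no_temp) c(atv, btv),
                  covs, Ve, mu0, sig0,
                  if (!no_temp) c(
                    vapply(tstates, `[[`, numeric(1L), "a"),
                    vapply(tstates, `[[`, numeric(1L), "V_cave"),
                    vapply(tstates, `[[`, numeric(1L), "V_year"),
                    vapply(tstates, `[[`, numeric(1L), "V_resid")))
        draws[rr2, ] <- vals
        chain_id[rr2] <- chn
        if (!is.null(z_draws)) z_draws[rr2, ] <- z[cbind(ci, ct)]
        if (!is.null(aug_draws) && length(miss_cells)) {
          aug_draws[rr2, ] <- tvals[miss_cells]
        }
        ranef_sum$cave <- ranef_sum$cave + Ac
        ranef_sum$year <- ranef_sum$year + Ay
        ranef_sum$caveyear <- ranef_sum$caveyear + Acy
      }
    }
    krow <- krow + kept
  }

  summary <- summarize_draw_matrix(draws, chain_id)
  converged <- all(summary$rhat < rhat_threshold, na.rm = TRUE)
  fit <- structure(list(
    draws = draws, chain = chain_id,
    z_draws = z_draws,
    z_cells = tibble::tibble(fish_id = fish$fish_id[ci], occasion = ct,
                             fish_index = ci),
    aug_draws = aug_draws,
    ranef_mean = lapply(ranef_sum, function(m) m / total_keep),
    seasons = seasons_out, eta_sq = eta_sq, zbar = zbar, tbar = tbar,
    obs_range = range(panel$obs, na.rm = TRUE),
    ablation = ablation, fixed = fixed,
    group_info = list(J = gd$J, n_sy = gd$n_sy, sy_levels = gd$sy_levels,
                      caves = panel$caves),
    summary = summary, converged = converged,
    rhat_threshold = rhat_threshold,
    seed = seed, mcmc = mcmc, priors = priors),
    class = "growth_fit")
  fit
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("growth_fit (", paste(x$seasons, collapse = "/"), " seasons",
      if (length(x$ablation)) paste0("; ablation: ",
                                     paste(x$ablation, collapse = ", ")),
      ")\n", sep = "")
  cat("  chains:", x$mcmc$n_chains, "| kept draws:", nrow(x$draws),
      "| converged:", x$converged, "\n")
  print(x$summary, n = 20)
  invisible(x)
}

#' Posterior predictive summary of a fish's size at an occasion
#'
#' Summarises the posterior of the latent size plus measurement noise for
#' the requested fish-occasion pairs, whether or not the fish was measured
#' there. Vectorised over `fish_id`/`occasion`.
#'
#' @param fit A `growth_fit` with stored latent draws.
#' @param fish_id Fish identifier(s).
#' @param occasion Occasion index(es), within each fish's latent support.
#' @return Tibble with `fish_id`, `occasion`, `mean`, `sd`, `lwr`, `upr`
#'   (95% predictive interval, measurement noise included).
#' @export
predict_size <- function(fit, fish_id, occasion) {
  if (is.null(fit$z_draws)) stop("fit was run with save_latent = FALSE")
  k <- match(paste(fish_id, occasion),
             paste(fit$z_cells$fish_id, fit$z_cells$occasion))
  if (anyNA(k)) {
    bad <- which(is.na(k))[1L]
    stop("occasion ", occasion[bad], " is outside the latent support of ",
         "fish ", fish_id[bad])
  }
  nd <- nrow(fit$z_draws)
  out <- lapply(seq_along(k), function(ii) {
    zd <- fit$z_draws[, k[ii]]
    pd <- if (fit$eta_sq > 0) {
      zd + with_seed(fit$seed + 104729L * k[ii],
                     rnorm(nd, 0, sqrt(fit$eta_sq)))
    } else zd
    c(mean(pd), sd(pd), quantile(pd, c(0.025, 0.975), names = FALSE))
  })
  m <- do.call(rbind, out)
  tibble::tibble(fish_id = fish_id, occasion = occasion, mean = m[, 1L],
                 sd = m[, 2L], lwr = m[, 3L], upr = m[, 4L])
}

level_key <- function(level) {
  lv <- c("space" = "cave", "time" = "year", "space-time" = "caveyear")
  if (!level %in% names(lv)) {
    stop("unknown level '", level, "' (use space, time or space-time)")
  }
  unname(lv[level])
}

#' Sample growth functions over a size range
#'
#' Visualisation draws mirroring a posterior simulation of level-specific
#' growth curves: for each requested level (space = cave, time = year,
#' space-time = cave-by-year) and season, curves
#' `g(z) = (alpha + d_a) + (b + d_b) (z - zbar)` are sampled with the
#' deviation pair `(d_a, d_b)` drawn from that level's fitted bivariate
#' distribution, one posterior draw per curve. Rates are mm/month at the
#' centred mean temperature.
#'
#' @param fit A `growth_fit`.
#' @param size_range Numeric length-2, must lie within the observed size
#'   range of the fitted data.
#' @param n_curves Curves per season-by-level panel.
#' @param seed Integer seed.
#' @param levels Subset of `c("space", "time", "space-time")`.
#' @param n_grid Grid points per curve.
#' @return Tibble with `season`, `level`, `curve`, `size_mm`,
#'   `growth_mm_month`.
#' @export
simulate_growth_functions <- function(fit, size_range = c(70, 120),
                                      n_curves = 30L, seed = 1L,
                                      levels = c("space", "time",
                                                 "space-time"),
                                      n_grid = 26L) {
  if (size_range[1L] < fit$obs_range[1L] ||
      size_range[2L] > fit$obs_range[2L]) {
    stop("size_range must lie within the observed data support [",
         fit$obs_range[1L], ", ", fit$obs_range[2L], "]")
  }
  lvs <- vapply(levels, level_key, character(1L))
  grid <- seq(size_range[1L], size_range[2L], length.out = n_grid)
  old <- save_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  res <- list()
  for (h in fit$seasons) {
    for (iL in seq_along(lvs)) {
      lv <- lvs[iL]
      rows <- sample.int(nrow(fit$draws), n_curves, replace = TRUE)
      va <- fit$draws[rows, sprintf("V_alpha_%s[%s]", lv, h)]
      vb <- fit$draws[rows, sprintf("V_b_%s[%s]", lv, h)]
      cab <- fit$draws[rows, sprintf("cov_ab_%s[%s]", lv, h)]
      al <- fit$draws[rows, sprintf("alpha[%s]", h)]
      bb <- fit$draws[rows, sprintf("b[%s]", h)]
      d_a <- rnorm(n_curves, 0, sqrt(va))
      mu_cond <- ifelse(va > 0, cab / va * d_a, 0)
      v_cond <- pmax(vb - ifelse(va > 0, cab^2 / va, 0), 0)
      d_b <- rnorm(n_curves, mu_cond, sqrt(v_cond))
      for (cv in seq_len(n_curves)) {
        res[[length(res) + 1L]] <- tibble::tibble(
          season = h, level = levels[iL], curve = cv, size_mm = grid,
          growth_mm_month = (al[cv] + d_a[cv]) +
            (bb[cv] + d_b[cv]) * (grid - fit$zbar))
      }
    }
  }
  do.call(rbind, res)
}

#' Asymptotic size from a linear growth function
#'
#' The size at which expected growth is zero: `z* = zbar - alpha / b` for a
#' growth function `g(z) = alpha + b (z - zbar)` with negative slope.
#'
#' @param alpha Intercept-level growth at the centring size (any time unit,
#'   as long as `b` shares it).
#' @param b Size-dependence slope (same time unit as `alpha`).
#' @param zbar Centring size in mm.
#' @return Size in mm; `NA` where `b >= 0` (undefined, growth never stops).
#' @export
asymptotic_size_point <- function(alpha, b, zbar) {
  ifelse(b < 0, zbar - alpha / b, NA_real_)
}

#' Per-draw asymptotic size from a fitted model
#'
#' Annualises the seasonal growth function (2 summer months + 10 winter
#' months) per posterior draw and solves for the size at which expected
#' annual growth is zero. Draws with non-negative annual slope are reported
#' as undefined, not dropped.
#'
#' @param fit A `growth_fit`.
#' @return Tibble with per-draw `alpha_annual` (mm/year at the centring
#'   size), `b_annual` (per year), `asymptotic_mm`, `defined`; summary
#'   statistics in `attr(, "summary")`.
#' @export
asymptotic_size <- function(fit) {
  if (identical(fit$seasons, "all")) {
    aa <- 12 * fit$draws[, "alpha[all]"]
    bb <- 12 * fit$draws[, "b[all]"]
  } else {
    aa <- 2 * fit$draws[, "alpha[summer]"] + 10 * fit$draws[, "alpha[winter]"]
    bb <- 2 * fit$draws[, "b[summer]"] + 10 * fit$draws[, "b[winter]"]
  }
  zs <- asymptotic_size_point(aa, bb, fit$zbar)
  out <- tibble::tibble(alpha_annual = aa, b_annual = bb,
                        asymptotic_mm = zs, defined = !is.na(zs))
  ok <- out$asymptotic_mm[out$defined]
  attr(out, "summary") <- list(
    n_defined = sum(out$defined), n_undefined = sum(!out$defined),
    mean = if (length(ok)) mean(ok) else NA_real_,
    q2.5 = if (length(ok)) quantile(ok, 0.025, names = FALSE) else NA_real_,
    q97.5 = if (length(ok)) quantile(ok, 0.975, names = FALSE) else NA_real_)
  out
}
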