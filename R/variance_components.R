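# Derived quantities: temperature-associated variances (V(a+bx) = b^2 V(x)),
# conversion of slope variance to growth-variance units, and per-draw
# repeatability proportions R. Everything is computed per posterior draw and
# only then summarised; a ratio of posterior means is NOT the posterior mean
# of the ratio.

season_cols <- function(fit) {
  if (identical(fit$seasons, "all")) "all" else SEASONS
}

#' Temperature-associated growth variance per draw
#'
#' Applies `V(a + b x) = b^2 V(x)`: the share of a growth variance component
#' attributable to temperature variation is the matching temperature variance
#' component times the squared temperature effect on the growth intercept.
#' Spatial uses the among-cave temperature variance, temporal the among-year
#' variance, and spatiotemporal the residual cave-by-year temperature
#' variance.
#'
#' @param fit A `growth_fit` (not run with the `no_temperature` ablation).
#' @param level `"space"`, `"time"` or `"space-time"`.
#' @param season `"summer"` or `"winter"`.
#' @param scale `"month"` (default, (mm/month)^2) or `"season"`
#'   ((mm/season)^2, i.e. multiplied by the squared months-in-season).
#' @return Numeric vector, one value per posterior draw.
#' @export
temperature_associated_variance <- function(fit, level, season,
                                            scale = c("month", "season")) {
  scale <- match.arg(scale)
  if ("no_temperature" %in% fit$ablation) {
    stop("temperature-associated components are unavailable: ",
         "the fit was run with the no_temperature ablation")
  }
  lv <- level_key(level)
  tv_col <- switch(lv, cave = "T_V_cave", year = "T_V_year",
                   caveyear = "T_V_resid")
  tv <- fit$draws[, paste0(tv_col, "[", season, "]")]
  at <- fit$draws[, paste0("alpha_T[",
                           if (identical(fit$seasons, "all")) "all"
                           else season, "]")]
  out <- tv * at^2
  if (scale == "season") out <- out * MONTHS_IN_SEASON[season]^2
  unname(out)
}

#' Fork-length variance after a season of growth
#'
#' The slope-variance conversion needs the variance of the sizes the slopes
#' act on: the spread of fork lengths among fish measured at occasions that
#' follow a period of the given season's growth (August occasions for
#' summer, June occasions for winter). Estimated as the total variance
#' (sum of cave, year and residual components) of an intercept
#' variance-components model with cave and year grouping factors.
#'
#' @param panel A `growth_panel`.
#' @param season `"summer"` or `"winter"`.
#' @param method `"lmm"` (default; lme4 intercept model) or `"simple"`
#'   (plain variance, ignoring grouping).
#' @param min_n Minimum post-season observations required.
#' @return A `fork_length_variance` list: `sigma_fl_sq` (mm^2), `components`,
#'   `n`, `season`.
#' @export
fork_length_variance <- function(panel, season, method = c("lmm", "simple"),
                                 min_n = 30L) {
  method <- match.arg(method)
  stopifnot(season %in% SEASONS)
  post_month <- if (season == "summer") "August" else "June"
  occs <- panel$occasions$occasion[panel$occasions$month == post_month]
  idx <- which(!is.na(panel$obs[, occs, drop = FALSE]), arr.ind = TRUE)
  if (nrow(idx) < min_n) {
    stop("only ", nrow(idx), " post-", season, " observations (need >= ",
         min_n, ")")
  }
  df <- data.frame(
    fl = panel$obs[, occs, drop = FALSE][idx],
    cave = panel$fish$cave_id[idx[, 1L]],
    year = panel$occasions$year[occs[idx[, 2L]]])
  if (method == "simple" || length(unique(df$cave)) < 2L ||
      length(unique(df$year)) < 2L) {
    comp <- c(cave = 0, year = 0, residual = var(df$fl))
  } else {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(fl ~ 1 + (1 | cave) + (1 | year), data = df,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    comp <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                     vc$grp))
    comp <- comp[c("cave", "year", "residual")]
  }
  structure(list(sigma_fl_sq = sum(comp), components = comp, n = nrow(idx),
                 season = season, method = method),
            class = "fork_length_variance")
}

#' Convert slope variance to growth-variance units
#'
#' A variance in size-dependence slopes is not comparable to a variance in
#' growth intercepts (the units differ); multiplying per draw by the variance
#' of the fork lengths the slopes act on expresses it as the variability in
#' growth it generates.
#'
#' @param vb_draws Per-draw slope-variance values (per month squared).
#' @param sigma_fl_sq Fork-length variance (mm^2), a scalar or a
#'   `fork_length_variance`.
#' @return Per-draw converted variances, (mm/month)^2.
#' @export
convert_slope_variance <- function(vb_draws, sigma_fl_sq) {
  if (inherits(sigma_fl_sq, "fork_length_variance")) {
    sigma_fl_sq <- sigma_fl_sq$sigma_fl_sq
  }
  stopifnot(sigma_fl_sq >= 0)
  vb_draws * sigma_fl_sq
}

#' Per-draw repeatability decomposition of growth variance
#'
#' For each season and draw, assembles the spatial, temporal and
#' spatiotemporal variance totals `V_j = V_alpha_j + V_alpha(b_j) + V_{j,T}`
#' (size-independent + converted size-dependent + temperature-associated),
#' their sum `V_g = V_j + V_t + V_jt`, and the nine proportions
#' `R = component / V_g`, which sum to exactly 1 per draw by construction.
#' Summaries (posterior means, equal-tailed 95% intervals) are computed from
#' the per-draw values, never from summarised inputs. The residual growth
#' variance `V_e` is excluded from the default denominator; an alternative
#' share including it is reported separately and labelled.
#'
#' @param fit A `growth_fit`.
#' @param sigma_fl_sq Named numeric (`summer`, `winter` — or `all`) of
#'   fork-length variances, or a list of `fork_length_variance` objects.
#' @param scale `"month"` or `"season"` (see
#'   [temperature_associated_variance()]).
#' @return A `variance_report`: `$table` (summary rows mirroring a variance
#'   decomposition table), `$draws` (per-draw component values), and
#'   `$n_undefined` (draws with `V_g = 0`, excluded from R summaries with a
#'   count).
#' @export
repeatability <- function(fit, sigma_fl_sq, scale = c("month", "season")) {
  scale <- match.arg(scale)
  seasons <- season_cols(fit)
  if (is.list(sigma_fl_sq) && !is.numeric(sigma_fl_sq)) {
    sigma_fl_sq <- vapply(sigma_fl_sq, function(x) x$sigma_fl_sq, numeric(1L))
  }
  if (is.null(names(sigma_fl_sq))) names(sigma_fl_sq) <- seasons
  no_temp <- "no_temperature" %in% fit$ablation
  mfac <- function(h) {
    if (scale == "season" && h %in% names(MONTHS_IN_SEASON)) {
      MONTHS_IN_SEASON[h]^2
    } else 1
  }
  lv_names <- c("space" = "cave", "time" = "year", "space-time" = "caveyear")
  all_draws <- list(); rows <- list(); n_undef <- integer()
  for (h in seasons) {
    per <- list()
    for (k in seq_along(lv_names)) {
      lv <- lv_names[k]
      per[[paste0("V_alpha_", lv)]] <-
        fit$draws[, sprintf("V_alpha_%s[%s]", lv, h)] * mfac(h)
      per[[paste0("V_alpha_b_", lv)]] <- convert_slope_variance(
        fit$draws[, sprintf("V_b_%s[%s]", lv, h)] * mfac(h),
        unname(sigma_fl_sq[h]))
      per[[paste0("V_temp_", lv)]] <- if (no_temp) {
        rep(0, nrow(fit$draws))
      } else {
        temperature_associated_variance(fit, names(lv_names)[k],
                                        if (h == "all") "summer" else h,
                                        scale)
      }
    }
    tot <- function(lv) per[[paste0("V_alpha_", lv)]] +
      per[[paste0("V_alpha_b_", lv)]] + per[[paste0("V_temp_", lv)]]
    Vj <- tot("cave"); Vt <- tot("year"); Vjt <- tot("caveyear")
    Vg <- Vj + Vt + Vjt
    Ve <- fit$draws[, sprintf("V_e[%s]", h)] * mfac(h)
    ok <- Vg > 0
    n_undef[h] <- sum(!ok)
    Rs <- lapply(per, function(v) ifelse(ok, v / Vg, NA_real_))
    names(Rs) <- sub("^V", "R", names(Rs))
    per$V_g <- Vg
    per$V_e <- Ve
    per$V_g_with_residual <- Vg + Ve
    all_draws[[h]] <- c(per, Rs)

    summ <- function(v) c(mean = mean(v, na.rm = TRUE),
                          q2.5 = quantile(v, 0.025, na.rm = TRUE,
                                          names = FALSE),
                          q97.5 = quantile(v, 0.975, na.rm = TRUE,
                                           names = FALSE))
    qq <- t(vapply(all_draws[[h]], summ, numeric(3L)))
    rows[[h]] <- tibble::tibble(
      season = h, quantity = rownames(qq),
      mean = unname(qq[, 1L]), q2.5 = unname(qq[, 2L]),
      q97.5 = unname(qq[, 3L]))
  }
  structure(list(table = do.call(rbind, rows), draws = all_draws,
                 n_undefined = n_undef, scale = scale,
                 sigma_fl_sq = sigma_fl_sq),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat("variance_report (scale:", x$scale, ")\n")
  if (any(x$n_undefined > 0)) {
    cat("  draws with V_g = 0 excluded from R summaries:",
        paste(names(x$n_undefined), x$n_undefined, collapse = ", "), "\n")
  }
  print(x$table, n = Inf)
  invisible(x)
}
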