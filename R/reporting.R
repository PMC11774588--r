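# Report assembly: seasonal summaries, table analogues, growth-curve samples
# and a reproducibility manifest.

#' Convert a monthly rate to a seasonal total
#'
#' Summer spans 2 months, winter 10, so a per-month growth rate (or CI
#' bound) times the month count gives the season total under the package's
#' month convention.
#'
#' @param value_per_month Numeric.
#' @param season `"summer"` or `"winter"`.
#' @export
monthly_to_seasonal <- function(value_per_month, season) {
  if (!all(season %in% SEASONS)) stop("unknown season: ", season)
  value_per_month * unname(MONTHS_IN_SEASON[season])
}

#' Seasonal growth summary
#'
#' Posterior means and equal-tailed 95% credible intervals for the growth of
#' the average-sized fish: mm/month and total mm/season, the temperature
#' effects, and the size-dependence slope per month and per year.
#'
#' @param fit A `growth_fit`.
#' @return Tibble with one row per season and quantity.
#' @export
seasonal_summary <- function(fit) {
  qs <- function(v) c(mean(v), quantile(v, c(0.025, 0.975), names = FALSE))
  rows <- list()
  for (h in fit$seasons) {
    al <- fit$draws[, sprintf("alpha[%s]", h)]
    b <- fit$draws[, sprintf("b[%s]", h)]
    mth <- if (h == "all") 12 else unname(MONTHS_IN_SEASON[h])
    add <- function(q, v) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        season = h, quantity = q, mean = qs(v)[1L], q2.5 = qs(v)[2L],
        q97.5 = qs(v)[3L])
    }
    add("growth_mm_per_month", al)
    add("growth_mm_per_season", al * mth)
    add("slope_per_month", b)
    add("slope_per_year", b * (if (h == "all") 12 else
      unname(MONTHS_IN_SEASON[h])))
    if (!"no_temperature" %in% fit$ablation) {
      add("temp_effect_mm_per_month_per_C",
          fit$draws[, sprintf("alpha_T[%s]", h)])
      add("temp_effect_slope_per_month_per_C",
          fit$draws[, sprintf("b_T[%s]", h)])
    }
  }
  do.call(rbind, rows)
}

summary_or_na <- function(fit, cols) {
  out <- lapply(cols, function(cc) {
    if (cc %in% colnames(fit$draws)) {
      v <- fit$draws[, cc]
      c(mean(v), quantile(v, c(0.025, 0.975), names = FALSE))
    } else rep(NA_real_, 3L)
  })
  m <- do.call(rbind, out)
  tibble::tibble(parameter = cols, mean = m[, 1L], q2.5 = m[, 2L],
                 q97.5 = m[, 3L])
}

#' Assemble a report directory
#'
#' Writes CSV analogues of the temperature and growth-variance tables, the
#' seasonal growth summary, sampled growth curves over the core size range,
#' the PPC point table when supplied, and a JSON run manifest (seed, config
#' hash, package version) sufficient to rerun the pipeline to identical
#' output. Every rendered number is recomputed from the stored draws, so
#' regeneration from the same fit is bit-identical. Components absent under
#' an ablation are rendered as `NA`, not dropped.
#'
#' @param fit A `growth_fit`.
#' @param variance_report Optional `variance_report` from [repeatability()].
#' @param ppc Optional `ppc_result`.
#' @param out_dir Output directory.
#' @param curve_seed Seed for the growth-curve draws.
#' @return Invisibly, the paths written.
#' @export
make_report <- function(fit, variance_report = NULL, ppc = NULL, out_dir,
                        curve_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(as.data.frame(df), p, row.names = FALSE)
    paths <<- c(paths, p)
  }

  temp_cols <- as.vector(outer(c("T_mean", "T_V_cave", "T_V_year",
                                 "T_V_resid"),
                               SEASONS, function(a, b) paste0(a, "[", b, "]")))
  wr(summary_or_na(fit, temp_cols), "temperature_table.csv")

  seasons <- if (identical(fit$seasons, "all")) "all" else SEASONS
  var_cols <- as.vector(outer(
    c("V_alpha_cave", "V_alpha_year", "V_alpha_caveyear", "V_b_cave",
      "V_b_year", "V_b_caveyear", "V_e"),
    seasons, function(a, b) paste0(a, "[", b, "]")))
  wr(summary_or_na(fit, var_cols), "variance_components_raw.csv")
  if (!is.null(variance_report)) {
    wr(variance_report$table, "variance_table.csv")
  }
  wr(seasonal_summary(fit), "seasonal_summary.csv")

  lo <- max(70, fit$obs_range[1L]); hi <- min(120, fit$obs_range[2L])
  if (lo < hi) {
    wr(simulate_growth_functions(fit, c(lo, hi), seed = curve_seed),
       "growth_curves.csv")
  }
  if (!is.null(ppc)) {
    wr(ppc$points, "ppc_points.csv")
    wr(tibble::tibble(metric = c("coverage", "correlation",
                                 "mean_abs_residual"),
                      value = c(ppc$coverage, ppc$correlation,
                                ppc$mean_abs_residual)),
       "ppc_summary.csv")
  }

  manifest <- list(
    package = "cavegrowth",
    version = as.character(utils::packageVersion("cavegrowth")),
    seed = fit$seed, curve_seed = curve_seed,
    mcmc = fit$mcmc[c("n_chains", "n_iter", "n_warmup", "thin")],
    ablation = fit$ablation, eta_sq = fit$eta_sq,
    centring = list(zbar = fit$zbar, tbar = fit$tbar),
    converged = fit$converged,
    config_hash = rlang::hash(list(fit$mcmc, fit$priors, fit$ablation,
                                   fit$eta_sq, fit$seed)))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}
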