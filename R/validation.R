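# Posterior-predictive validation: repeated rounds of single-observation
# removals, refit, predict, and score (coverage / correlation / mean absolute
# residual), plus convergence diagnostics.

#' Plan single-observation removals
#'
#' Reproducibly selects, for each round, a set of distinct fish and one
#' observed occasion to hold out from each. Eligible fish have at least 3
#' captures and at least one interior capture (strictly between their first
#' and last), so every holdout leaves a usable two-point trajectory and the
#' held-out occasion stays inside the latent support.
#'
#' @param panel A `growth_panel`.
#' @param n_fish_per_round Fish removed per round (default 10).
#' @param n_rounds Number of rounds (default 99; the defaults give 990
#'   holdout predictions).
#' @param seed Integer seed.
#' @return A `removal_plan`: tibble with `round`, `fish_id`, `occasion`.
#' @export
plan_removals <- function(panel, n_fish_per_round = 10L, n_rounds = 99L,
                          seed = 1L) {
  nobs <- rowSums(!is.na(panel$obs))
  interior <- lapply(seq_len(nrow(panel$fish)), function(i) {
    occ <- which(!is.na(panel$obs[i, ]))
    occ[occ > panel$fish$first_occasion[i] &
          occ < panel$fish$last_occasion[i]]
  })
  eligible <- which(nobs >= 3L & lengths(interior) > 0L)
  if (length(eligible) < n_fish_per_round) {
    stop("only ", length(eligible), " eligible fish (>= 3 captures with an ",
         "interior one); need ", n_fish_per_round, " per round")
  }
  old <- save_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  rounds <- lapply(seq_len(n_rounds), function(r) {
    pick <- sample(eligible, n_fish_per_round)
    occ <- vapply(pick, function(i) {
      cand <- interior[[i]]
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, integer(1L))
    tibble::tibble(round = r, fish_id = panel$fish$fish_id[pick],
                   occasion = occ)
  })
  plan <- do.call(rbind, rounds)
  structure(plan, class = c("removal_plan", class(plan)), seed = seed)
}

#' Run the holdout posterior predictive check
#'
#' For each round of the plan, refits the full joint model with that round's
#' observations masked, predicts each held-out measurement via
#' [predict_size()] (latent size plus measurement noise), and aggregates:
#' the fraction of observed values inside the 95% predictive interval, the
#' Pearson correlation between observed and predicted, and the mean absolute
#' residual in mm. Rounds whose refit fails the convergence threshold are
#' flagged and excluded from the aggregates, with counts reported.
#'
#' @param panel A `growth_panel`.
#' @param plan A `removal_plan`.
#' @param eta_sq Measurement-error variance passed to [fit_growth()].
#' @param priors,fit_config,ablation Passed to [fit_growth()];
#'   `fit_config` may reduce MCMC effort for desk-scale runs.
#' @param seed Integer seed (each round derives its own fit seed).
#' @param rhat_threshold Convergence threshold passed to [fit_growth()].
#' @return A `ppc_result`: `$points` (per-holdout observed, predicted mean
#'   and interval, round, converged flag), `$coverage`, `$correlation`,
#'   `$mean_abs_residual`, `$n_rounds`, `$n_converged`.
#' @export
run_ppc <- function(panel, plan, eta_sq, priors = priors_config(),
                    fit_config = mcmc_config(n_chains = 2L, n_iter = 900L,
                                             n_warmup = 300L),
                    ablation = character(), seed = 1L,
                    rhat_threshold = 1.05) {
  rounds <- sort(unique(plan$round))
  pts <- list()
  conv <- logical(length(rounds))
  for (ri in seq_along(rounds)) {
    sub <- plan[plan$round == rounds[ri], ]
    p2 <- remove_observations(panel, sub)
    fit <- fit_growth(p2, eta_sq, priors = priors, mcmc = fit_config,
                      seed = seed + 613L * ri, ablation = ablation,
                      rhat_threshold = rhat_threshold)
    conv[ri] <- fit$converged
    pred <- predict_size(fit, sub$fish_id, sub$occasion)
    fi <- match(sub$fish_id, panel$fish$fish_id)
    pts[[ri]] <- tibble::tibble(
      round = rounds[ri], fish_id = sub$fish_id, occasion = sub$occasion,
      observed = panel$obs[cbind(fi, sub$occasion)],
      predicted = pred$mean, lwr = pred$lwr, upr = pred$upr,
      converged = conv[ri])
  }
  points <- do.call(rbind, pts)
  use <- points[points$converged, ]
  structure(list(
    points = points,
    coverage = mean(use$observed >= use$lwr & use$observed <= use$upr),
    correlation = if (nrow(use) > 2L) cor(use$observed, use$predicted)
                  else NA_real_,
    mean_abs_residual = mean(abs(use$observed - use$predicted)),
    n_rounds = length(rounds), n_converged = sum(conv),
    n_points = nrow(points), n_points_used = nrow(use)),
    class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("Posterior predictive check:", x$n_points, "holdout predictions in",
      x$n_rounds, "rounds (", x$n_converged, "converged )\n")
  cat(sprintf("  95%% interval coverage: %.3f\n", x$coverage))
  cat(sprintf("  observed-predicted correlation: %.3f\n", x$correlation))
  cat(sprintf("  mean absolute residual: %.2f mm\n", x$mean_abs_residual))
  invisible(x)
}

#' Convergence diagnostics for a fit
#'
#' Split-chain R-hat and effective sample size per scalar parameter, with an
#' overall pass verdict: pass iff every R-hat is below the threshold and
#' every effective sample size above the minimum. Loosening either threshold
#' can only turn failures into passes (the rule is monotone).
#'
#' @param fit A `growth_fit`, `temperature_fit`, or a draws matrix with a
#'   `chain` attribute/argument.
#' @param thresholds List with `rhat` (default 1.05) and `min_ess`
#'   (default 100).
#' @param chain Chain index vector when `fit` is a bare matrix.
#' @return A `diagnostics_report`: `$table`, `$pass`, `$thresholds`.
#' @export
diagnostics <- function(fit, thresholds = list(rhat = 1.05, min_ess = 100),
                        chain = NULL) {
  if (inherits(fit, c("growth_fit", "temperature_fit"))) {
    draws <- fit$draws; chain <- fit$chain
  } else {
    draws <- as.matrix(fit)
    if (is.null(chain)) stop("chain indices required for a bare draws matrix")
  }
  if (length(unique(chain)) < 2L) {
    stop("diagnostics need at least 2 chains")
  }
  tab <- summarize_draw_matrix(draws, chain)
  pass <- all(tab$rhat < thresholds$rhat, na.rm = TRUE) &&
    all(tab$ess >= thresholds$min_ess, na.rm = TRUE)
  structure(list(table = tab[, c("parameter", "rhat", "ess")], pass = pass,
                 thresholds = thresholds),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Convergence:", if (x$pass) "PASS" else "FAIL",
      sprintf("(rhat < %.3f, ess >= %d)\n", x$thresholds$rhat,
              as.integer(x$thresholds$min_ess)))
  worst <- x$table[order(-x$table$rhat), ]
  print(head(worst, 10L))
  invisible(x)
}
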