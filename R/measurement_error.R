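#' Estimate fork-length measurement-error variance from repeat measures
#'
#' Repeat measures taken in immediate succession on the same fish differ only
#' by measurement error, so the within-individual variance of an intercept
#' model with fish identity as a grouping factor estimates the
#' measurement-error variance eta^2 of the growth observation model. The
#' default estimator is Bayesian (Gibbs sampler on the one-way random-effects
#' model, half-t priors on both SDs); `method = "mom"` gives the
#' method-of-moments decomposition (pooled within-group variance), which is
#' an independent route to the same quantity and is used as a cross-check in
#' the test-suite.
#'
#' @param repeats Tibble from [read_repeats()] (columns `fish_id`,
#'   `fork_length_mm`; `replicate_index` is ignored by the estimator).
#' @param method `"bayes"` (default) or `"mom"`.
#' @param n_iter,n_warmup,n_chains MCMC controls for the Bayesian route.
#' @param seed Integer seed (Bayesian route).
#' @return A `measurement_error_estimate`: `eta_sq` (point estimate, mm^2),
#'   `interval` (95%, Bayesian route), `between_fish_variance`, `n_fish`,
#'   `n_measurements`, `method`.
#' @export
estimate_measurement_error <- function(repeats, method = c("bayes", "mom"),
                                       n_iter = 2000L, n_warmup = 500L,
                                       n_chains = 2L, seed = 1L) {
  method <- match.arg(method)
  y <- repeats$fork_length_mm
  g <- factor(repeats$fish_id)
  n_i <- table(g)
  if (sum(n_i >= 2L) < 2L) {
    stop("need at least 2 fish with at least 2 replicates each")
  }
  if (any(n_i < 2L)) {
    keep <- g %in% names(n_i)[n_i >= 2L]
    y <- y[keep]; g <- droplevels(g[keep]); n_i <- table(g)
  }
  n_fish <- nlevels(g)
  n_meas <- length(y)
  gi <- as.integer(g)
  ybar_i <- tapply(y, gi, mean)
  ss_within <- sum((y - ybar_i[gi])^2)
  mom_within <- ss_within / (n_meas - n_fish)

  if (method == "mom") {
    # unbalanced one-way ANOVA between-component (Searle); floored at zero
    ss_between <- sum(n_i * (ybar_i - mean(y))^2)
    ms_between <- ss_between / (n_fish - 1L)
    n0 <- (n_meas - sum(n_i^2) / n_meas) / (n_fish - 1L)
    between <- max(0, (ms_between - mom_within) / n0)
    return(structure(list(
      eta_sq = mom_within, interval = c(NA_real_, NA_real_),
      between_fish_variance = between, n_fish = n_fish,
      n_measurements = n_meas, method = "mom", draws = NULL),
      class = "measurement_error_estimate"))
  }

  old <- save_rng_state(); on.exit(restore_rng_state(old))
  ni_vec <- as.numeric(n_i)
  draws <- matrix(NA_real_, 0L, 3L,
                  dimnames = list(NULL, c("eta_sq", "between", "mu")))
  chain_id <- integer()
  for (ch in seq_len(n_chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    mu <- mean(y)
    eta2 <- max(mom_within, 1e-6)
    vb <- max(var(ybar_i), 1e-6)
    aux_e <- 1; aux_b <- 1
    u <- ybar_i - mu
    keep <- matrix(NA_real_, n_iter - n_warmup, 3L)
    for (it in seq_len(n_iter)) {
      # fish effects
      prec <- 1 / vb + ni_vec / eta2
      mn <- (tapply(y - mu, gi, sum) / eta2) / prec
      u <- rnorm(n_fish, mn, sqrt(1 / prec))
      # grand mean, diffuse N(0, 1000^2)
      pr <- 1 / 1000^2 + n_meas / eta2
      mu <- rnorm(1L, sum(y - u[gi]) / eta2 / pr, sqrt(1 / pr))
      # variances: half-t(3, 5) on the error SD, half-t(3, 50) between fish
      r <- y - mu - u[gi]
      up <- update_halft_var(sum(r^2), n_meas, aux_e, 3, 5)
      eta2 <- up$var; aux_e <- up$aux
      up <- update_halft_var(sum(u^2), n_fish, aux_b, 3, 50)
      vb <- up$var; aux_b <- up$aux
      if (it > n_warmup) keep[it - n_warmup, ] <- c(eta2, vb, mu)
    }
    draws <- rbind(draws, keep)
    chain_id <- c(chain_id, rep(ch, nrow(keep)))
  }
  structure(list(
    eta_sq = mean(draws[, "eta_sq"]),
    interval = unname(quantile(draws[, "eta_sq"], c(0.025, 0.975))),
    between_fish_variance = mean(draws[, "between"]),
    n_fish = n_fish, n_measurements = n_meas, method = "bayes",
    draws = draws, chain = chain_id),
    class = "measurement_error_estimate")
}

#' @export
print.measurement_error_estimate <- function(x, ...) {
  cat("Measurement-error variance (eta^2):", signif(x$eta_sq, 4), "mm^2")
  if (!anyNA(x$interval)) {
    cat(sprintf(" [%.3g; %.3g]", x$interval[1], x$interval[2]))
  }
  cat("\n  method:", x$method, "|", x$n_fish, "fish,", x$n_measurements,
      "measurements\n  between-fish variance:",
      signif(x$between_fish_variance, 4), "mm^2\n")
  invisible(x)
}
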