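# Shared Gibbs-sampler building blocks: conjugate variance updates under
# half-t priors (inverse-gamma mixture representation), 2x2 inverse-Wishart
# updates for intercept-slope blocks, and split-chain convergence diagnostics.

rinvgamma <- function(n, shape, rate) 1 / rgamma(n, shape = shape, rate = rate)

# Half-t(df, scale) prior on an SD via the inverse-gamma mixture:
#   sigma^2 | a ~ IG(df/2, df/a),  a ~ IG(1/2, 1/scale^2)
# Conditionals given n deviations with sum of squares ss:
update_halft_var <- function(ss, n, aux, df, scale) {
  v <- rinvgamma(1L, (df + n) / 2, df / aux + ss / 2)
  aux_new <- rinvgamma(1L, (df + 1) / 2, df / v + 1 / scale^2)
  list(var = v, aux = aux_new)
}

# Huang-Wand prior for a p x p covariance: Sigma | a ~ IW(nu + p - 1,
# 2 nu diag(1/a_k)), a_k ~ IG(1/2, 1/scale_k^2). With nu = 2 the marginal
# prior on each SD is half-t(2, scale_k) and the correlation is ~uniform.
update_hw_cov <- function(S, n, aux, nu, scales) {
  p <- length(scales)
  df <- nu + p - 1 + n
  scale_mat <- 2 * nu * diag(1 / aux, p) + S
  prec <- stats::rWishart(1L, df, solve(scale_mat))[, , 1L]
  Sigma <- solve(prec)
  om <- solve(Sigma)
  aux_new <- rinvgamma(p, (nu + p) / 2, nu * diag(om) + 1 / scales^2)
  list(Sigma = Sigma, aux = aux_new)
}

# Draw from N(mean, Sigma) for a small covariance
rmvnorm1 <- function(mean, Sigma) {
  L <- chol(Sigma)
  as.numeric(mean + t(L) %*% rnorm(length(mean)))
}

# Vectorised bivariate-normal draws: for each group g, posterior
# precision P_g = Omega + [[sw, swx], [swx, swxx]]_g and rhs
# [swy, swxy]_g; returns matrix of (intercept, slope) draws.
draw_pairs_posterior <- function(sw_, swx, swxx, swy, swxy, Omega) {
  p11 <- Omega[1, 1] + sw_
  p12 <- Omega[1, 2] + swx
  p22 <- Omega[2, 2] + swxx
  det <- p11 * p22 - p12^2
  v11 <- p22 / det; v22 <- p11 / det; v12 <- -p12 / det
  m1 <- v11 * swy + v12 * swxy
  m2 <- v12 * swy + v22 * swxy
  # draw via the Cholesky of each 2x2 covariance [[v11, v12], [v12, v22]]
  l11 <- sqrt(v11)
  l21 <- v12 / l11
  l22 <- sqrt(pmax(v22 - l21^2, 0))
  z1 <- rnorm(length(sw_)); z2 <- rnorm(length(sw_))
  cbind(m1 + l11 * z1, m2 + l21 * z1 + l22 * z2)
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

with_seed <- function(seed, expr) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

#' Split-chain convergence statistic (R-hat)
#'
#' The potential scale reduction factor computed on chains split in half
#' (so within-chain trends register as between-chain disagreement).
#'
#' @param x Numeric matrix, iterations by chains (or a vector with a single
#'   chain, which is split in two).
#' @return Scalar R-hat; 1 indicates convergence, values above ~1.05 are
#'   suspect.
#' @export
split_rhat <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mu <- colMeans(sub)
  s2 <- apply(sub, 2L, var)
  W <- mean(s2)
  B <- nn * var(mu)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size, summing paired
#' autocorrelations until the first negative pair (Geyer initial positive
#' sequence), pooled across chains.
#'
#' @inheritParams split_rhat
#' @export
ess_basic <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x); m <- ncol(x)
  if (var(as.numeric(x)) == 0) return(n * m)
  rho <- rep(0, n - 1L)
  for (k in seq_len(m)) {
    xc <- x[, k] - mean(x[, k])
    ac <- stats::acf(xc, lag.max = min(n - 1L, 200L), plot = FALSE,
                     demean = FALSE)$acf[-1L]
    rho[seq_along(ac)] <- rho[seq_along(ac)] + ac / m
  }
  s <- 0
  for (j in seq(1L, length(rho) - 1L, by = 2L)) {
    pair <- rho[j] + rho[j + 1L]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  min(n * m, n * m / (1 + 2 * s))
}

summarize_draw_matrix <- function(draws, chain) {
  nm <- colnames(draws)
  chains <- sort(unique(chain))
  tibble::tibble(
    parameter = nm,
    mean = colMeans(draws),
    sd = apply(draws, 2L, sd),
    q2.5 = apply(draws, 2L, quantile, 0.025, names = FALSE),
    q97.5 = apply(draws, 2L, quantile, 0.975, names = FALSE),
    rhat = vapply(nm, function(p) {
      split_rhat(vapply(chains, function(cc) draws[chain == cc, p],
                        numeric(sum(chain == chains[1L]))))
    }, numeric(1L)),
    ess = vapply(nm, function(p) {
      ess_basic(vapply(chains, function(cc) draws[chain == cc, p],
                       numeric(sum(chain == chains[1L]))))
    }, numeric(1L)))
}

#' MCMC run configuration
#'
#' @param n_chains Number of independent chains.
#' @param n_iter Iterations per chain (including warmup).
#' @param n_warmup Discarded warmup iterations per chain.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param save_latent Store per-draw latent sizes (needed by
#'   [predict_size()]; switch off for very large panels).
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 2500L, n_warmup = 500L,
                        thin = 1L, save_latent = TRUE) {
  stopifnot(n_chains >= 1L, n_iter > n_warmup, thin >= 1L)
  list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
       n_warmup = as.integer(n_warmup), thin = as.integer(thin),
       save_latent = isTRUE(save_latent))
}

#' Prior configuration
#'
#' Minimally informative defaults: diffuse normals on means and fixed
#' effects; half-t(3, scale) priors on standard deviations, with scales
#' matched to each parameter's natural magnitude; intercept-slope blocks get
#' a Huang-Wand covariance prior (half-t(2) marginal SDs, near-uniform
#' correlation).
#'
#' @param sd_fixed SD of the normal prior on growth fixed effects.
#' @param sd_mu0 SD of the normal prior on the initial-size mean.
#' @param halft_df Degrees of freedom of the half-t SD priors.
#' @param scale_alpha,scale_b Half-t scales for intercept-level (mm/month)
#'   and slope-level (per month) random-effect SDs.
#' @param scale_e Half-t scale for the residual growth SD.
#' @param scale_sigma0 Half-t scale for the initial-size SD.
#' @param scale_temp Half-t scale for temperature-model SDs.
#' @param sd_temp_mean SD of the normal prior on seasonal mean temperature.
#' @param temp_obs_var Fixed observation-error variance of a recorded
#'   temperature cell; essentially zero, kept nonzero only so the data
#'   augmentation treats observed and missing cells uniformly.
#' @export
priors_config <- function(sd_fixed = 100, sd_mu0 = 1000, halft_df = 3,
                          scale_alpha = 5, scale_b = 0.5, scale_e = 10,
                          scale_sigma0 = 50, scale_temp = 5,
                          sd_temp_mean = 100, temp_obs_var = 1e-4) {
  list(sd_fixed = sd_fixed, sd_mu0 = sd_mu0, halft_df = halft_df,
       scale_alpha = scale_alpha, scale_b = scale_b, scale_e = scale_e,
       scale_sigma0 = scale_sigma0, scale_temp = scale_temp,
       sd_temp_mean = sd_temp_mean, temp_obs_var = temp_obs_var)
}
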