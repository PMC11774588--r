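# Shared fixtures, built in code and cached for the test session (several
# files reuse the same small simulated panel and fit).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

quick_mcmc <- function(n_chains = 2L, n_iter = 800L, n_warmup = 300L, ...) {
  mcmc_config(n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup, ...)
}

small_sim <- function() {
  cached("small_sim", simulate_scenario(preset("paper-small"), 4242))
}

small_panel <- function() {
  cached("small_panel", {
    s <- small_sim()
    build_panel(validate_captures(s$captures), s$temperatures)
  })
}

small_fit <- function() {
  cached("small_fit",
         fit_growth(small_panel(), eta_sq = 0.6, mcmc = quick_mcmc(),
                    seed = 99L))
}

# captures table for n fish in one cave over the given (year, month) grid;
# fill_fun(i, t) gives the length or NA
make_captures <- function(lengths, years, months, cave = "C01",
                          fish_prefix = "F") {
  n <- nrow(lengths)
  rows <- which(!is.na(lengths), arr.ind = TRUE)
  tibble::tibble(
    fish_id = sprintf("%s%03d", fish_prefix, rows[, 1L]),
    cave_id = cave,
    year = years[rows[, 2L]],
    month = months[rows[, 2L]],
    fork_length_mm = lengths[rows],
    capture_date = as.Date(NA))
}

full_temp_grid <- function(caves, years, value = 6) {
  g <- expand.grid(cave_id = caves, year = years,
                   season = c("summer", "winter"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$mean_temp_C <- value
  tibble::as_tibble(g)
}

# minimal growth_fit stand-in with caller-supplied scalar draws, for exact
# arithmetic tests of the derivation layer
make_fake_fit <- function(draws, seasons = c("summer", "winter"), zbar = 92,
                          tbar = 5, eta_sq = 0.6, ablation = character()) {
  m <- as.matrix(draws)
  structure(list(
    draws = m, chain = rep(1:2, length.out = nrow(m)),
    z_draws = NULL, z_cells = NULL, aug_draws = NULL,
    seasons = seasons, eta_sq = eta_sq, zbar = zbar, tbar = tbar,
    obs_range = c(40, 200), ablation = ablation, fixed = list(),
    converged = TRUE, seed = 1L,
    mcmc = mcmc_config(n_chains = 2L, n_iter = 2L + nrow(m), n_warmup = 2L)),
    class = "growth_fit")
}
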