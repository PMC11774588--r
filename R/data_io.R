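#' @importFrom stats rnorm rgamma runif rbinom quantile var sd setNames
#'   complete.cases median qnorm cor aggregate
#' @importFrom utils read.csv write.csv head
NULL

MONTH_TAGS <- c("June", "August")
NOMINAL_DAY <- c(June = 16L, August = 22L)

#' Nominal capture date for an occasion
#'
#' Sampling visits cluster around fixed mid-dates each year: 16 June and
#' 22 August. These nominal dates are used to compute interval lengths in
#' days whenever actual capture dates are not available for both endpoints
#' of a growth interval.
#'
#' @param year Calendar year (integer).
#' @param month_tag `"June"` or `"August"`.
#' @return A `Date`.
#' @export
nominal_date <- function(year, month_tag) {
  stopifnot(all(month_tag %in% MONTH_TAGS))
  mon <- ifelse(month_tag == "June", 6L, 8L)
  as.Date(sprintf("%04d-%02d-%02d", as.integer(year), mon,
                  NOMINAL_DAY[month_tag]))
}

#' Build the capture-occasion grid
#'
#' A capture occasion is one month-by-year sampling cell (June or August of a
#' study year). Occasions must be strictly increasing in calendar time and
#' alternate June/August, so that every consecutive pair is either a summer
#' (June to August) or winter (August to June) growth interval.
#'
#' @param years Integer vector of calendar years, one per occasion.
#' @param months Character vector (`"June"`/`"August"`), one per occasion.
#' @return A tibble with columns `occasion` (1-based index), `year`,
#'   `month`, `nominal_date`.
#' @export
occasion_grid <- function(years, months) {
  stopifnot(length(years) == length(months))
  if (!all(months %in% MONTH_TAGS)) {
    stop("unknown month tag(s): ",
         paste(unique(months[!months %in% MONTH_TAGS]), collapse = ", "),
         " (expected June or August)")
  }
  d <- nominal_date(years, months)
  o <- order(d)
  years <- as.integer(years[o]); months <- months[o]; d <- d[o]
  if (anyDuplicated(d)) stop("duplicate occasions in grid")
  if (length(d) > 1L) {
    alt <- months[-1L] != months[-length(months)]
    if (!all(alt)) {
      stop("occasion months must alternate June/August; gap detected at ",
           paste(years[-1L][!alt], months[-1L][!alt], collapse = ", "))
    }
  }
  tibble::tibble(occasion = seq_along(d), year = years, month = months,
                 nominal_date = d)
}

#' Exact number of days between two dates
#'
#' Calendar-accurate day count used for the interval lengths D in the growth
#' process model (growth accrues per day between captures). Leap years are
#' honoured: a nominal winter (22 August to 16 June) is 298 days, or 299 when
#' it spans a 29 February.
#'
#' @param from_date,to_date `Date`s (or strings coercible to `Date`).
#' @return Integer day count, strictly positive.
#' @export
interval_days <- function(from_date, to_date) {
  from_date <- as.Date(from_date); to_date <- as.Date(to_date)
  d <- as.integer(to_date - from_date)
  if (any(d <= 0L)) stop("interval must span a positive number of days")
  d
}

season_of_interval <- function(from_month) {
  ifelse(from_month == "June", "summer", "winter")
}

MONTHS_IN_SEASON <- c(summer = 2, winter = 10)

#' Season interval table for an occasion grid
#'
#' One row per consecutive-occasion transition: June to August intervals are
#' summer (2 months), August to June intervals are winter (10 months). The
#' `season_year` of a winter is the year of its August start.
#'
#' @param occasions An occasion grid from [occasion_grid()].
#' @return A tibble with `from_occasion`, `to_occasion`, `season`,
#'   `season_year`, `n_days` (nominal), `n_months`.
#' @export
season_intervals <- function(occasions) {
  T <- nrow(occasions)
  if (T < 2L) {
    return(tibble::tibble(from_occasion = integer(), to_occasion = integer(),
                          season = character(), season_year = integer(),
                          n_days = integer(), n_months = numeric()))
  }
  from <- seq_len(T - 1L)
  season <- season_of_interval(occasions$month[from])
  tibble::tibble(
    from_occasion = from,
    to_occasion = from + 1L,
    season = season,
    season_year = occasions$year[from],
    n_days = interval_days(occasions$nominal_date[from],
                           occasions$nominal_date[from + 1L]),
    n_months = unname(MONTHS_IN_SEASON[season])
  )
}

check_window <- function(x, window, what, rows) {
  bad <- which(!is.na(x) & (x < window[1] | x > window[2]))
  if (length(bad)) {
    stop(what, " outside plausibility window [", window[1], ", ", window[2],
         "] in row(s): ", paste(head(rows[bad], 10L), collapse = ", "))
  }
}

#' Read capture records
#'
#' Reads a long-format CSV of individual capture records (one observed fork
#' length of one fish at one occasion) and infers the occasion grid from the
#' distinct (year, month) pairs present.
#'
#' @param path CSV with columns `fish_id`, `cave_id`, `year`, `month`
#'   (June|August), `fork_length_mm`, and optional `capture_date` (ISO-8601).
#' @param plausibility_window Numeric length-2; fork lengths outside it are an
#'   error. Default 30--300 mm.
#' @return A list with `captures` (tibble, one row per record, with an
#'   `occasion` index column) and `occasions` (the inferred grid).
#' @export
read_captures <- function(path, plausibility_window = c(30, 300)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "cave_id", "year", "month", "fork_length_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  validate_captures(df, plausibility_window)
}

#' Validate an in-memory capture table
#'
#' Same contract as [read_captures()] but starting from a data frame.
#' @inheritParams read_captures
#' @param df Data frame of capture records.
#' @export
validate_captures <- function(df, plausibility_window = c(30, 300)) {
  df <- tibble::as_tibble(df)
  if (!all(df$month %in% MONTH_TAGS)) {
    stop("unknown month tag(s): ",
         paste(unique(df$month[!df$month %in% MONTH_TAGS]), collapse = ", "))
  }
  check_window(df$fork_length_mm, plausibility_window, "fork_length_mm",
               seq_len(nrow(df)))
  key <- paste(df$fish_id, df$year, df$month, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    stop("duplicate fish x occasion record(s), e.g. fish ", d$fish_id[1],
         " at ", d$month[1], " ", d$year[1])
  }
  ncave <- tapply(df$cave_id, df$fish_id, function(x) length(unique(x)))
  if (any(ncave > 1L)) {
    stop("fish with records in more than one cave: ",
         paste(head(names(ncave)[ncave > 1L], 5L), collapse = ", "))
  }
  # the sampling design is semi-annual, so the grid is the complete
  # alternating June/August sequence over the observed span; occasions with
  # no captures in this table are still part of the design
  obs_dates <- nominal_date(df$year, df$month)
  yrs <- seq(min(df$year), max(df$year))
  full_years <- rep(yrs, each = 2L)
  full_months <- rep(c("June", "August"), length(yrs))
  keep <- nominal_date(full_years, full_months) >= min(obs_dates) &
    nominal_date(full_years, full_months) <= max(obs_dates)
  grid <- occasion_grid(full_years[keep], full_months[keep])
  df$occasion <- grid$occasion[match(paste(df$year, df$month),
                                     paste(grid$year, grid$month))]
  cd <- if ("capture_date" %in% names(df)) df[["capture_date"]] else
    rep(NA, nrow(df))
  if (!inherits(cd, "Date")) {
    cd <- as.character(cd)
    cd[!is.na(cd) & cd == ""] <- NA
    cd <- as.Date(cd)
  }
  df$capture_date <- cd
  list(captures = df, occasions = grid)
}

#' Read seasonal water-temperature records
#'
#' One record per cave by year by season cell; an empty `mean_temp_C` field
#' encodes a missing cell (to be integrated over by data augmentation).
#'
#' @param path CSV with columns `cave_id`, `year`, `season` (summer|winter),
#'   `mean_temp_C` (empty = missing).
#' @param plausibility_window Observed values outside it are an error.
#'   Default 0--20 degrees C.
#' @return Tibble of temperature records; `mean_temp_C` is `NA` where missing.
#' @export
read_temperatures <- function(path, plausibility_window = c(0, 20)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("cave_id", "year", "season", "mean_temp_C")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$season %in% c("summer", "winter"))) {
    stop("unknown season tag(s): ",
         paste(unique(df$season[!df$season %in% c("summer", "winter")]),
               collapse = ", "))
  }
  key <- paste(df$cave_id, df$year, df$season)
  if (anyDuplicated(key)) {
    stop("duplicate temperature cell(s): ",
         paste(head(unique(key[duplicated(key)]), 5L), collapse = "; "))
  }
  df$mean_temp_C <- as.numeric(df$mean_temp_C)
  check_window(df$mean_temp_C, plausibility_window, "mean_temp_C",
               seq_len(nrow(df)))
  df
}

#' Read repeat fork-length measurements
#'
#' Repeat measures taken in immediate succession on a subset of fish are used
#' to estimate the fork-length measurement-error variance.
#'
#' @param path CSV with columns `fish_id`, `replicate_index`,
#'   `fork_length_mm`.
#' @return Tibble of repeat-measure records.
#' @export
read_repeats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("fish_id", "replicate_index", "fork_length_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$fork_length_mm <= 0)) stop("non-positive fork length in repeats")
  n <- table(df$fish_id)
  if (any(n < 2L)) {
    stop("fish with fewer than 2 replicates: ",
         paste(head(names(n)[n < 2L], 5L), collapse = ", "))
  }
  df
}

#' Write capture / temperature / repeat tables
#'
#' CSV writers matching the readers field-for-field (UTF-8, header row,
#' missing encoded as empty field), so that a write-then-read round trip
#' reproduces the records exactly.
#'
#' @param captures,temperatures,repeats Tibbles as produced by the readers or
#'   the synthetic-data generator.
#' @param path Output CSV path.
#' @name writers
#' @export
write_captures <- function(captures, path) {
  df <- as.data.frame(captures[, c("fish_id", "cave_id", "year", "month",
                                   "fork_length_mm", "capture_date")])
  df$capture_date <- ifelse(is.na(df$capture_date), "",
                            as.character(df$capture_date))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_temperatures <- function(temperatures, path) {
  df <- as.data.frame(temperatures[, c("cave_id", "year", "season",
                                       "mean_temp_C")])
  df$mean_temp_C <- ifelse(is.na(df$mean_temp_C), "",
                           format(df$mean_temp_C, digits = 15, trim = TRUE,
                                  scientific = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_repeats <- function(repeats, path) {
  write.csv(as.data.frame(
    repeats[, c("fish_id", "replicate_index", "fork_length_mm")]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a growth panel
#'
#' Builds the container the state-space fit consumes: a fish roster, a
#' fish-by-occasion fork-length matrix with `NA` where a fish was not
#' captured, the per-fish interval-length matrix in days, the season-interval
#' sequence, the cave-by-season-year temperature grid with its missingness
#' mask, and the centring constants (grand mean observed size and
#' temperature). Each fish's latent-size support runs from its first to its
#' last capture occasion inclusive; single-capture fish have one-point support
#' and contribute no growth intervals (they still inform the initial-size
#' distribution and the measurement model).
#'
#' Interval lengths use actual capture dates when a fish was measured with a
#' recorded date at both endpoints of a consecutive-occasion transition, and
#' the nominal mid-dates (16 June, 22 August) otherwise.
#'
#' @param captures Output of [read_captures()]/[validate_captures()] (the
#'   list, or just its `captures` tibble together with `occasions`).
#' @param temperatures Tibble from [read_temperatures()].
#' @param occasions Occasion grid; defaults to the grid attached to
#'   `captures`.
#' @return An object of class `growth_panel`.
#' @export
build_panel <- function(captures, temperatures, occasions = NULL) {
  if (is.list(captures) && !is.data.frame(captures) &&
      !is.null(captures$captures)) {
    if (is.null(occasions)) occasions <- captures$occasions
    captures <- captures$captures
  }
  if (is.null(occasions)) stop("occasion grid required")
  T <- nrow(occasions)
  ids <- sort(unique(captures$fish_id))
  n <- length(ids)
  if (n == 0L) stop("no fish in capture table")
  fi <- match(captures$fish_id, ids)

  Z <- matrix(NA_real_, n, T, dimnames = list(ids, NULL))
  Z[cbind(fi, captures$occasion)] <- captures$fork_length_mm
  Dt <- matrix(as.Date(NA), n, T)
  Dt[cbind(fi, captures$occasion)] <- captures$capture_date

  first <- apply(Z, 1L, function(z) which(!is.na(z))[1L])
  last <- apply(Z, 1L, function(z) max(which(!is.na(z))))
  cave <- captures$cave_id[match(ids, captures$fish_id)]
  fish <- tibble::tibble(fish_id = ids, cave_id = cave,
                         first_occasion = as.integer(first),
                         last_occasion = as.integer(last))

  ints <- season_intervals(occasions)

  # per-fish x step day counts: nominal by default, actual dates if both ends
  D <- matrix(NA_real_, n, max(T - 1L, 1L))
  if (T > 1L) {
    for (s in seq_len(T - 1L)) D[, s] <- ints$n_days[s]
    both <- !is.na(Dt[, -T, drop = FALSE]) & !is.na(Dt[, -1L, drop = FALSE])
    if (any(both)) {
      idx <- which(both, arr.ind = TRUE)
      dd <- as.integer(Dt[cbind(idx[, 1], idx[, 2] + 1L)]) -
        as.integer(Dt[cbind(idx[, 1], idx[, 2])])
      if (any(dd <= 0L)) stop("non-positive actual-date interval for a fish")
      D[idx] <- dd
    }
  }

  caves <- sort(unique(cave))
  tg <- temperatures
  tg$cell <- seq_len(nrow(tg))
  need <- unique(ints[, c("season", "season_year")])
  have <- unique(paste(tg$season, tg$year))
  lack <- !(paste(need$season, need$season_year) %in% have)
  if (any(lack)) {
    stop("temperature grid does not cover interval season-year(s): ",
         paste(need$season[lack], need$season_year[lack], collapse = ", "))
  }
  if (!all(caves %in% tg$cave_id)) {
    stop("temperature grid missing cave(s): ",
         paste(setdiff(caves, tg$cave_id), collapse = ", "))
  }

  zbar <- mean(captures$fork_length_mm)
  tbar <- mean(tg$mean_temp_C, na.rm = TRUE)
  if (!is.finite(zbar) || !is.finite(tbar)) {
    stop("centring constants must be finite (no observed sizes or temperatures?)")
  }

  structure(list(
    fish = fish, caves = caves, occasions = occasions, intervals = ints,
    obs = Z, days = D, temperatures = tg,
    zbar = zbar, tbar = tbar,
    n_missing_temp = sum(is.na(tg$mean_temp_C))
  ), class = "growth_panel")
}

#' @export
print.growth_panel <- function(x, ...) {
  cat("growth_panel:", nrow(x$fish), "fish,", length(x$caves), "caves,",
      nrow(x$occasions), "occasions\n")
  cat("  observations:", sum(!is.na(x$obs)),
      "| growth intervals:", n_growth_intervals(x), "\n")
  cat("  temperature cells:", nrow(x$temperatures),
      paste0("(", x$n_missing_temp, " missing, flagged for augmentation)"), "\n")
  cat("  centring: mean size", round(x$zbar, 2), "mm, mean temperature",
      round(x$tbar, 2), "C\n")
  invisible(x)
}

#' Total number of growth intervals in a panel
#'
#' Equals the sum over fish of (last capture occasion - first capture
#' occasion), independent of how many interior occasions were observed.
#' @param panel A `growth_panel`.
#' @export
n_growth_intervals <- function(panel) {
  sum(panel$fish$last_occasion - panel$fish$first_occasion)
}

#' Remove individual observations from a panel
#'
#' Masks the given (fish, occasion) measurements, used by the holdout
#' posterior predictive check. Masking must not touch a fish's first or last
#' capture (the latent support would shrink and the held-out occasion could
#' fall outside it).
#'
#' @param panel A `growth_panel`.
#' @param holdouts Data frame with columns `fish_id`, `occasion`.
#' @return The modified panel (centring constants are kept from the full
#'   panel so fits stay comparable).
#' @export
remove_observations <- function(panel, holdouts) {
  fi <- match(holdouts$fish_id, panel$fish$fish_id)
  if (anyNA(fi)) stop("unknown fish_id in holdouts")
  occ <- holdouts$occasion
  if (any(is.na(panel$obs[cbind(fi, occ)]))) {
    stop("holdout points to an occasion with no observation")
  }
  if (any(occ <= panel$fish$first_occasion[fi] |
          occ >= panel$fish$last_occasion[fi])) {
    stop("holdouts must be interior captures (not a fish's first or last)")
  }
  panel$obs[cbind(fi, occ)] <- NA_real_
  panel
}
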