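#' Life table of expected population mortality rates
#'
#' Builds a life-table object from a long-format data frame with columns
#' \code{age} (integer attained age, years), \code{year} (integer calendar
#' year), \code{rate} (deaths per person-year) and any further columns, which
#' are treated as stratifying labels (e.g. sex). Rates are piecewise constant
#' on 1-year \eqn{\times} 1-year Lexis squares, with age and calendar time
#' advancing together along follow-up. Each stratum must cover the full
#' age-by-year grid; lookups above the covered range are capped at the oldest
#' age / latest year (never extrapolated downward), lookups below it are
#' errors.
#'
#' @param df long-format data frame (columns \code{age}, \code{year},
#'   \code{rate}, optional strata columns).
#' @return An object of class \code{life_table}.
#' @examples
#' lt <- life_table(expand.grid(age = 50:60, year = 2010:2012, rate = 0.02))
#' pop_hazard(lt, age = 55.5, year = 2011.2)
#' @export
life_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("age", "year", "rate")
  if (!all(need %in% names(df)))
    stop("life table needs columns 'age', 'year', 'rate'")
  if (any(!is.finite(df$rate)) || any(df$rate < 0))
    stop("life-table rates must be finite and nonnegative")
  if (any(df$age != floor(df$age)) || any(df$year != floor(df$year)))
    stop("life-table 'age' and 'year' must be integers")
  strata_cols <- setdiff(names(df), need)
  key <- if (length(strata_cols))
    do.call(paste, c(df[strata_cols], sep = "|"))
  else rep("all", nrow(df))
  ages <- sort(unique(df$age))
  years <- sort(unique(df$year))
  if (!identical(ages, seq(min(ages), max(ages))) ||
      !identical(years, seq(min(years), max(years))))
    stop("life-table age and year ranges must be contiguous")
  strata <- sort(unique(key))
  rates <- array(NA_real_, dim = c(length(ages), length(years),
                                   length(strata)),
                 dimnames = list(ages, years, strata))
  rates[cbind(match(df$age, ages), match(df$year, years),
              match(key, strata))] <- df$rate
  if (anyNA(rates))
    stop("each stratum must cover the full age-by-year grid")
  structure(list(ages = ages, years = years, strata = strata, rates = rates,
                 strata_cols = strata_cols),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat("Life table: ages ", min(x$ages), "-", max(x$ages),
      ", years ", min(x$years), "-", max(x$years),
      ", ", length(x$strata), " stratum(s)",
      if (length(x$strata_cols))
        paste0(" [", paste(x$strata_cols, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Read / write a life table in long delimited format
#'
#' The on-disk format is a plain delimited text file with header columns
#' \code{age}, \code{year}, optional strata columns and \code{rate}.
#'
#' @param path file path; a \code{.csv} extension implies comma separation,
#'   otherwise whitespace/tab.
#' @return \code{read_life_table} returns a \code{\link{life_table}};
#'   \code{write_life_table} returns \code{path} invisibly.
#' @export
read_life_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  life_table(utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE))
}

#' @rdname read_life_table
#' @param lt a \code{life_table} object.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  grid <- expand.grid(age = lt$ages, year = lt$years, stratum = lt$strata,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rate <- lt$rates[cbind(match(grid$age, lt$ages),
                              match(grid$year, lt$years),
                              match(grid$stratum, lt$strata))]
  if (length(lt$strata_cols) == 1L)
    names(grid)[names(grid) == "stratum"] <- lt$strata_cols
  else if (!length(lt$strata_cols)) grid$stratum <- NULL
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(grid, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic Gompertz-shaped life table
#'
#' Generates a population life table with log-linear (Gompertz) age-specific
#' mortality rates \eqn{r(a) = \exp(c_0 + c_1 a)}, constant across calendar
#' years, with two sex strata (female rates multiplied by
#' \code{female_multiplier}). This synthetic table is a stand-in for national
#' life tables, which are typically not redistributable, and is the background
#' mortality used by the bundled simulation scenarios.
#'
#' @param ages integer vector of attained ages covered (default 0-99).
#' @param years integer vector of calendar years covered.
#' @param c0,c1 Gompertz intercept and slope on the log-rate scale.
#' @param female_multiplier multiplicative factor for the female stratum.
#' @return A \code{\link{life_table}} with a \code{sex} stratum
#'   (\code{"male"}, \code{"female"}).
#' @export
make_gompertz_life_table <- function(ages = 0:99, years = 2005:2019,
                                     c0 = -10, c1 = 0.09,
                                     female_multiplier = 0.8) {
  grid <- expand.grid(age = ages, year = years,
                      sex = c("female", "male"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rate <- exp(c0 + c1 * grid$age) *
    ifelse(grid$sex == "female", female_multiplier, 1)
  life_table(grid)
}

# resolve stratum labels to indices (vectorized, recycled to length n)
strata_index <- function(lt, strata, n) {
  if (is.null(strata)) {
    if (length(lt$strata) != 1L)
      stop("life table has multiple strata; 'strata' must be given")
    return(rep(1L, n))
  }
  idx <- match(as.character(strata), lt$strata)
  if (anyNA(idx))
    stop("unknown life-table stratum: ",
         paste(unique(strata[is.na(idx)]), collapse = ", "))
  rep_len(idx, n)
}

# capped cell indices; errors below the covered range (D8/D9)
age_index <- function(lt, age) {
  a <- floor(age + 1e-12)
  if (any(a < lt$ages[1])) stop("age below the life-table range")
  pmin(a, lt$ages[length(lt$ages)]) - lt$ages[1] + 1L
}
year_index <- function(lt, year) {
  y <- floor(year + 1e-12)
  if (any(y < lt$years[1])) stop("year below the life-table range")
  pmin(y, lt$years[length(lt$years)]) - lt$years[1] + 1L
}

#' Expected population mortality rate lookup
#'
#' Returns the piecewise-constant rate \eqn{h_P} of the Lexis cell containing
#' (\code{age}, \code{year}), by flooring both coordinates; coordinates above
#' the covered range are capped at the oldest age / latest year.
#'
#' @param lt a \code{\link{life_table}}.
#' @param age attained age(s), years (real).
#' @param year calendar time(s) (real).
#' @param strata stratum label(s); may be \code{NULL} for a one-stratum table.
#' @return Rates in deaths per person-year, recycled to a common length.
#' @export
pop_hazard <- function(lt, age, year, strata = NULL) {
  stopifnot(inherits(lt, "life_table"))
  n <- max(length(age), length(year), length(strata), 1L)
  age <- rep_len(age, n); year <- rep_len(year, n)
  lt$rates[cbind(age_index(lt, age), year_index(lt, year),
                 strata_index(lt, strata, n))]
}

# shared piecewise-constant walk along the Lexis diagonal.
# mode "increment": integrate the rate over [0, t] of follow-up.
# mode "invert":    find T with integral equal to target E.
lexis_walk <- function(lt, age, year, strata, tval, mode) {
  n <- max(length(age), length(year), length(strata), length(tval), 1L)
  age <- rep_len(as.numeric(age), n); year <- rep_len(as.numeric(year), n)
  sidx <- strata_index(lt, strata, n)
  amax <- lt$ages[length(lt$ages)]; ymax <- lt$years[length(lt$years)]
  a <- age; y <- year
  acc <- numeric(n)          # accumulated hazard
  off <- numeric(n)          # accumulated time
  out <- numeric(n)
  if (mode == "increment") {
    rem <- rep_len(as.numeric(tval), n)
    if (any(rem < 0)) stop("'t' must be nonnegative")
    active <- rem > 0
  } else {
    E <- rep_len(as.numeric(tval), n)
    out[] <- NA_real_
    active <- E > 0
    out[!active] <- 0
  }
  while (any(active)) {
    ai <- age_index(lt, a[active]); yi <- year_index(lt, y[active])
    r <- lt$rates[cbind(ai, yi, sidx[active])]
    capped <- a[active] >= amax + 1 - 1e-12 & y[active] >= ymax + 1 - 1e-12
    # segment until the next integer age or year boundary (Inf once capped:
    # the rate no longer changes)
    d_age <- floor(a[active] + 1e-12) + 1 - a[active]
    d_year <- floor(y[active] + 1e-12) + 1 - y[active]
    d <- ifelse(capped, Inf, pmin(d_age, d_year))
    if (mode == "increment") {
      d <- pmin(d, rem[active])
      acc[active] <- acc[active] + r * d
      rem[active] <- rem[active] - d
      still <- rem[active] > 1e-14
    } else {
      need <- E[active] - acc[active]
      done <- r * d >= need | (capped & r == 0)
      tdone <- ifelse(r > 0, off[active] + need / r, Inf)
      out[active][done] <- tdone[done]
      acc[active] <- acc[active] + r * d
      off[active] <- off[active] + d
      still <- !done
    }
    a[active] <- a[active] + d
    y[active] <- y[active] + d
    active[active] <- still
  }
  if (mode == "increment") acc else out
}

#' Cumulative population hazard over a follow-up interval
#'
#' Integrates the life-table rate from diagnosis (\code{age}, \code{year}) over
#' \code{t} years of follow-up, with attained age and calendar time advancing
#' together: \eqn{H_P(\mathrm{age}+t;\mathrm{year}+t) -
#' H_P(\mathrm{age};\mathrm{year})}. Additive in \code{t}: splitting the
#' interval and chaining gives the same total.
#'
#' @inheritParams pop_hazard
#' @param t nonnegative follow-up duration(s), years.
#' @return Nonnegative cumulative hazards.
#' @export
pop_cum_hazard_increment <- function(lt, age, year, strata = NULL, t) {
  stopifnot(inherits(lt, "life_table"))
  lexis_walk(lt, age, year, strata, t, "increment")
}

#' Simulate time to death from other causes
#'
#' Exact inverse-transform simulation from the piecewise-exponential survival
#' implied by the life table: the returned \eqn{T} solves
#' \eqn{H_P(\mathrm{age}+T) - H_P(\mathrm{age}) = -\log u}, so small \code{u}
#' gives long survival (\eqn{S(T) = u}). Returns \code{Inf} when the total
#' available hazard never reaches \eqn{-\log u} (possible only with
#' zero-rate tail cells).
#'
#' @inheritParams pop_hazard
#' @param u uniform draws in \eqn{(0, 1)}.
#' @return Simulated times (years), possibly \code{Inf}.
#' @export
simulate_other_cause_time <- function(lt, age, year, strata = NULL, u) {
  stopifnot(inherits(lt, "life_table"))
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stop("'u' must lie in (0, 1)")
  lexis_walk(lt, age, year, strata, -log(u), "invert")
}
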