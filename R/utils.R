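# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables use the conventional
#' half-away-from-zero rule, so displayed values match hand computation.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Age in completed (floored) whole years at `at`.
floor_age <- function(birth_date, at) {
  birth <- as.POSIXlt(birth_date)
  ref <- as.POSIXlt(at)
  age <- ref$year - birth$year
  before_birthday <- ref$mon < birth$mon |
    (ref$mon == birth$mon & ref$mday < birth$mday)
  age - as.integer(before_birthday)
}

# Calendar year-month key as "YYYY-MM".
year_month <- function(date) {
  format(date, "%Y-%m")
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_rng <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Draw integer dates uniformly in the closed interval [from, to] (Date scalars
# or vectors recycled against n).
runif_dates <- function(n, from, to) {
  span <- as.integer(to - from)
  from + floor(runif(n) * (span + 1))
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a single nonnegative integer.", name))
  }
  invisible(as.integer(x))
}
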