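# Internal helpers shared across modules.

# Days since the calibration date (2000-01-01) used for the report time stamp.
CALIBRATION_DATE <- as.Date("2000-01-01")

days_since_calibration <- function(date) {
  as.integer(date - CALIBRATION_DATE)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

clamp01 <- function(p) pmin(pmax(p, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# month*100 + day, for window comparisons that treat every year uniformly
month_day_code <- function(date) {
  lt <- as.POSIXlt(date)
  (lt$mon + 1L) * 100L + lt$mday
}

parse_month_day <- function(md) {
  # "03-11" -> 311L
  parts <- strsplit(md, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("month-day must be 'MM-DD', got: ", md)
  as.integer(parts[1]) * 100L + as.integer(parts[2])
}

report_year <- function(reports) {
  as.integer(format(reports$date, "%Y"))
}

stopifnot_scalar_chr <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be a single non-missing string", call. = FALSE)
  }
}
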