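#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stop with a message that names the offending field/column; all user-facing
## validation errors in the package flow through here so tests can match on
## the field name.
fb_stop <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

fb_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

## Require columns in a data.frame, naming the first missing one.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    fb_stop("%s is missing required column '%s'", what, missing[[1L]])
  }
  invisible(df)
}

check_nonneg <- function(df, cols, what = "input") {
  for (cl in cols) {
    v <- df[[cl]]
    if (any(!is.finite(v))) {
      fb_stop("%s column '%s' contains missing or non-finite values", what, cl)
    }
    if (any(v < 0)) {
      fb_stop("%s column '%s' contains negative values", what, cl)
    }
  }
  invisible(df)
}

## Deterministic per-stage seed derived from a master seed.  Kept well below
## .Machine$integer.max so downstream set.seed() always receives a valid
## 32-bit integer.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, portfolio = 23L, commitments = 37L,
               flyers = 53L, geo = 71L, profile = 89L, replicate = 101L)
  off <- offsets[[stage]] %||% 131L
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% 2147483647)
}

## Midranks (average ranks), the tie convention used by every rank statistic
## in the package.
midrank <- function(x) rank(x, ties.method = "average")
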