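# Internal helpers shared across modules.

# Abort with a kgdemand error class so callers can condition on failures.
kgd_abort <- function(message, class = "kgd_error", ...) {
  abort(message, class = c(class, "kgd_error"), ...)
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    kgd_abort(
      sprintf(
        "%s is missing required column(s): %s",
        what, paste(missing, collapse = ", ")
      ),
      class = "kgd_error_schema"
    )
  }
  invisible(df)
}

# ISO-8601 year-week label ("2023-W05") for a Date vector.
iso_week_label <- function(dates) {
  format(dates, "%G-W%V")
}

# Monday that starts the ISO week containing each date.
iso_week_start <- function(dates) {
  wday <- as.integer(format(dates, "%u")) # 1 = Monday
  dates - (wday - 1L)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a vector of n child seeds (< 2^31) from one root seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

relu <- function(x) {
  pmax(x, 0)
}

sigmoid <- function(x) {
  stats::plogis(x)
}
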