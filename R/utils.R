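# Internal input-validation helpers.  All user-facing functions funnel
# range checks through these so error messages are uniform.

check_range <- function(x, lo, hi, what) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric with no missing values.", what))
  }
  if (any(x < lo | x > hi)) {
    abort(sprintf("`%s` must lie in [%g, %g].", what, lo, hi))
  }
  invisible(x)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric with no missing values.", what))
  }
  if (any(x < 0)) {
    abort(sprintf("`%s` must be non-negative.", what))
  }
  invisible(x)
}

check_month <- function(month) {
  if (anyNA(month) || any(month != as.integer(month)) ||
      any(month < 1L) || any(month > 12L)) {
    abort("`month` must be an integer calendar month in 1..12.")
  }
  invisible(as.integer(month))
}

check_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Recycle scalar arguments against a common length, erroring on mismatches.
recycle_common <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- lengths(args) != 1L & lengths(args) != n
  if (any(bad)) {
    abort(sprintf("Arguments %s cannot be recycled to a common length.",
                  paste(names(args)[bad], collapse = ", ")))
  }
  lapply(args, rep_len, n)
}

# Fast clamps for hot loops (indexing beats pmax/pmin attribute handling).
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
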