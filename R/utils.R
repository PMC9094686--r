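# small shared helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

# strictly increasing check with index of first offender
assert_increasing <- function(t, what) {
  if (length(t) >= 2) {
    bad <- which(diff(t) <= 0)
    if (length(bad) > 0)
      stop(sprintf("%s: non-monotonic timestamps (first offending index %d)",
                   what, bad[1] + 1L), call. = FALSE)
  }
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# intervals: n x 2 matrix [start, end); helpers used by occupancy/glances
interval_matrix <- function(start, end) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  if (nrow(m) && any(m[, 2] < m[, 1])) stop("interval end before start")
  m
}

interval_total <- function(m) if (is.null(m) || nrow(m) == 0) 0 else sum(m[, 2] - m[, 1])

# membership of time points in a union of [start, end) intervals
in_intervals <- function(t, m) {
  if (is.null(m) || nrow(m) == 0) return(rep(FALSE, length(t)))
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(m))) inside <- inside | (t >= m[i, 1] & t < m[i, 2])
  inside
}
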