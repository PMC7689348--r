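# Small shared helpers. All angles in degrees, all lengths in meters,
# all times in seconds unless a name says otherwise.

#' Wrap an angle to (-180, 180]
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s) in degrees.
#' @keywords internal
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Unwrap a heading sequence (degrees)
#'
#' Removes +/-360 jumps so consecutive samples differ by less than 180 deg.
#' NA samples are passed through and do not reset the unwrapping.
#' @keywords internal
unwrap_deg <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) < 2L) return(x)
  v <- x[ok]
  d <- wrap_angle(diff(v))
  x[ok] <- v[1L] + c(0, cumsum(d))
  x
}

# Euclidean norm of rows of a 2- or 3-column matrix
row_norms <- function(m) sqrt(rowSums(m^2))

# deterministic 31-bit sub-seed derived from a base seed and stream indices
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 9973 + 101) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

# run code under a temporary RNG state; restores .Random.seed afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_nav <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
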