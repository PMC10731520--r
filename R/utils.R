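# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lo || x > hi)
    stopf("'%s' must be in [%s, %s], got %s", name, lo, hi, x)
  invisible(x)
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% (.Machine$integer.max - 1L)) + 1L
}

# View a T x H x W stack as a T x (H*W) matrix (no copy semantics guaranteed,
# but dims are column-major so pixel p = h + (w-1)*H).
as_tp <- function(x) {
  d <- dim(x)
  matrix(x, d[1L], d[2L] * d[3L])
}

tp_to_stack <- function(m, h, w) {
  array(m, dim = c(nrow(m), h, w))
}

# Normalized 1-D Gaussian kernel truncated at `radius` (default 4 sigma).
gauss_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution with reflect padding, kernel must be odd-length.
conv_reflect <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- length(x)
  if (r == 0L) return(x * k)
  pad <- c(x[(r + 1L):2L], x, x[(n - 1L):(n - r)])
  stats::filter(pad, k, method = "convolution", sides = 2L)[(r + 1L):(r + n)]
}

# Zero-phase (forward-backward) filtering of every column, replicating
# signal::filtfilt semantics (zero padding by twice the coefficient length,
# forward then time-reversed pass); compiled inner loop.
filtfilt_mat <- function(x, b, a) {
  filtfilt_cols_cpp(as.matrix(x), as.numeric(b), as.numeric(a))
}

# Hash of an R object (configuration provenance); md5 of its serialization.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
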