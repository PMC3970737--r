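# Internal helpers shared across modules.

# Local maxima of `x` with a minimum peak separation (in samples) and a
# minimum height. Greedy selection in decreasing height order, so the tallest
# peak in any crowded neighbourhood wins. Returns sorted sample indices.
find_peaks <- function(x, min_dist = 1L, min_height = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  cand <- which(is_peak & x >= min_height)
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

# Quadratic Savitzky-Golay smoothing with an odd window of `n` samples.
`%||%` <- function(a, b) if (is.null(a)) b else a

sg_smooth <- function(x, n) {
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L
  n <- max(n, 5L)
  if (n >= length(x)) return(x)
  as.numeric(signal::sgolayfilt(x, p = 2, n = n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
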