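# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Deterministic child seed derived from a root seed and a stage label, so one
# root seed reproduces every stage. Kept below 2^31 - 1 (valid R integer).
child_seed <- function(seed, label) {
  bytes <- utf8ToInt(as.character(label))
  h <- as.numeric(seed) %% 2147483647
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# Low-pass-filtered standard-normal noise: white noise convolved with a
# Gaussian kernel whose time constant matches the requested cutoff (Hz),
# rescaled to unit marginal variance. Deterministic under the caller's RNG.
smooth_noise <- function(n, fps, cutoff = 0.5) {
  sd_samp <- max(fps / (2 * pi * cutoff), 0.5)
  half <- ceiling(4 * sd_samp)
  k <- stats::dnorm(seq(-half, half), sd = sd_samp)
  k <- k / sqrt(sum(k^2)) # unit output variance for unit white input
  w <- stats::rnorm(n + 2 * half)
  out <- stats::filter(w, k, method = "convolution", sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}
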