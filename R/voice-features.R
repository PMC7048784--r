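# Praat-style prosody extraction: autocorrelation pitch, glottal-cycle
# analogues, jitter/shimmer families, harmonics-to-noise ratio, MFCCs.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Autocorrelation pitch track
#'
#' Estimates a fundamental-frequency track with the windowed-autocorrelation
#' method: per analysis frame, the normalized autocorrelation of the
#' mean-removed, Hann-windowed signal is divided by the autocorrelation of
#' the window itself (undoing the window's tapering bias), candidate lags are
#' searched in `[1/fmax, 1/fmin]`, and the best peak is refined by parabolic
#' interpolation. A small octave cost favors the shorter lag among
#' near-equal peaks, preventing subharmonic (halved-F0) errors. A frame is
#' voiced when the corrected peak correlation reaches `voicing_threshold`;
#' that correlation, clipped to (0, 1), is kept as the frame's harmonicity.
#'
#' @param wave Numeric mono signal.
#' @param rate Sampling rate (Hz); must be at least `4 * fmax`.
#' @param fmin,fmax Pitch search floor/ceiling in Hz (defaults 75 and 500,
#'   covering adult male and female speech).
#' @param frame Analysis frame length in seconds (default 0.04).
#' @param hop Hop between frames in seconds (default 0.01).
#' @param voicing_threshold Minimum corrected autocorrelation for a voiced
#'   frame (default 0.45).
#' @param octave_cost Per-octave score penalty on longer lags (default 0.05);
#'   breaks near-ties between the true period and its subharmonics in favor
#'   of the higher F0.
#' @return Data frame (class `pitch_track`): `time` (frame center, s), `f0`
#'   (Hz, `NA` when unvoiced), `voiced`, `harmonicity_r`.
#' @export
estimate_pitch <- function(wave, rate, fmin = 75, fmax = 500,
                           frame = 0.04, hop = 0.01,
                           voicing_threshold = 0.45, octave_cost = 0.05) {
  assert_that(rate >= 4 * fmax, "sampling rate must be at least 4 * fmax")
  flen <- round(frame * rate)
  hlen <- max(1L, round(hop * rate))
  assert_that(length(wave) >= flen,
              "wave shorter than one analysis frame")
  lmin <- max(2L, floor(rate / fmax))
  lmax <- min(flen - 2L, ceiling(rate / fmin))
  assert_that(lmax > lmin + 2L, "frame too short for the pitch floor")
  starts <- seq(1L, length(wave) - flen + 1L, by = hlen)
  win <- hann_window(flen)
  nfft <- 2^ceiling(log2(2 * flen))

  # autocorrelation of the window itself (computed once)
  wpad <- c(win, rep(0, nfft - flen))
  rw <- Re(stats::fft(Mod(stats::fft(wpad))^2, inverse = TRUE))
  rw <- rw[1:(lmax + 2L)] / rw[1]

  n_frames <- length(starts)
  f0 <- rep(NA_real_, n_frames)
  rbest <- rep(NA_real_, n_frames)
  idx <- outer(0:(flen - 1L), starts, "+")
  block <- 256L
  for (b0 in seq(1L, n_frames, by = block)) {
    b1 <- min(b0 + block - 1L, n_frames)
    X <- matrix(wave[idx[, b0:b1, drop = FALSE]], nrow = flen)
    X <- sweep(X, 2, colMeans(X)) * win
    Xp <- rbind(X, matrix(0, nfft - flen, ncol(X)))
    S <- Mod(stats::mvfft(Xp))^2
    A <- Re(stats::mvfft(S, inverse = TRUE))[1:(lmax + 2L), , drop = FALSE]
    a0 <- A[1, ]
    a0[a0 <= 0] <- Inf
    R <- sweep(A, 2, a0, "/") / rw  # window-corrected normalized ACF
    lags <- lmin:lmax
    score <- R[lags + 1L, , drop = FALSE] -
      octave_cost * log2(lags / lmin)
    pick <- max.col(t(score), ties.method = "first")
    for (k in seq_along(pick)) {
      l <- lags[pick[k]]
      j <- b0 + k - 1L
      rm1 <- R[l, k]; r0 <- R[l + 1L, k]; rp1 <- R[l + 2L, k]
      denom <- rm1 - 2 * r0 + rp1
      delta <- if (is.finite(denom) && abs(denom) > 1e-12) {
        max(-0.5, min(0.5, 0.5 * (rm1 - rp1) / denom))
      } else 0
      rpk <- r0 - 0.25 * (rm1 - rp1) * delta
      f <- rate / (l + delta)
      if (is.finite(rpk) && rpk >= voicing_threshold && f >= fmin && f <= fmax) {
        f0[j] <- f
        rbest[j] <- min(max(rpk, 1e-6), 1 - 1e-6)
      }
    }
  }
  out <- data.frame(
    time = (starts - 1L) / rate + frame / 2,
    f0 = f0,
    voiced = !is.na(f0),
    harmonicity_r = rbest
  )
  class(out) <- c("pitch_track", "data.frame")
  attr(out, "frame") <- frame
  attr(out, "hop") <- hop
  out
}

#' Glottal-cycle analogue extraction
#'
#' Locates successive cycle peaks within each contiguous voiced stretch of a
#' pitch track by searching the waveform maximum inside consecutive windows
#' of width one predicted period (from the local F0). Periods are inter-peak
#' intervals; amplitudes are peak absolute amplitudes. Stretches shorter
#' than 3 cycles are dropped, and no cycle spans an unvoiced gap.
#'
#' @param wave Numeric mono signal.
#' @param rate Sampling rate (Hz).
#' @param track A `pitch_track` from [estimate_pitch()].
#' @return Object of class `period_sequence`: list of stretches, each with
#'   `peak_times` (s), `periods` (s) and `amplitudes` (linear).
#' @export
extract_periods <- function(wave, rate, track) {
  frame <- attr(track, "frame") %||% 0.04
  runs <- rle(track$voiced)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  stretches <- list()
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    t_lo <- max(track$time[i0] - frame / 2, 0)
    t_hi <- min(track$time[i1] + frame / 2, (length(wave) - 1) / rate)
    f0_med <- stats::median(track$f0[i0:i1])
    f0_local <- if (i1 > i0) {
      # clamp local predictions to a plausible band around the stretch
      # median so an isolated octave-error frame cannot derail the cycle
      # marker, while genuine F0 drift is still followed
      function(t) {
        f <- stats::approx(track$time[i0:i1], track$f0[i0:i1],
                           xout = t, rule = 2)$y
        pmin(pmax(f, f0_med / 1.4), f0_med * 1.4)
      }
    } else {
      function(t) rep(track$f0[i0], length(t))
    }
    T0 <- 1 / f0_local(t_lo)
    w0 <- floor(t_lo * rate) + 1L
    w1 <- min(floor((t_lo + T0) * rate) + 1L, length(wave))
    if (w1 <= w0) next
    p_idx <- w0 - 1L + which.max(wave[w0:w1])
    peaks <- p_idx
    repeat {
      t_prev <- (peaks[length(peaks)] - 1L) / rate
      Tl <- 1 / f0_local(t_prev)
      lo <- t_prev + 0.5 * Tl
      hi <- t_prev + 1.5 * Tl
      if (hi > t_hi) break
      a <- floor(lo * rate) + 1L
      b <- min(floor(hi * rate) + 1L, length(wave))
      if (b <= a) break
      peaks <- c(peaks, a - 1L + which.max(wave[a:b]))
    }
    if (length(peaks) >= 4L) {  # >= 3 cycles
      # sub-sample peak refinement: least-squares parabola over +/-3 samples
      # around the maximum, so period estimates are neither quantized to the
      # sample grid nor dominated by additive noise at a single sample
      pt <- numeric(length(peaks))
      pa <- numeric(length(peaks))
      for (q in seq_along(peaks)) {
        p <- peaks[q]
        h <- min(3L, p - 1L, length(wave) - p)
        if (h >= 1L) {
          off <- (-h):h
          y <- wave[p + off]
          cf <- stats::.lm.fit(cbind(1, off, off^2), y)$coefficients
          dlt <- if (abs(cf[3]) > 1e-30) max(-1, min(1, -cf[2] / (2 * cf[3]))) else 0
          pt[q] <- (p - 1L + dlt) / rate
          pa[q] <- abs(cf[1] + cf[2] * dlt + cf[3] * dlt^2)
        } else {
          pt[q] <- (p - 1L) / rate
          pa[q] <- abs(wave[p])
        }
      }
      stretches[[length(stretches) + 1L]] <- list(
        peak_times = pt,
        periods = diff(pt),
        amplitudes = pa
      )
    }
  }
  structure(list(stretches = stretches, rate = rate),
            class = "period_sequence")
}

#' @export
print.period_sequence <- function(x, ...) {
  cat(sprintf("<period_sequence> %d voiced stretch(es), %d cycles\n",
              length(x$stretches),
              sum(vapply(x$stretches, function(s) length(s$periods),
                         integer(1)))))
  invisible(x)
}

as_stretch_list <- function(x, field) {
  if (inherits(x, "period_sequence")) {
    lapply(x$stretches, `[[`, field)
  } else if (is.list(x)) {
    x
  } else {
    list(as.numeric(x))
  }
}

# pooled neighborhood-deviation mean: mean over all positions (in all
# stretches) with a full k-point centered window of |x_i - mean(window)|
pooled_apq <- function(chunks, k) {
  h <- (k - 1L) %/% 2L
  devs <- unlist(lapply(chunks, function(x) {
    n <- length(x)
    if (n < k) return(numeric(0))
    vapply((h + 1L):(n - h), function(i) {
      abs(x[i] - mean(x[(i - h):(i + h)]))
    }, numeric(1))
  }))
  if (length(devs)) mean(devs) else NA_real_
}

#' Jitter measures (period perturbation)
#'
#' The five standard period-perturbation measures on a cycle-period
#' sequence: `local` (mean absolute consecutive difference over mean
#' period), `local_abs` (same, in seconds), `rap` (3-point relative average
#' perturbation), `ppq5` (5-point period perturbation quotient) and
#' `ddp` (= 3 * rap). Differences never span stretch boundaries.
#'
#' @param T A numeric vector of periods (seconds), a list of such vectors
#'   (one per voiced stretch), or a `period_sequence`.
#' @return Named numeric vector `jitter_local`, `jitter_local_abs`,
#'   `jitter_rap`, `jitter_ppq5`, `jitter_ddp`; all `NA` with fewer than 3
#'   periods.
#' @export
jitter_measures <- function(T) {
  chunks <- as_stretch_list(T, "periods")
  all_T <- unlist(chunks)
  out <- c(jitter_local = NA_real_, jitter_local_abs = NA_real_,
           jitter_rap = NA_real_, jitter_ppq5 = NA_real_,
           jitter_ddp = NA_real_)
  if (length(all_T) < 3) return(out)
  assert_that(all(all_T > 0), "periods must be positive")
  mT <- mean(all_T)
  d1 <- unlist(lapply(chunks, function(x) abs(diff(x))))
  if (length(d1)) {
    out["jitter_local_abs"] <- mean(d1)
    out["jitter_local"] <- mean(d1) / mT
  }
  rap <- pooled_apq(chunks, 3L)
  out["jitter_rap"] <- rap / mT
  out["jitter_ppq5"] <- pooled_apq(chunks, 5L) / mT
  d2 <- unlist(lapply(chunks, function(x) {
    if (length(x) >= 3) abs(diff(diff(x))) else numeric(0)
  }))
  if (length(d2)) out["jitter_ddp"] <- mean(d2) / mT
  out
}

#' Shimmer measures (amplitude perturbation)
#'
#' The six standard amplitude-perturbation measures: `local`, `local_db`
#' (mean absolute dB change between consecutive cycles), `apq3`, `apq5`,
#' `apq11` (k-point amplitude perturbation quotients; `apq11` is `NA` unless
#' some stretch has at least 11 cycles) and `dda` (= 3 * apq3).
#'
#' @param A A numeric vector of cycle amplitudes (> 0), a list of such
#'   vectors, or a `period_sequence`.
#' @return Named numeric vector `shimmer_local`, `shimmer_local_db`,
#'   `shimmer_apq3`, `shimmer_apq5`, `shimmer_apq11`, `shimmer_dda`.
#' @export
shimmer_measures <- function(A) {
  chunks <- as_stretch_list(A, "amplitudes")
  all_A <- unlist(chunks)
  out <- c(shimmer_local = NA_real_, shimmer_local_db = NA_real_,
           shimmer_apq3 = NA_real_, shimmer_apq5 = NA_real_,
           shimmer_apq11 = NA_real_, shimmer_dda = NA_real_)
  if (length(all_A) < 3) return(out)
  assert_that(all(all_A > 0), "amplitudes must be positive")
  mA <- mean(all_A)
  d1 <- unlist(lapply(chunks, function(x) abs(diff(x))))
  r1 <- unlist(lapply(chunks, function(x) {
    if (length(x) >= 2) abs(20 * log10(x[-1] / x[-length(x)])) else numeric(0)
  }))
  if (length(d1)) {
    out["shimmer_local"] <- mean(d1) / mA
    out["shimmer_local_db"] <- mean(r1)
  }
  out["shimmer_apq3"] <- pooled_apq(chunks, 3L) / mA
  out["shimmer_apq5"] <- pooled_apq(chunks, 5L) / mA
  out["shimmer_apq11"] <- pooled_apq(chunks, 11L) / mA
  out["shimmer_dda"] <- 3 * out["shimmer_apq3"]
  out
}

#' Harmonics-to-noise ratio summary
#'
#' Per voiced frame, HNR in dB is `10 * log10(r / (1 - r))` where `r` is the
#' frame's corrected autocorrelation peak (the fraction of frame power that
#' is periodic); values are clipped to [-20, 40] dB and summarized over
#' voiced frames.
#'
#' @param track A `pitch_track` from [estimate_pitch()].
#' @return Named numeric vector `hnr_mean`, `hnr_median`, `hnr_sd` (dB);
#'   all `NA` without voiced frames.
#' @export
hnr_stats <- function(track) {
  r <- track$harmonicity_r[track$voiced]
  if (!length(r)) {
    return(c(hnr_mean = NA_real_, hnr_median = NA_real_, hnr_sd = NA_real_))
  }
  h <- pmin(pmax(10 * log10(r / (1 - r)), -20), 40)
  c(hnr_mean = mean(h), hnr_median = stats::median(h),
    hnr_sd = if (length(h) > 1) stats::sd(h) else 0)
}

mel_of_hz <- function(f) 2595 * log10(1 + f / 700)
hz_of_mel <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters equally spaced on the mel scale between 0 Hz and
#' `rate / 2`, evaluated on the positive-frequency FFT bins.
#'
#' @param n_mel Number of filters.
#' @param nfft FFT length.
#' @param rate Sampling rate (Hz).
#' @return `n_mel x (nfft/2 + 1)` matrix.
#' @export
mel_filterbank <- function(n_mel, nfft, rate) {
  n_bins <- nfft / 2 + 1
  freqs <- (0:(n_bins - 1)) * rate / nfft
  edges <- hz_of_mel(seq(0, mel_of_hz(rate / 2), length.out = n_mel + 2))
  fb <- matrix(0, n_mel, n_bins)
  for (m in seq_len(n_mel)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Orthonormal DCT-II matrix
#'
#' @param n_out Number of output coefficients (rows).
#' @param n_in Input length (columns); default `n_out`.
#' @return `n_out x n_in` matrix `C` with `C %*% x` the first `n_out`
#'   orthonormal DCT-II coefficients of `x`; for `n_out = n_in` the matrix
#'   is orthogonal (`t(C) %*% C = I`).
#' @export
dct_matrix <- function(n_out, n_in = n_out) {
  j <- 0:(n_out - 1)
  i <- 0:(n_in - 1)
  C <- sqrt(2 / n_in) * cos(pi * outer(j, i + 0.5) / n_in)
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

#' Mean mel-frequency cepstral coefficients
#'
#' Hann-windowed magnitude spectrogram, mel filterbank (default 64 filters,
#' 0 to Nyquist), log with floor `1e-10`, orthonormal DCT-II; returns the
#' per-coefficient mean over frames of coefficients 0..`n_coeff - 1`.
#'
#' @param wave Numeric mono signal (non-empty).
#' @param rate Sampling rate (Hz).
#' @param n_coeff Number of coefficients (default 40).
#' @param frame,hop Frame length and hop in seconds (defaults 0.025, 0.010).
#' @param n_mel Number of mel filters (default 64); must be `>= n_coeff`.
#' @return Named numeric vector `mfcc_01` ... (length `n_coeff`).
#' @export
mfcc_mean <- function(wave, rate, n_coeff = 40, frame = 0.025, hop = 0.010,
                      n_mel = 64) {
  assert_that(length(wave) > 0, "wave must be non-empty")
  assert_that(n_coeff <= n_mel, "n_coeff must not exceed n_mel")
  flen <- round(frame * rate)
  hlen <- max(1L, round(hop * rate))
  if (length(wave) < flen) wave <- c(wave, rep(0, flen - length(wave)))
  starts <- seq(1L, length(wave) - flen + 1L, by = hlen)
  win <- hann_window(flen)
  nfft <- 2^ceiling(log2(flen))
  idx <- outer(0:(flen - 1L), starts, "+")
  X <- matrix(wave[idx], nrow = flen) * win
  Xp <- rbind(X, matrix(0, nfft - flen, ncol(X)))
  mag <- Mod(stats::mvfft(Xp))[1:(nfft / 2 + 1), , drop = FALSE]
  fb <- mel_filterbank(n_mel, nfft, rate)
  loge <- log(pmax(fb %*% mag, 1e-10))
  C <- dct_matrix(n_coeff, n_mel)
  cep <- C %*% loge
  stats::setNames(rowMeans(cep), sprintf("mfcc_%02d", seq_len(n_coeff)))
}

#' Full prosodic summary of one recording
#'
#' Composes pitch tracking, cycle extraction, jitter/shimmer, HNR, overall
#' root-mean-square energy and mean MFCCs into the 57-field per-recording
#' voice feature vector.
#'
#' @param wave Numeric mono signal.
#' @param rate Sampling rate (Hz).
#' @param fmin,fmax,voicing_threshold Passed to [estimate_pitch()].
#' @param n_mfcc Number of MFCCs (default 40).
#' @return Named numeric vector with 57 fields: `f0_mean`, `f0_sd`, 5 jitter,
#'   6 shimmer, 3 HNR aggregates, `rms_energy` and 40 MFCC means. Fields
#'   that cannot be computed (e.g. no voiced frames) are `NA`.
#' @export
voice_summary <- function(wave, rate, fmin = 75, fmax = 500,
                          voicing_threshold = 0.45, n_mfcc = 40) {
  track <- estimate_pitch(wave, rate, fmin = fmin, fmax = fmax,
                          voicing_threshold = voicing_threshold)
  f0v <- track$f0[track$voiced]
  ps <- extract_periods(wave, rate, track)
  c(
    f0_mean = if (length(f0v)) mean(f0v) else NA_real_,
    f0_sd = if (length(f0v) > 1) stats::sd(f0v) else NA_real_,
    jitter_measures(ps),
    shimmer_measures(ps),
    hnr_stats(track),
    rms_energy = sqrt(mean(wave^2)),
    mfcc_mean(wave, rate, n_coeff = n_mfcc)
  )
}
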