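# Short-time Fourier analysis primitives shared by all spectral descriptors.
# Frame length 2048, hop 512, Hann window, frames fully inside the signal
# (no boundary padding). These are the extractor defaults recorded in the
# settings sidecar of every run.

.default_n_fft <- 2048L
.default_hop <- 512L

#' Default frame-analysis settings used by the descriptor registry
#' @return List with `n_fft` and `hop` (samples).
#' @export
stft_settings <- function() list(n_fft = .default_n_fft, hop = .default_hop)

# slice a signal into n_fft x n_frames columns
frame_signal <- function(x, n_fft = .default_n_fft, hop = .default_hop) {
  n <- length(x)
  if (n < n_fft) {
    stop("input too short: ", n, " samples < one analysis frame (",
         n_fft, " samples)")
  }
  n_frames <- 1L + (n - n_fft) %/% hop
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1L) * hop, `+`)
  matrix(x[idx], nrow = n_fft)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

# magnitude spectrogram: (n_fft/2 + 1) x n_frames, plus bin frequencies
stft_magnitude <- function(clip, n_fft = .default_n_fft, hop = .default_hop) {
  frames <- frame_signal(clip$samples, n_fft, hop) * hann_window(n_fft)
  spec <- stats::mvfft(frames)
  n_bins <- n_fft %/% 2L + 1L
  list(mag = abs(spec[seq_len(n_bins), , drop = FALSE]),
       freqs = (seq_len(n_bins) - 1L) * clip$sample_rate / n_fft)
}

# ---- filterbanks (cached per sample rate) ---------------------------------

.fb_cache <- new.env(parent = emptyenv())

# hz <-> mel (Slaney-style: linear below 1 kHz, log above)
hz_to_mel <- function(f) {
  ifelse(f < 1000, f / (200 / 3),
         15 + log(pmax(f, 1000) / 1000) / (log(6.4) / 27))
}
mel_to_hz <- function(m) {
  ifelse(m < 15, m * (200 / 3), 1000 * exp((m - 15) * (log(6.4) / 27)))
}

# n_mels x n_bins triangular mel filterbank on the STFT bin frequencies
mel_filterbank <- function(sr, n_fft = .default_n_fft, n_mels = 128L) {
  key <- paste0("mel_", sr, "_", n_fft, "_", n_mels)
  if (!is.null(.fb_cache[[key]])) return(.fb_cache[[key]])
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * sr / n_fft
  mel_pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(sr / 2),
                           length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- mel_pts[m]; ce <- mel_pts[m + 1L]; hi <- mel_pts[m + 2L]
    up <- (freqs - lo) / max(ce - lo, .Machine$double.eps)
    dn <- (hi - freqs) / max(hi - ce, .Machine$double.eps)
    fb[m, ] <- pmax(0, pmin(up, dn))
    # area normalization so filters carry comparable energy
    width <- (hi - lo) / 2
    if (width > 0) fb[m, ] <- fb[m, ] * 2 / (hi - lo)
  }
  .fb_cache[[key]] <- fb
  fb
}

# log-frequency (constant-Q style) triangular filterbank folded later into
# chroma; centers at semitones from C1, optional bandwidth broadening
# (gamma, in fractions of a semitone) for the variable-Q variant
logfreq_filterbank <- function(sr, n_fft = .default_n_fft,
                               fmin = 32.70320, gamma = 0) {
  key <- paste0("lq_", sr, "_", n_fft, "_", round(gamma, 3))
  if (!is.null(.fb_cache[[key]])) return(.fb_cache[[key]])
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1L) * sr / n_fft
  n_notes <- floor(12 * log2((sr / 2) / fmin))
  centers <- fmin * 2^((seq_len(n_notes) - 1L) / 12)
  lf <- suppressWarnings(log2(freqs / fmin) * 12)   # semitones above fmin
  lf[1] <- -Inf
  half_width <- 1 + gamma                            # semitones
  fb <- matrix(0, n_notes, n_bins)
  for (m in seq_len(n_notes)) {
    fb[m, ] <- pmax(0, 1 - abs(lf - (m - 1L)) / half_width)
  }
  attr(fb, "pitch_class") <- (seq_len(n_notes) - 1L) %% 12L  # 0 = C
  .fb_cache[[key]] <- fb
  fb
}
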