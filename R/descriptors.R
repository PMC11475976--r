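# The 15 frame-level descriptor methods. Each takes a shared analysis
# context (time-domain frames + magnitude spectrogram) and returns a
# coefficients x frames matrix. Descriptor output shapes follow the common
# audio-analysis conventions: 12 chroma classes, 20 MFCCs, 128 mel bands,
# 7 contrast bands, 6 tonnetz dimensions, 2 polynomial coefficients, and one
# row for the scalar per-frame measures.

.spectral_amin <- 1e-10

# shared per-clip analysis context so the spectrogram is computed once
analysis_context <- function(clip, n_fft = .default_n_fft,
                             hop = .default_hop) {
  st <- stft_magnitude(clip, n_fft, hop)
  list(clip = clip,
       frames = frame_signal(clip$samples, n_fft, hop),
       mag = st$mag, power = st$mag^2, freqs = st$freqs,
       sr = clip$sample_rate, n_fft = n_fft, hop = hop)
}

normalize_cols_max <- function(m) {
  mx <- apply(m, 2, max)
  mx[mx <= 0] <- 1
  sweep(m, 2, mx, "/")
}

# fold a log-frequency filterbank response into 12 pitch classes
fold_chroma <- function(notes, pitch_class) {
  ch <- matrix(0, 12, ncol(notes))
  for (pc in 0:11) {
    rows <- which(pitch_class == pc)
    ch[pc + 1L, ] <- colSums(notes[rows, , drop = FALSE])
  }
  ch
}

d_chroma_stft <- function(ctx) {
  # pitch class of every STFT bin by nearest semitone (A440 reference)
  midi <- rep(NA_integer_, length(ctx$freqs))
  pos <- ctx$freqs > 0
  midi[pos] <- round(69 + 12 * log2(ctx$freqs[pos] / 440))
  ch <- matrix(0, 12, ncol(ctx$power))
  for (pc in 0:11) {
    rows <- which(!is.na(midi) & midi %% 12L == pc)
    ch[pc + 1L, ] <- colSums(ctx$power[rows, , drop = FALSE])
  }
  normalize_cols_max(ch)
}

d_chroma_cqt <- function(ctx) {
  fb <- logfreq_filterbank(ctx$sr, ctx$n_fft)
  notes <- fb %*% ctx$mag
  normalize_cols_max(fold_chroma(notes, attr(fb, "pitch_class")))
}

d_chroma_cens <- function(ctx) {
  ch <- d_chroma_cqt(ctx)
  # L1 normalize, quantize energy into 5 levels, smooth over 9 frames, L2 norm
  l1 <- colSums(ch); l1[l1 <= 0] <- 1
  ch <- sweep(ch, 2, l1, "/")
  q <- matrix(0, nrow(ch), ncol(ch))
  thresholds <- c(0.05, 0.1, 0.2, 0.4)
  for (k in seq_along(thresholds)) q <- q + 0.25 * (ch > thresholds[k])
  win <- hann_window(9); win <- win / sum(win)
  sm <- t(apply(q, 1, function(row) {
    as.numeric(stats::filter(c(rep(row[1], 4), row, rep(row[length(row)], 4)),
                             win, sides = 2))[5:(length(row) + 4)]
  }))
  if (ncol(q) == 1) sm <- matrix(sm, nrow = 12)
  l2 <- sqrt(colSums(sm^2)); l2[l2 <= 0] <- 1
  sweep(sm, 2, l2, "/")
}

d_chroma_vqt <- function(ctx) {
  fb <- logfreq_filterbank(ctx$sr, ctx$n_fft, gamma = 0.5)
  notes <- fb %*% ctx$mag
  normalize_cols_max(fold_chroma(notes, attr(fb, "pitch_class")))
}

d_melspec <- function(ctx) mel_filterbank(ctx$sr, ctx$n_fft) %*% ctx$power

d_mfcc <- function(ctx, n_mfcc = 20L) {
  mel <- d_melspec(ctx)
  mel_db <- 10 * log10(pmax(mel, .spectral_amin))
  n_mels <- nrow(mel)
  # orthonormal DCT-II over the mel axis
  k <- seq_len(n_mfcc) - 1L
  n <- seq_len(n_mels) - 1L
  dct <- sqrt(2 / n_mels) * cos(pi / n_mels * outer(k, n + 0.5))
  dct[1, ] <- dct[1, ] / sqrt(2)
  dct %*% mel_db
}

d_rms <- function(ctx) {
  matrix(sqrt(colMeans(ctx$frames^2)), nrow = 1)
}

d_spec_centroid <- function(ctx) {
  tot <- colSums(ctx$mag)
  cent <- colSums(ctx$mag * ctx$freqs) / ifelse(tot > 0, tot, 1)
  matrix(cent, nrow = 1)
}

d_spec_bandwidth <- function(ctx) {
  tot <- colSums(ctx$mag)
  safe <- ifelse(tot > 0, tot, 1)
  cent <- colSums(ctx$mag * ctx$freqs) / safe
  dev2 <- sweep(outer(ctx$freqs, cent, `-`)^2 * ctx$mag, 2, safe, "/")
  matrix(sqrt(colSums(dev2)), nrow = 1)
}

.contrast_edges <- function(sr) c(0, 200 * 2^(0:5), sr / 2)

d_spec_contrast <- function(ctx, alpha = 0.02) {
  edges <- .contrast_edges(ctx$sr)
  n_band <- length(edges) - 1L
  out <- matrix(0, n_band, ncol(ctx$power))
  for (b in seq_len(n_band)) {
    rows <- which(ctx$freqs >= edges[b] & ctx$freqs < edges[b + 1L])
    if (length(rows) == 0) next
    sub <- ctx$power[rows, , drop = FALSE]
    k <- max(1L, round(alpha * length(rows)))
    out[b, ] <- apply(sub, 2, function(v) {
      v <- sort(v)
      peak <- mean(v[(length(v) - k + 1L):length(v)])
      valley <- mean(v[seq_len(k)])
      log(peak + .spectral_amin) - log(valley + .spectral_amin)
    })
  }
  out
}

d_spec_flatness <- function(ctx) {
  p <- pmax(ctx$power, .spectral_amin)
  matrix(exp(colMeans(log(p))) / colMeans(p), nrow = 1)
}

d_spec_rolloff <- function(ctx, roll_percent = 0.85) {
  cum <- apply(ctx$mag, 2, cumsum)
  tot <- cum[nrow(cum), ]
  roll <- vapply(seq_len(ncol(cum)), function(j) {
    if (tot[j] <= 0) return(0)
    ctx$freqs[which(cum[, j] >= roll_percent * tot[j])[1]]
  }, numeric(1))
  matrix(roll, nrow = 1)
}

d_poly <- function(ctx, order = 1L) {
  # least-squares polynomial fit of each spectrogram column against frequency
  design <- outer(ctx$freqs, order:0, `^`)
  qr.coef(qr(design), ctx$mag)   # (order + 1) x frames
}

.tonnetz_basis <- local({
  l <- 0:11
  rbind(sin(l * 7 * pi / 6), cos(l * 7 * pi / 6),
        sin(l * 3 * pi / 2), cos(l * 3 * pi / 2),
        sin(l * 2 * pi / 3), cos(l * 2 * pi / 3)) *
    c(1, 1, 1, 1, 0.5, 0.5)
})

d_tonnetz <- function(ctx) {
  ch <- d_chroma_cqt(ctx)
  l1 <- colSums(ch); l1[l1 <= 0] <- 1
  .tonnetz_basis %*% sweep(ch, 2, l1, "/")
}

d_zcr <- function(ctx) {
  signs <- ctx$frames >= 0
  matrix(colMeans(signs[-1, , drop = FALSE] !=
                  signs[-nrow(signs), , drop = FALSE]), nrow = 1)
}

.descriptor_registry <- list(
  chroma_stft    = d_chroma_stft,
  chroma_cqt     = d_chroma_cqt,
  chroma_cens    = d_chroma_cens,
  chroma_vqt     = d_chroma_vqt,
  mfcc           = d_mfcc,
  melspec        = d_melspec,
  rms            = d_rms,
  spec_centroid  = d_spec_centroid,
  spec_bandwidth = d_spec_bandwidth,
  spec_contrast  = d_spec_contrast,
  spec_flatness  = d_spec_flatness,
  spec_rolloff   = d_spec_rolloff,
  poly           = d_poly,
  tonnetz        = d_tonnetz,
  zcr            = d_zcr
)

#' Compute one descriptor's coefficients x frames matrix for a clip
#'
#' Runs a single frame-level descriptor over an audio clip (Hann window,
#' frame 2048, hop 512) and returns the raw frame matrix before statistical
#' pooling. All 15 methods are deterministic for a fixed input.
#'
#' @param clip an [audio_clip()].
#' @param method_id one of [descriptor_ids()].
#' @return A list of class `spectral_feature_matrix` with `method_id` and
#'   `values` (numeric matrix, coefficients x frames, no non-finite entries).
#' @export
#' @examples
#' clip <- audio_clip(sin(2 * pi * 440 * seq_len(22050) / 22050), 22050)
#' m <- extract_frame_features(clip, "spec_centroid")
#' dim(m$values)
extract_frame_features <- function(clip, method_id) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!method_id %in% names(.descriptor_registry)) {
    stop("unknown method_id '", method_id, "'; valid ids: ",
         paste(names(.descriptor_registry), collapse = ", "))
  }
  ctx <- analysis_context(clip)
  values <- .descriptor_registry[[method_id]](ctx)
  if (any(!is.finite(values))) {
    stop("descriptor '", method_id, "' produced non-finite values")
  }
  structure(list(method_id = method_id, values = values),
            class = "spectral_feature_matrix")
}
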