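#' Specification for a synthetic toy-audio dataset
#'
#' Two acoustic classes designed so that standard spectral descriptors
#' separate them: class `"tonal"` clips are a pair of band-limited carriers
#' plus periodic impulse bursts (a crude stand-in for structured adventitious
#' lung sounds); class `"noisy"` clips are broadband Gaussian noise. Only
#' statistical separability is intended, not realistic acoustics.
#'
#' @param n_clips_per_class positive integer (default 3).
#' @param duration_s clip duration in seconds (default 0.75).
#' @param sample_rate sampling rate in Hz (default 22050).
#' @param seed integer seed.
#' @return An object of class `synthetic_audio_spec`.
#' @export
synthetic_audio_spec <- function(n_clips_per_class = 3, duration_s = 0.75,
                                 sample_rate = 22050, seed = 1L) {
  if (n_clips_per_class < 1) stop("n_clips_per_class: must be positive")
  if (duration_s <= 0) stop("duration_s: must be positive")
  if (sample_rate <= 0) stop("sample_rate: must be positive")
  if (duration_s * sample_rate < 2048) {
    stop("duration_s: clip shorter than one analysis frame (2048 samples)")
  }
  structure(
    list(n_clips_per_class = as.integer(n_clips_per_class),
         duration_s = duration_s, sample_rate = as.integer(sample_rate),
         seed = as.integer(seed)),
    class = "synthetic_audio_spec"
  )
}

#' Construct an audio clip object
#' @param samples finite numeric vector of mono samples in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz.
#' @param recording_id identifier string.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, recording_id = "clip") {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples: must be finite")
  if (sample_rate <= 0) stop("sample_rate: must be positive")
  structure(list(samples = samples, sample_rate = sample_rate,
                 recording_id = recording_id),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat("<audio_clip> ", x$recording_id, ": ", length(x$samples),
      " samples @ ", x$sample_rate, " Hz (",
      round(length(x$samples) / x$sample_rate, 3), " s)\n", sep = "")
  invisible(x)
}

# carrier frequencies (Hz) and burst rate (Hz) of the tonal class; fixed
# synthesis constants, documented here rather than exposed as arguments
.tonal_carriers <- c(220, 660)
.burst_rate_hz <- 4

#' Generate a labelled synthetic audio dataset
#'
#' @param spec a [synthetic_audio_spec()].
#' @return A list with `clips` (list of [audio_clip()]) and `labels` (factor
#'   with levels `tonal`, `noisy`), in clip order. Every clip is normalized
#'   to max absolute amplitude 0.9.
#' @export
generate_audio_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_audio_spec"))
  n_samp <- round(spec$duration_s * spec$sample_rate)
  t <- seq_len(n_samp) / spec$sample_rate
  withr::with_seed(spec$seed, {
    clips <- list()
    labels <- character(0)
    for (i in seq_len(spec$n_clips_per_class)) {
      phase <- runif(length(.tonal_carriers), 0, 2 * pi)
      x <- rowSums(vapply(seq_along(.tonal_carriers), function(j) {
        sin(2 * pi * .tonal_carriers[j] * t + phase[j])
      }, numeric(n_samp)))
      # periodic impulse bursts: short decaying clicks at the burst rate
      burst_period <- round(spec$sample_rate / .burst_rate_hz)
      onsets <- seq(1, n_samp, by = burst_period)
      click <- exp(-seq(0, 5, length.out = 64))
      for (o in onsets) {
        idx <- o:min(o + 63, n_samp)
        x[idx] <- x[idx] + 3 * click[seq_along(idx)] *
          rnorm(length(idx), sd = 0.5)
      }
      x <- x + rnorm(n_samp, sd = 0.05)
      clips[[length(clips) + 1]] <-
        audio_clip(0.9 * x / max(abs(x)), spec$sample_rate,
                   sprintf("tonal_%03d", i))
      labels <- c(labels, "tonal")
    }
    for (i in seq_len(spec$n_clips_per_class)) {
      x <- rnorm(n_samp)
      clips[[length(clips) + 1]] <-
        audio_clip(0.9 * x / max(abs(x)), spec$sample_rate,
                   sprintf("noisy_%03d", i))
      labels <- c(labels, "noisy")
    }
  })
  list(clips = clips, labels = factor(labels, levels = c("tonal", "noisy")))
}

#' Write a mono clip as 16-bit PCM RIFF WAV
#' @param clip an [audio_clip()]; samples are clipped to `[-1, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmax(pmin(clip$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(clip$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * 2L), con, size = 4,
           endian = "little")                              # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM RIFF WAV file written by [write_wav()]
#' @param path input path.
#' @param recording_id identifier for the resulting clip; defaults to the
#'   file name without extension.
#' @return An [audio_clip()] with samples in `[-1, 1]`.
#' @export
read_wav <- function(path, recording_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    chunk <- readChar(con, 4)
    if (length(chunk) == 0 || nchar(chunk) < 4) stop("no data chunk in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(chunk, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop("only mono 16-bit PCM WAV is supported")
      }
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, raw(), n = size - 8L))
    } else if (identical(chunk, "data")) {
      pcm <- readBin(con, integer(), n = size / 2L, size = 2,
                     signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(sample_rate)) stop("no fmt chunk in ", path)
  if (is.null(recording_id)) {
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  }
  audio_clip(pcm / 32767, sample_rate, recording_id)
}

#' Write an audio dataset to a directory of WAV files plus a labels CSV
#' @param dataset output of [generate_audio_dataset()].
#' @param dir output directory (created if absent).
#' @return Path of the labels CSV (`labels.csv`: `recording_id,diagnosis`).
#' @export
write_audio_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (clip in dataset$clips) {
    write_wav(clip, file.path(dir, paste0(clip$recording_id, ".wav")))
  }
  labels_path <- file.path(dir, "labels.csv")
  write.csv(data.frame(
    recording_id = vapply(dataset$clips, `[[`, character(1), "recording_id"),
    diagnosis = as.character(dataset$labels)),
    labels_path, row.names = FALSE, quote = FALSE)
  labels_path
}

#' Read a directory of WAV files with a labels CSV
#' @param dir directory containing `*.wav` and `labels.csv`.
#' @return A list with `clips` and `labels`, as [generate_audio_dataset()].
#' @export
read_audio_dataset <- function(dir) {
  lab <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  clips <- lapply(lab$recording_id, function(id) {
    read_wav(file.path(dir, paste0(id, ".wav")), id)
  })
  list(clips = clips, labels = factor(lab$diagnosis))
}
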