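#' Read a 16-bit PCM mono WAV file
#'
#' Minimal RIFF/WAVE reader for the recording format the pipeline expects
#' (16-bit linear PCM).  Stereo input is averaged to mono.  Samples are
#' returned in \[-1, 1).
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("Not a RIFF file.")
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("Not a WAVE file.")
  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
      invisible(readBin(con, "integer", 1L, size = 2L, endian = "little"))
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
      if (fmt[1] != 1L || bits != 16L) {
        abort("Only 16-bit linear PCM WAV is supported.")
      }
    } else if (identical(id, "data")) {
      raw16 <- readBin(con, "integer", size / 2L, size = 2L,
                       signed = TRUE, endian = "little")
      samples <- raw16 / 32768
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples) || is.null(sample_rate)) {
    abort("Malformed WAV: missing fmt or data chunk.")
  }
  if (n_channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = n_channels))
  }
  list(samples = samples, sample_rate = sample_rate)
}

#' Write a 16-bit PCM mono WAV file
#'
#' @param samples Numeric vector in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  pcm <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 1L), con, size = 2L, endian = "little")        # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4L, endian = "little")
  writeBin(c(2L, 16L), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Resample audio to a target rate
#'
#' Linear-interpolation resampling, sufficient for downsampling clinical
#' recordings (e.g. 50 kHz) to the 16 kHz analysis rate.
#'
#' @param samples Numeric sample vector.
#' @param from,to Source and target rates in Hz.
#' @return Resampled vector.
#' @export
resample_audio <- function(samples, from, to) {
  if (from == to) return(samples)
  n_out <- floor(length(samples) * to / from)
  t_out <- (seq_len(n_out) - 1) * from / to + 1
  stats::approx(seq_along(samples), samples, xout = t_out, rule = 2L)$y
}

# Triangular mel filterbank on FFT bins (n_filters x (nfft/2 + 1)).
mel_filterbank <- function(n_filters, nfft, sample_rate,
                           f_min = 0, f_max = sample_rate / 2) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  mel_pts <- seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_filters + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- (0:(nfft / 2)) * sample_rate / nfft
  fb <- matrix(0, n_filters, nfft / 2 + 1L)
  for (m in seq_len(n_filters)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bin_freqs - lo) / (ctr - lo)
    down <- (hi - bin_freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II basis (n_coef x n_filters).
dct_basis <- function(n_coef, n_filters) {
  k <- seq_len(n_coef) - 1L
  n <- seq_len(n_filters) - 1L
  B <- sqrt(2 / n_filters) *
    cos(outer(k, n + 0.5, function(kk, nn) pi * kk * nn / n_filters))
  B[1, ] <- B[1, ] / sqrt(2)
  B
}

# Delta coefficients by +-`width`-frame linear regression, edges padded by
# replication.
delta_features <- function(M, width = 2L) {
  n <- nrow(M)
  denom <- 2 * sum((1:width)^2)
  out <- matrix(0, n, ncol(M))
  idx <- function(i) pmin(pmax(i, 1L), n)
  for (d in seq_len(width)) {
    out <- out + d * (M[idx(seq_len(n) + d), , drop = FALSE] -
                        M[idx(seq_len(n) - d), , drop = FALSE])
  }
  out / denom
}

#' MFCC features with first-order derivatives
#'
#' Standard short-term spectral-envelope front-end: pre-emphasis, 25 ms
#' Hamming windows at a 10 ms hop, power spectrum, triangular mel
#' filterbank, log, and orthonormal DCT.  The first cepstral coefficient
#' is replaced by the frame log-energy when `use_energy = TRUE`.  Delta
#' coefficients from a +-2-frame regression are appended, giving
#' `2 * n_cep` dimensions (default 40 = 20 static + 20 delta).
#'
#' @param audio Numeric samples in \[-1, 1\], or a list as from
#'   [read_wav()] (in which case `sample_rate` is taken from it and the
#'   audio is resampled to 16 kHz if needed).
#' @param sample_rate Sampling rate in Hz; the analysis expects 16000.
#' @param n_cep Number of static coefficients (default 20).
#' @param n_filters Mel filters (default 26).
#' @param window_ms,hop_ms Analysis window and hop in milliseconds.
#' @param preemphasis Pre-emphasis coefficient (default 0.97).
#' @param use_energy Replace c0 with log-energy (default TRUE).
#' @param deltas Append first-order derivatives (default TRUE).
#' @return A `frames x D` feature matrix with attribute
#'   `frame_rate` (frames/second).
#' @export
extract_mfcc <- function(audio, sample_rate = 16000L, n_cep = 20L,
                         n_filters = 26L, window_ms = 25, hop_ms = 10,
                         preemphasis = 0.97, use_energy = TRUE,
                         deltas = TRUE) {
  if (is.list(audio)) {
    sample_rate_in <- audio$sample_rate
    audio <- audio$samples
    if (sample_rate_in != sample_rate) {
      audio <- resample_audio(audio, sample_rate_in, sample_rate)
    }
  }
  win_len <- round(window_ms * sample_rate / 1000)
  hop_len <- round(hop_ms * sample_rate / 1000)
  if (length(audio) < win_len) {
    abort(sprintf("Audio too short: %d samples < one %d-sample window.",
                  length(audio), win_len))
  }
  n_frames <- floor((length(audio) - win_len) / hop_len) + 1L
  emph <- c(audio[1], audio[-1] - preemphasis * audio[-length(audio)])
  nfft <- 2^ceiling(log2(win_len))
  window <- 0.54 - 0.46 * cos(2 * pi * (0:(win_len - 1)) / (win_len - 1))
  fb <- mel_filterbank(n_filters, nfft, sample_rate)
  dct_m <- dct_basis(n_cep, n_filters)
  frames <- matrix(0, n_frames, win_len)
  starts <- (seq_len(n_frames) - 1L) * hop_len
  for (i in seq_len(n_frames)) {
    frames[i, ] <- emph[starts[i] + seq_len(win_len)]
  }
  energy <- log(pmax(rowSums(frames^2), .Machine$double.xmin))
  windowed <- sweep(frames, 2L, window, "*")
  padded <- cbind(windowed, matrix(0, n_frames, nfft - win_len))
  spec <- t(apply(padded, 1L, function(f) {
    Mod(stats::fft(f)[1:(nfft / 2 + 1L)])^2
  }))
  fbank <- log(pmax(spec %*% t(fb), .Machine$double.xmin))
  cep <- fbank %*% t(dct_m)
  if (use_energy) cep[, 1] <- energy
  out <- if (deltas) cbind(cep, delta_features(cep)) else cep
  attr(out, "frame_rate") <- sample_rate / hop_len
  out
}
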