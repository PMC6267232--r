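# Band-limiting, instantaneous phase, epoch segmentation.

#' Brick-wall FFT band-pass filter
#'
#' Zeroes all Fourier bins whose frequency lies outside \code{[loHz, hiHz]}
#' (edges inclusive) and inverse-transforms.  The filter is zero-phase by
#' construction, which matters because downstream phase-lag statistics must
#' not be distorted by filter group delay.  Applying it twice equals
#' applying it once (it is a projection).
#'
#' @param ts a \linkS4class{RoiTimeSeries}
#' @param band a \linkS4class{BandDefinition}; must lie strictly below the
#'   Nyquist frequency
#' @return a band-limited \linkS4class{RoiTimeSeries}
#' @examples
#' ts <- roiTimeSeries(matrix(rnorm(2 * 1250), 2), 625,
#'                     roiLabels = c("A", "B"))
#' th <- bandpass(ts, bandDefinition("theta", 4, 8))
#' @export
bandpass <- function(ts, band) {
  stopifnot(is(ts, "RoiTimeSeries"), is(band, "BandDefinition"))
  fs <- sampleRate(ts)
  if (band@hiHz >= fs / 2)
    stop("band '", band@name, "' upper edge (", band@hiHz,
         " Hz) must lie below the Nyquist frequency (", fs / 2, " Hz)")
  x <- ts@data
  nT <- ncol(x)
  X <- mvfft(t(x))                       # columns = ROIs
  fbin <- (seq_len(nT) - 1) * fs / nT
  f <- pmin(fbin, fs - fbin)             # absolute frequency per bin
  keep <- f >= band@loHz & f <= band@hiHz
  X[!keep, ] <- 0
  y <- Re(mvfft(X, inverse = TRUE)) / nT
  roiTimeSeries(t(y), fs, roiLabels = roiLabels(ts),
                subjectId = subjectId(ts))
}

# analytic signal of each column of a real matrix (FFT construction)
.analytic <- function(xc) {
  nT <- nrow(xc)
  X <- mvfft(xc)
  h <- numeric(nT)
  if (nT %% 2 == 0) {
    h[1] <- 1; h[2:(nT / 2)] <- 2; h[nT / 2 + 1] <- 1
  } else {
    h[1] <- 1; h[2:((nT + 1) / 2)] <- 2
  }
  mvfft(X * h, inverse = TRUE) / nT
}

#' Instantaneous phase via the analytic signal
#'
#' Computes, per ROI, the angle of the analytic signal (Hilbert
#' construction: negative-frequency components zeroed, positive doubled),
#' wrapped to (-pi, pi].  Input should already be band-limited for the
#' phase to be interpretable.
#'
#' @param ts a band-limited \linkS4class{RoiTimeSeries}
#' @return numeric N x T matrix of phases in radians, rownames = ROI labels
#' @export
instantaneousPhase <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeries"))
  x <- ts@data
  flat <- apply(x, 1L, function(r) max(r) == min(r))
  if (any(flat))
    stop("undefined phase: constant signal in ROI(s) ",
         paste(rownames(x)[flat], collapse = ", "))
  z <- .analytic(t(x))
  ph <- t(atan2(Im(z), Re(z)))
  dimnames(ph) <- list(rownames(x), NULL)
  ph
}

#' Split a recording into fixed-length epochs
#'
#' Non-overlapping consecutive epochs of \code{epochSamples} samples;
#' any trailing remainder shorter than one epoch is discarded.
#'
#' @param ts a \linkS4class{RoiTimeSeries}
#' @param epochSamples epoch length in samples
#' @return list of \linkS4class{RoiTimeSeries}, one per epoch
#' @export
segmentEpochs <- function(ts, epochSamples) {
  stopifnot(is(ts, "RoiTimeSeries"))
  epochSamples <- as.integer(epochSamples)
  if (epochSamples < 2L) stop("epochSamples must be >= 2")
  nT <- nSamples(ts)
  if (nT < epochSamples)
    stop("recording too short: ", nT, " samples < one epoch of ",
         epochSamples)
  k <- nT %/% epochSamples
  lapply(seq_len(k), function(e) {
    idx <- ((e - 1L) * epochSamples + 1L):(e * epochSamples)
    roiTimeSeries(ts@data[, idx, drop = FALSE], sampleRate(ts),
                  roiLabels = roiLabels(ts), subjectId = subjectId(ts))
  })
}

#' Band-limited phase epochs of a recording
#'
#' Convenience composition used by the pipeline: band-pass the continuous
#' recording, segment it into epochs, then extract the instantaneous phase
#' per epoch (phase is computed per epoch, not on the continuous record, to
#' avoid cross-epoch edge effects).
#'
#' @inheritParams bandpass
#' @inheritParams segmentEpochs
#' @return list of \linkS4class{PhaseEpoch}
#' @export
phaseEpochs <- function(ts, band, epochSamples) {
  filtered <- bandpass(ts, band)
  epochs <- segmentEpochs(filtered, epochSamples)
  lapply(seq_along(epochs), function(e) {
    new("PhaseEpoch", phases = instantaneousPhase(epochs[[e]]),
        band = band, epochIndex = as.integer(e))
  })
}
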