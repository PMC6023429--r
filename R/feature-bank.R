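#' Detect peaks with prominence and interpolated FWHM
#'
#' Locates strict local maxima of the signal (positive polarity) or of its
#' negation (negative polarity), keeps those whose topographic prominence is
#' at least `min_prominence`, and measures each peak's full width at half
#' maximum by linear interpolation at half the peak's prominence-referenced
#' height (`height - prominence / 2`), clipped at the window edges.
#' Positive-polarity peaks must have positive amplitude (and negative ones
#' negative), so the returned amplitudes share the polarity's sign.
#'
#' @param x Numeric vector, length >= 3.
#' @param polarity `"positive"` or `"negative"`.
#' @param min_prominence Minimum prominence; defaults to 5% of `max(abs(x))`,
#'   which suppresses numerical ripple.
#' @return A tibble with one row per peak: `location` (1-based sample index,
#'   strictly increasing), `amplitude` (signed value of `x`), `prominence`,
#'   `fwhm` (samples, fractional).
#' @export
detect_peaks <- function(x, polarity = c("positive", "negative"),
                         min_prominence = NULL) {
  polarity <- match.arg(polarity)
  n <- length(x)
  if (n < 3L) stop("signal must have at least 3 samples", call. = FALSE)
  if (is.null(min_prominence)) min_prominence <- 0.05 * max(abs(x))
  y <- if (polarity == "positive") x else -x

  i <- 2:(n - 1L)
  cand <- i[y[i] > y[i - 1L] & y[i] > y[i + 1L] & y[i] > 0]
  if (length(cand) == 0L) return(empty_peakset())

  prom <- vapply(cand, peak_prominence, numeric(1), y = y)
  keep <- prom >= min_prominence & prom > 0
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0L) return(empty_peakset())

  fwhm <- vapply(seq_along(cand), function(k) {
    peak_fwhm(y, cand[k], prom[k])
  }, numeric(1))

  tibble::tibble(
    location = as.integer(cand),
    amplitude = x[cand],
    prominence = prom,
    fwhm = fwhm
  )
}

empty_peakset <- function() {
  tibble::tibble(location = integer(), amplitude = numeric(),
                 prominence = numeric(), fwhm = numeric())
}

## topographic prominence of the local maximum at index i of y: height above
## the higher of the two key saddles (minima scanned until higher ground or
## the window edge)
peak_prominence <- function(y, i) {
  n <- length(y)
  left <- y[i]
  j <- i - 1L
  while (j >= 1L && y[j] < y[i]) {
    left <- min(left, y[j])
    j <- j - 1L
  }
  right <- y[i]
  j <- i + 1L
  while (j <= n && y[j] < y[i]) {
    right <- min(right, y[j])
    j <- j + 1L
  }
  y[i] - max(left, right)
}

## width at the half-prominence reference level, linear interpolation,
## clipped at the window edges
peak_fwhm <- function(y, i, prom) {
  n <- length(y)
  ref <- y[i] - prom / 2
  xl <- 1
  for (j in seq(i - 1L, 1L)) {
    if (y[j] <= ref) {
      xl <- j + (ref - y[j]) / (y[j + 1L] - y[j])
      break
    }
  }
  xr <- n
  for (j in seq(i + 1L, n)) {
    if (y[j] <= ref) {
      xr <- j - (ref - y[j]) / (y[j - 1L] - y[j])
      break
    }
  }
  xr - xl
}

#' Time-domain features (#1--#19)
#'
#' Peak, area and morphology statistics of the (windowed) signal: amplitudes
#' and locations of the extreme positive and negative peaks (#1--#4),
#' variance (#5), RMS value (#6), counts, mean amplitudes, mean FWHMs and
#' mean within-polarity separations of the positive and negative peaks
#' (#7--#14), zero-crossing count (#15), discrete integrals of the signal
#' and of its absolute value (#16--#17), and positive/negative percentage
#' areas (#18--#19). Empty peak sets map count and mean features to 0.
#'
#' @param x Numeric signal (any length >= 3; signatures are 60 samples).
#' @param fs Sampling rate in GHz (sets the integration step `1 / fs` ns).
#' @return Named numeric vector `f01..f19`.
#' @export
time_features <- function(x, fs = 30) {
  dt <- 1 / fs
  pos <- detect_peaks(x, "positive")
  neg <- detect_peaks(x, "negative")
  mean0 <- function(v) if (length(v) == 0L) 0 else mean(v)
  sep0 <- function(loc) if (length(loc) < 2L) 0 else mean(diff(loc))

  f1 <- if (nrow(pos)) max(pos$amplitude) else 0
  f2 <- if (nrow(pos)) pos$location[which.max(pos$amplitude)] else 0
  f3 <- if (nrow(neg)) min(neg$amplitude) else 0
  f4 <- if (nrow(neg)) neg$location[which.min(neg$amplitude)] else 0

  tot_abs <- sum(abs(x))
  c(
    f01 = f1,
    f02 = as.numeric(f2),
    f03 = f3,
    f04 = as.numeric(f4),
    f05 = var(x),
    f06 = sqrt(mean(x^2)),
    f07 = as.numeric(nrow(pos)),
    f08 = as.numeric(nrow(neg)),
    f09 = mean0(pos$amplitude),
    f10 = mean0(neg$amplitude),
    f11 = mean0(pos$fwhm),
    f12 = mean0(neg$fwhm),
    f13 = sep0(pos$location),
    f14 = sep0(neg$location),
    f15 = sum(x[-length(x)] * x[-1] < 0),
    f16 = sum(x) * dt,
    f17 = sum(abs(x)) * dt,
    f18 = if (tot_abs > 0) 100 * sum(x[x > 0]) / tot_abs else 0,
    f19 = if (tot_abs > 0) 100 * -sum(x[x < 0]) / tot_abs else 0
  )
}

#' Autocorrelation sequence over non-negative lags
#'
#' `r[k] = sum_n x[n] x[n + k]` for lags `0 .. length(x) - 1`, normalised so
#' the zero-lag value is 1. Computed via FFT (equal to the definitional sums
#' to numerical precision).
#'
#' @param x Numeric signal with nonzero energy.
#' @return Numeric vector of length `length(x)`.
#' @export
autocorr_sequence <- function(x) {
  n <- length(x)
  m <- 2^ceiling(log2(2 * n))
  X <- fft(c(x, numeric(m - n)))
  r <- Re(fft(X * Conj(X), inverse = TRUE))[1:n] / m
  r / r[1]
}

#' Autocorrelation features (#20--#24)
#'
#' Statistics of the normalised autocorrelation sequence: its mean (#20) and
#' the count, mean amplitude, mean FWHM and mean separation of its peaks
#' (#21--#24), with the lag-0 endpoint excluded from peak detection. A
#' zero-energy input maps all five features to 0.
#'
#' @param x Numeric signal.
#' @return Named numeric vector `f20..f24`.
#' @export
autocorr_features <- function(x) {
  if (all(x == 0)) {
    return(setNames(numeric(5), sprintf("f%02d", 20:24)))
  }
  r <- autocorr_sequence(x)
  pk <- detect_peaks(r, "positive")
  mean0 <- function(v) if (length(v) == 0L) 0 else mean(v)
  c(
    f20 = mean(r),
    f21 = as.numeric(nrow(pk)),
    f22 = mean0(pk$amplitude),
    f23 = mean0(pk$fwhm),
    f24 = if (nrow(pk) < 2L) 0 else mean(diff(pk$location))
  )
}

## one-sided PSD of a windowed segment: |X_k|^2 / (fs * sum(w^2)), interior
## bins doubled; bins 0 .. floor(n/2)
one_sided_psd <- function(xw, w, fs) {
  n <- length(xw)
  X <- fft(xw)
  nb <- n %/% 2L + 1L
  p <- Mod(X[1:nb])^2 / (fs * sum(w^2))
  scale <- rep(2, nb)
  scale[1] <- 1
  if (n %% 2L == 0L) scale[nb] <- 1
  p * scale
}

#' Welch power-spectral-density estimate
#'
#' Average of one-sided modified periodograms over Hann-windowed segments
#' with 50% overlap (segment length 30 by default, giving 3 segments on a
#' 60-sample signature).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in GHz.
#' @param segment Segment length in samples.
#' @return Numeric vector of PSD values over bins `0 .. segment / 2`.
#' @export
welch_psd <- function(x, fs = 30, segment = 30L) {
  n <- length(x)
  segment <- min(segment, n)
  hop <- max(1L, segment %/% 2L)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(segment) - 1L) / (segment - 1L))
  starts <- seq(1L, n - segment + 1L, by = hop)
  psds <- vapply(starts, function(s) {
    one_sided_psd(x[s:(s + segment - 1L)] * w, w, fs)
  }, numeric(segment %/% 2L + 1L))
  rowMeans(psds)
}

#' Periodogram power-spectral-density estimate
#'
#' One-sided full-length periodogram with a rectangular window.
#'
#' @inheritParams welch_psd
#' @return Numeric vector of PSD values over bins `0 .. length(x) / 2`.
#' @export
periodogram_psd <- function(x, fs = 30) {
  one_sided_psd(x, rep(1, length(x)), fs)
}

#' Power-spectral-density features (#25--#30)
#'
#' Mean of the Welch estimate (#25), mean of the periodogram (#26), and the
#' count, mean amplitude, mean FWHM (in frequency bins) and mean separation
#' (in bins) of the periodogram peaks (#27--#30). A zero signal maps all six
#' features to 0.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in GHz.
#' @return Named numeric vector `f25..f30`.
#' @export
psd_features <- function(x, fs = 30) {
  if (all(x == 0)) {
    return(setNames(numeric(6), sprintf("f%02d", 25:30)))
  }
  pgram <- periodogram_psd(x, fs)
  pk <- detect_peaks(pgram, "positive")
  mean0 <- function(v) if (length(v) == 0L) 0 else mean(v)
  c(
    f25 = mean(welch_psd(x, fs)),
    f26 = mean(pgram),
    f27 = as.numeric(nrow(pk)),
    f28 = mean0(pk$amplitude),
    f29 = mean0(pk$fwhm),
    f30 = if (nrow(pk) < 2L) 0 else mean(diff(pk$location))
  )
}

#' Extract the full 30-descriptor feature vector
#'
#' Concatenates the time-domain (#1--#19), autocorrelation (#20--#24) and
#' PSD (#25--#30) features of one signal. Each vector depends only on its
#' own signal -- no computation crosses observations, so feature extraction
#' cannot leak information between training and test sets. Degenerate
#' (all-zero) inputs map to a fully defined default vector.
#'
#' @param x Numeric signal (a 60-sample signature, or a raw full-length
#'   signal in FE mode -- the definitions are length-agnostic).
#' @param fs Sampling rate of `x` in GHz.
#' @return Named numeric vector of length 30 (`f01..f30`), all finite.
#' @export
extract_features <- function(x, fs = 30) {
  c(time_features(x, fs), autocorr_features(x), psd_features(x, fs))
}

#' Canonical feature names
#' @return Character vector `f01..f30`.
#' @export
feature_names <- function() sprintf("f%02d", 1:30)

#' Feature table for a set of signatures or signals
#'
#' Applies [extract_features()] to every row of a signature tibble (from
#' [prepare_signatures()]), returning the classifier input for the FE and
#' TW+FE processing modes.
#'
#' @param signatures Tibble with a `signature` list-column (plus metadata).
#' @param fs Sampling rate of the signatures in GHz.
#' @return A wide tibble: the metadata columns plus `f01..f30`.
#' @export
extract_feature_table <- function(signatures, fs = 30) {
  stopifnot(is.data.frame(signatures), "signature" %in% names(signatures))
  m <- do.call(rbind, lapply(signatures$signature, extract_features, fs = fs))
  dplyr::bind_cols(
    dplyr::select(signatures, -"signature"),
    tibble::as_tibble(m)
  )
}
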