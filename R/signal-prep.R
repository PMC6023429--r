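#' Three-media propagation model
#'
#' Average propagation speeds used for the round-trip delay: the ray from an
#' antenna to a point inside the breast crosses the immersion medium, the
#' skin annulus and the breast interior; each medium propagates at
#' `c / sqrt(eps)`.
#'
#' @param eps_immersion,eps_skin,eps_interior Relative permittivities (>= 1).
#' @param skin_thickness Skin thickness in mm (0 < t < radius).
#' @param breast_radius Outer breast radius in mm.
#' @param breast_centre Length-2 numeric, breast centre in mm.
#' @return An object of class `media_model`.
#' @export
media_model <- function(eps_immersion = 9, eps_skin = 36, eps_interior = 12,
                        skin_thickness = 2, breast_radius = 50,
                        breast_centre = c(0, 0)) {
  stopifnot(eps_immersion >= 1, eps_skin >= 1, eps_interior >= 1,
            skin_thickness > 0, skin_thickness < breast_radius,
            length(breast_centre) == 2L)
  structure(
    list(eps_immersion = eps_immersion, eps_skin = eps_skin,
         eps_interior = eps_interior, skin_thickness = skin_thickness,
         breast_radius = breast_radius,
         breast_centre = as.numeric(breast_centre)),
    class = "media_model"
  )
}

#' @rdname media_model
#' @param breast A [breast_spec()] to convert.
#' @export
as_media_model <- function(breast) {
  stopifnot(inherits(breast, "breast_spec"))
  media_model(breast$eps_immersion, breast$eps_skin, breast$eps_interior,
              breast$skin_thickness, breast$radius, breast$centre)
}

## Straight-ray segment lengths (mm) through immersion / skin / interior for
## rays from points `a` (m x 2, outside the breast) to a single interior
## point `p`. Returns a list of vectors imm, skin, interior.
ray_segments <- function(a, p, media) {
  c0 <- media$breast_centre
  r_out <- media$breast_radius
  r_in <- r_out - media$skin_thickness
  p <- as.numeric(p)
  if (sqrt(sum((p - c0)^2)) >= r_in) {
    stop("point lies outside the breast interior", call. = FALSE)
  }
  d <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  L <- sqrt(rowSums(d^2))
  if (any(sqrt((a[, 1] - c0[1])^2 + (a[, 2] - c0[2])^2) <= r_out)) {
    stop("antenna lies inside the breast", call. = FALSE)
  }
  ## entering crossing of |a + s d - c0| = R: smallest root in [0, 1]
  cross <- function(R) {
    ac <- cbind(a[, 1] - c0[1], a[, 2] - c0[2])
    A <- rowSums(d^2)
    B <- 2 * rowSums(d * ac)
    C <- rowSums(ac^2) - R^2
    disc <- pmax(B^2 - 4 * A * C, 0)
    (-B - sqrt(disc)) / (2 * A)
  }
  s_out <- cross(r_out)
  s_in <- cross(r_in)
  list(imm = s_out * L, skin = (s_in - s_out) * L, interior = (1 - s_in) * L)
}

## one-way delays (ns) from antenna points `a` (m x 2) to interior point `p`
one_way_delay <- function(a, p, media) {
  seg <- ray_segments(a, p, media)
  (seg$imm * sqrt(media$eps_immersion) +
     seg$skin * sqrt(media$eps_skin) +
     seg$interior * sqrt(media$eps_interior)) / C_MM_PER_NS
}

#' Round-trip propagation delay of a tumour echo
#'
#' Sum over the two legs (Tx -> tumour, tumour -> Rx) of the straight-ray
#' segment lengths in each medium divided by that medium's speed
#' `c / sqrt(eps)`. Used to position the tumour window in each backscattered
#' signal.
#'
#' @param tumour_position Length-2 numeric, mm; must lie strictly inside the
#'   breast interior.
#' @param channels Tibble with integer columns `tx`, `rx` (0-based antenna
#'   indices); any subset of [enumerate_channels()].
#' @param array A [ring_array()].
#' @param media A [media_model()] (or [breast_spec()], converted).
#' @return Numeric vector of delays in ns, one per channel row.
#' @export
roundtrip_delay <- function(tumour_position, channels, array, media) {
  if (inherits(media, "breast_spec")) media <- as_media_model(media)
  stopifnot(inherits(media, "media_model"), inherits(array, "ring_array"))
  one_way_delay(antenna_xy(array, channels$tx), tumour_position, media) +
    one_way_delay(antenna_xy(array, channels$rx), tumour_position, media)
}

#' Subtract the antenna-only reference signal
#'
#' Removes the direct antenna-coupling artefact by pointwise subtraction of
#' the reference (antenna-only) simulation from the backscattered signal.
#'
#' @param signal,reference Equal-length numeric vectors at the same sampling
#'   rate.
#' @return `signal - reference`.
#' @export
remove_artifact <- function(signal, reference) {
  if (length(signal) != length(reference)) {
    stop("signal and reference must have the same length", call. = FALSE)
  }
  signal - reference
}

#' Extract the raw tumour window from a backscattered signal
#'
#' Cuts a contiguous slice of length `round(2.5 * width_tp * fs)` samples
#' (2.5 pulse widths) around the predicted tumour arrival. The window starts
#' at `delay - 0.75 * width_tp`, leaving more room after the arrival where
#' spicule sub-echoes trail the principal echo. Slices that overrun the
#' record are zero-padded with a warning.
#'
#' @param signal Numeric vector sampled at `fs`.
#' @param delay Predicted round-trip delay in ns ([roundtrip_delay()]).
#' @param pulse The [mw_pulse()] (its `width_tp` sets the window length).
#' @param fs Sampling rate in GHz (samples per ns).
#' @return Numeric vector of length `round(2.5 * width_tp * fs)`.
#' @export
window_tumour <- function(signal, delay, pulse, fs = 600) {
  stopifnot(inherits(pulse, "mw_pulse"), fs > 0)
  n <- length(signal)
  if (delay < 0 || delay > (n - 1) / fs) {
    stop("delay lies beyond the recorded signal", call. = FALSE)
  }
  len <- round(2.5 * pulse$width_tp * fs)
  start <- round((delay - 0.75 * pulse$width_tp) * fs) + 1L
  idx <- seq(start, length.out = len)
  inside <- idx >= 1L & idx <= n
  if (!all(inside)) {
    warning("tumour window overruns the record; zero-padding", call. = FALSE)
  }
  out <- numeric(len)
  out[inside] <- signal[idx[inside]]
  out
}

## cached anti-alias FIR (zero-phase application via filtfilt)
.fir_cache <- new.env(parent = emptyenv())
anti_alias_fir <- function(fs_in, fs_out, n_taps = 385L) {
  key <- paste(fs_in, fs_out, n_taps, sep = "|")
  if (!is.null(.fir_cache[[key]])) return(.fir_cache[[key]])
  ## cutoff at the output Nyquist (fs_out / 2), normalised to input Nyquist
  b <- as.numeric(signal::fir1(n_taps - 1L, (fs_out / 2) / (fs_in / 2)))
  .fir_cache[[key]] <- b
  b
}

#' Align and downsample a raw tumour window into a 60-sample signature
#'
#' Applies an anti-alias low-pass (FIR, cutoff at the output Nyquist,
#' zero-phase), keeps every `fs_in / fs_out`-th sample to obtain 60 signature
#' samples, then locates the peak energy (sample of maximum absolute
#' amplitude) and circularly shifts the signature so the peak sits at the
#' fixed alignment index. Aligning an already-aligned signature is therefore
#' the identity. An all-zero window yields an all-zero signature flagged
#' `low_quality`.
#'
#' @param raw_window Numeric vector from [window_tumour()]; length must be at
#'   least `60 * fs_in / fs_out`.
#' @param fs_in,fs_out Input and output sampling rates in GHz; their ratio
#'   must be an integer.
#' @param alignment_index 1-based signature sample the peak is aligned to.
#'   The default 34 places the dominant sample where the time-window
#'   classifiers see it.
#' @return An object of class `tumour_signature`: list with `samples`
#'   (length 60), `fs_out`, `alignment_index`, `low_quality`.
#' @export
align_and_downsample <- function(raw_window, fs_in = 600, fs_out = 30,
                                 alignment_index = 34L) {
  dec <- fs_in / fs_out
  if (abs(dec - round(dec)) > 1e-9) {
    stop("fs_in / fs_out must be an integer decimation factor", call. = FALSE)
  }
  dec <- as.integer(round(dec))
  n_out <- 60L
  if (length(raw_window) < n_out * dec) {
    stop("raw window too short for a 60-sample signature", call. = FALSE)
  }
  if (all(raw_window == 0)) {
    return(new_tumour_signature(numeric(n_out), fs_out, alignment_index,
                                low_quality = TRUE))
  }
  filt <- if (dec > 1L) {
    b <- anti_alias_fir(fs_in, fs_out)
    as.numeric(signal::filtfilt(b, 1, raw_window))
  } else {
    raw_window
  }
  x <- filt[seq(1L, by = dec, length.out = n_out)]
  peak <- which.max(abs(x))
  shift <- (alignment_index - peak) %% n_out
  x <- c(tail(x, shift), head(x, n_out - shift))
  new_tumour_signature(x, fs_out, alignment_index, low_quality = FALSE)
}

new_tumour_signature <- function(samples, fs_out, alignment_index, low_quality) {
  structure(
    list(samples = samples, fs_out = fs_out,
         alignment_index = as.integer(alignment_index),
         low_quality = low_quality),
    class = "tumour_signature"
  )
}

#' @export
print.tumour_signature <- function(x, ...) {
  cat(sprintf("<tumour_signature> %d samples at %g GHz, peak aligned to sample %d%s\n",
              length(x$samples), x$fs_out, x$alignment_index,
              if (x$low_quality) " [low quality]" else ""))
  invisible(x)
}

#' Window, align and downsample every channel of a scan set
#'
#' Runs the full tumour-windowing stage over a scan set: per channel,
#' subtracts the antenna-only reference (optional), computes the three-media
#' round-trip delay from the true tumour position recorded in the scan
#' metadata, windows 2.5 pulse widths around the arrival, and aligns and
#' downsamples to a 60-sample signature at 30 GHz.
#'
#' @param scans A scan set from [generate_dataset()].
#' @param angles Optional numeric vector of channel angles to keep (e.g.
#'   `c(0, 30)`); `NULL` processes every channel.
#' @param remove_reference Subtract the antenna-only reference first?
#' @param fs_out Signature sampling rate in GHz.
#' @param alignment_index 1-based alignment sample (see
#'   [align_and_downsample()]).
#' @return A tibble with one row per (scan, channel): scan metadata columns,
#'   `tx`, `rx`, `angle`, `path_mm`, `delay_ns`, `low_quality`, and a
#'   `signature` list-column of length-60 numeric vectors.
#' @export
prepare_signatures <- function(scans, angles = NULL, remove_reference = TRUE,
                               fs_out = 30, alignment_index = 34L) {
  stopifnot(inherits(scans, "scan_set"))
  array <- attr(scans, "array")
  pulse <- attr(scans, "pulse")
  fs <- attr(scans, "fs")
  channels <- attr(scans, "channels")
  keep <- if (is.null(angles)) rep(TRUE, nrow(channels)) else channels$angle %in% angles
  ch <- channels[keep, , drop = FALSE]
  if (nrow(ch) == 0L) stop("no channels at the requested angles", call. = FALSE)

  refs <- if (remove_reference) {
    reference_bank(ch, scans, array, pulse, fs)
  } else NULL

  rows <- lapply(seq_len(nrow(scans)), function(i) {
    scan <- scans[i, ]
    sig <- scan$signals[[1]][keep, , drop = FALSE]
    if (remove_reference) sig <- sig - refs
    p <- c(scan$pos_x, scan$pos_y)
    media <- media_model(scan$eps_immersion, scan$eps_skin, scan$eps_interior,
                         scan$skin_thickness, scan$breast_radius)
    delays <- roundtrip_delay(p, ch, array, media)
    sigs <- vector("list", nrow(ch))
    lowq <- logical(nrow(ch))
    for (j in seq_len(nrow(ch))) {
      w <- window_tumour(sig[j, ], delays[j], pulse, fs)
      ts <- align_and_downsample(w, fs, fs_out, alignment_index)
      sigs[[j]] <- ts$samples
      lowq[j] <- ts$low_quality
    }
    tibble::tibble(
      scan_id = scan$scan_id,
      label = scan$label,
      glandular_fraction = scan$glandular_fraction,
      tumour_id = scan$tumour_id,
      site = scan$site,
      tx = ch$tx, rx = ch$rx, angle = ch$angle,
      path_mm = channel_path_mm(ch, p, array),
      delay_ns = delays,
      low_quality = lowq,
      signature = sigs
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fs_out") <- fs_out
  attr(out, "alignment_index") <- as.integer(alignment_index)
  out
}

## matrix of reference signals for the given channels (rows), computed once
## per unique Tx-Rx distance and recycled (ring symmetry)
reference_bank <- function(ch, scans, array, pulse, fs) {
  n_samples <- attr(scans, "n_samples")
  eps_imm <- scans$eps_immersion[1]
  txy <- antenna_xy(array, ch$tx)
  rxy <- antenna_xy(array, ch$rx)
  dist <- sqrt(rowSums((txy - rxy)^2))
  key <- round(dist, 9)
  refs <- matrix(0, nrow(ch), n_samples)
  for (d in unique(key)) {
    r <- reference_waveform(d, pulse, fs, n_samples, eps_imm)
    refs[key == d, ] <- matrix(r, sum(key == d), n_samples, byrow = TRUE)
  }
  refs
}

#' Spread a signature tibble into a wide time-sample table
#'
#' Produces the classifier input for the time-window (TW) processing mode:
#' one column per signature sample (`t01` .. `t60`) plus the metadata
#' columns.
#'
#' @param signatures Output of [prepare_signatures()].
#' @return A wide tibble with predictor columns `t01..t60`.
#' @export
signature_table <- function(signatures) {
  stopifnot(is.data.frame(signatures), "signature" %in% names(signatures))
  m <- do.call(rbind, signatures$signature)
  colnames(m) <- sprintf("t%02d", seq_len(ncol(m)))
  dplyr::bind_cols(
    dplyr::select(signatures, -"signature"),
    tibble::as_tibble(m)
  )
}
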