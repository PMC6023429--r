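#' Breast model specification
#'
#' Geometric and dielectric description of a simulated breast: a circular
#' coronal section with a skin annulus, immersed in an adipose-matched
#' medium. `glandular_fraction` (1%, 5% and 27% presets in the default
#' dataset design) controls the expected number of glandular clutter echoes.
#'
#' @param radius Outer breast radius in mm.
#' @param skin_thickness Skin thickness in mm (0 < t < radius).
#' @param glandular_fraction Proportion of fibroglandular tissue in `[0, 1]`.
#' @param eps_immersion,eps_skin,eps_interior Relative permittivities (>= 1).
#' @param centre Length-2 numeric, breast centre in mm.
#' @return An object of class `breast_spec`.
#' @export
breast_spec <- function(radius = 50, skin_thickness = 2,
                        glandular_fraction = 0.05,
                        eps_immersion = 9, eps_skin = 36, eps_interior = 12,
                        centre = c(0, 0)) {
  stopifnot(radius > 0, skin_thickness > 0, skin_thickness < radius,
            glandular_fraction >= 0, glandular_fraction <= 1,
            eps_immersion >= 1, eps_skin >= 1, eps_interior >= 1,
            length(centre) == 2L)
  structure(
    list(radius = radius, skin_thickness = skin_thickness,
         glandular_fraction = glandular_fraction,
         eps_immersion = eps_immersion, eps_skin = eps_skin,
         eps_interior = eps_interior, centre = as.numeric(centre)),
    class = "breast_spec"
  )
}

#' Tumour model specification
#'
#' A tumour is described by its diameter, position and spiculation parameter
#' `s` in `[0, 1]`: smooth-bordered benign tumours have `0 <= s <= 0.25`,
#' spiculated malignant tumours `0.50 <= s <= 0.90`. When `label` is omitted
#' it is inferred from these bands; an explicit `label` allows studying
#' spiculation values outside them (e.g. class-gap sweeps).
#'
#' @param diameter Tumour diameter in mm.
#' @param spiculation Spiculation parameter `s` in `[0, 1]`.
#' @param position Length-2 numeric, tumour centre in mm.
#' @param label `"benign"` or `"malignant"`; inferred from `spiculation` when
#'   `NULL`.
#' @return An object of class `tumour_spec`.
#' @export
tumour_spec <- function(diameter, spiculation, position, label = NULL) {
  stopifnot(diameter > 0, spiculation >= 0, spiculation <= 1,
            length(position) == 2L)
  if (is.null(label)) {
    label <- if (spiculation <= 0.25) {
      "benign"
    } else if (spiculation >= 0.50 && spiculation <= 0.90) {
      "malignant"
    } else {
      stop("spiculation outside the benign [0, 0.25] and malignant [0.50, 0.90] bands; ",
           "give `label` explicitly", call. = FALSE)
    }
  }
  label <- match.arg(label, c("benign", "malignant"))
  structure(
    list(diameter = diameter, spiculation = spiculation,
         position = as.numeric(position), label = label),
    class = "tumour_spec"
  )
}

#' Canonical tumour sites of a breast model
#'
#' The five positions tumours are placed at: the central portion and the
#' four quadrants, the latter at half the breast radius along the
#' `+/- 45` degree diagonals.
#'
#' @param breast A [breast_spec()].
#' @return A tibble with columns `site`, `x`, `y` (mm).
#' @export
tumour_sites <- function(breast) {
  stopifnot(inherits(breast, "breast_spec"))
  r <- breast$radius / 2
  d <- r / sqrt(2)
  tibble::tibble(
    site = c("centre", "Q1", "Q2", "Q3", "Q4"),
    x = breast$centre[1] + c(0, d, -d, -d, d),
    y = breast$centre[2] + c(0, d, d, -d, -d)
  )
}

#' Draw a random tumour of a given class
#'
#' Spiculation is drawn uniformly from the class band (`[0, 0.25]` benign,
#' `[0.50, 0.90]` malignant, overridable) and the diameter uniformly from
#' `diameter_range`. Uses the current RNG state; seed at the call site for
#' reproducibility.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param position Length-2 numeric, tumour centre in mm.
#' @param diameter_range Length-2 numeric, diameter bounds in mm.
#' @param spiculation_range Optional length-2 override of the class band.
#' @return A [tumour_spec()].
#' @export
sample_tumour <- function(label, position = c(0, 0),
                          diameter_range = c(6, 20),
                          spiculation_range = NULL) {
  label <- match.arg(label, c("benign", "malignant"))
  band <- if (!is.null(spiculation_range)) {
    spiculation_range
  } else if (label == "benign") c(0, 0.25) else c(0.50, 0.90)
  tumour_spec(
    diameter = runif(1, diameter_range[1], diameter_range[2]),
    spiculation = runif(1, band[1], band[2]),
    position = position,
    label = label
  )
}

## direct Tx -> Rx coupling waveform through the immersion medium
reference_waveform <- function(distance, pulse, fs, n_samples, eps_immersion) {
  delay <- distance * sqrt(eps_immersion) / C_MM_PER_NS
  add_echo(numeric(n_samples), fs, delay, 1 / (1 + distance), pulse)
}

#' Antenna-only reference signal for a channel
#'
#' The deterministic antenna-coupling waveform recorded with no breast
#' present: the excitation pulse propagated directly from Tx to Rx through
#' the immersion medium, with amplitude decaying with antenna separation.
#' Channels with equal Tx--Rx distance (equal channel angle) share an
#' identical reference; a monostatic channel carries the self-coupling echo
#' at zero delay.
#'
#' @param channel One-row tibble (or list) with `tx`, `rx` antenna indices.
#' @param array A [ring_array()].
#' @param breast A [breast_spec()] (only `eps_immersion` is used).
#' @param pulse An [mw_pulse()].
#' @param fs Sampling rate in GHz.
#' @param n_samples Record length in samples.
#' @return Numeric vector of length `n_samples`.
#' @export
simulate_reference <- function(channel, array, breast, pulse, fs = 600,
                               n_samples = 4096) {
  txy <- antenna_xy(array, channel$tx)
  rxy <- antenna_xy(array, channel$rx)
  reference_waveform(sqrt(sum((txy - rxy)^2)), pulse, fs, n_samples,
                     breast$eps_immersion)
}

## add a delayed, scaled pulse copy in place, touching only its support
add_echo <- function(signal, fs, delay, amplitude, pulse) {
  half <- pulse_half_support(pulse)
  n <- length(signal)
  i0 <- max(1L, floor((delay - half) * fs) + 1L)
  i1 <- min(n, ceiling((delay + half) * fs) + 1L)
  if (i0 > i1) return(signal)
  t <- (i0:i1 - 1L) / fs
  signal[i0:i1] <- signal[i0:i1] + amplitude * pulse_waveform(t - delay, pulse)
  signal
}

#' Simulate one backscattered channel signal
#'
#' Builds the per-channel time signal as the superposition of: the direct
#' antenna-coupling waveform (the reference), a skin reflection whose
#' amplitude is `skin_ratio` times the principal tumour echo (an order of
#' magnitude larger by default), the tumour response, glandular clutter and
#' additive white Gaussian noise. The tumour response is a pulse copy at the
#' three-media round-trip delay with amplitude decaying as the inverse path
#' length, plus `k ~ Poisson(round(spicule_rate * s))` spicule sub-echoes at
#' uniform delay offsets within one pulse width and uniform amplitudes in
#' `[0.2, 0.8]` of the principal -- the waveform-distortion mechanism that
#' separates spiculated (malignant) from smooth (benign) tumours. Clutter
#' comprises `Poisson(clutter_rate * glandular_fraction)` echoes from random
#' interior points with amplitudes at most half the principal echo.
#'
#' Draws from the current RNG state; seed at the call site.
#'
#' @param breast A [breast_spec()].
#' @param tumour A [tumour_spec()]; its position must lie inside the breast
#'   interior.
#' @param channel One-row tibble (or list) with `tx`, `rx`.
#' @param array A [ring_array()]; the breast must fit inside the ring.
#' @param pulse An [mw_pulse()].
#' @param fs Sampling rate in GHz.
#' @param n_samples Record length in samples.
#' @param noise_sigma Noise standard deviation relative to the principal
#'   tumour-echo amplitude.
#' @param skin_ratio Skin-echo amplitude as a multiple of the principal
#'   tumour echo (>= 10 preserves the amplitude ordering of real scans; 0
#'   disables the skin reflection).
#' @param clutter_rate Clutter intensity per unit glandular fraction.
#' @param spicule_rate Spicule sub-echo intensity per unit spiculation.
#' @param include_reference Include the antenna-coupling waveform?
#' @return Numeric vector of length `n_samples`.
#' @export
simulate_channel_signal <- function(breast, tumour, channel, array, pulse,
                                    fs = 600, n_samples = 4096,
                                    noise_sigma = 0.05, skin_ratio = 15,
                                    clutter_rate = 20, spicule_rate = 10,
                                    include_reference = TRUE) {
  stopifnot(inherits(breast, "breast_spec"), inherits(tumour, "tumour_spec"),
            inherits(array, "ring_array"), inherits(pulse, "mw_pulse"))
  if (breast$radius >= array$radius) {
    stop("breast does not fit inside the antenna ring", call. = FALSE)
  }
  media <- as_media_model(breast)
  p <- tumour$position
  if (sqrt(sum((p - breast$centre)^2)) >= breast$radius - breast$skin_thickness) {
    stop("tumour lies outside the breast interior", call. = FALSE)
  }
  txy <- antenna_xy(array, channel$tx)[1, ]
  rxy <- antenna_xy(array, channel$rx)[1, ]
  ch <- tibble::tibble(tx = channel$tx[1], rx = channel$rx[1])

  x <- numeric(n_samples)
  if (include_reference) {
    x <- x + reference_waveform(sqrt(sum((txy - rxy)^2)), pulse, fs, n_samples,
                                breast$eps_immersion)
  }

  ## principal tumour echo
  delay_t <- roundtrip_delay(p, ch, array, media)
  path <- sqrt(sum((txy - p)^2)) + sqrt(sum((rxy - p)^2))
  amp_t <- 1 / (1 + path)
  x <- add_echo(x, fs, delay_t, amp_t, pulse)

  ## skin reflection at the specular entry points towards the breast centre
  if (skin_ratio > 0) {
    e_tx <- skin_entry(txy, breast)
    e_rx <- skin_entry(rxy, breast)
    d_skin <- (sqrt(sum((txy - e_tx)^2)) + sqrt(sum((rxy - e_rx)^2))) *
      sqrt(breast$eps_immersion) / C_MM_PER_NS
    x <- add_echo(x, fs, d_skin, skin_ratio * amp_t, pulse)
  }

  ## spicule sub-echoes: increasingly distorted waveform with spiculation
  k <- rpois(1, round(spicule_rate * tumour$spiculation))
  if (k > 0) {
    off <- runif(k, -pulse$width_tp, pulse$width_tp)
    amp <- runif(k, 0.2, 0.8) * amp_t
    for (j in seq_len(k)) x <- add_echo(x, fs, delay_t + off[j], amp[j], pulse)
  }

  ## glandular clutter from random interior points
  m <- rpois(1, clutter_rate * breast$glandular_fraction)
  if (m > 0) {
    r_in <- breast$radius - breast$skin_thickness
    rr <- r_in * 0.98 * sqrt(runif(m))
    th <- runif(m, 0, 2 * pi)
    for (j in seq_len(m)) {
      q <- breast$centre + rr[j] * c(cos(th[j]), sin(th[j]))
      d_c <- roundtrip_delay(q, ch, array, media)
      x <- add_echo(x, fs, d_c, runif(1, 0.05, 0.5) * amp_t, pulse)
    }
  }

  if (noise_sigma > 0) x <- x + rnorm(n_samples, 0, noise_sigma * amp_t)
  x
}

## point on the outer skin circle along the antenna -> breast-centre line
skin_entry <- function(a, breast) {
  v <- breast$centre - a
  a + v * (1 - breast$radius / sqrt(sum(v^2)))
}

#' Simulate a full multistatic scan
#'
#' One backscattered signal per enumerated channel of the array (78 for the
#' default 12-antenna ring), stacked as a channels x samples matrix.
#'
#' @inheritParams simulate_channel_signal
#' @param seed Optional integer seed; when given the scan is reproducible.
#' @return A list of class `mw_scan` with `signals` (matrix), `channels`,
#'   `breast`, `tumour`, `fs`, `seed`.
#' @export
simulate_scan <- function(breast, tumour, array, pulse = mw_pulse(),
                          fs = 600, n_samples = 4096, noise_sigma = 0.05,
                          skin_ratio = 15, clutter_rate = 20,
                          spicule_rate = 10, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  channels <- enumerate_channels(array)
  signals <- matrix(0, nrow(channels), n_samples)
  for (i in seq_len(nrow(channels))) {
    signals[i, ] <- simulate_channel_signal(
      breast, tumour, channels[i, ], array, pulse, fs, n_samples,
      noise_sigma, skin_ratio, clutter_rate, spicule_rate
    )
  }
  structure(
    list(signals = signals, channels = channels, breast = breast,
         tumour = tumour, fs = fs, seed = seed),
    class = "mw_scan"
  )
}

#' Generate a synthetic multistatic scan dataset
#'
#' Emulates the full-factorial study design: `n_breasts` breast presets
#' (one per glandular fraction) crossed with `n_tumours` tumour models
#' (balanced benign/malignant classes) in `n_positions` canonical positions,
#' one scan per combination. The default design (3 breasts x 72 tumours x
#' 5 positions) yields 1080 scans and, with the 12-antenna ring,
#' 84,240 backscattered signals. Tumour spiculation and diameter are drawn
#' once per tumour model and reused across breasts and positions.
#'
#' @param design List with counts `n_breasts`, `n_tumours` (even, for
#'   balanced classes), `n_positions` (at most 5).
#' @param glandular_fractions Numeric vector of length `n_breasts`; the
#'   heterogeneity presets.
#' @param array A [ring_array()].
#' @param pulse An [mw_pulse()].
#' @param fs Sampling rate in GHz.
#' @param n_samples Record length in samples. Scan counts are independent of
#'   record length, so reduced lengths can be used when only the design
#'   matters.
#' @param noise_sigma,skin_ratio,clutter_rate,spicule_rate See
#'   [simulate_channel_signal()].
#' @param benign_s,malignant_s Spiculation bands per class.
#' @param diameter_range Tumour diameter bounds in mm.
#' @param breast Template [breast_spec()] whose geometry/permittivities are
#'   shared by all presets.
#' @param seed Integer seed; the whole dataset is reproducible under it.
#' @return A tibble of class `scan_set`, one row per scan, with metadata
#'   columns and a `signals` list-column of channels x samples matrices.
#'   Attributes: `array`, `pulse`, `channels`, `fs`, `n_samples`, `design`.
#' @export
generate_dataset <- function(design = list(n_breasts = 3, n_tumours = 72,
                                           n_positions = 5),
                             glandular_fractions = c(0.01, 0.05, 0.27),
                             array = ring_array(),
                             pulse = mw_pulse(),
                             fs = 600, n_samples = 4096,
                             noise_sigma = 0.05, skin_ratio = 15,
                             clutter_rate = 20, spicule_rate = 10,
                             benign_s = c(0, 0.25), malignant_s = c(0.50, 0.90),
                             diameter_range = c(6, 20),
                             breast = breast_spec(),
                             seed = 1) {
  stopifnot(design$n_breasts >= 1, design$n_tumours >= 2,
            design$n_positions >= 1, design$n_positions <= 5,
            length(glandular_fractions) == design$n_breasts)
  if (design$n_tumours %% 2L != 0L) {
    stop("n_tumours must be even: stratification requires balanced classes",
         call. = FALSE)
  }
  withr::local_seed(seed)

  sites <- tumour_sites(breast)[seq_len(design$n_positions), ]
  half <- design$n_tumours / 2L
  tumours <- tibble::tibble(
    tumour_id = sprintf("tum%03d", seq_len(design$n_tumours)),
    label = rep(c("benign", "malignant"), each = half),
    s = c(runif(half, benign_s[1], benign_s[2]),
          runif(half, malignant_s[1], malignant_s[2])),
    diameter = runif(design$n_tumours, diameter_range[1], diameter_range[2])
  )

  grid <- tidyr::expand_grid(
    breast_id = seq_len(design$n_breasts),
    tumour_id = tumours$tumour_id,
    site = sites$site
  )
  grid <- dplyr::left_join(grid, tumours, by = "tumour_id")
  grid <- dplyr::left_join(grid, sites, by = "site")
  grid$glandular_fraction <- glandular_fractions[grid$breast_id]
  grid$scan_id <- sprintf("scan%04d", seq_len(nrow(grid)))
  grid$scan_seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))

  grid$signals <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    b <- breast_spec(breast$radius, breast$skin_thickness,
                     g$glandular_fraction, breast$eps_immersion,
                     breast$eps_skin, breast$eps_interior, breast$centre)
    tum <- tumour_spec(g$diameter, g$s, c(g$x, g$y), g$label)
    simulate_scan(b, tum, array, pulse, fs, n_samples, noise_sigma,
                  skin_ratio, clutter_rate, spicule_rate,
                  seed = g$scan_seed)$signals
  })

  out <- tibble::tibble(
    scan_id = grid$scan_id,
    breast_id = grid$breast_id,
    glandular_fraction = grid$glandular_fraction,
    tumour_id = grid$tumour_id,
    label = grid$label,
    s = grid$s,
    diameter = grid$diameter,
    site = grid$site,
    pos_x = grid$x,
    pos_y = grid$y,
    breast_radius = breast$radius,
    skin_thickness = breast$skin_thickness,
    eps_immersion = breast$eps_immersion,
    eps_skin = breast$eps_skin,
    eps_interior = breast$eps_interior,
    scan_seed = grid$scan_seed,
    signals = grid$signals
  )
  structure(
    out,
    array = array, pulse = pulse, channels = enumerate_channels(array),
    fs = fs, n_samples = n_samples, design = design, seed = seed,
    class = c("scan_set", class(out))
  )
}
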