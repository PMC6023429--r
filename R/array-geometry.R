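#' Build a circular multistatic antenna array
#'
#' Models the acquisition geometry of a multistatic microwave breast scanner:
#' `n_antennas` point antennas equally spaced on a ring, antenna 0 at polar
#' angle 0 degrees, numbered counter-clockwise. With the default 12 antennas
#' the adjacent angular spacing is 30 degrees and a fully multistatic scan
#' yields 78 transmit--receive channels (see [enumerate_channels()]).
#'
#' @param n_antennas Number of antennas on the ring (>= 1).
#' @param radius Ring radius in mm (> 0).
#' @param centre Length-2 numeric, ring centre in mm.
#'
#' @return An object of class `ring_array` with fields `n_antennas`, `radius`,
#'   `centre` and `positions` (an `n_antennas` x 2 matrix of mm coordinates;
#'   row `i + 1` holds antenna `i`).
#' @examples
#' arr <- ring_array(12, radius = 70)
#' antenna_positions(arr)
#' @export
ring_array <- function(n_antennas = 12, radius = 70, centre = c(0, 0)) {
  if (length(n_antennas) != 1L || is.na(n_antennas) || n_antennas < 1) {
    stop("invalid geometry: `n_antennas` must be a single integer >= 1", call. = FALSE)
  }
  if (length(radius) != 1L || is.na(radius) || radius <= 0) {
    stop("invalid geometry: `radius` must be a single positive number", call. = FALSE)
  }
  stopifnot(length(centre) == 2L, all(is.finite(centre)))
  n <- as.integer(n_antennas)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  positions <- cbind(
    x = centre[1] + radius * cos(theta),
    y = centre[2] + radius * sin(theta)
  )
  structure(
    list(n_antennas = n, radius = radius, centre = as.numeric(centre),
         positions = positions),
    class = "ring_array"
  )
}

#' @export
print.ring_array <- function(x, ...) {
  cat(sprintf("<ring_array> %d antennas, radius %.1f mm, centre (%.1f, %.1f)\n",
              x$n_antennas, x$radius, x$centre[1], x$centre[2]))
  cat(sprintf("  adjacent spacing %.1f deg, %d multistatic channels\n",
              360 / x$n_antennas, x$n_antennas * (x$n_antennas + 1L) / 2L))
  invisible(x)
}

#' Antenna positions as a tibble
#'
#' @param array A [ring_array()].
#' @return A tibble with columns `antenna` (0-based index), `x`, `y` (mm).
#' @export
antenna_positions <- function(array) {
  stopifnot(inherits(array, "ring_array"))
  tibble::tibble(
    antenna = seq_len(array$n_antennas) - 1L,
    x = array$positions[, 1],
    y = array$positions[, 2]
  )
}

## positions of (0-based) antenna indices as an m x 2 matrix
antenna_xy <- function(array, idx) {
  array$positions[idx + 1L, , drop = FALSE]
}

#' Channel angle between a transmit and a receive antenna
#'
#' The channel angle Z is the angular separation of the two antennas of a
#' channel on the ring: `min(|tx - rx|, n - |tx - rx|) * 360 / n` degrees.
#' For an even number of antennas Z lies in \[0, 180\]; Z = 0 is a monostatic
#' channel (antenna transmits and receives).
#'
#' @param tx,rx Integer antenna indices in `[0, n)`. Vectorised.
#' @param array A [ring_array()].
#' @return Channel angle(s) in degrees.
#' @export
channel_angle <- function(tx, rx, array) {
  stopifnot(inherits(array, "ring_array"))
  n <- array$n_antennas
  if (any(tx < 0 | tx >= n | rx < 0 | rx >= n)) {
    stop("antenna index out of range [0, n)", call. = FALSE)
  }
  d <- abs(tx - rx)
  pmin(d, n - d) * 360 / n
}

#' Enumerate all multistatic channels of an array
#'
#' All unordered transmit--receive pairs, including monostatic ones
#' (tx = rx), canonicalised with `tx <= rx`: `n * (n + 1) / 2` channels in
#' total (78 for 12 antennas).
#'
#' @param array A [ring_array()].
#' @return A tibble with one row per channel: `tx`, `rx` (0-based indices,
#'   `tx <= rx`), `angle` (channel angle in degrees) and `channel_id`.
#' @export
enumerate_channels <- function(array) {
  stopifnot(inherits(array, "ring_array"))
  n <- array$n_antennas
  tx <- unlist(lapply(seq_len(n) - 1L, function(i) rep(i, n - i)))
  rx <- unlist(lapply(seq_len(n) - 1L, function(i) i:(n - 1L)))
  tibble::tibble(
    tx = as.integer(tx),
    rx = as.integer(rx),
    angle = channel_angle(tx, rx, array),
    channel_id = sprintf("ch%02d_%02d", tx, rx)
  )
}

#' Distinct channel angles of an array
#'
#' For an even number of antennas `n` these are `{0, s, 2s, ..., 180}` with
#' `s = 360 / n`; seven angles for the default 12-antenna ring.
#'
#' @param array A [ring_array()].
#' @return Sorted numeric vector of distinct channel angles in degrees.
#' @export
distinct_angles <- function(array) {
  sort(unique(enumerate_channels(array)$angle))
}

#' Rank channels by proximity to a tumour
#'
#' Orders the channels of a scan by the two-leg signal path length
#' Tx -> tumour -> Rx (the physical propagation path; for a monostatic channel
#' it reduces to twice the antenna--tumour distance). Ties are broken by
#' `(tx, rx)` lexicographic order, so the ranking is deterministic. This is
#' the ranking consumed by the ranked antenna-grouping majority vote
#' ([antenna_grouping()]).
#'
#' @param channels A channel tibble from [enumerate_channels()] (any subset).
#' @param tumour_position Length-2 numeric, tumour centre in mm. Should lie
#'   strictly inside the ring; if not, a warning is issued but the ranking is
#'   still defined.
#' @param array A [ring_array()].
#' @return The input channels with an added `path_mm` column, sorted ascending
#'   by `path_mm` (ties by `tx`, `rx`) with a `rank` column `1..nrow`.
#' @export
rank_channels_by_proximity <- function(channels, tumour_position, array) {
  stopifnot(inherits(array, "ring_array"), length(tumour_position) == 2L)
  if (sqrt(sum((tumour_position - array$centre)^2)) >= array$radius) {
    warning("tumour position lies on or outside the antenna ring; ranking is still defined",
            call. = FALSE)
  }
  channels$path_mm <- channel_path_mm(channels, tumour_position, array)
  out <- dplyr::arrange(channels, .data$path_mm, .data$tx, .data$rx)
  out$rank <- seq_len(nrow(out))
  out
}

## two-leg Euclidean path length |Tx - p| + |p - Rx| in mm, vectorised
channel_path_mm <- function(channels, tumour_position, array) {
  txy <- antenna_xy(array, channels$tx)
  rxy <- antenna_xy(array, channels$rx)
  p <- as.numeric(tumour_position)
  sqrt((txy[, 1] - p[1])^2 + (txy[, 2] - p[2])^2) +
    sqrt((rxy[, 1] - p[1])^2 + (rxy[, 2] - p[2])^2)
}

#' Classification-model families supported by an array
#'
#' Enumerates the channel-angle architectures that can be built on a given
#' ring: one equal-angle (EA) model per distinct channel angle, and one
#' multiple-angle (MA) and equal-angle-combined (EAC) model per cumulative
#' angle range `[0, i * s]` for `i = 1 .. n_angles - 1` (the range `[0, 0]`
#' would coincide with EA 0). For the 12-antenna ring this gives 7 EA,
#' 6 MA and 6 EAC models.
#'
#' @param array A [ring_array()].
#' @return A tibble with columns `kind` ("EA", "MA", "EAC"), `angle` (the EA
#'   angle or the upper bound of the range, degrees) and `label`.
#' @export
model_families <- function(array) {
  angles <- distinct_angles(array)
  dplyr::bind_rows(
    tibble::tibble(kind = "EA", angle = angles,
                   label = sprintf("EA %g°", angles)),
    tibble::tibble(kind = "MA", angle = angles[-1],
                   label = sprintf("MA 0–%g°", angles[-1])),
    tibble::tibble(kind = "EAC", angle = angles[-1],
                   label = sprintf("EAC 0–%g°", angles[-1]))
  )
}
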