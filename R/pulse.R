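#' Differentiated Gaussian excitation pulse
#'
#' The interrogating waveform of the scanner: the first derivative of a
#' Gaussian, whose amplitude spectrum `|F(f)| ~ f exp(-2 pi^2 sigma^2 f^2)`
#' peaks at `f_c = 1 / (2 pi sigma)`. The Gaussian width is therefore set
#' from the requested centre frequency (6 GHz by default). `width_tp` is the
#' nominal pulse width used by the windowing stage (the tumour window spans
#' 2.5 pulse widths); with the 0.8 ns default, a window at 600 GHz holds
#' 1200 raw samples and downsamples to exactly 60 signature samples at
#' 30 GHz.
#'
#' @param centre_frequency Spectral peak in GHz.
#' @param width_tp Nominal pulse width in ns (> 0), the windowing time unit.
#' @param amplitude Peak absolute amplitude (arbitrary units).
#' @return An object of class `mw_pulse`.
#' @examples
#' p <- mw_pulse()
#' t <- seq(-0.2, 0.2, by = 1 / 600)
#' w <- pulse_waveform(t, p)
#' @export
mw_pulse <- function(centre_frequency = 6, width_tp = 0.8, amplitude = 1) {
  stopifnot(centre_frequency > 0, width_tp > 0, is.finite(amplitude))
  structure(
    list(centre_frequency = centre_frequency, width_tp = width_tp,
         amplitude = amplitude),
    class = "mw_pulse"
  )
}

#' @export
print.mw_pulse <- function(x, ...) {
  cat(sprintf("<mw_pulse> differentiated Gaussian, %.3g GHz centre, width %.3g ns, amplitude %.3g\n",
              x$centre_frequency, x$width_tp, x$amplitude))
  invisible(x)
}

## Gaussian sigma (ns) giving the requested spectral peak
pulse_sigma <- function(pulse) 1 / (2 * pi * pulse$centre_frequency)

#' Evaluate the pulse waveform
#'
#' First derivative of a Gaussian centred at `t = 0`, normalised so the
#' extreme values are `+/- amplitude`. Odd about its centre: zero at `t = 0`
#' and zero integral over its support.
#'
#' @param t Time in ns (vectorised).
#' @param pulse An [mw_pulse()].
#' @return Amplitudes at `t`.
#' @export
pulse_waveform <- function(t, pulse) {
  stopifnot(inherits(pulse, "mw_pulse"))
  s <- pulse_sigma(pulse)
  ## -(t / s^2) exp(-t^2 / 2 s^2) has extrema 1/s * exp(-1/2) at t = -/+ s
  pulse$amplitude * (-(t / s) * exp(0.5 - t^2 / (2 * s^2)))
}

## effective half-support of the waveform (|w| < 1e-8 outside), in ns
pulse_half_support <- function(pulse) 7 * pulse_sigma(pulse)
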