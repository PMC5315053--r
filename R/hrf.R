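#' Parameters of the double-gamma haemodynamic response function
#'
#' The canonical BOLD impulse response is modelled as the difference of two
#' gamma densities: a positive lobe peaking at `peak_delay` seconds and an
#' undershoot peaking at `undershoot_delay` seconds, scaled by
#' `undershoot_ratio`.  Gamma shapes are chosen so that each lobe's mode
#' falls exactly at its stated delay (shape = delay / dispersion + 1,
#' scale = dispersion).
#'
#' @param peak_delay time-to-peak of the positive lobe, s (default 6).
#' @param undershoot_delay time-to-peak of the undershoot, s (default 16).
#' @param peak_dispersion,undershoot_dispersion gamma scale of each lobe, s.
#' @param undershoot_ratio relative amplitude of the undershoot (default 1/6).
#' @param length total kernel support, s (default 32).
#' @return A list of class `HrfParams`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, length = 32) {
  for (nm in c("peak_delay", "undershoot_delay", "peak_dispersion",
               "undershoot_dispersion", "undershoot_ratio", "length"))
    check_scalar(get(nm), nm, lower = .Machine$double.eps)
  if (length <= undershoot_delay)
    stop("kernel 'length' must exceed 'undershoot_delay'")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio, length = length),
            class = "HrfParams")
}

# Evaluate the (unscaled) double-gamma response at times t (seconds).
double_gamma_eval <- function(t, params) {
  shape1 <- params$peak_delay / params$peak_dispersion + 1
  shape2 <- params$undershoot_delay / params$undershoot_dispersion + 1
  stats::dgamma(t, shape = shape1, scale = params$peak_dispersion) -
    params$undershoot_ratio *
      stats::dgamma(t, shape = shape2, scale = params$undershoot_dispersion)
}

#' Sample the double-gamma haemodynamic response function
#'
#' Returns the kernel sampled on `[0, length]` at `tr`-second spacing,
#' scaled so its maximum is 1.
#'
#' @param tr sampling interval, s (> 0).
#' @param params an [hrf_params()] object.
#' @return Numeric vector of kernel samples, attribute `times` giving the
#'   sample times in seconds.
#' @export
double_gamma_hrf <- function(tr, params = hrf_params()) {
  check_scalar(tr, "tr", lower = .Machine$double.eps)
  if (!inherits(params, "HrfParams")) stop("'params' must be an HrfParams object")
  times <- seq(0, params$length, by = tr)
  h <- double_gamma_eval(times, params)
  # scale to unit peak on a dense grid so coarse TRs keep the same amplitude
  dense <- double_gamma_eval(seq(0, params$length, by = 0.01), params)
  h <- h / max(dense)
  attr(h, "times") <- times
  h
}
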