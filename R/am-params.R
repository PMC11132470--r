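#' Designated amplitude-modulation parameters
#'
#' Construct the parameter set of the shifted-lognormal AM spectrum used to
#' design a stimulus: the peak (mode) modulation frequency `m` in Hz and the
#' regularity parameter `sigma` (the log-SD of the lognormal; smaller values
#' concentrate modulation power around the peak, giving more isochronous
#' envelopes). The x-shift `b = -1.2813 m` and the location
#' `mu = log(m - b) + sigma^2` are derived so that the mode of the shifted
#' lognormal sits exactly at `m`: `b + exp(mu - sigma^2) = m`.
#'
#' @param m Peak AM frequency in Hz; must be positive. Values near 1-2 Hz are
#'   typical of music envelopes, 3.5-5.5 Hz of speech.
#' @param sigma Regularity parameter (unitless, > 0); 0.35 is the package-wide
#'   reference value.
#' @return A tibble of class `am_params` with columns `m`, `sigma`, `b`, `mu`
#'   (one row per parameter combination; inputs are recycled).
#' @examples
#' am_params(m = 2, sigma = 0.35)
#' @export
am_params <- function(m, sigma = 0.35) {
  if (!is.numeric(m) || any(!is.finite(m)) || any(m <= 0)) {
    abort("`m` (peak AM frequency, Hz) must be positive and finite.")
  }
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort("`sigma` (regularity parameter) must be positive and finite.")
  }
  out <- tibble::tibble(m = as.numeric(m), sigma = as.numeric(sigma))
  out$b <- -1.2813 * out$m
  out$mu <- log(out$m - out$b) + out$sigma^2
  class(out) <- c("am_params", class(out))
  out
}

#' @export
format.am_params <- function(x, ...) {
  c(sprintf("<am_params: %d parameter set(s)>", nrow(x)),
    format(tibble::as_tibble(x), ...))
}
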