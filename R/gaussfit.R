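#' Fit a 1D Gaussian with constant offset
#'
#' Least-squares fit of `a * exp(-(x - mu)^2 / (2 * sigma^2)) + c` by
#' Levenberg-Marquardt, initialised from intensity-weighted moments of the
#' background-subtracted signal. Used both for sub-pixel focus centring and
#' for the per-line effective diameters of the angular profile sweep.
#'
#' @param position numeric vector of sample positions.
#' @param intensity numeric vector of intensities, same length.
#' @param maxiter maximum LM iterations.
#' @return list: `amplitude`, `centre`, `sigma` (always positive), `offset`,
#'   `rmse`, `converged`.
#' @export
fit_gaussian_1d <- function(position, intensity, maxiter = 200L) {
  stopifnot(length(position) == length(intensity), length(position) >= 4L)
  if (!all(is.finite(position)) || !all(is.finite(intensity)))
    return(list(amplitude = NA_real_, centre = NA_real_, sigma = NA_real_,
                offset = NA_real_, rmse = NA_real_, converged = FALSE))
  c0 <- min(intensity)
  a0 <- max(intensity) - c0
  # flat signal (allowing for float rounding): no peak to fit
  if (a0 <= max(1e-12, 1e-9 * max(abs(intensity))))
    return(list(amplitude = 0, centre = mean(position), sigma = NA_real_,
                offset = c0, rmse = 0, converged = FALSE))
  w <- pmax(intensity - c0, 0)
  mu0 <- sum(w * position) / sum(w)
  s0 <- sqrt(sum(w * (position - mu0)^2) / sum(w))
  s0 <- max(s0, diff(range(position)) / (2 * length(position)))
  resid_fn <- function(p)
    intensity - (p[1] * exp(-(position - p[2])^2 / (2 * p[3]^2)) + p[4])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(a0, mu0, s0, c0), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-8, ptol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4) || !all(is.finite(fit$par)))
    return(list(amplitude = NA_real_, centre = NA_real_, sigma = NA_real_,
                offset = NA_real_, rmse = NA_real_, converged = FALSE))
  p <- fit$par
  list(amplitude = p[1], centre = p[2], sigma = abs(p[3]), offset = p[4],
       rmse = sqrt(mean(resid_fn(p)^2)), converged = TRUE)
}
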