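#' Coherently driven two-level model
#'
#' Closed-form first-order perturbation theory in the rotating-wave
#' approximation for a two-level system driven by a Gaussian pulse
#' `E(t) = E0 exp(-t^2 / 2 tau^2) cos(omega0 t)`. The upper-state coefficient
#' involves the error function of complex argument; it is evaluated through the
#' scaled complementary error function (Faddeeva w) so that large reduced
#' detunings `tau * Omega` do not overflow.
#'
#' @param mu transition dipole mu_ba, au.
#' @param E0 field amplitude, au.
#' @param tau_fs Gaussian envelope parameter tau, fs.
#' @param detuning_ev detuning Omega = omega0 - omega_ba, eV.
#' @return Object of class `two_level_params`. A `weak_field` flag records
#'   whether the predicted asymptotic upper population stays below 1 percent.
#' @export
two_level_params <- function(mu, E0, tau_fs, detuning_ev = 0) {
  stopifnot(tau_fs > 0)
  tau <- fs_to_au(tau_fs)
  Omega <- ev_to_hartree(detuning_ev)
  p_inf <- 2 * pi * (mu * E0 * tau / 4)^2 * 4 * exp(-tau^2 * Omega^2)
  structure(list(mu = mu, E0 = E0, tau = tau, Omega = Omega,
                 tau_fs = tau_fs, detuning_ev = detuning_ev,
                 weak_field = p_inf <= 0.01),
            class = "two_level_params")
}

#' Faddeeva function w(z) = exp(-z^2) erfc(-iz)
#'
#' Weideman's rational approximation, accurate to ~1e-13 on the upper half
#' plane with the default number of terms; the lower half plane is reached via
#' `w(z) = 2 exp(-z^2) - w(-z)` (callers below avoid that branch entirely by
#' symmetry, keeping everything overflow-free).
#'
#' @param z complex vector with `Im(z) >= 0`.
#' @param n number of expansion terms.
#' @return complex vector w(z).
#' @export
faddeeva_w <- function(z, n = 64) {
  if (any(Im(z) < -1e-12))
    stop("faddeeva_w requires Im(z) >= 0", call. = FALSE)
  M <- 2L * n
  M2 <- 2L * M
  k <- seq.int(-M + 1L, M - 1L)
  L <- sqrt(n / sqrt(2))
  theta <- k * pi / M
  t <- L * tan(theta / 2)
  f <- c(0, exp(-t^2) * (L^2 + t^2))
  # fftshift then FFT gives the polynomial coefficients of the expansion
  fsh <- c(f[(M + 1L):M2], f[1:M])
  a <- Re(stats::fft(fsh)) / M2
  a <- rev(a[2:(n + 1L)])
  Z <- (L + 1i * z) / (L - 1i * z)
  p <- rep(0 + 0i, length(z))
  for (coef in a) p <- p * Z + coef
  2 * p / (L - 1i * z)^2 + (1 / sqrt(pi)) / (L - 1i * z)
}

# Stable evaluation of F(u, v) = exp(-v^2) * (1 + erf(u - i v)),
# with u = t / (sqrt(2) tau) and v = tau * Omega / sqrt(2).
# For u >= 0:  F = 2 exp(-v^2) - exp(-u^2) exp(2iuv) w(v + iu)
# For u <  0:  F = exp(-u^2) exp(2iuv) w(-v - iu)
# Both branches keep the Faddeeva argument on the upper half plane and every
# exponential bounded by 1.
erf_envelope <- function(u, v) {
  out <- complex(length.out = max(length(u), length(v)))
  u <- rep_len(u, length(out)); v <- rep_len(v, length(out))
  pos <- u >= 0
  ph <- exp(-u^2 + 2i * u * v)
  if (any(pos))
    out[pos] <- 2 * exp(-v[pos]^2) - ph[pos] * faddeeva_w(v[pos] + 1i * u[pos])
  if (any(!pos))
    out[!pos] <- ph[!pos] * faddeeva_w(-v[!pos] - 1i * u[!pos])
  out
}

#' Upper-state coefficient of the driven two-level system
#'
#' `c_a(t) = -sqrt(2 pi) i mu E0 tau / 4 * exp(-tau^2 Omega^2 / 2) *
#'   (1 + erf(t / (sqrt(2) tau) - i tau Omega / sqrt(2)))`.
#'
#' @param p a [two_level_params()].
#' @param t_fs time(s), fs (pulse centered at 0).
#' @return complex coefficient(s).
#' @export
tl_upper_coefficient <- function(p, t_fs) {
  t <- fs_to_au(t_fs)
  u <- t / (sqrt(2) * p$tau)
  v <- p$tau * p$Omega / sqrt(2)
  pref <- -sqrt(2 * pi) * 1i * p$mu * p$E0 * p$tau / 4
  pref * erf_envelope(u, v)
}

#' Instantaneous excitation rate of the two-level system
#'
#' Time derivative of the upper-state population,
#' `d|c_a|^2/dt = sqrt(2 pi) mu^2 E0^2 tau / 4 * exp(-t^2/2tau^2 - tau^2
#' Omega^2 / 2) * Re[exp(i t Omega) (1 + erf(t/(sqrt 2 tau) - i tau Omega /
#' sqrt 2))]`. Negative values (back-transfer) are returned as-is.
#'
#' @inheritParams tl_upper_coefficient
#' @return rate(s) in 1/fs.
#' @export
tl_excitation_rate <- function(p, t_fs) {
  t <- fs_to_au(t_fs)
  u <- t / (sqrt(2) * p$tau)
  v <- p$tau * p$Omega / sqrt(2)
  pref <- sqrt(2 * pi) * p$mu^2 * p$E0^2 * p$tau / 4
  rate_au <- pref * exp(-u^2) * Re(exp(1i * t * p$Omega) * erf_envelope(u, v))
  rate_au / .FS  # per fs
}

#' Excitation-probability distribution in reduced coordinates
#'
#' Evaluates the excitation rate on a grid of reduced time `t/tau` and reduced
#' detuning `tau * Omega` (the distribution shape depends only on tau, which
#' stretches it). Negative rate values are clamped to zero, the grid is
#' normalized to unit mass, and the smallest region containing `level` of the
#' mass is flagged. This "teardrop" distribution characterizes where selected
#' (energy, start time) pairs should fall.
#'
#' @param t_red vector of reduced times `t/tau`.
#' @param det_red vector of reduced detunings `tau * Omega`.
#' @param level probability level in (0, 1).
#' @return tibble with columns `t_red`, `det_red`, `density` (normalized),
#'   `in_region` (logical: inside the smallest `level`-mass region).
#' @export
tl_probability_region <- function(t_red = seq(-4, 6, length.out = 201),
                                  det_red = seq(-4, 4, length.out = 201),
                                  level = 0.99) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  # reduced-unit rate: tau = 1 au, mu*E0 chosen so the prefactor is 1
  p <- structure(list(mu = 1, E0 = 1, tau = 1, Omega = 0), class = "two_level_params")
  grid <- expand.grid(t_red = t_red, det_red = det_red)
  u <- grid$t_red / sqrt(2)
  v <- grid$det_red / sqrt(2)
  rate <- exp(-u^2) * Re(exp(1i * grid$t_red * grid$det_red) *
                           erf_envelope(u, v))
  dens <- pmax(rate, 0)
  dens <- dens / sum(dens)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord])
  inreg <- logical(length(dens))
  inreg[ord[cum <= level]] <- TRUE
  # include the boundary cell that crosses the level
  ib <- which(cum > level)[1]
  if (!is.na(ib)) inreg[ord[ib]] <- TRUE
  out <- tibble::tibble(t_red = grid$t_red, det_red = grid$det_red,
                        density = dens, in_region = inreg)
  attr(out, "level") <- level
  out
}
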