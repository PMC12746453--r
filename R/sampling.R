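#' Wigner transform of a single-state nuclear wavefunction
#'
#' Computes `W(R, P) = (1/pi) Int psi*(R + y) psi(R - y) exp(2 i P y) dy` on
#' the position grid of the wavefunction, by FFT over the correlation variable
#' for each grid point. The wavefunction must describe a single nuclear state;
#' for the vibrational ground state of a coupled two-state model the total
#' density is collapsed to one real, nodeless amplitude `sqrt(rho(R))` before
#' transforming (the bundled ground states carry negligible upper-diabat
#' population, so this is exact up to numerics).
#'
#' @param wf a [grid_wavefunction()] (vibrational ground state).
#' @param max_upper_population maximum tolerated population outside the
#'   dominant diabat before the input is rejected as multi-state.
#' @return Object of class `wigner_distribution`: list with `R` (bohr), `P`
#'   (au), matrix `W` (length(R) x length(P)), and step sizes `dR`, `dP`.
#' @export
wigner_distribution <- function(wf, max_upper_population = 1e-6) {
  stopifnot(inherits(wf, "grid_wavefunction"))
  pops <- colSums(abs(wf$psi)^2) * wf$dR
  if (min(pops) > max_upper_population)
    stop("wavefunction has significant population on both states; ",
         "the Wigner transform expects a single nuclear state", call. = FALSE)
  nrm <- sum(pops)
  chi <- sqrt((abs(wf$psi[, 1])^2 + abs(wf$psi[, 2])^2) / nrm)
  n <- length(wf$R)
  dR <- wf$dR
  # correlation over y = m * dR, m = -n/2 .. n/2 - 1, zero outside the grid
  pad <- c(rep(0, n), chi, rep(0, n))
  mseq <- -(n %/% 2):(n %/% 2 - 1)
  phase <- (-1)^(0:(n - 1))  # centers the P grid
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    f <- pad[n + j + mseq] * pad[n + j - mseq]
    W[j, ] <- Re(stats::fft(f * phase)) * phase
  }
  dP <- pi / (n * dR)
  P <- (mseq) * dP
  # normalization: sum(W) * dR * dP = 1
  W <- W / (sum(W) * dR * dP)
  structure(list(R = wf$R, P = P, W = W, dR = dR, dP = dP),
            class = "wigner_distribution")
}

#' Marginals of a Wigner distribution
#'
#' @param wd a [wigner_distribution()].
#' @return list with `position` (density over R) and `momentum` (density over
#'   P), both normalized to unit integral.
#' @export
wigner_marginals <- function(wd) {
  list(position = rowSums(wd$W) * wd$dP,
       momentum = colSums(wd$W) * wd$dR)
}

#' Draw phase-space samples from a Wigner distribution
#'
#' Cells with (numerically) negative quasi-probability are clipped to zero
#' before sampling; the clipped mass is recorded as an attribute. Sampling is
#' by the inverse-CDF over grid cells with uniform jitter within each cell, and
#' is reproducible under `seed`. Momenta are converted to velocities with the
#' supplied mass.
#'
#' @param wd a [wigner_distribution()].
#' @param n number of samples.
#' @param mass reduced mass, electron masses (velocity = P / mass).
#' @param seed integer seed.
#' @return tibble with columns `geometry_id`, `R` (bohr), `v` (au),
#'   `weight` (all 1); attribute `clipped_mass`.
#' @export
wigner_sample <- function(wd, n, mass, seed) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  Wc <- pmax(wd$W, 0)
  clipped <- -sum(pmin(wd$W, 0)) * wd$dR * wd$dP
  prob <- as.vector(Wc)
  rng <- local_rng(seed)
  idx <- rng$sample_int(length(prob), n, replace = TRUE, prob = prob)
  jit <- matrix(rng$unif(2 * n), n, 2) - 0.5
  i <- (idx - 1L) %% length(wd$R) + 1L
  j <- (idx - 1L) %/% length(wd$R) + 1L
  out <- tibble::tibble(
    geometry_id = seq_len(n),
    R = wd$R[i] + jit[, 1] * wd$dR,
    v = (wd$P[j] + jit[, 2] * wd$dP) / mass,
    weight = 1)
  attr(out, "clipped_mass") <- clipped
  out
}

#' Simulated absorption spectrum from phase-space samples
#'
#' Sum over samples of oscillator-strength-weighted Gaussians centred at the
#' vertical excitation energy of each geometry, with the given energy FWHM,
#' normalized to unit maximum.
#'
#' @param samples tibble from [wigner_sample()] (column `R` is used).
#' @param model a [diabatic_model()].
#' @param fwhm_ev Gaussian convolution FWHM, eV.
#' @param energy_ev optional energy grid, eV.
#' @return tibble with columns `energy_ev`, `intensity` (unit maximum).
#' @export
absorption_spectrum <- function(samples, model, fwhm_ev = 0.1,
                                energy_ev = NULL) {
  ad <- adiabatize_n(model, samples$R)
  de <- hartree_to_ev(ad$energies[, 2] - ad$energies[, 1])
  mu01 <- ad$tdm_adiabatic[1, 2, ]
  fosc <- (2 / 3) * ev_to_hartree(de) * mu01^2
  if (is.null(energy_ev))
    energy_ev <- seq(min(de) - 3 * fwhm_ev, max(de) + 3 * fwhm_ev,
                     length.out = 400L)
  sig <- fwhm_ev / (2 * sqrt(2 * log(2)))
  inten <- vapply(energy_ev, function(e)
    sum(fosc * exp(-(e - de)^2 / (2 * sig^2))), numeric(1))
  tibble::tibble(energy_ev = energy_ev, intensity = inten / max(inten))
}
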