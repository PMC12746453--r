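#' Grid wavefunctions for two-state quantum dynamics
#'
#' A `grid_wavefunction` holds complex amplitudes for both diabatic states on a
#' uniform position grid (FFT convention: the right endpoint is excluded).
#'
#' @param R uniform grid, bohr.
#' @param psi n x 2 complex matrix of diabatic amplitudes.
#' @param time_fs current time stamp, fs.
#' @return Object of class `grid_wavefunction`.
#' @export
grid_wavefunction <- function(R, psi, time_fs = 0) {
  stopifnot(is.matrix(psi), nrow(psi) == length(R), ncol(psi) == 2)
  dR <- diff(R)
  if (max(abs(dR - dR[1])) > 1e-9 * dR[1])
    stop("grid must be uniform", call. = FALSE)
  structure(list(R = R, dR = dR[1], psi = psi, time_fs = time_fs),
            class = "grid_wavefunction")
}

#' @export
print.grid_wavefunction <- function(x, ...) {
  cat(sprintf("<grid_wavefunction> %d points on [%g, %g] bohr, t = %g fs, norm = %.8f\n",
              length(x$R), min(x$R), max(x$R) + x$dR, x$time_fs, wf_norm(x)))
  invisible(x)
}

#' Norm and energy of a grid wavefunction
#'
#' @param wf a [grid_wavefunction()].
#' @param model a [diabatic_model()] (for `wf_energy`).
#' @return `wf_norm`: total norm integral; `wf_energy`: energy expectation
#'   value in hartree.
#' @export
wf_norm <- function(wf) sum(abs(wf$psi)^2) * wf$dR

#' @rdname wf_norm
#' @export
wf_energy <- function(wf, model) {
  n <- length(wf$R)
  k <- fft_wavenumbers(n, wf$dR)
  tk <- k^2 / (2 * model$mass)
  kin <- sum(vapply(1:2, function(s) {
    ft <- stats::fft(wf$psi[, s])
    Re(sum(Conj(ft) * (tk * ft))) / n
  }, numeric(1))) * wf$dR
  v <- model$pot(wf$R)
  pot <- sum(v$v11 * abs(wf$psi[, 1])^2 + v$v22 * abs(wf$psi[, 2])^2 +
               2 * v$v12 * Re(Conj(wf$psi[, 1]) * wf$psi[, 2])) * wf$dR
  kin + pot
}

fft_wavenumbers <- function(n, dR)
  2 * pi / (n * dR) * c(0:(n %/% 2 - 1), -(n %/% 2):-1)

# pointwise 2x2 symmetric matrix exponential factors, exp(s * H) applied as
# three component vectors (p11, p12, p22); s may be complex (-1i*dt for real
# time, -dt for imaginary time)
sym2_exp <- function(v11, v12, v22, s) {
  a <- (v11 + v22) / 2
  d <- (v11 - v22) / 2
  b <- sqrt(d^2 + v12^2)
  ea <- exp(s * a)
  # cosh(sb) and sinh(sb)/b with the b -> 0 limit
  ch <- cosh(s * b)
  sb <- rep_len(s, length(b)) + 0 * b
  nz <- b > 0
  sb[nz] <- sinh(s * b[nz]) / b[nz]
  list(p11 = ea * (ch + sb * d), p12 = ea * (sb * v12), p22 = ea * (ch - sb * d))
}

apply_sym2 <- function(p, psi)
  cbind(p$p11 * psi[, 1] + p$p12 * psi[, 2],
        p$p12 * psi[, 1] + p$p22 * psi[, 2])

#' Vibrational ground state by imaginary-time propagation
#'
#' Split-operator propagation in imaginary time on the coupled two-state
#' diabatic Hamiltonian, renormalizing each step; this relaxes to the lowest
#' vibronic state, i.e. the vibrational ground state of the lower adiabatic
#' surface. Convergence is declared when the energy change per step drops
#' below `tol`.
#'
#' @param model a [diabatic_model()].
#' @param n number of grid points.
#' @param rmin,rmax grid extent, bohr.
#' @param dt_au imaginary-time step, atomic units.
#' @param tol convergence threshold on the energy change per step, hartree.
#' @param max_steps maximum number of imaginary-time steps.
#' @return A [grid_wavefunction()] with attribute `energy` (hartree).
#' @export
#' @examples
#' m <- harmonic_fixture(omega = 2e-3, gap = 0.1, tdm = 0.1, mass = 2000)
#' wf <- qd_ground_state(m, n = 256, rmin = -2, rmax = 2)
#' attr(wf, "energy")  # ~ omega / 2
qd_ground_state <- function(model, n = 1024, rmin = 3, rmax = 40,
                            dt_au = 2, tol = 1e-12, max_steps = 100000L) {
  dR <- (rmax - rmin) / n
  R <- rmin + (0:(n - 1)) * dR
  v <- model$pot(R)
  k <- fft_wavenumbers(n, dR)
  eT <- exp(-k^2 / (2 * model$mass) * dt_au)
  pv <- sym2_exp(v$v11, v$v12, v$v22, -dt_au / 2)
  # start from a Gaussian at the lower-adiabat minimum with harmonic width
  e1 <- (v$v11 + v$v22) / 2 - sqrt(((v$v11 - v$v22) / 2)^2 + v$v12^2)
  i0 <- which.min(e1)
  curv <- if (i0 > 1 && i0 < n)
    (e1[i0 - 1] - 2 * e1[i0] + e1[i0 + 1]) / dR^2 else NA
  w <- if (is.finite(curv) && curv > 0) sqrt(curv / model$mass) else 1e-3
  sig <- sqrt(1 / (2 * model$mass * w))
  psi <- cbind(exp(-(R - R[i0])^2 / (4 * sig^2)) + 0i, rep(0i, n))
  psi <- psi / sqrt(sum(abs(psi)^2) * dR)
  wf <- grid_wavefunction(R, psi)
  check_every <- 20L
  e_old <- Inf
  for (it in seq_len(max_steps)) {
    psi <- apply_sym2(pv, psi)
    psi <- cbind(stats::fft(eT * stats::fft(psi[, 1]), inverse = TRUE) / n,
                 stats::fft(eT * stats::fft(psi[, 2]), inverse = TRUE) / n)
    psi <- apply_sym2(pv, psi)
    psi <- psi / sqrt(sum(abs(psi)^2) * dR)
    if (it %% check_every == 0L) {
      wf$psi <- psi
      e_new <- wf_energy(wf, model)
      if (abs(e_new - e_old) / check_every < tol) {
        # remove the residual global phase; the ground state is real positive
        psi <- psi * exp(-1i * Arg(psi[which.max(abs(psi[, 1])), 1]))
        wf$psi <- psi
        attr(wf, "energy") <- e_new
        attr(wf, "iterations") <- it
        return(wf)
      }
      e_old <- e_new
    }
  }
  stop("imaginary-time propagation did not converge in ", max_steps, " steps",
       call. = FALSE)
}

#' Closed-form ground state of a harmonic fixture on a grid
#'
#' The exact Gaussian ground vibrational state of the lower diabat of a
#' [harmonic_fixture()], discretized on a uniform grid. Used as an analytic
#' oracle for the imaginary-time and Wigner-transform code.
#'
#' @param model a [harmonic_fixture()] model.
#' @param n,rmin,rmax grid specification.
#' @return A [grid_wavefunction()] with attribute `energy = omega/2`.
#' @export
analytic_ground_state <- function(model, n = 512, rmin = NULL, rmax = NULL) {
  p <- model$params
  if (is.null(p$omega))
    stop("analytic ground state is only available for harmonic fixtures",
         call. = FALSE)
  sig <- sqrt(1 / (2 * p$mass * p$omega))
  if (is.null(rmin)) rmin <- p$r0 - 10 * sig
  if (is.null(rmax)) rmax <- p$r0 + 10 * sig
  dR <- (rmax - rmin) / n
  R <- rmin + (0:(n - 1)) * dR
  chi <- exp(-(R - p$r0)^2 / (4 * sig^2))
  chi <- chi / sqrt(sum(chi^2) * dR)
  wf <- grid_wavefunction(R, cbind(chi + 0i, rep(0i, n)))
  attr(wf, "energy") <- p$omega / 2
  wf
}

#' Split-operator real-time propagation
#'
#' Second-order (Strang) split-operator propagation of the two-state
#' wavepacket: half potential step, spectral kinetic step, half potential step.
#' When a field table is supplied, the dipole--field coupling `-mu(R) E_z(t)`
#' is added to the diabatic potential inside each potential half-step, with the
#' field evaluated at the midpoint of that half-step (the molecular axis is z).
#' The grid has no absorbing boundary; the density at the grid edges is
#' monitored and a warning is issued when it exceeds `edge_tol`.
#'
#' @param wf initial [grid_wavefunction()].
#' @param model a [diabatic_model()].
#' @param field a [laser_pulse()] (evaluated exactly at the half-step
#'   midpoints), a `field_table` (spline-interpolated at the midpoints), or
#'   `NULL` for field-free propagation.
#' @param dt_fs time step, fs.
#' @param t_end_fs final time, fs (absolute; propagation starts at `wf$time_fs`).
#' @param stride store observables every `stride` steps.
#' @param store_wavefunctions if `TRUE`, keep a copy of the wavefunction at
#'   every stored step (memory permitting).
#' @param edge_tol edge-density warning threshold.
#' @return Object of class `qd_trajectory`: list with `observables` (tibble:
#'   `time_fs`, `norm`, `energy`, pop/mean/sd for the upper adiabatic state S1
#'   and the full density), `final` (final wavefunction), and optionally
#'   `wavefunctions`.
#' @export
qd_propagate <- function(wf, model, field = NULL, dt_fs, t_end_fs,
                         stride = 1L, store_wavefunctions = FALSE,
                         edge_tol = 1e-6) {
  stopifnot(dt_fs > 0)
  n <- length(wf$R)
  dR <- wf$dR
  dt <- fs_to_au(dt_fs)
  v <- model$pot(wf$R)
  mu <- model$dip(wf$R)
  k <- fft_wavenumbers(n, dR)
  eT <- exp(-1i * k^2 / (2 * model$mass) * dt)
  nsteps <- max(0L, as.integer(round((t_end_fs - wf$time_fs) / dt_fs)))
  fz <- if (is.null(field)) {
    NULL
  } else if (inherits(field, "laser_pulse")) {
    function(t_fs) field_at(field, t_fs)[3]
  } else {
    # cubic spline: the carrier oscillates on the scale of the table step
    sf <- stats::splinefun(field$time_fs, field$Ez, method = "natural")
    lo <- min(field$time_fs); hi <- max(field$time_fs)
    function(t_fs) if (t_fs < lo || t_fs > hi) 0 else sf(t_fs)
  }
  pv0 <- sym2_exp(v$v11, v$v12, v$v22, -1i * dt / 2)
  ad <- adiabatize_grid(model, wf$R)
  psi <- wf$psi
  times <- wf$time_fs + dt_fs * seq(0L, nsteps)
  stored <- seq(0L, nsteps) %% stride == 0L
  obs <- vector("list", sum(stored))
  wfs <- if (store_wavefunctions) vector("list", sum(stored)) else NULL
  js <- 0L
  edge_warned <- FALSE
  take_obs <- function(psi, t_fs) {
    o <- wp_observables(psi, wf$R, dR, ad)
    o$time_fs <- t_fs
    wfx <- grid_wavefunction(wf$R, psi, t_fs)
    o$energy <- wf_energy(wfx, model)
    o
  }
  for (i in seq(0L, nsteps)) {
    if (stored[i + 1L]) {
      js <- js + 1L
      obs[[js]] <- take_obs(psi, times[i + 1L])
      if (store_wavefunctions)
        wfs[[js]] <- grid_wavefunction(wf$R, psi, times[i + 1L])
      edge <- max(abs(psi[1, ])^2 + 0, abs(psi[n, ])^2) * dR
      if (!edge_warned && edge > edge_tol) {
        warning(sprintf("wavepacket density at grid edge exceeds %g at t = %g fs (possible boundary reflection)",
                        edge_tol, times[i + 1L]))
        edge_warned <- TRUE
      }
    }
    if (i == nsteps) break
    t0 <- fs_to_au(times[i + 1L])
    if (is.null(fz)) {
      psi <- apply_sym2(pv0, psi)
      psi <- cbind(stats::fft(eT * stats::fft(psi[, 1]), inverse = TRUE) / n,
                   stats::fft(eT * stats::fft(psi[, 2]), inverse = TRUE) / n)
      psi <- apply_sym2(pv0, psi)
    } else {
      e1 <- fz(au_to_fs(t0 + dt / 4))
      e2 <- fz(au_to_fs(t0 + 3 * dt / 4))
      p1 <- sym2_exp(v$v11 - mu$m11 * e1, v$v12 - mu$m12 * e1,
                     v$v22 - mu$m22 * e1, -1i * dt / 2)
      psi <- apply_sym2(p1, psi)
      psi <- cbind(stats::fft(eT * stats::fft(psi[, 1]), inverse = TRUE) / n,
                   stats::fft(eT * stats::fft(psi[, 2]), inverse = TRUE) / n)
      p2 <- sym2_exp(v$v11 - mu$m11 * e2, v$v12 - mu$m12 * e2,
                     v$v22 - mu$m22 * e2, -1i * dt / 2)
      psi <- apply_sym2(p2, psi)
    }
  }
  out <- list(observables = tibble::as_tibble(do.call(rbind, lapply(obs, as.data.frame))),
              final = grid_wavefunction(wf$R, psi, times[nsteps + 1L]),
              wavefunctions = wfs,
              model_label = model$label)
  class(out) <- "qd_trajectory"
  out
}

adiabatize_grid <- function(model, R) {
  v <- model$pot(R)
  eig2(v$v11, v$v12, v$v22)
}

# observables of one wavepacket snapshot: total density and upper-adiabat (S1)
# projection
wp_observables <- function(psi, R, dR, ad) {
  rho_tot <- abs(psi[, 1])^2 + abs(psi[, 2])^2
  # adiabatic amplitudes: psi_ad[, a] = sum_i U[i, a] psi[, i]
  psi_s1 <- ad$u2x * psi[, 1] + ad$u2y * psi[, 2]
  rho_s1 <- abs(psi_s1)^2
  m <- function(rho) {
    nrm <- sum(rho) * dR
    if (nrm < 1e-12) return(c(nrm, NA_real_, NA_real_))
    mean_r <- sum(R * rho) * dR / nrm
    var_r <- max(0, sum(R^2 * rho) * dR / nrm - mean_r^2)
    c(nrm, mean_r, sqrt(var_r))
  }
  a <- m(rho_tot); b <- m(rho_s1)
  list(norm = a[1], mean_R = a[2], sd_R = a[3],
       pop_S1 = b[1], mean_R_S1 = b[2], sd_R_S1 = b[3])
}

#' Ensemble observables of a quantum-dynamics trajectory
#'
#' Recomputes position mean and standard deviation from stored wavefunctions,
#' projected on a selected adiabatic state (or the full density). Requires
#' `store_wavefunctions = TRUE` in [qd_propagate()].
#'
#' @param traj a `qd_trajectory`.
#' @param model the [diabatic_model()] used for the propagation.
#' @param state `"S1"` (upper adiabat), `"S0"` (lower adiabat) or `"total"`.
#' @return tibble with columns `time_fs`, `pop`, `mean_R`, `sd_R`; rows where
#'   the projected norm vanishes carry `NA` with `defined = FALSE`.
#' @export
qd_observables <- function(traj, model, state = c("S1", "S0", "total")) {
  state <- match.arg(state)
  if (is.null(traj$wavefunctions))
    stop("trajectory was run without store_wavefunctions = TRUE", call. = FALSE)
  wfs <- traj$wavefunctions
  ad <- adiabatize_grid(model, wfs[[1]]$R)
  rows <- lapply(wfs, function(w) {
    psi <- w$psi
    rho <- switch(state,
      total = abs(psi[, 1])^2 + abs(psi[, 2])^2,
      S1 = abs(ad$u2x * psi[, 1] + ad$u2y * psi[, 2])^2,
      S0 = abs(ad$u1x * psi[, 1] + ad$u1y * psi[, 2])^2)
    nrm <- sum(rho) * w$dR
    if (nrm < 1e-12)
      return(data.frame(time_fs = w$time_fs, pop = nrm, mean_R = NA_real_,
                        sd_R = NA_real_, defined = FALSE))
    mean_r <- sum(w$R * rho) * w$dR / nrm
    sd_r <- sqrt(max(0, sum(w$R^2 * rho) * w$dR / nrm - mean_r^2))
    data.frame(time_fs = w$time_fs, pop = nrm, mean_R = mean_r, sd_R = sd_r,
               defined = TRUE)
  })
  tibble::as_tibble(do.call(rbind, rows))
}
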