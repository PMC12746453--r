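#' Electron-only dynamics: frozen-nuclei electronic TDSE under a laser
#'
#' Propagates the electronic coefficients of one geometry under
#' `H(t) = diag(E) + coupling - mu . E(t)` (electric-dipole light--matter
#' coupling over the per-geometry electronic data), using the exponential of
#' the Hamiltonian evaluated at each step midpoint. Nuclei are frozen: the
#' electronic data are reused unchanged at every step and the time-derivative
#' coupling is zero. Every `stride`-th step is stored.
#'
#' @param snap an [snapshot()] (or any `electronic_snapshot`).
#' @param field a `field_table`.
#' @param beta initial state index (coefficients start as the delta on beta).
#' @param stride store every `stride`-th step.
#' @param polarization optional unit 3-vector: molecular orientation factor
#'   `d_k` multiplying the field direction. Default uses the field as-is.
#' @param include_static_dipoles,include_excited_tdm flags mirroring the
#'   simplifications available for response-method data: when `FALSE`, static
#'   (diagonal) dipole elements resp. excited--excited transition dipoles are
#'   zeroed in the coupling.
#' @return Object of class `population_trace`: list with `geometry_id`,
#'   `times_fs` (stored times), `coeff` (stored complex coefficients, n_t x
#'   n_states), `pops` (populations), `beta`, `polarization_used`.
#' @export
eod_propagate <- function(snap, field, beta = 1L, stride = 1L,
                          polarization = NULL,
                          include_static_dipoles = FALSE,
                          include_excited_tdm = TRUE) {
  stopifnot(inherits(snap, "electronic_snapshot"))
  ns <- length(snap$energies)
  dt <- fs_to_au(field_table_dt_fs(field))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  H0 <- diag(snap$energies, ns)
  if (!is.null(snap$coupling)) {
    if (max(abs(snap$coupling - Conj(t(snap$coupling)))) > 1e-12)
      stop("coupling matrix must be Hermitian", call. = FALSE)
    H0 <- H0 + snap$coupling
  }
  tdm <- snap$tdm
  if (max(abs(tdm - aperm(tdm, c(1, 3, 2)))) > 1e-12)
    stop("transition-dipole matrix must be symmetric", call. = FALSE)
  if (!include_static_dipoles) for (a in 1:ns) tdm[, a, a] <- 0
  if (!include_excited_tdm && ns > 2)
    for (a in 2:ns) for (b in 2:ns) if (a != b) tdm[, a, b] <- 0
  E <- cbind(field$Ex, field$Ey, field$Ez)
  if (!is.null(polarization)) {
    # random-orientation factor: project the field on the molecular frame axis
    # sampled for this geometry
    scale <- as.numeric(E %*% polarization)
    Edir <- c(0, 0, 1)
    E <- outer(scale, Edir)
  }
  nsteps <- nrow(field) - 1L
  c_t <- rep(0 + 0i, ns); c_t[beta] <- 1
  stored <- which(seq(0L, nsteps) %% stride == 0L)
  coeff <- matrix(0i, length(stored), ns)
  js <- 1L
  coeff[1L, ] <- c_t
  # field at step midpoints (midpoint rule for H(t)); the carrier oscillates
  # on the step scale, so midpoints are spline-interpolated, not averaged
  Emid_all <- field_midpoints(field$time_fs, E)
  for (s in seq_len(nsteps)) {
    Emid <- Emid_all[s, ]
    H <- H0 - (tdm[1, , ] * Emid[1] + tdm[2, , ] * Emid[2] + tdm[3, , ] * Emid[3])
    c_t <- expm_herm(H, dt) %*% c_t
    if (s %% stride == 0L) {
      js <- js + 1L
      coeff[js, ] <- c_t
    }
  }
  structure(
    list(geometry_id = snap$geometry_id,
         times_fs = field$time_fs[stored],
         coeff = coeff,
         pops = abs(coeff)^2,
         beta = beta,
         polarization_used = if (is.null(polarization)) NULL else polarization),
    class = "population_trace")
}

# spline interpolation of sampled field columns at the step midpoints
field_midpoints <- function(time_fs, E) {
  tm <- (time_fs[-1] + time_fs[-length(time_fs)]) / 2
  if (is.null(dim(E))) E <- matrix(E, ncol = 1)
  out <- matrix(0, length(tm), ncol(E))
  for (j in seq_len(ncol(E)))
    out[, j] <- if (all(E[, j] == 0)) 0 else
      stats::spline(time_fs, E[, j], xout = tm)$y
  out
}

# exp(-i H dt) for a small Hermitian matrix
expm_herm <- function(H, dt) {
  e <- eigen(H, symmetric = TRUE)
  e$vectors %*% (exp(-1i * e$values * dt) * Conj(t(e$vectors)))
}

#' Random polarization directions
#'
#' i.i.d. directions uniform on the unit sphere, used to emulate randomly
#' oriented molecules in the laboratory frame.
#'
#' @param n number of directions.
#' @param seed integer seed.
#' @return n x 3 matrix of unit vectors.
#' @export
random_polarizations <- function(n, seed) {
  stopifnot(n > 0)
  rng <- local_rng(seed)
  m <- matrix(rng$norm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Electron-only dynamics for a phase-space ensemble
#'
#' Runs [eod_propagate()] for every sampled geometry with the same pulse. For
#' the bundled two-state models the propagation is carried out in a vectorized
#' closed form across all geometries simultaneously (identical mathematics:
#' per-step exponential of the 2x2 Hermitian Hamiltonian at the field
#' midpoint), which makes 10,000 geometries a matter of seconds. Populations
#' are stored every `stride`-th step, so stored times are multiples of
#' `stride * dt` of the field table.
#'
#' @param samples tibble from [wigner_sample()] (columns `geometry_id`, `R`).
#' @param model a [diabatic_model()].
#' @param field a `field_table` (e.g. from [sample_pulse()]; its grid must
#'   contain the pulse).
#' @param beta initial electronic state (1 = ground).
#' @param stride storage stride.
#' @param polarizations `NULL` (use the field as-is; the study setting with
#'   polarization parallel to the molecular axis) or an n x 3 matrix of
#'   per-geometry molecular orientations, e.g. from [random_polarizations()].
#' @return Object of class `population_ensemble`: list with `times_fs`,
#'   `pops` array (n_geometries x n_times x 2), `beta`, `geometry_id`, `R`,
#'   `energy_gap` (hartree).
#' @export
eod_ensemble <- function(samples, model, field, beta = 1L, stride = 8L,
                         polarizations = NULL) {
  ad <- adiabatize_n(model, samples$R)
  de <- ad$energies[, 2] - ad$energies[, 1]
  mu01 <- ad$tdm_adiabatic[1, 2, ]
  # effective scalar coupling: TDM along the molecular axis (z); for random
  # orientations the projection of the orientation on the field direction
  # rescales the coupling per geometry
  dt <- fs_to_au(field_table_dt_fs(field))
  ez <- field$Ez
  if (!is.null(polarizations)) {
    E <- cbind(field$Ex, field$Ey, field$Ez)
    # per-geometry scalar field amplitude: |E(t)| signed by the dominant axis
    # times the orientation projection is equivalent to projecting the fixed-
    # direction field onto each molecular axis
    edir <- E[which.max(rowSums(E^2)), ]
    edir <- edir / sqrt(sum(edir^2))
    proj <- as.numeric(polarizations %*% edir)
  } else {
    proj <- rep(1, nrow(samples))
  }
  scal <- sqrt(field$Ex^2 + field$Ey^2 + field$Ez^2) * sign_of_dominant(field)
  nk <- nrow(samples)
  nsteps <- nrow(field) - 1L
  stopifnot(beta == 1L)
  c1 <- rep(1 + 0i, nk); c2 <- rep(0i, nk)
  stored <- which(seq(0L, nsteps) %% stride == 0L)
  pops2 <- matrix(0, nk, length(stored))
  js <- 1L
  half_de <- de / 2
  emid_all <- drop(field_midpoints(field$time_fs, scal))
  for (s in seq_len(nsteps)) {
    emid <- emid_all[s]
    v <- -(mu01 * proj) * emid
    # 2x2 Hermitian exponential, vectorized over geometries:
    # H = [[0, v], [v, de]]; exp(-i H dt)
    b <- sqrt(half_de^2 + v^2)
    ph <- exp(-1i * half_de * dt)
    cb <- cos(b * dt)
    sb <- numeric(nk) + dt
    nzb <- b > 0
    sb[nzb] <- sin(b[nzb] * dt) / b[nzb]
    n1 <- ph * ((cb + 1i * sb * half_de) * c1 - 1i * sb * v * c2)
    n2 <- ph * (-1i * sb * v * c1 + (cb - 1i * sb * half_de) * c2)
    c1 <- n1; c2 <- n2
    if (s %% stride == 0L) {
      js <- js + 1L
      pops2[, js] <- Re(abs(c2)^2)
    }
  }
  pops <- array(0, c(nk, length(stored), 2L))
  pops[, , 2L] <- pops2
  pops[, , 1L] <- 1 - pops2
  structure(
    list(times_fs = field$time_fs[stored],
         pops = pops,
         beta = beta,
         geometry_id = samples$geometry_id,
         R = samples$R,
         energy_gap = de,
         polarizations = polarizations),
    class = "population_ensemble")
}

#' Convert a list of population traces into a population ensemble
#'
#' @param traces list of `population_trace` objects sharing the same stored
#'   time grid and initial state.
#' @return A `population_ensemble`.
#' @export
as_population_ensemble <- function(traces) {
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]$times_fs
  ns <- ncol(traces[[1]]$pops)
  pops <- array(0, c(length(traces), length(t0), ns))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    stopifnot(length(tr$times_fs) == length(t0), tr$beta == traces[[1]]$beta)
    pops[i, , ] <- tr$pops
  }
  structure(
    list(times_fs = t0, pops = pops, beta = traces[[1]]$beta,
         geometry_id = vapply(traces, function(x)
           as.integer(x$geometry_id %||% NA_integer_), integer(1)),
         R = NULL, energy_gap = NULL),
    class = "population_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
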