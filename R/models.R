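#' Analytic two-state diabatic models
#'
#' A `diabatic_model` bundles a one-dimensional two-state diabatic potential
#' matrix V(R), the diabatic electric-dipole matrix mu(R) projected on the
#' molecular axis, the nuclear reduced mass, and a validity domain. All
#' quantities are in atomic units (hartree, bohr). The diabatic components are
#' supplied as vectorized functions of the internuclear distance R; symmetry of
#' V and mu is guaranteed by construction (only the upper triangle is stored).
#'
#' @param pot function(R) returning `list(v11, v12, v22)` in hartree,
#'   vectorized over R (bohr).
#' @param dip function(R) returning `list(m11, m12, m22)` in atomic units
#'   (projection of the dipole matrix on the molecular axis), vectorized.
#' @param mass nuclear reduced mass in electron masses.
#' @param domain length-2 numeric, validity range in bohr.
#' @param label character label.
#' @param dpot optional function(R) returning the derivatives
#'   `list(v11, v12, v22)` (hartree/bohr). When absent, a central finite
#'   difference is used where gradients are required.
#' @param params optional list of raw model parameters (kept for provenance).
#' @return An object of class `diabatic_model`.
#' @seealso [nai_model()], [harmonic_fixture()], [adiabatize()], [snapshot()]
#' @export
diabatic_model <- function(pot, dip, mass, domain, label = "model",
                           dpot = NULL, params = list()) {
  stopifnot(is.function(pot), is.function(dip), is.numeric(mass), mass > 0,
            length(domain) == 2, domain[1] < domain[2])
  structure(
    list(pot = pot, dip = dip, dpot = dpot, mass = mass,
         domain = as.numeric(domain), label = label, params = params),
    class = "diabatic_model")
}

#' @export
print.diabatic_model <- function(x, ...) {
  cat("<diabatic_model>", x$label, "\n",
      " reduced mass:", format(x$mass), "a.u.\n",
      " domain: [", x$domain[1], ",", x$domain[2], "] bohr\n")
  invisible(x)
}

check_domain <- function(model, R) {
  if (any(R < model$domain[1] | R > model$domain[2]))
    stop("R outside model validity range [", model$domain[1], ", ",
         model$domain[2], "] bohr", call. = FALSE)
  invisible(R)
}

#' Evaluate the diabatic potential or dipole matrix
#'
#' @param model a [diabatic_model()].
#' @param R internuclear distance(s), bohr.
#' @return For scalar `R` a symmetric 2x2 matrix (hartree resp. au); for vector
#'   `R` a 2 x 2 x length(R) array.
#' @export
potential_matrix <- function(model, R) {
  check_domain(model, R)
  v <- model$pot(R)
  build_sym(v$v11, v$v12, v$v22)
}

#' @rdname potential_matrix
#' @export
dipole_matrix <- function(model, R) {
  check_domain(model, R)
  m <- model$dip(R)
  build_sym(m$m11, m$m12, m$m22)
}

build_sym <- function(a11, a12, a22) {
  n <- length(a11)
  if (n == 1L) return(matrix(c(a11, a12, a12, a22), 2, 2))
  out <- array(0, c(2, 2, n))
  out[1, 1, ] <- a11; out[2, 2, ] <- a22
  out[1, 2, ] <- a12; out[2, 1, ] <- a12
  out
}

# Closed-form eigendecomposition of the 2x2 symmetric diabatic matrix,
# vectorized over R. Columns of U sorted by ascending eigenvalue; sign fixed so
# the largest-magnitude component of each eigenvector is positive, ties broken
# toward the first diabat.
eig2 <- function(v11, v12, v22) {
  a <- (v11 + v22) / 2
  d <- (v11 - v22) / 2
  b <- sqrt(d^2 + v12^2)
  e1 <- a - b
  e2 <- a + b
  # eigenvector of e1: (-v12, d + b) up to sign/norm; degenerate v12 == 0
  u1x <- -v12
  u1y <- d + b
  flat <- abs(u1x) < .Machine$double.xmin & abs(u1y) < .Machine$double.xmin
  # v12 == 0: lower state is the diabat with the smaller diagonal
  u1x[flat] <- ifelse(v11[flat] <= v22[flat], 1, 0)
  u1y[flat] <- ifelse(v11[flat] <= v22[flat], 0, 1)
  nrm <- sqrt(u1x^2 + u1y^2)
  u1x <- u1x / nrm; u1y <- u1y / nrm
  # orthogonal complement
  u2x <- -u1y; u2y <- u1x
  # sign convention per column
  s1 <- sign_fix(u1x, u1y); u1x <- u1x * s1; u1y <- u1y * s1
  s2 <- sign_fix(u2x, u2y); u2x <- u2x * s2; u2y <- u2y * s2
  list(e1 = e1, e2 = e2, u1x = u1x, u1y = u1y, u2x = u2x, u2y = u2y)
}

sign_fix <- function(x, y) {
  s <- ifelse(abs(x) > abs(y), sign(x),
       ifelse(abs(y) > abs(x), sign(y), sign(x)))
  ifelse(s == 0, 1, s)
}

#' Adiabatic transform of a diabatic model at a geometry
#'
#' Diagonalizes the diabatic potential matrix at internuclear distance `R` and
#' rotates the dipole matrix into the adiabatic basis. Eigenvalues are sorted
#' ascending; the eigenvector sign convention is "largest-magnitude component
#' positive, ties broken toward the first diabat", which makes overlaps between
#' transforms at neighbouring geometries reproducible.
#'
#' @inheritParams potential_matrix
#' @return For scalar `R`: `list(energies, U, tdm_adiabatic)` with `energies`
#'   ascending (hartree), `U` the 2x2 orthogonal transform satisfying
#'   `t(U) %*% V %*% U == diag(energies)`, and `tdm_adiabatic = t(U) mu U`.
#'   For vector `R`: `energies` is an n x 2 matrix and `U`, `tdm_adiabatic` are
#'   2 x 2 x n arrays.
#' @export
#' @examples
#' m <- harmonic_fixture(omega = 2e-3, gap = 0.1, tdm = 0.2)
#' adiabatize(m, 0.1)$energies
adiabatize <- function(model, R) {
  check_domain(model, R)
  v <- model$pot(R)
  mu <- model$dip(R)
  e <- eig2(v$v11, v$v12, v$v22)
  # t(U) mu U with U = [u1 u2]
  t11 <- e$u1x * (mu$m11 * e$u1x + mu$m12 * e$u1y) +
         e$u1y * (mu$m12 * e$u1x + mu$m22 * e$u1y)
  t22 <- e$u2x * (mu$m11 * e$u2x + mu$m12 * e$u2y) +
         e$u2y * (mu$m12 * e$u2x + mu$m22 * e$u2y)
  t12 <- e$u1x * (mu$m11 * e$u2x + mu$m12 * e$u2y) +
         e$u1y * (mu$m12 * e$u2x + mu$m22 * e$u2y)
  n <- length(R)
  if (n == 1L) {
    list(energies = c(e$e1, e$e2),
         U = matrix(c(e$u1x, e$u1y, e$u2x, e$u2y), 2, 2),
         tdm_adiabatic = matrix(c(t11, t12, t12, t22), 2, 2))
  } else {
    U <- array(0, c(2, 2, n))
    U[1, 1, ] <- e$u1x; U[2, 1, ] <- e$u1y
    U[1, 2, ] <- e$u2x; U[2, 2, ] <- e$u2y
    list(energies = cbind(e$e1, e$e2, deparse.level = 0),
         U = U,
         tdm_adiabatic = build_sym(t11, t12, t22))
  }
}

# adiabatize that always returns the array/matrix (vector-R) layout
adiabatize_n <- function(model, R) {
  ad <- adiabatize(model, R)
  if (length(R) == 1L) {
    ad$energies <- matrix(ad$energies, 1)
    ad$U <- array(ad$U, c(2, 2, 1))
    ad$tdm_adiabatic <- array(ad$tdm_adiabatic, c(2, 2, 1))
  }
  ad
}

#' Per-geometry electronic snapshot
#'
#' Runs the analytic "single-point calculation" at a geometry: adiabatic
#' energies and the transition-dipole vectors in the adiabatic basis. The
#' molecular axis is taken as the laboratory z axis, so all dipole vectors
#' point along `c(0, 0, 1)`.
#'
#' @inheritParams potential_matrix
#' @param geometry_id integer index of the geometry (bookkeeping).
#' @return An object of class `electronic_snapshot`: list with `energies`
#'   (ascending, hartree), `tdm` (3 x 2 x 2 array of dipole vectors, au),
#'   `coupling` (2x2 matrix or NULL), `geometry_id`, `R`.
#' @export
snapshot <- function(model, R, geometry_id = NA_integer_) {
  stopifnot(length(R) == 1L)
  ad <- adiabatize(model, R)
  tdm <- array(0, c(3, 2, 2))
  tdm[3, , ] <- ad$tdm_adiabatic
  structure(
    list(energies = ad$energies, tdm = tdm, coupling = NULL,
         geometry_id = geometry_id, R = R),
    class = "electronic_snapshot")
}

#' Oscillator strengths of a snapshot
#'
#' f_osc = (2/3) * dE * |mu_0a|^2 in atomic units, for transitions from the
#' lowest adiabatic state.
#'
#' @param snap an [snapshot()] result.
#' @return Numeric vector, one entry per excited state.
#' @export
oscillator_strengths <- function(snap) {
  stopifnot(inherits(snap, "electronic_snapshot"))
  n <- length(snap$energies)
  de <- snap$energies[-1] - snap$energies[1]
  mu2 <- vapply(seq_len(n - 1L) + 1L,
                function(a) sum(snap$tdm[, 1, a]^2), numeric(1))
  (2 / 3) * de * mu2
}

#' Bundled NaI two-state diabatic model
#'
#' Faist--Levine-type model: a Rittner ionic diabat (Born--Mayer repulsion,
#' Coulomb attraction, induction and dispersion terms, offset by the difference
#' of the Na ionization potential and the I electron affinity), an exponential
#' covalent diabat, and a Gaussian diabatic coupling localized at the curve
#' crossing near 13 bohr. The diabatic transition dipole moment is constant.
#' Parameters are data-driven: they are read from a plain-text YAML file with
#' explicit units per entry, defaulting to the parameter set bundled under
#' `inst/extdata/nai_model.yaml` (values from the classic quantum-dynamics
#' literature on NaI photodissociation).
#'
#' @param file path to a YAML parameter file; `NULL` uses the bundled default.
#' @return A [diabatic_model()].
#' @export
#' @examples
#' m <- nai_model()
#' hartree_to_ev(diff(adiabatize(m, 5.06)$energies))  # vertical gap, eV
nai_model <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "nai_model.yaml", package = "eoexcite")
  p <- read_model_parameters(file)
  ion <- p$ionic; cov <- p$covalent; cpl <- p$coupling
  # component functions take R in bohr and return hartree; the raw parameters
  # are in eV/angstrom as tabulated in the literature
  v11 <- function(Ra)
    ((ion$A2 + (ion$B2 / Ra)^8) * exp(-Ra / ion$rho) - ion$e2 / Ra -
       ion$e2 * (ion$lambda_plus + ion$lambda_minus) / (2 * Ra^4) -
       ion$C2 / Ra^6 - 2 * ion$e2 * ion$lambda_plus * ion$lambda_minus / Ra^7 +
       ion$delta_E0) / .EV
  v22 <- function(Ra) cov$A1 * exp(-cov$beta1 * (Ra - cov$R0)) / .EV
  v12 <- function(Ra) cpl$A12 * exp(-cpl$beta12 * (Ra - cpl$Rx)^2) / .EV
  dv11 <- function(Ra)
    ((-8 * ion$B2^8 / Ra^9) * exp(-Ra / ion$rho) -
       (ion$A2 + (ion$B2 / Ra)^8) * exp(-Ra / ion$rho) / ion$rho +
       ion$e2 / Ra^2 +
       2 * ion$e2 * (ion$lambda_plus + ion$lambda_minus) / Ra^5 +
       6 * ion$C2 / Ra^7 +
       14 * ion$e2 * ion$lambda_plus * ion$lambda_minus / Ra^8) / .EV
  dv22 <- function(Ra) -cov$beta1 * cov$A1 * exp(-cov$beta1 * (Ra - cov$R0)) / .EV
  dv12 <- function(Ra)
    -2 * cpl$beta12 * (Ra - cpl$Rx) * cpl$A12 *
      exp(-cpl$beta12 * (Ra - cpl$Rx)^2) / .EV
  mu12 <- p$transition_dipole$mu12
  diabatic_model(
    pot = function(R) {
      Ra <- R * .ANG
      list(v11 = v11(Ra), v12 = v12(Ra), v22 = v22(Ra))
    },
    dip = function(R) {
      n <- length(R)
      list(m11 = rep(0, n), m12 = rep(mu12, n), m22 = rep(0, n))
    },
    dpot = function(R) {
      Ra <- R * .ANG
      list(v11 = dv11(Ra) * .ANG, v12 = dv12(Ra) * .ANG, v22 = dv22(Ra) * .ANG)
    },
    mass = p$reduced_mass * .AMU,
    domain = p$domain,
    label = p$label,
    params = p)
}

#' Read / write model parameter files
#'
#' Plain-text YAML, one `{value:, unit:}` pair per entry. Units are fixed per
#' entry and checked on read; the reader returns plain numeric values grouped
#' by section.
#'
#' @param file path to the YAML file.
#' @return `read_model_parameters`: nested list of numeric parameter values.
#' @export
read_model_parameters <- function(file) {
  raw <- yaml::read_yaml(file)
  strip <- function(x) {
    if (is.list(x) && !is.null(x$value)) return(x$value)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  out <- lapply(raw, strip)
  out$domain <- c(out$domain$min, out$domain$max)
  out
}

#' Harmonic two-state test fixture
#'
#' Two harmonic diabats sharing the force constant `mass * omega^2`: the lower
#' one centred at `r0`, the upper one displaced by `displacement` and offset by
#' `gap`, with a constant diabatic transition dipole `tdm` and zero diabatic
#' coupling. The ground vibrational state is known in closed form
#' (energy `omega/2` above the minimum, sigma_R = sqrt(1/(2 m omega))), which
#' makes the fixture the oracle for grid and sampling code.
#'
#' @param omega harmonic frequency, hartree (atomic angular frequency).
#' @param gap vertical energy offset of the upper diabat, hartree.
#' @param tdm constant diabatic transition dipole, au.
#' @param mass reduced mass, electron masses.
#' @param r0 minimum of the lower diabat, bohr.
#' @param displacement displacement of the upper minimum, bohr. When `NULL`
#'   and `seed` is given, drawn uniformly from `[0, 2 sigma_R]` under the seed;
#'   when both are `NULL` the surfaces are undisplaced.
#' @param seed integer; fixes the randomized displacement. Same seed, same
#'   model.
#' @return A [diabatic_model()].
#' @export
harmonic_fixture <- function(omega, gap, tdm, mass = 2000, r0 = 0,
                             displacement = NULL, seed = NULL) {
  if (omega <= 0 || gap <= 0 || tdm <= 0 || mass <= 0)
    stop("omega, gap, tdm and mass must be positive", call. = FALSE)
  if (is.null(displacement)) {
    if (is.null(seed)) {
      displacement <- 0
    } else {
      sigma <- sqrt(1 / (2 * mass * omega))
      displacement <- local({
        rng <- local_rng(seed)
        rng$unif(1) * 2 * sigma
      })
    }
  }
  k <- mass * omega^2
  diabatic_model(
    pot = function(R) list(
      v11 = 0.5 * k * (R - r0)^2,
      v12 = rep(0, length(R)),
      v22 = 0.5 * k * (R - r0 - displacement)^2 + gap),
    dip = function(R) list(
      m11 = rep(0, length(R)),
      m12 = rep(tdm, length(R)),
      m22 = rep(0, length(R))),
    dpot = function(R) list(
      v11 = k * (R - r0),
      v12 = rep(0, length(R)),
      v22 = k * (R - r0 - displacement)),
    mass = mass,
    domain = r0 + c(-1, 1) * 60 * sqrt(1 / (2 * mass * omega)),
    label = "harmonic fixture",
    params = list(omega = omega, gap = gap, tdm = tdm, mass = mass,
                  r0 = r0, displacement = displacement))
}

# Seeded RNG stream that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  withstate <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(unif = withstate(stats::runif),
       norm = withstate(stats::rnorm),
       sample_int = withstate(function(n, size, replace = FALSE, prob = NULL)
         sample.int(n, size, replace = replace, prob = prob)))
}
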