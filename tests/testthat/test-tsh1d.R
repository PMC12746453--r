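test_that("uncoupled surfaces give hop-free bound motion with conserved energy", {
  m <- harmonic_fixture(omega = 2e-3, gap = 0.15, tdm = 0.1, mass = 2000,
                        displacement = 0.4)
  # excited start at the lower-surface minimum: oscillates on the upper diabat
  tr <- tsh_trajectory(m, R0 = 0, v0 = 0, state0 = 2, t_end_fs = 400,
                       dt_fs = 0.5, seed = 9)
  expect_identical(nrow(tr$hop_events), 0L)
  expect_equal(tr$pops[, 2], rep(1, nrow(tr$pops)), tolerance = 1e-10)
  expect_equal(range(tr$R), c(0, 0.8), tolerance = 1e-3)
  expect_lt(max(abs(tr$energy - tr$energy[1])), 1e-6)
  # determinism
  tr2 <- tsh_trajectory(m, R0 = 0, v0 = 0, state0 = 2, t_end_fs = 400,
                        dt_fs = 0.5, seed = 9)
  expect_identical(tr, tr2)
})

test_that("NaI total energy drifts less than 1e-5 hartree over 2000 fs", {
  nai <- nai_cached()
  tr <- tsh_trajectory(nai, R0 = 5.06, v0 = 0, state0 = 2, t_end_fs = 2000,
                       dt_fs = 0.5, seed = 2)
  hops <- tr$hop_events$time_fs
  # energy is conserved between hops; with this seed the trajectory stays
  # on the upper surface (no hops), so the drift bound applies throughout
  expect_identical(nrow(tr$hop_events), 0L)
  expect_lt(max(abs(tr$energy - tr$energy[1])), 1e-5)
  expect_lt(max(abs(rowSums(tr$pops) - 1)), 1e-8)
})

test_that("electronic coefficients match an independent ODE integration along the path", {
  nai <- nai_cached()
  tr <- tsh_trajectory(nai, R0 = 5.0, v0 = 0, state0 = 2, t_end_fs = 700,
                       dt_fs = 0.5, seed = 2, decoherence_C = NA)
  expect_identical(nrow(tr$hop_events), 0L)  # same surface, same path
  # reference: deSolve integration of i dc/dt = V(R(t)) c on the recorded path
  rfun <- stats::approxfun(fs_to_au(tr$times_fs), tr$R)
  deriv <- function(t, y, parms) {
    c1 <- complex(real = y[1], imaginary = y[2])
    c2 <- complex(real = y[3], imaginary = y[4])
    v <- nai$pot(rfun(t))
    d1 <- -1i * (v$v11 * c1 + v$v12 * c2)
    d2 <- -1i * (v$v12 * c1 + v$v22 * c2)
    list(c(Re(d1), Im(d1), Re(d2), Im(d2)))
  }
  e0 <- adiabatize(nai, tr$R[1])
  c_dia0 <- e0$U[, 2]  # start in the upper adiabatic state
  sol <- deSolve::ode(y = c(Re(c_dia0[1]), Im(c_dia0[1]),
                            Re(c_dia0[2]), Im(c_dia0[2])),
                      times = fs_to_au(tr$times_fs), func = deriv,
                      parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  # compare adiabatic populations at the end (after the crossing passage)
  nT <- nrow(sol)
  cd <- complex(real = sol[nT, 2], imaginary = sol[nT, 3])
  cd2 <- complex(real = sol[nT, 4], imaginary = sol[nT, 5])
  en <- adiabatize(nai, tr$R[nT])
  pops_ref <- abs(t(en$U) %*% c(cd, cd2))^2
  expect_lt(max(abs(tr$pops[nT, ] - as.vector(pops_ref))), 1e-6)
  # a crossing was actually passed and population transferred
  expect_gt(tr$pops[nT, 1], 1e-4)
})

test_that("frustrated upward hops are rejected without velocity change", {
  # linear (Landau-Zener) crossing traversed with total energy below the upper
  # adiabat everywhere: strong population mixing at the crossing, but every
  # upward hop lacks the kinetic energy and must be frustrated
  f <- 0.02; cc <- 0.002
  m <- diabatic_model(
    pot = function(R) list(v11 = f * R, v12 = rep(cc, length(R)), v22 = -f * R),
    dip = function(R) list(m11 = 0 * R, m12 = rep(0.1, length(R)), m22 = 0 * R),
    dpot = function(R) list(v11 = rep(f, length(R)), v12 = 0 * R,
                            v22 = rep(-f, length(R))),
    mass = 2000, domain = c(-60, 60))
  E1 <- function(R) -sqrt((f * R)^2 + cc^2)
  v0 <- sqrt(2 * (-0.001 - E1(-2)) / 2000)  # total energy -0.001 hartree
  found <- 0L
  for (seed in 14:19) {
    tr <- tsh_trajectory(m, R0 = -2, v0 = v0, state0 = 1, t_end_fs = 400,
                         dt_fs = 0.5, seed = seed, decoherence_C = NA)
    found <- found + tr$n_frustrated
    expect_identical(nrow(tr$hop_events), 0L)
    expect_true(all(tr$active == 1L))
    # kinetic energy stays below the adiabatic gap along the whole path
    expect_lt(max(0.5 * 2000 * tr$v^2 - 2 * sqrt((f * tr$R)^2 + cc^2)), 0)
  }
  expect_gt(found, 0L)
})

test_that("trajectories leaving the model domain terminate with a status", {
  m <- diabatic_model(
    pot = function(R) list(v11 = 0.05 * exp(-R), v12 = 0 * R,
                           v22 = 0.2 + 0 * R),
    dip = function(R) list(m11 = 0 * R, m12 = rep(0.1, length(R)), m22 = 0 * R),
    mass = 1000, domain = c(0.5, 15))
  tr <- tsh_trajectory(m, R0 = 2, v0 = 0, state0 = 1, t_end_fs = 3000,
                       dt_fs = 0.5, seed = 1)
  expect_identical(tr$status, "left_domain")
  expect_lt(length(tr$times_fs), 6001L)
})

test_that("time shifting averages as expected and defaults to the unshifted case", {
  m <- harmonic_fixture(omega = 2e-3, gap = 0.15, tdm = 0.1, mass = 2000,
                        displacement = 0.5)
  # two identical bound trajectories on the upper surface
  tr <- tsh_trajectory(m, R0 = 0, v0 = 0, state0 = 2, t_end_fs = 600,
                       dt_fs = 0.5, seed = 3)
  mk_swarm <- function(shifts) structure(
    list(trajectories = list(tr, tr), t_start_fs = shifts,
         geometry_id = 1:2, dt_fs = 0.5), class = "tsh_ensemble")
  obs0 <- shifted_observables(mk_swarm(c(0, 0)))
  obs0n <- shifted_observables(mk_swarm(c(-10, 10)), shift = FALSE)
  expect_equal(obs0$mean_R_S1, obs0n$mean_R_S1)
  expect_equal(obs0$mean_R_S1[obs0$n == 2], tr$R, tolerance = 1e-12)
  # +/-10 fs shifts damp the averaged oscillation amplitude
  obs_s <- shifted_observables(mk_swarm(c(-10, 10)))
  common <- obs_s$n == 2
  amp_single <- diff(range(tr$R))
  amp_avg <- diff(range(obs_s$mean_R_S1[common]))
  # closed form for sinusoids: averaging two copies shifted by 2d multiplies
  # the amplitude by |cos(omega d)|
  omega_vib <- 2e-3  # same curvature on both diabats
  damp <- abs(cos(omega_vib * fs_to_au(10)))
  expect_lt(amp_avg, amp_single)
  expect_equal(amp_avg / amp_single, damp, tolerance = 0.05)
  # incommensurate shifts are rejected
  expect_error(shifted_observables(mk_swarm(c(0.3, 0))), "commensurate")
})

test_that("the fraction of hopped trajectories tracks the mean electronic population", {
  # one crossing passage of the NaI avoided crossing, no decoherence
  nai <- nai_cached()
  n <- 60
  pops_end <- numeric(n)
  hopped <- logical(n)
  for (i in seq_len(n)) {
    tr <- tsh_trajectory(nai, R0 = 5.06, v0 = 0, state0 = 2, t_end_fs = 700,
                         dt_fs = 0.5, seed = 3000L + i, decoherence_C = NA)
    pops_end[i] <- tr$pops[nrow(tr$pops), 1]
    hopped[i] <- any(tr$active == 1L)
  }
  p_mean <- mean(pops_end)
  frac <- mean(hopped)
  expect_lt(abs(frac - p_mean), 4 * sqrt(p_mean * (1 - p_mean) / n) + 0.01)
})
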