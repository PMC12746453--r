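test_that("populations stay constant without field or coupling, and norm is conserved", {
  m <- fix_harmonic()
  sn <- snapshot(m, 0.1)
  tab <- field_table(seq(0, 10, by = 0.0625), Ex = 0 * seq(0, 10, by = 0.0625))
  tr <- eod_propagate(sn, tab, beta = 1L, stride = 4L)
  expect_lt(max(abs(tr$pops[, 1] - 1)), 1e-12)
  # with a field: norm conserved to 1e-10 at every stored step
  p <- laser_pulse(E0 = 1e-3, omega0_ev = hartree_to_ev(0.15),
                   fwhm_intensity_fs = 5)
  tabf <- sample_pulse(p, 0.0625, pad_multiple = 8)
  trf <- eod_propagate(sn, tabf, stride = 8L)
  expect_lt(max(abs(rowSums(trf$pops) - 1)), 1e-10)
  expect_true(all(diff(trf$times_fs) - 0.5 < 1e-12))
})

test_that("weak-field propagation matches the analytic two-level model to one percent", {
  m <- fix_harmonic(tdm = 0.2)     # gap 0.15 hartree
  sn <- snapshot(m, 0)
  gap_ev <- hartree_to_ev(0.15)
  for (det_ev in c(0, 0.12)) {
    p <- laser_pulse(E0 = 1e-5, omega0_ev = gap_ev + det_ev,
                     fwhm_intensity_fs = 10)
    tab <- sample_pulse(p, 0.015625, pad_multiple = 8)
    tr <- eod_propagate(sn, tab, stride = 8L)
    tl <- two_level_params(mu = 0.2, E0 = 1e-5, tau_fs = pulse_tau_fs(p),
                           detuning_ev = det_ev)
    p_num <- tr$pops[nrow(tr$pops), 2]
    p_an <- abs(tl_upper_coefficient(tl, max(tab$time_fs)))^2
    expect_equal(p_num, p_an, tolerance = 0.01)
  }
})

test_that("field polarization perpendicular to the transition dipole transfers nothing", {
  m <- fix_harmonic()
  sn <- snapshot(m, 0)  # TDM along z
  p <- laser_pulse(E0 = 1e-3, omega0_ev = hartree_to_ev(0.15),
                   fwhm_intensity_fs = 5, polarization = c(1, 0, 0))
  tab <- sample_pulse(p, 0.0625, pad_multiple = 8)
  tr <- eod_propagate(sn, tab, stride = 8L)
  expect_lt(max(tr$pops[, 2]), 1e-20)
})

test_that("random polarizations are uniform on the sphere and give the 1/3 orientation average", {
  d <- random_polarizations(1e5, seed = 12)
  expect_lt(max(abs(sqrt(rowSums(d^2)) - 1)), 1e-14)
  expect_lt(max(abs(colMeans(d))), 3 / sqrt(1e5))
  expect_identical(d, random_polarizations(1e5, seed = 12))
  # isotropic average of the weak-field transfer is 1/3 of the aligned value
  m <- fix_harmonic(tdm = 0.1)
  samp <- tibble::tibble(geometry_id = 1:800, R = rep(0, 800), v = 0, weight = 1)
  p <- laser_pulse(E0 = 1e-5, omega0_ev = hartree_to_ev(0.15),
                   fwhm_intensity_fs = 10)
  tab <- sample_pulse(p, 0.0625, pad_multiple = 8)
  aligned <- eod_ensemble(samp[1, ], m, tab)
  pol <- random_polarizations(800, seed = 5)
  rnd <- eod_ensemble(samp, m, tab, polarizations = pol)
  p_aligned <- aligned$pops[1, dim(aligned$pops)[2], 2]
  p_mean <- mean(rnd$pops[, dim(rnd$pops)[2], 2])
  # mean of cos^2 over the sphere is 1/3; MC spread of the mean ~ 2/(3 sqrt(5 n))
  expect_equal(p_mean / p_aligned, 1 / 3, tolerance = 4 * sqrt(4 / 45) / sqrt(800) * 3)
})

test_that("ensemble fast path reproduces per-trace propagation and perturbative scaling", {
  m <- fix_harmonic(tdm = 0.15)
  samp <- tibble::tibble(geometry_id = 1:4, R = c(-0.2, -0.05, 0.1, 0.3),
                         v = 0, weight = 1)
  p <- laser_pulse(E0 = 1e-4, omega0_ev = hartree_to_ev(0.15),
                   fwhm_intensity_fs = 8)
  tab <- sample_pulse(p, 0.0625, pad_multiple = 8)
  ens <- eod_ensemble(samp, m, tab, stride = 8L)
  for (i in 1:4) {
    tr <- eod_propagate(snapshot(m, samp$R[i]), tab, stride = 8L)
    expect_lt(max(abs(tr$pops[, 2] - ens$pops[i, , 2])), 1e-12)
    expect_equal(tr$times_fs, ens$times_fs)
  }
  # doubling E0 quadruples the transferred population in the weak field
  p2 <- laser_pulse(E0 = 2e-4, omega0_ev = hartree_to_ev(0.15),
                    fwhm_intensity_fs = 8)
  ens2 <- eod_ensemble(samp, m, sample_pulse(p2, 0.0625, pad_multiple = 8),
                       stride = 8L)
  nt <- dim(ens$pops)[2]
  expect_equal(ens2$pops[, nt, 2] / ens$pops[, nt, 2], rep(4, 4),
               tolerance = 1e-3)
})

test_that("study configuration stores start times as multiples of the TSH step", {
  # dt = 0.0625 fs, stride 8 -> stored times on a 0.5 fs lattice through tc
  p <- laser_pulse(E0 = 1e-3, omega0_ev = 3.68, fwhm_intensity_fs = 20)
  tab <- sample_pulse(p, 0.0625, pad_multiple = 8L)
  m <- fix_harmonic()
  samp <- tibble::tibble(geometry_id = 1:2, R = c(0, 0.05), v = 0, weight = 1)
  ens <- eod_ensemble(samp, m, tab, stride = 8L)
  rel <- (ens$times_fs - p$tc_fs) / 0.5
  expect_lt(max(abs(rel - round(rel))), 1e-9)
})

test_that("static dipoles are excluded by default and can be switched on", {
  m <- fix_harmonic()
  sn <- snapshot(m, 0)
  sn$tdm[3, 1, 1] <- 2.0   # a large static dipole on the ground state
  sn$tdm[3, 2, 2] <- -1.0
  p <- laser_pulse(E0 = 5e-3, omega0_ev = hartree_to_ev(0.15),
                   fwhm_intensity_fs = 5)
  tab <- sample_pulse(p, 0.03125, pad_multiple = 8)
  tr_off <- eod_propagate(sn, tab, stride = 8L)
  tr_on <- eod_propagate(sn, tab, stride = 8L, include_static_dipoles = TRUE)
  # the dynamic Stark term changes the dynamics when included
  expect_gt(max(abs(tr_on$pops[, 2] - tr_off$pops[, 2])), 1e-8)
  # excluding it reproduces the plain two-state coupling result
  sn0 <- snapshot(m, 0)
  tr_ref <- eod_propagate(sn0, tab, stride = 8L)
  expect_equal(tr_off$pops, tr_ref$pops, tolerance = 1e-14)
})
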