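test_that("leave probability follows the clamped population-ratio rule", {
  tr <- make_trace(cbind(c(1, 0.998, 0.002), c(0, 0.002, 0.998)))
  expect_equal(leave_probability(tr, 1), 0.002, tolerance = 1e-12)
  expect_equal(leave_probability(tr, 2), 1 - 0.002 / 0.998, tolerance = 1e-12)
  # constant population: zero
  trc <- make_trace(cbind(c(1, 1, 1), c(0, 0, 0)))
  expect_equal(leave_probability(trc, 1), 0)
  # growing initial-state population: clamped at zero
  trg <- make_trace(cbind(c(0.9, 0.95, 1), c(0.1, 0.05, 0)))
  expect_equal(leave_probability(trg, 1), 0)
  expect_equal(leave_probability(trg, 2), 0)
})

test_that("total leave probability telescopes for decay and blocks revivals", {
  # monotone decay to 0.995: P_tot = 0.005 regardless of the number of steps
  for (steps in c(2, 5, 40)) {
    pb <- seq(1, 0.995, length.out = steps + 1)
    tr <- make_trace(cbind(pb, 1 - pb))
    expect_equal(total_probability(tr), 0.005, tolerance = 1e-12)
  }
  expect_equal(total_probability(make_trace(cbind(c(1, 1, 1), c(0, 0, 0)))), 0)
  # decay then full revival: the min(1, ratio) keeps the transfer counted
  trr <- make_trace(cbind(c(1, 0.99, 1), c(0, 0.01, 0)))
  expect_equal(total_probability(trr), 0.01, tolerance = 1e-12)
})

test_that("renormalization satisfies the exact difference and bound identities", {
  traces <- random_traces(40, 60, seed = 21, scale = 2e-3)
  ens <- as_population_ensemble(traces)
  rens <- renormalize_traces(ens)
  # the trace achieving P_max self-normalizes: monotone version reaches 1
  mono <- lapply(1:10, function(k) {
    p2 <- c(0, cumsum(runif(49)))
    p2 <- 3e-3 * k / 10 * p2 / max(p2)
    make_trace(cbind(1 - p2, p2), id = k)
  })
  rmono <- renormalize_traces(as_population_ensemble(mono))
  kmax <- which.max(rmono$Ptot)
  ntm <- length(rmono$times_fs)
  expect_equal(rmono$rpops[kmax, ntm, 2], 1, tolerance = 1e-12)
  # per-step population differences scale exactly by 1/P_max (all states)
  nt <- dim(rens$pops)[2]
  for (a in 1:2) {
    d_raw <- rens$pops[, -1, a] - rens$pops[, -nt, a]
    d_ren <- rens$rpops[, -1, a] - rens$rpops[, -nt, a]
    expect_lt(max(abs(d_ren - d_raw / rens$Pmax)), 1e-12)
  }
  # induction inequality: 1 - P_max <= |c_beta(t)|^2 everywhere
  expect_true(all(rens$pops[, , 1] >= 1 - rens$Pmax - 1e-14))
  expect_true(all(rens$rpops >= -1e-14 & rens$rpops <= 1 + 1e-14))
  # no excitation anywhere: explicit error
  flat <- as_population_ensemble(list(make_trace(cbind(c(1, 1), c(0, 0)))))
  expect_error(renormalize_traces(flat), "no selectable")
})

test_that("GFSH probabilities split the leave probability over gaining states", {
  expect_equal(gfsh_probabilities(c(1, 0), c(0.9, 0.1), 1), c(0, 0.1),
               tolerance = 1e-14)
  expect_equal(gfsh_probabilities(c(0.5, 0.5), c(0.5, 0.5), 1), c(0, 0))
  p3 <- gfsh_probabilities(c(1, 0, 0), c(0.9, 0.075, 0.025), 1)
  expect_equal(p3, c(0, 0.075, 0.025), tolerance = 1e-14)
  # a state losing population gets zero even when the active state loses too
  p_neg <- gfsh_probabilities(c(0.8, 0.1, 0.1), c(0.7, 0.3, 0), 1)
  expect_equal(p_neg[3], 0)
  expect_gt(p_neg[2], 0)
})

test_that("renormalized GFSH reduces to plain GFSH at P_max = 1 and obeys the ratio identity", {
  # a trace transferring everything: P_tot = P_max = 1
  full <- make_trace(cbind(c(1, 0.5, 0), c(0, 0.5, 1)))
  rfull <- renormalize_traces(as_population_ensemble(list(full)))
  expect_equal(rfull$Pmax, 1)
  for (t in 1:2) {
    p14 <- renormalized_gfsh(rfull, 1, 1, t)
    p3 <- gfsh_probabilities(full$pops[t, ], full$pops[t + 1, ], 1)
    expect_equal(p14, p3, tolerance = 1e-14)
  }
  # random weak traces: Eq14/Eq3 ratio equals p_beta / (p_beta - (1 - P_max))
  traces <- random_traces(10, 40, seed = 4, scale = 0.05)
  rens <- renormalize_traces(as_population_ensemble(traces))
  for (k in c(1, 5, 10)) for (t in c(3, 17, 33)) {
    p3 <- gfsh_probabilities(rens$pops[k, t, ], rens$pops[k, t + 1, ], 1)
    p14 <- renormalized_gfsh(rens, k, 1, t)
    if (p3[2] > 0) {
      pb <- rens$pops[k, t, 1]
      expect_equal(p14[2] / p3[2], pb / (pb - (1 - rens$Pmax)),
                   tolerance = 1e-12)
    } else {
      expect_equal(p14[2], 0)
    }
  }
})

test_that("selection rejects hopless traces and is reproducible", {
  flat1 <- make_trace(cbind(c(1, 1, 1, 1), 0 * (1:4)))
  weak <- make_trace(cbind(c(1, 1 - 1e-3, 1 - 2e-3, 1 - 2e-3),
                           c(0, 1e-3, 2e-3, 2e-3)))
  rens <- renormalize_traces(as_population_ensemble(list(flat1, weak)))
  sel <- eoe_select(rens, seed = 3, tsh_dt_fs = 0.5)
  expect_false(sel$accepted[1])
  expect_identical(nrow(sel$hops[[1]]), 0L)
  sel2 <- eoe_select(rens, seed = 3, tsh_dt_fs = 0.5)
  expect_identical(sel, sel2)
  # incommensurate TSH step errors out
  expect_error(eoe_select(rens, seed = 1, tsh_dt_fs = 0.3), "commensurate")
})

test_that("acceptance frequency equals the total renormalized leave probability", {
  # monotone traces: no back-hops, so P(accept) = P_tot,k / P_max exactly
  set.seed(8)
  mono <- lapply(1:6, function(k) {
    p2 <- c(0, cumsum(runif(29)))
    p2 <- (1e-3 + 2e-3 * (k - 1) / 5) * p2 / max(p2)
    make_trace(cbind(1 - p2, p2), id = k)
  })
  rens <- renormalize_traces(as_population_ensemble(mono))
  nrep <- 400L
  acc <- matrix(FALSE, nrep, 6)
  for (i in seq_len(nrep))
    acc[i, ] <- eoe_select(rens, seed = 5000L + i)$accepted
  expected <- rens$Ptot / rens$Pmax
  freq <- colMeans(acc)
  sd_bin <- sqrt(expected * (1 - expected) / nrep)
  expect_true(all(abs(freq - expected) < 4 * pmax(sd_bin, 1e-3)))
})

test_that("off-resonance populate-then-depopulate traces are mostly rejected by a second hop", {
  # excited population rises mid-pulse and vanishes again
  p2 <- c(0, 0.4, 0.8, 0.4, 1e-9) * 1e-2
  offres <- make_trace(cbind(1 - p2, p2))
  # add a resonant trace so P_max reflects a strongly transferring partner
  res <- make_trace(cbind(1 - (0:4) * 2.5e-3, (0:4) * 2.5e-3), id = 2L)
  rens <- renormalize_traces(as_population_ensemble(list(offres, res)))
  n_acc <- 0L; n_two <- 0L; n_hopped <- 0L
  for (i in 1:300) {
    s <- eoe_select(rens, seed = 100L + i)
    if (s$n_hops[1] > 0) n_hopped <- n_hopped + 1L
    if (s$n_hops[1] >= 2) n_two <- n_two + 1L
    if (s$accepted[1]) n_acc <- n_acc + 1L
  }
  expect_gt(n_hopped, 100)          # the transient does cause first hops
  expect_gt(n_two / n_hopped, 0.8)  # almost all are undone in the decay phase
  expect_lt(n_acc / n_hopped, 0.2)  # so the off-resonance trace is rejected
})

test_that("three-state selection agrees with the two-state fast path on embedded problems", {
  # embed a two-state problem as states 1-2 of a three-state ensemble with a
  # silent third state; per-trajectory streams make the paths comparable
  traces2 <- random_traces(5, 25, seed = 31, scale = 2e-3)
  ens2 <- as_population_ensemble(traces2)
  pops3 <- array(0, c(5, 25, 3))
  pops3[, , 1:2] <- ens2$pops
  ens3 <- ens2
  ens3$pops <- pops3
  r2 <- renormalize_traces(ens2)
  r3 <- renormalize_traces(ens3)
  s2 <- eoe_select(r2, seed = 77)
  s3 <- eoe_select(r3, seed = 77)
  expect_identical(s2$accepted, s3$accepted)
  expect_identical(s2$t_start_fs, s3$t_start_fs)
  expect_identical(s2$n_hops, s3$n_hops)
})

test_that("vertical selection honors windows, modes and scale invariance", {
  nai <- nai_cached()
  samples <- nai_small_samples(2000, seed = 5)
  win <- c(3.65, 3.71)
  sel <- vertical_select(samples, nai, win, seed = 6)
  expect_true(all(sel$t_start_fs[sel$accepted] == 0))
  expect_true(all(sel$energy_ev[sel$accepted] >= win[1] &
                    sel$energy_ev[sel$accepted] <= win[2]))
  # single in-window geometry: probability one, always accepted
  one <- samples[which(sel$energy_ev >= win[1] & sel$energy_ev <= win[2])[1], ]
  sone <- vertical_select(one, nai, win, seed = 11)
  expect_equal(sone$prob, 1)
  expect_true(sone$accepted)
  # global TDM rescaling cancels in the normalization: identical selection
  f <- system.file("extdata", "nai_model.yaml", package = "eoexcite")
  p <- yaml::read_yaml(f)
  p$transition_dipole$mu12$value <- 0.9
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(p, tmp)
  sel_scaled <- vertical_select(samples, nai_model(tmp), win, seed = 6)
  unlink(tmp)
  expect_identical(sel$accepted, sel_scaled$accepted)
  # empty window: zero selections, no error
  none <- vertical_select(samples, nai, c(10, 10.1), seed = 2)
  expect_equal(sum(none$accepted), 0)
  # flux mode differs from intensity mode by one power of the energy
  self <- vertical_select(samples, nai, win, mode = "flux", seed = 6)
  inw <- sel$prob > 0
  ratio <- self$prob[inw] / sel$prob[inw]
  expect_equal(ratio / max(ratio), sel$energy_ev[inw] / max(sel$energy_ev[inw]),
               tolerance = 1e-10)
})
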