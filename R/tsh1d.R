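#' Field-free 1D trajectory surface hopping
#'
#' Propagates one trajectory: velocity-Verlet nuclear motion on the active
#' adiabatic surface (Hellmann--Feynman gradients from the diabatic model),
#' electronic coefficients propagated with `n_substeps` short-time exponentials
#' in the (locally) diabatic frame along the linearly interpolated path -- the
#' exact limit of local diabatization, where the overlap between consecutive
#' adiabatic bases is the product of the adiabatic-diabatic transformation
#' matrices at both ends of the step. Hops are decided once per nuclear step
#' from GFSH probabilities of the adiabatic populations; accepted hops rescale
#' the (scalar, 1D) velocity to conserve total energy, frustrated hops leave
#' the velocity unchanged. An energy-based decoherence correction with
#' parameter `C` (default 0.1 hartree) damps non-active adiabatic amplitudes
#' each step.
#'
#' @param model a [diabatic_model()].
#' @param R0 initial position, bohr.
#' @param v0 initial velocity, au.
#' @param state0 initial adiabatic state (1 = lower, 2 = upper).
#' @param t_end_fs propagation time, fs (trajectory clock starts at 0).
#' @param dt_fs nuclear time step, fs.
#' @param n_substeps electronic substeps per nuclear step.
#' @param seed integer seed of this trajectory's hopping stream.
#' @param decoherence_C energy-based decoherence parameter, hartree; `NA`
#'   disables the correction.
#' @param decoherence_order apply decoherence `"after"` (default) or
#'   `"before"` the hop decision.
#' @return Object of class `tsh_trajectory`: list with vectors `times_fs`,
#'   `R`, `v`, `active`, matrix `pops` (adiabatic), `energy` (hartree),
#'   `status` (`"finished"` or `"left_domain"`), `n_frustrated`, data frame
#'   `hop_events`.
#' @export
tsh_trajectory <- function(model, R0, v0, state0, t_end_fs, dt_fs = 0.5,
                           n_substeps = 25L, seed = 1L, decoherence_C = 0.1,
                           decoherence_order = c("after", "before")) {
  decoherence_order <- match.arg(decoherence_order)
  stopifnot(dt_fs > 0, n_substeps >= 1L)
  dt <- fs_to_au(dt_fs)
  dsub <- dt / n_substeps
  m <- model$mass
  nsteps <- as.integer(round(t_end_fs / dt_fs))
  rng <- local_rng(seed)
  rdraws <- rng$unif(nsteps)
  rdraws[rdraws == 0] <- 1
  adia <- function(R) {
    v <- model$pot(R)
    eig2(v$v11, v$v12, v$v22)
  }
  grad_active <- function(R, act) {
    d <- if (!is.null(model$dpot)) model$dpot(R) else num_dpot(model, R)
    v <- model$pot(R)
    da <- (d$v11 + d$v22) / 2
    dd <- (v$v11 - v$v22) / 2
    b <- sqrt(dd^2 + v$v12^2)
    db <- if (b > 0) (dd * (d$v11 - d$v22) / 2 + v$v12 * d$v12) / b else 0
    if (act == 1L) da - db else da + db
  }
  R <- R0; v <- v0
  e <- adia(R)
  U <- matrix(c(e$u1x, e$u1y, e$u2x, e$u2y), 2, 2)
  c_ad <- c(0i, 0i); c_ad[state0] <- 1
  c_dia <- U %*% c_ad
  active <- as.integer(state0)
  times <- dt_fs * (0:nsteps)
  Rrec <- numeric(nsteps + 1L); vrec <- numeric(nsteps + 1L)
  arec <- integer(nsteps + 1L); erec <- numeric(nsteps + 1L)
  pops <- matrix(0, nsteps + 1L, 2)
  n_frustrated <- 0L
  hop_events <- list()
  status <- "finished"
  last <- nsteps + 1L
  for (i in 0:nsteps) {
    e <- adia(R)
    Ead <- c(e$e1, e$e2)
    U <- matrix(c(e$u1x, e$u1y, e$u2x, e$u2y), 2, 2)
    c_ad <- t(U) %*% c_dia
    Rrec[i + 1L] <- R; vrec[i + 1L] <- v; arec[i + 1L] <- active
    pops[i + 1L, ] <- abs(c_ad)^2
    erec[i + 1L] <- 0.5 * m * v^2 + Ead[active]
    if (i == nsteps) break
    if (R <= model$domain[1] || R >= model$domain[2]) {
      status <- "left_domain"; last <- i + 1L; break
    }
    pops_prev <- abs(c_ad)^2
    # velocity Verlet on the active surface
    g0 <- grad_active(R, active)
    a0 <- -g0 / m
    Rn <- R + v * dt + 0.5 * a0 * dt^2
    if (Rn <= model$domain[1] || Rn >= model$domain[2]) {
      status <- "left_domain"; last <- i + 1L; break
    }
    g1 <- grad_active(Rn, active)
    vn <- v + 0.5 * (a0 - g1 / m) * dt
    # electronic propagation in the diabatic frame along the interpolated path
    rm <- R + (Rn - R) * (seq_len(n_substeps) - 0.5) / n_substeps
    vv <- model$pot(rm)
    pr <- sym2_exp(vv$v11, vv$v12, vv$v22, -1i * dsub)
    c1 <- c_dia[1]; c2 <- c_dia[2]
    for (j in seq_len(n_substeps)) {
      t1 <- pr$p11[j] * c1 + pr$p12[j] * c2
      c2 <- pr$p12[j] * c1 + pr$p22[j] * c2
      c1 <- t1
    }
    c_dia <- c(c1, c2)
    en <- adia(Rn)
    Un <- matrix(c(en$u1x, en$u1y, en$u2x, en$u2y), 2, 2)
    c_ad <- t(Un) %*% c_dia
    pops_new <- as.vector(abs(c_ad)^2)
    Ead_n <- c(en$e1, en$e2)
    do_decoherence <- function(c_dia, vloc) {
      if (is.na(decoherence_C)) return(c_dia)
      c_a <- t(Un) %*% c_dia
      ekin <- 0.5 * m * vloc^2
      other <- setdiff(1:2, active)
      de <- abs(Ead_n[other] - Ead_n[active])
      if (de > 0) {
        tau_d <- (1 / de) * (1 + decoherence_C / ekin)
        c_a[other] <- c_a[other] * exp(-dt / tau_d)
        rest <- 1 - abs(c_a[other])^2
        if (abs(c_a[active]) > 0)
          c_a[active] <- c_a[active] * sqrt(rest) / abs(c_a[active])
        else
          c_a[active] <- sqrt(rest)
      }
      Un %*% c_a
    }
    if (decoherence_order == "before") c_dia <- do_decoherence(c_dia, vn)
    # hop decision (GFSH + cumulative-interval rule)
    p <- gfsh_probabilities(pops_prev, pops_new, active)
    cum <- cumsum(p)
    r <- rdraws[i + 1L]
    tostate <- which(r <= cum)[1]
    if (!is.na(tostate) && p[tostate] > 0) {
      ekin_new <- 0.5 * m * vn^2 + Ead_n[active] - Ead_n[tostate]
      if (ekin_new >= 0) {
        sgn <- if (vn >= 0) 1 else -1
        vn <- sgn * sqrt(2 * ekin_new / m)
        hop_events[[length(hop_events) + 1L]] <-
          data.frame(time_fs = times[i + 2L], from = active, to = tostate)
        active <- tostate
      } else {
        n_frustrated <- n_frustrated + 1L
      }
    }
    if (decoherence_order == "after") c_dia <- do_decoherence(c_dia, vn)
    R <- Rn; v <- vn
  }
  keep <- seq_len(last)
  structure(
    list(times_fs = times[keep], R = Rrec[keep], v = vrec[keep],
         active = arec[keep], pops = pops[keep, , drop = FALSE],
         energy = erec[keep], status = status, n_frustrated = n_frustrated,
         hop_events = if (length(hop_events)) do.call(rbind, hop_events)
                      else data.frame(time_fs = numeric(), from = integer(),
                                      to = integer())),
    class = "tsh_trajectory")
}

num_dpot <- function(model, R, h = 1e-5) {
  vp <- model$pot(R + h); vm <- model$pot(R - h)
  list(v11 = (vp$v11 - vm$v11) / (2 * h),
       v12 = (vp$v12 - vm$v12) / (2 * h),
       v22 = (vp$v22 - vm$v22) / (2 * h))
}

#' Propagate a swarm of trajectories from selected initial conditions
#'
#' One independent trajectory per accepted initial condition, starting from its
#' sampled phase-space point in its selected initial state, seeded per
#' geometry. No laser is included: the excitation is encoded entirely in the
#' initial state and the start time.
#'
#' @param selection tibble from [eoe_select()] or [vertical_select()].
#' @param samples tibble from [wigner_sample()].
#' @param model a [diabatic_model()].
#' @param t_end_fs,dt_fs,n_substeps,decoherence_C see [tsh_trajectory()].
#' @param seed integer; per-trajectory streams are keyed by `(seed, k)`.
#' @param max_trajectories optional cap (subsampling the accepted set
#'   deterministically: the first `max_trajectories` accepted geometries).
#' @return Object of class `tsh_ensemble`: list with `trajectories`,
#'   `t_start_fs`, `geometry_id`, `dt_fs`.
#' @export
tsh_swarm <- function(selection, samples, model, t_end_fs, dt_fs = 0.5,
                      n_substeps = 25L, decoherence_C = 0.1, seed = 1L,
                      max_trajectories = Inf) {
  acc <- which(selection$accepted)
  if (length(acc) > max_trajectories) acc <- acc[seq_len(max_trajectories)]
  trajs <- vector("list", length(acc))
  for (i in seq_along(acc)) {
    k <- acc[i]
    row <- match(selection$geometry_id[k], samples$geometry_id)
    trajs[[i]] <- tsh_trajectory(
      model, R0 = samples$R[row], v0 = samples$v[row],
      state0 = selection$state[k], t_end_fs = t_end_fs, dt_fs = dt_fs,
      n_substeps = n_substeps, decoherence_C = decoherence_C,
      seed = trace_seed(seed, selection$geometry_id[k]))
  }
  structure(
    list(trajectories = trajs,
         t_start_fs = selection$t_start_fs[acc],
         geometry_id = selection$geometry_id[acc],
         dt_fs = dt_fs),
    class = "tsh_ensemble")
}

#' Time-shifted ensemble observables
#'
#' Shifts each trajectory's time axis by its selection start time and computes
#' ensemble averages over the trajectories that are active in the upper
#' adiabatic state at each shifted time: fraction in the upper state, mean and
#' standard deviation of the position.
#'
#' @param swarm a [tsh_swarm()] result.
#' @param shift if `TRUE` (default) shift each trajectory by its start time;
#'   `FALSE` averages on the unshifted trajectory clock.
#' @return tibble with `time_fs`, `n` (trajectories with data), `pop_upper`,
#'   `mean_R_S1`, `sd_R_S1` (NA where no trajectory is in the upper state).
#' @export
shifted_observables <- function(swarm, shift = TRUE) {
  dt <- swarm$dt_fs
  shifts <- if (shift) swarm$t_start_fs else rep(0, length(swarm$trajectories))
  if (any(abs(shifts / dt - round(shifts / dt)) > 1e-9))
    stop("start times are not commensurate with the trajectory output step",
         call. = FALSE)
  off <- as.integer(round(shifts / dt))
  lens <- vapply(swarm$trajectories, function(tr) length(tr$times_fs), integer(1))
  imin <- min(off)
  imax <- max(off + lens - 1L)
  grid <- (imin:imax)
  nbin <- length(grid)
  nhere <- integer(nbin); nup <- integer(nbin)
  sumR <- numeric(nbin); sumR2 <- numeric(nbin)
  for (j in seq_along(swarm$trajectories)) {
    tr <- swarm$trajectories[[j]]
    idx <- (off[j] - imin) + seq_along(tr$times_fs)
    nhere[idx] <- nhere[idx] + 1L
    up <- tr$active == 2L
    iu <- idx[up]
    nup[iu] <- nup[iu] + 1L
    sumR[iu] <- sumR[iu] + tr$R[up]
    sumR2[iu] <- sumR2[iu] + tr$R[up]^2
  }
  mean_R <- ifelse(nup > 0, sumR / nup, NA_real_)
  var_R <- ifelse(nup > 1, pmax(0, sumR2 / nup - mean_R^2), NA_real_)
  tibble::tibble(
    time_fs = grid * dt,
    n = nhere,
    pop_upper = ifelse(nhere > 0, nup / nhere, NA_real_),
    mean_R_S1 = mean_R,
    sd_R_S1 = sqrt(var_R))
}
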