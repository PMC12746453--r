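#' Per-step probability to leave the initial state
#'
#' `P_beta->any(t) = max(0, 1 - |c_beta(t+dt)|^2 / |c_beta(t)|^2)` between two
#' consecutive stored steps of a population trace.
#'
#' @param trace a `population_trace`.
#' @param t_index index of the earlier stored step (1-based; uses steps
#'   `t_index` and `t_index + 1`).
#' @return probability in `[0, 1]`.
#' @export
leave_probability <- function(trace, t_index) {
  p <- trace$pops[, trace$beta]
  stopifnot(t_index >= 1, t_index < length(p))
  if (p[t_index] <= 0)
    stop("initial-state population vanished; leave probability undefined",
         call. = FALSE)
  max(0, 1 - p[t_index + 1] / p[t_index])
}

#' Total probability to leave the initial state over a trace
#'
#' `P_tot = 1 - prod_t (1 - P_beta->any(t)) = 1 - prod_t min(1, ratio)`. For a
#' monotonically decaying initial-state population this telescopes to the final
#' excited population; the `min` blocks revivals from cancelling earlier
#' transfer.
#'
#' @param trace a `population_trace`.
#' @return probability in `[0, 1]`.
#' @export
total_probability <- function(trace) {
  p <- trace$pops[, trace$beta]
  ratios <- p[-1] / p[-length(p)]
  1 - prod(pmin(ratios, 1))
}

ensemble_total_probability <- function(ens) {
  pb <- ens$pops[, , ens$beta]
  if (is.null(dim(pb))) pb <- matrix(pb, 1)
  ratios <- pb[, -1, drop = FALSE] / pb[, -ncol(pb), drop = FALSE]
  1 - apply(pmin(ratios, 1), 1, prod)
}

#' Renormalize electron-only population traces
#'
#' Applies the global renormalization: `P_max = max_k P_tot,k`, excited
#' populations divided by `P_max`, and the initial-state population rescaled as
#' `(|c_beta|^2 - (1 - P_max)) / P_max` so that populations still sum to one.
#' Per-step population differences scale exactly by `1/P_max`.
#'
#' @param ens a `population_ensemble` (or list of `population_trace`s).
#' @return Object of class `renormalized_ensemble`: the ensemble plus `rpops`
#'   (renormalized populations), `Ptot` (per-trace totals) and `Pmax`.
#' @export
renormalize_traces <- function(ens) {
  if (is.list(ens) && !inherits(ens, "population_ensemble"))
    ens <- as_population_ensemble(ens)
  Ptot <- ensemble_total_probability(ens)
  Pmax <- max(Ptot)
  if (Pmax <= 0)
    stop("no selectable initial conditions: no trace transfers population ",
         "out of the initial state (P_max = 0)", call. = FALSE)
  rpops <- ens$pops / Pmax
  rpops[, , ens$beta] <- (ens$pops[, , ens$beta] - (1 - Pmax)) / Pmax
  out <- ens
  out$rpops <- rpops
  out$Ptot <- Ptot
  out$Pmax <- Pmax
  class(out) <- c("renormalized_ensemble", class(ens))
  out
}

#' Global flux surface hopping probabilities
#'
#' GFSH hopping probabilities from the populations at two consecutive steps:
#' the probability to leave the active state is split over the states whose
#' population increases, in proportion to their population gain. The
#' active-to-active probability and negative probabilities are zero.
#'
#' @param pops_prev,pops_next population vectors (summing to one).
#' @param active index of the active state.
#' @return vector of per-state hop probabilities (zero for `active`).
#' @export
gfsh_probabilities <- function(pops_prev, pops_next, active) {
  dp <- pops_next - pops_prev
  denom <- sum(pmax(dp, 0))
  leave <- 1 - pops_next[active] / pops_prev[active]
  if (denom <= 0 || leave <= 0) return(numeric(length(pops_prev)))
  p <- leave * dp / denom
  p[active] <- 0
  pmax(p, 0)
}

#' Renormalized GFSH probabilities (selection step)
#'
#' For `active == beta` the leave factor uses the renormalized populations,
#' `1 - (p_beta(t+dt) - (1 - P_max)) / (p_beta(t) - (1 - P_max))` (raw
#' populations shifted by the renormalization constant); the flux-splitting
#' factor is unchanged. For `active != beta` the `1/P_max` factors cancel and
#' the plain GFSH expression applies to the renormalized populations.
#'
#' @param rens a [renormalize_traces()] result.
#' @param k trace index.
#' @param active active state index.
#' @param t_index earlier stored step index.
#' @return vector of per-state hop probabilities.
#' @export
renormalized_gfsh <- function(rens, k, active, t_index) {
  rp_prev <- rens$rpops[k, t_index, ]
  rp_next <- rens$rpops[k, t_index + 1, ]
  if (active == rens$beta) {
    den <- rp_prev[active]
    if (den <= 0)
      stop("renormalized initial-state population is non-positive; violates ",
           "the 1 - P_max <= |c_beta|^2 inequality", call. = FALSE)
    dp <- rp_next - rp_prev
    denom <- sum(pmax(dp, 0))
    leave <- 1 - rp_next[active] / den
    if (denom <= 0 || leave <= 0) return(numeric(length(rp_prev)))
    p <- leave * dp / denom
    p[active] <- 0
    pmax(p, 0)
  } else {
    gfsh_probabilities(rp_prev, rp_next, active)
  }
}

# deterministic per-trajectory substream seed
trace_seed <- function(seed, k)
  as.integer((as.double(seed) %% 65536) * 30269 + 104729 * (k %% 65536)) %% 2147483399L

#' Stochastic selection of initial states and start times (EOE core)
#'
#' Sweeps every renormalized trace over all stored steps, drawing one uniform
#' number per step from a per-trajectory stream keyed by `(seed, k)`, and
#' applies the cumulative-interval hop rule. After a hop away from the initial
#' state, subsequent probabilities are recomputed for leaving the new active
#' state; multiple hops are allowed. The state of the last hop becomes the
#' selected initial state and the corresponding time the start time; traces
#' whose last hop returns to the initial state, or that never hop, are
#' rejected. Start times are reported relative to `t_ref_fs` (the pulse
#' center, which the study convention shifts to zero) and must land on
#' multiples of the surface-hopping time step.
#'
#' @param rens a [renormalize_traces()] result.
#' @param seed integer seed.
#' @param tsh_dt_fs nuclear time step of the subsequent TSH simulations, fs.
#' @param t_ref_fs reference time subtracted from the stored times (defaults
#'   to the midpoint of the stored time grid, i.e. the pulse center for tables
#'   from [sample_pulse()]).
#' @param warn_hops warn when more than this fraction of traces needs three or
#'   more hops.
#' @return tibble with one row per trace: `geometry_id`, `accepted`, `state`,
#'   `t_start_fs`, `n_hops`, `P_tot`, and a `hops` list-column with the full
#'   hop history (`time_fs`, `from`, `to`). Attributes: `Pmax`, `seed`,
#'   `tsh_dt_fs`.
#' @export
eoe_select <- function(rens, seed, tsh_dt_fs = 0.5, t_ref_fs = NULL,
                       warn_hops = 0.05) {
  stopifnot(inherits(rens, "renormalized_ensemble"))
  times <- rens$times_fs
  nT <- length(times) - 1L
  nk <- dim(rens$pops)[1]
  ns <- dim(rens$pops)[3]
  if (is.null(t_ref_fs)) t_ref_fs <- times[(length(times) + 1L) %/% 2L]
  stored_dt <- times[2] - times[1]
  if (abs(stored_dt / tsh_dt_fs - round(stored_dt / tsh_dt_fs)) > 1e-9)
    stop("stored trace times are not commensurate with the TSH time step",
         call. = FALSE)
  # per-trajectory uniform streams
  rmat <- matrix(0, nk, nT)
  for (k in seq_len(nk)) {
    rng <- local_rng(trace_seed(seed, k))
    rmat[k, ] <- rng$unif(nT)
  }
  # draws in (0, 1]: map 0 -> 1 (runif is in [0, 1))
  rmat[rmat == 0] <- 1
  active <- rep.int(rens$beta, nk)
  last_state <- rep(NA_integer_, nk)
  last_time <- rep(NA_real_, nk)
  n_hops <- integer(nk)
  events <- list()
  if (ns == 2L) {
    beta <- rens$beta; alpha <- 3L - beta
    rp_b <- rens$rpops[, , beta, drop = FALSE][, , 1]
    rp_a <- rens$rpops[, , alpha, drop = FALSE][, , 1]
    if (nk == 1L) { rp_b <- matrix(rp_b, 1); rp_a <- matrix(rp_a, 1) }
    for (t in seq_len(nT)) {
      # leave-beta: renormalized leave factor; flux factor = 1 in a two-state
      # system (all lost population flows to the other state)
      pb <- pmax(0, 1 - rp_b[, t + 1] / rp_b[, t])
      pb[rp_a[, t + 1] <= rp_a[, t]] <- 0
      pa <- rep(0, nk)
      pos <- rp_a[, t] > 0
      pa[pos] <- pmax(0, 1 - rp_a[pos, t + 1] / rp_a[pos, t])
      pa[rp_b[, t + 1] <= rp_b[, t]] <- 0
      r <- rmat[, t]
      hop <- (active == beta & r <= pb) | (active == alpha & r <= pa)
      if (any(hop)) {
        active[hop] <- (beta + alpha) - active[hop]
        last_state[hop] <- active[hop]
        last_time[hop] <- times[t + 1]
        n_hops[hop] <- n_hops[hop] + 1L
        events[[length(events) + 1L]] <-
          data.frame(k = which(hop), time_fs = times[t + 1] - t_ref_fs,
                     from = (beta + alpha) - active[hop], to = active[hop])
      }
    }
  } else {
    for (k in seq_len(nk)) {
      for (t in seq_len(nT)) {
        p <- renormalized_gfsh(rens, k, active[k], t)
        cum <- cumsum(p)
        r <- rmat[k, t]
        tostate <- which(r <= cum)[1]
        if (!is.na(tostate) && (tostate == 1L || r > cum[tostate - 1L])) {
          events[[length(events) + 1L]] <-
            data.frame(k = k, time_fs = times[t + 1] - t_ref_fs,
                       from = active[k], to = tostate)
          active[k] <- tostate
          last_state[k] <- tostate
          last_time[k] <- times[t + 1]
          n_hops[k] <- n_hops[k] + 1L
        }
      }
    }
  }
  accepted <- !is.na(last_state) & last_state != rens$beta
  t_start <- ifelse(accepted, last_time - t_ref_fs, NA_real_)
  bad <- accepted & abs(t_start / tsh_dt_fs - round(t_start / tsh_dt_fs)) > 1e-9
  if (any(bad))
    warning("some selected start times are not multiples of the TSH step")
  frac3 <- mean(n_hops >= 3L)
  if (frac3 > warn_hops)
    warning(sprintf("%.1f%% of traces performed three or more hops", 100 * frac3))
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(k = integer(), time_fs = numeric(), from = integer(),
               to = integer())
  hops_by_k <- split(ev[c("time_fs", "from", "to")], factor(ev$k, levels = seq_len(nk)))
  out <- tibble::tibble(
    geometry_id = rens$geometry_id %||% seq_len(nk),
    accepted = accepted,
    state = ifelse(accepted, last_state, NA_integer_),
    t_start_fs = t_start,
    n_hops = n_hops,
    P_tot = rens$Ptot,
    hops = unname(hops_by_k))
  attr(out, "Pmax") <- rens$Pmax
  attr(out, "seed") <- seed
  attr(out, "tsh_dt_fs") <- tsh_dt_fs
  out
}

#' Vertical (energy-window) initial-state selection
#'
#' The sudden-excitation comparison scheme: per geometry, selection
#' probabilities proportional to `f_osc / dE^2` (constant intensity, default)
#' or `f_osc / dE` (constant photon flux) for states whose excitation energy
#' lies inside the window; probabilities are normalized to the maximum over all
#' in-window transitions, and acceptance is decided stochastically. All start
#' times are zero.
#'
#' @param samples tibble from [wigner_sample()].
#' @param model a [diabatic_model()].
#' @param window_ev numeric length-2, energy window in eV.
#' @param mode `"intensity"` (f/dE^2) or `"flux"` (f/dE).
#' @param seed integer seed.
#' @return tibble with `geometry_id`, `accepted`, `state`, `t_start_fs`,
#'   `energy_ev`, `prob`.
#' @export
vertical_select <- function(samples, model, window_ev,
                            mode = c("intensity", "flux"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(window_ev) == 2, window_ev[1] < window_ev[2])
  ad <- adiabatize_n(model, samples$R)
  de_h <- ad$energies[, 2] - ad$energies[, 1]
  de <- hartree_to_ev(de_h)
  fosc <- (2 / 3) * de_h * ad$tdm_adiabatic[1, 2, ]^2
  p <- switch(mode, intensity = fosc / de_h^2, flux = fosc / de_h)
  inwin <- de >= window_ev[1] & de <= window_ev[2]
  p[!inwin] <- 0
  pmaxv <- max(p)
  prob <- if (pmaxv > 0) p / pmaxv else p
  rng <- local_rng(seed)
  r <- rng$unif(nrow(samples))
  accepted <- inwin & r <= prob
  tibble::tibble(
    geometry_id = samples$geometry_id,
    accepted = accepted,
    state = ifelse(accepted, 2L, NA_integer_),
    t_start_fs = ifelse(accepted, 0, NA_real_),
    energy_ev = de,
    prob = prob)
}
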