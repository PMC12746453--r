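#' Read and write initial-conditions files
#'
#' Plain-text table of phase-space samples, one record per geometry:
#' `index / R [bohr] / v [au]`, extensible with the selection results
#' (`accepted`, `state`, `t_start [fs]`). Rejected records are kept and
#' flagged, never dropped. The header carries a format version.
#'
#' @param samples tibble from [wigner_sample()].
#' @param file path.
#' @param selection optional tibble from [eoe_select()] / [vertical_select()]
#'   to merge into the records.
#' @export
write_initconds <- function(samples, file, selection = NULL) {
  df <- data.frame(index = samples$geometry_id,
                   R_bohr = sprintf("%.17g", samples$R),
                   v_au = sprintf("%.17g", samples$v))
  hdr <- c("# eoexcite initial conditions v1",
           "# columns: index R_bohr v_au")
  if (!is.null(selection)) {
    stopifnot(identical(selection$geometry_id, samples$geometry_id))
    df$accepted <- ifelse(selection$accepted, "T", "F")
    df$state <- ifelse(selection$accepted, selection$state, 0L)
    df$t_start_fs <- ifelse(selection$accepted,
                            sprintf("%.6f", selection$t_start_fs), "NA")
    hdr[2] <- "# columns: index R_bohr v_au accepted state t_start_fs"
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_initconds
#' @return `read_initconds`: tibble with the stored columns.
#' @export
read_initconds <- function(file) {
  lines <- readLines(file)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  dat <- utils::read.table(text = body, na.strings = "NA")
  out <- tibble::tibble(geometry_id = as.integer(dat[[1]]),
                        R = dat[[2]], v = dat[[3]], weight = 1)
  if (ncol(dat) >= 6) {
    out$accepted <- if (is.logical(dat[[4]])) dat[[4]] else dat[[4]] == "T"
    out$state <- ifelse(out$accepted, as.integer(dat[[5]]), NA_integer_)
    out$t_start_fs <- as.numeric(dat[[6]])
  }
  out
}

#' Write ensemble observables as CSV
#'
#' @param observables tibble (e.g. from [shifted_observables()] or a
#'   `qd_trajectory`'s `$observables`).
#' @param file path.
#' @export
write_observables_csv <- function(observables, file) {
  utils::write.csv(observables, file, row.names = FALSE)
  invisible(file)
}

#' End-to-end EOE workflow
#'
#' Orchestrates ground-state sampling, electron-only dynamics, renormalized
#' selection (or the vertical comparison scheme) and, optionally, the TSH
#' swarm with time-shifted observables, from a single configuration. The
#' configuration is a plain named list (or a YAML file with the same fields);
#' all randomness flows from the named seeds.
#'
#' Configuration fields (defaults in parentheses): `scheme` ("eoe" or
#' "vertical"), `n_samples` (10000), `grid_n` (1024), `grid_range`
#' (c(3, 40)), pulse: `E0` (0.001), `omega0_ev`, `fwhm_intensity_fs`,
#' `eod_dt_fs` (0.0625), `eod_stride` (8), `tsh_dt_fs` (0.5), `window_ev`
#' (vertical scheme), `seed_sampling`, `seed_selection`, `seed_tsh`,
#' `run_tsh` (FALSE), `tsh_t_end_fs` (1600), `tsh_max_trajectories` (Inf).
#'
#' @param config named list or path to a YAML file.
#' @param model optional [diabatic_model()]; default [nai_model()].
#' @return list with `samples`, `selection`, and (when run) `ensemble`
#'   (population ensemble), `swarm`, `observables`; plus `provenance` (the
#'   fully expanded config and package version).
#' @export
eoe_pipeline <- function(config, model = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(scheme = "eoe", n_samples = 10000L, grid_n = 1024L,
              grid_range = c(3, 40), E0 = 0.001, omega0_ev = 3.68,
              fwhm_intensity_fs = 20, eod_dt_fs = 0.0625, eod_stride = 8L,
              tsh_dt_fs = 0.5, window_ev = NULL,
              seed_sampling = 1L, seed_selection = 2L, seed_tsh = 3L,
              run_tsh = FALSE, tsh_t_end_fs = 1600,
              tsh_max_trajectories = Inf)
  cfg <- utils::modifyList(def, config)
  if (is.null(model)) model <- nai_model()
  wf <- qd_ground_state(model, n = cfg$grid_n, rmin = cfg$grid_range[1],
                        rmax = cfg$grid_range[2])
  wd <- wigner_distribution(wf)
  samples <- wigner_sample(wd, cfg$n_samples, model$mass, cfg$seed_sampling)
  out <- list(samples = samples)
  if (cfg$scheme == "eoe") {
    pulse <- laser_pulse(E0 = cfg$E0, omega0_ev = cfg$omega0_ev,
                         fwhm_intensity_fs = cfg$fwhm_intensity_fs)
    tab <- sample_pulse(pulse, cfg$eod_dt_fs, pad_multiple = cfg$eod_stride)
    ens <- eod_ensemble(samples, model, tab, stride = cfg$eod_stride)
    rens <- renormalize_traces(ens)
    out$ensemble <- rens
    out$selection <- eoe_select(rens, seed = cfg$seed_selection,
                                tsh_dt_fs = cfg$tsh_dt_fs,
                                t_ref_fs = pulse$tc_fs)
  } else if (cfg$scheme == "vertical") {
    if (is.null(cfg$window_ev))
      stop("vertical scheme requires window_ev", call. = FALSE)
    out$selection <- vertical_select(samples, model, cfg$window_ev,
                                     seed = cfg$seed_selection)
  } else stop("unknown scheme: ", cfg$scheme, call. = FALSE)
  if (isTRUE(cfg$run_tsh)) {
    out$swarm <- tsh_swarm(out$selection, samples, model,
                           t_end_fs = cfg$tsh_t_end_fs,
                           dt_fs = cfg$tsh_dt_fs, seed = cfg$seed_tsh,
                           max_trajectories = cfg$tsh_max_trajectories)
    out$observables <- shifted_observables(out$swarm)
  }
  out$provenance <- list(
    config = cfg,
    package_version = as.character(utils::packageVersion("eoexcite")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  out
}
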