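#' Gaussian laser pulses
#'
#' Constructs a transform-limited Gaussian pulse
#' `E(t) = E0 * exp(-4 ln2 (t - tc)^2 / FWHM^2) * cos(omega0 (t - tc) + theta) * e`,
#' where FWHM is the full width at half maximum of the *field envelope*. Study
#' parameters are usually quoted as intensity FWHMs; since the intensity is the
#' squared envelope, `fwhm_field = fwhm_intensity * sqrt(2)`. Exactly one of
#' `fwhm_field_fs` / `fwhm_intensity_fs` must be given.
#'
#' @param E0 maximum field amplitude, atomic units.
#' @param omega0_ev carrier photon energy, eV.
#' @param fwhm_field_fs FWHM of the field envelope, fs.
#' @param fwhm_intensity_fs FWHM of the intensity envelope, fs.
#' @param tc_fs temporal center of the envelope, fs.
#' @param theta carrier phase at `t = tc`, rad.
#' @param polarization unit 3-vector.
#' @return Object of class `laser_pulse`.
#' @export
#' @examples
#' p <- laser_pulse(E0 = 0.001, omega0_ev = 3.68, fwhm_intensity_fs = 20)
#' p$fwhm_field_fs  # 20 * sqrt(2)
laser_pulse <- function(E0, omega0_ev, fwhm_field_fs = NULL,
                        fwhm_intensity_fs = NULL, tc_fs = 0, theta = 0,
                        polarization = c(0, 0, 1)) {
  if (is.null(fwhm_field_fs) == is.null(fwhm_intensity_fs))
    stop("give exactly one of fwhm_field_fs / fwhm_intensity_fs", call. = FALSE)
  if (is.null(fwhm_field_fs)) {
    if (fwhm_intensity_fs <= 0) stop("pulse width must be positive", call. = FALSE)
    fwhm_field_fs <- fwhm_intensity_fs * sqrt(2)
  }
  if (fwhm_field_fs <= 0) stop("pulse width must be positive", call. = FALSE)
  if (E0 < 0) stop("E0 must be >= 0", call. = FALSE)
  nrm <- sqrt(sum(polarization^2))
  if (abs(nrm - 1) > 1e-8)
    stop("polarization must be a unit vector", call. = FALSE)
  structure(
    list(E0 = E0,
         omega0 = ev_to_hartree(omega0_ev),
         fwhm_field = fs_to_au(fwhm_field_fs),
         tc = fs_to_au(tc_fs),
         theta = theta,
         polarization = polarization / nrm,
         # user-facing mirrors
         omega0_ev = omega0_ev,
         fwhm_field_fs = fwhm_field_fs,
         fwhm_intensity_fs = fwhm_field_fs / sqrt(2),
         tc_fs = tc_fs),
    class = "laser_pulse")
}

#' @export
print.laser_pulse <- function(x, ...) {
  cat(sprintf("<laser_pulse> E0 = %g au, omega0 = %.4f eV, field FWHM = %.4f fs (intensity %.4f fs), tc = %g fs, theta = %g\n",
              x$E0, x$omega0_ev, x$fwhm_field_fs, x$fwhm_intensity_fs,
              x$tc_fs, x$theta))
  invisible(x)
}

#' Gaussian envelope time constant tau
#'
#' The envelope written as `exp(-t^2 / (2 tau^2))` has
#' `tau = fwhm_field / (2 sqrt(2 ln 2))`. Returned in fs; this is the
#' convention used by the analytic two-level model.
#'
#' @param pulse a [laser_pulse()].
#' @return tau in fs.
#' @export
pulse_tau_fs <- function(pulse) pulse$fwhm_field_fs / (2 * sqrt(2 * log(2)))

#' Evaluate the pulse field
#'
#' @param pulse a [laser_pulse()].
#' @param t_fs time(s), fs.
#' @return For scalar `t_fs` a 3-vector (au); for vector input a
#'   `length(t_fs)` x 3 matrix.
#' @export
field_at <- function(pulse, t_fs) {
  t <- fs_to_au(t_fs) - pulse$tc
  env <- pulse$E0 * exp(-4 * log(2) * t^2 / pulse$fwhm_field^2)
  amp <- env * cos(pulse$omega0 * t + pulse$theta)
  out <- outer(amp, pulse$polarization)
  if (length(t_fs) == 1L) drop(out) else out
}

#' Sample a pulse into a field table
#'
#' The table spans the interval where the envelope exceeds `cutoff * E0`,
#' extended outward so that `tc` falls exactly on a grid point and the number
#' of steps on each side is a multiple of `pad_multiple` (so that
#' stride-decimated storage stays aligned with downstream time steps).
#'
#' @param pulse a [laser_pulse()].
#' @param dt_fs sampling step, fs.
#' @param cutoff envelope cutoff relative to `E0`; must be in (0, 1).
#' @param pad_multiple integer; each half of the grid is rounded up to a
#'   multiple of this many steps.
#' @return A `field_table`: tibble with columns `time_fs`, `Ex`, `Ey`, `Ez`
#'   (au), with the pulse stored in `attr(, "pulse")`.
#' @export
sample_pulse <- function(pulse, dt_fs, cutoff = 1e-8, pad_multiple = 1L) {
  stopifnot(dt_fs > 0)
  if (cutoff <= 0)
    stop("cutoff must be positive: a Gaussian envelope has unbounded support",
         call. = FALSE)
  if (cutoff >= 1) stop("cutoff must be < 1", call. = FALSE)
  half_au <- pulse$fwhm_field * sqrt(log(1 / cutoff) / (4 * log(2)))
  nhalf <- ceiling(au_to_fs(half_au) / dt_fs)
  nhalf <- as.integer(ceiling(nhalf / pad_multiple) * pad_multiple)
  t_fs <- pulse$tc_fs + (-nhalf:nhalf) * dt_fs
  f <- field_at(pulse, t_fs)
  out <- tibble::tibble(time_fs = t_fs, Ex = f[, 1], Ey = f[, 2], Ez = f[, 3])
  attr(out, "pulse") <- pulse
  class(out) <- c("field_table", class(out))
  out
}

#' Build a field table from raw samples
#'
#' @param time_fs uniformly spaced times, fs.
#' @param Ex,Ey,Ez field components, au.
#' @return A `field_table` tibble.
#' @export
field_table <- function(time_fs, Ex, Ey = 0 * Ex, Ez = 0 * Ex) {
  dt <- diff(time_fs)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop("field table requires a uniform time grid", call. = FALSE)
  if (!all(is.finite(c(Ex, Ey, Ez))))
    stop("field values must be finite", call. = FALSE)
  out <- tibble::tibble(time_fs = time_fs, Ex = Ex, Ey = Ey, Ez = Ez)
  class(out) <- c("field_table", class(out))
  out
}

field_table_dt_fs <- function(table) {
  dt <- diff(table$time_fs)
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop("field table grid is not uniform", call. = FALSE)
  dt[1]
}

#' Power spectrum of a sampled field
#'
#' Discrete Fourier magnitude-squared of the (scalar magnitude of the) field,
#' zero-padded for frequency resolution. Reports the spectral intensity FWHM
#' in eV and warns when the envelope has not decayed at the table edges or a
#' zero-frequency component is present above tolerance.
#'
#' @param table a `field_table`.
#' @param pad zero-padding factor (table is padded to `pad *` next power of 2).
#' @param dc_tol relative tolerance for the zero-frequency diagnostic.
#' @return A tibble with columns `energy_ev`, `intensity` (normalized to unit
#'   maximum), with attributes `fwhm_ev` (numeric) and `dc_fraction`.
#' @export
power_spectrum <- function(table, pad = 8, dc_tol = 1e-6) {
  dt_fs <- field_table_dt_fs(table)
  f <- sqrt(table$Ex^2 + table$Ey^2 + table$Ez^2) *
    sign_of_dominant(table)
  n <- length(f)
  edge <- max(abs(f[c(1, n)]))
  if (edge > 1e-6 * max(abs(f)))
    warning("field not decayed at table edges; spectrum of a truncated pulse")
  nfft <- pad * 2^ceiling(log2(n))
  ft <- stats::fft(c(f, rep(0, nfft - n)))
  dt <- fs_to_au(dt_fs)
  freq <- 2 * pi * (0:(nfft - 1)) / (nfft * dt)         # angular, au
  keep <- seq_len(nfft %/% 2)
  inten <- abs(ft[keep])^2
  dc_fraction <- inten[1] / max(inten)
  if (dc_fraction > dc_tol)
    warning(sprintf("zero-frequency component above tolerance (%.2e of peak)",
                    dc_fraction))
  inten <- inten / max(inten)
  out <- tibble::tibble(energy_ev = hartree_to_ev(freq[keep]),
                        intensity = inten)
  attr(out, "fwhm_ev") <- curve_fwhm(out$energy_ev, out$intensity)
  attr(out, "dc_fraction") <- dc_fraction
  out
}

# project the 3-component field onto its dominant polarization direction so the
# spectrum sees a signed scalar field
sign_of_dominant <- function(table) {
  E <- cbind(table$Ex, table$Ey, table$Ez)
  i <- which.max(colSums(E^2))
  sign(E[, i] + (E[, i] == 0))
}

# FWHM of a sampled curve by linear interpolation around the half maximum
curve_fwhm <- function(x, y) {
  imax <- which.max(y)
  half <- y[imax] / 2
  left <- which(y[seq_len(imax)] <= half)
  right <- which(y[imax:length(y)] <= half) + imax - 1L
  if (!length(left) || !length(right)) return(NA_real_)
  i1 <- max(left)
  x1 <- x[i1] + (half - y[i1]) / (y[i1 + 1] - y[i1]) * (x[i1 + 1] - x[i1])
  i2 <- min(right)
  x2 <- x[i2 - 1] + (half - y[i2 - 1]) / (y[i2] - y[i2 - 1]) * (x[i2] - x[i2 - 1])
  x2 - x1
}

#' Time-integrated field (zero-frequency diagnostic)
#'
#' @param table a `field_table`.
#' @return 3-vector, integral of each field component over time (au).
#' @export
field_integral <- function(table) {
  dt <- fs_to_au(field_table_dt_fs(table))
  c(sum(table$Ex), sum(table$Ey), sum(table$Ez)) * dt
}

#' Read / write plain-text laser files
#'
#' Columns: time, Ex, Ey, Ez (field in au). The time unit is declared in the
#' header (`# time_unit: fs` or `au`).
#'
#' @param table a `field_table`.
#' @param file path.
#' @param time_unit `"fs"` or `"au"`.
#' @export
write_laser_file <- function(table, file, time_unit = "fs") {
  t <- switch(time_unit, fs = table$time_fs, au = fs_to_au(table$time_fs),
              stop("time_unit must be 'fs' or 'au'", call. = FALSE))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# eoexcite laser file v1",
               paste0("# time_unit: ", time_unit),
               "# columns: time Ex Ey Ez [field in au]"), con)
  utils::write.table(
    data.frame(t = sprintf("%.17g", t),
               Ex = sprintf("%.17g", table$Ex),
               Ey = sprintf("%.17g", table$Ey),
               Ez = sprintf("%.17g", table$Ez)),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_laser_file
#' @return `read_laser_file`: a `field_table`.
#' @export
read_laser_file <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  unit <- "fs"
  m <- grep("time_unit:", hdr, value = TRUE)
  if (length(m)) unit <- trimws(sub(".*time_unit:", "", m[1]))
  dat <- utils::read.table(text = lines[!grepl("^#", lines) & nzchar(lines)])
  t_fs <- if (unit == "au") au_to_fs(dat[[1]]) else dat[[1]]
  field_table(t_fs, dat[[2]], dat[[3]], dat[[4]])
}
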