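#' Atomic-unit conversion constants
#'
#' All internal quantities in this package are kept in Hartree atomic units
#' (hartree, bohr, atomic time, atomic field strength); conversions happen only
#' at the user-facing surface (times in fs, energies in eV where documented).
#' `au_constants()` returns the conversion factors used throughout.
#'
#' @return Named list with elements
#'   \describe{
#'     \item{ev_per_hartree}{27.2114 (eV per hartree)}
#'     \item{fs_per_autime}{0.02418884 (fs per atomic time unit)}
#'     \item{angstrom_per_bohr}{0.52917721}
#'     \item{me_per_amu}{1822.888 (electron masses per unified amu)}
#'   }
#' @export
#' @examples
#' au_constants()$ev_per_hartree
au_constants <- function() {
  list(
    ev_per_hartree   = 27.211386245988,
    fs_per_autime    = 0.02418884326586,
    angstrom_per_bohr = 0.529177210903,
    me_per_amu       = 1822.888486209
  )
}

# internal shorthands
.EV  <- 27.211386245988
.FS  <- 0.02418884326586
.ANG <- 0.529177210903
.AMU <- 1822.888486209

#' @rdname au_constants
#' @param x numeric value(s) to convert.
#' @export
fs_to_au <- function(x) x / .FS

#' @rdname au_constants
#' @export
au_to_fs <- function(x) x * .FS

#' @rdname au_constants
#' @export
ev_to_hartree <- function(x) x / .EV

#' @rdname au_constants
#' @export
hartree_to_ev <- function(x) x * .EV

#' @rdname au_constants
#' @export
bohr_to_angstrom <- function(x) x * .ANG
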