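## Unit conventions: all electrostatics is done in Hartree atomic units
## (Bohr, e, Hartree); all geometry I/O and cavity bookkeeping is in Angstrom.
## The conversion constant lives here and nowhere else.

#' Physical constants used throughout the package
#'
#' Returns the conversion factors the package uses internally: the Bohr
#' radius in Angstrom and the Hartree in kcal/mol. Geometry (cavities, XYZ
#' and COSMO files, radii tables) is handled in Angstrom; all electrostatic
#' quantities (potentials, Coulomb matrices, energies) are in atomic units.
#'
#' @return Named list with elements `bohr_angstrom` (0.52917721092) and
#'   `hartree_kcal` (627.509).
#' @export
#' @examples
#' cosmo_constants()$bohr_angstrom
cosmo_constants <- function() {
  list(bohr_angstrom = 0.52917721092, hartree_kcal = 627.509)
}

.BOHR <- 0.52917721092   # Angstrom per Bohr
.HARTREE_KCAL <- 627.509 # kcal/mol per Hartree

ang2bohr <- function(x) x / .BOHR
bohr2ang <- function(x) x * .BOHR

## erf via the exact pnorm relation; valid for all real x
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
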