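## Physical constants (CODATA 2018) and unit conventions used throughout:
## couplings in MHz, magnetic fields in mT, microwave frequencies in GHz,
## distances in Angstrom, correlation times in ns.

#' Physical constants used by histbrace
#'
#' A named list of CODATA 2018 constants and nuclear properties, exposed so
#' that analysis scripts and tests can assemble quantities independently.
#'
#' @format Named list with elements:
#' \describe{
#'   \item{h}{Planck constant, J s}
#'   \item{hbar}{reduced Planck constant, J s}
#'   \item{muB}{Bohr magneton, J/T}
#'   \item{mu0_4pi}{mu0 / 4 pi, T m / A}
#'   \item{ge}{free-electron g value 2.0023 used for all Delta-g}
#'   \item{gammabar}{nuclear gyromagnetic ratios gamma/2pi in MHz/T for
#'     1H, 14N, 15N (signed)}
#'   \item{gamma_rad}{gyromagnetic ratios in rad s-1 T-1 for 1H, 15N}
#'   \item{ratio_15N_14N}{|gamma(15N)/gamma(14N)| = 1.4027 used for
#'     isotopologue rescaling}
#'   \item{R_kcal}{gas constant in kcal mol-1 K-1}
#' }
#' @export
hb_constants <- list(
  h        = 6.62607015e-34,
  hbar     = 1.054571817e-34,
  muB      = 9.2740100783e-24,
  mu0_4pi  = 1e-7,
  ge       = 2.0023,
  gammabar = c("1H" = 42.577478518, "14N" = 3.0766, "15N" = -4.3173),
  gamma_rad = c("1H" = 2.6752218744e8, "15N" = -2.7126180e7),
  ratio_15N_14N = 1.4027,
  R_kcal   = 1.98720e-3
)

## MHz of electron Zeeman energy per mT at g = 1: muB * 1 mT / h in MHz
.mhz_per_mT_g1 <- hb_constants$muB * 1e-3 / hb_constants$h * 1e-6

.assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}
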