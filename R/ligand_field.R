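## Ligand-field decomposition of the Cu hyperfine coupling for a d(x2-y2)
## SOMO in a distorted square-pyramidal geometry: Fermi contact from the
## Aiso relation, spin density from the rhombic A3 relation, and the
## breakdown into Fermi / dipolar / orbital contributions.
##
## Conventions: Pd is the dipolar hyperfine parameter in MHz (default 1180),
## a and b are the orbital coefficients of d(x2-y2) and d(z2) with
## a^2 + b^2 = 1, Delta-g_n = g_n - 2.0023, and the Fermi contact is -Pd*K.

.lft_coeffs <- function(b2) {
  if (!is.finite(b2) || b2 < 0 || b2 > 0.1)
    stop("b2 must lie in [0, 0.1]", call. = FALSE)
  a <- sqrt(1 - b2); b <- sqrt(b2)
  list(a = a, b = b,
       c_dip = 4 * (a^2 - b^2) / 7,                # coefficient of alpha^2
       c_g2  = (3 * a - 3 * b) / (14 * (a + 3 * b)), # Delta-g2 term
       c_g1  = (3 * a + 3 * b) / (14 * (a - 3 * b))) # Delta-g1 term
}

#' Fermi-contact contribution from the Aiso ligand-field relation
#'
#' From Aiso = Pd(-K + (1/3) sum Delta-g_n), the Fermi contact -Pd*K equals
#' Aiso - (Pd/3) sum(g_n - g_e).
#'
#' @param Aiso sign-resolved isotropic Cu hyperfine coupling in MHz.
#' @param g `g_tensor` or numeric triple.
#' @param Pd dipolar parameter in MHz (default 1180).
#' @return list with `fermi` (the Fermi contact -Pd*K, MHz) and `kappa`
#'   (the dimensionless Fermi-contact parameter K).
#' @examples
#' fermi_contact(9.67, c(2.027, 2.095, 2.261))$fermi # about -138
#' @export
fermi_contact <- function(Aiso, g, Pd = 1180) {
  if (!is.finite(Pd) || Pd <= 0) stop("Pd must be positive", call. = FALSE)
  .assert_finite(Aiso, "Aiso")
  dg <- delta_g(g)
  fermi <- Aiso - (Pd / 3) * sum(dg)
  list(fermi = fermi, kappa = -fermi / Pd)
}

#' Copper spin density from the rhombic A3 relation
#'
#' Solves for the ground-state spin density alpha^2 in
#' A3 = -Pd\[K + (4 alpha^2 (a^2 - b^2))/7
#'          - (3a - 3b) Dg2 / (14(a + 3b))
#'          - (3a + 3b) Dg1 / (14(a - 3b)) - Dg3\],
#' with a = sqrt(1 - b2), b = sqrt(b2). The relation is linear in alpha^2;
#' the solution must land in \[0, 1.2\] or the inputs are flagged as
#' inconsistent.
#'
#' @param A3_signed signed A3 in MHz (negative for these systems).
#' @param g `g_tensor` or numeric triple.
#' @param kappa dimensionless Fermi-contact parameter K (from
#'   [fermi_contact()]).
#' @param b2 d(z2) mixing fraction, in \[0, 0.1\].
#' @param Pd dipolar parameter in MHz.
#' @return alpha^2 (dimensionless spin density on Cu).
#' @export
solve_spin_density <- function(A3_signed, g, kappa, b2 = 0.02, Pd = 1180) {
  if (!is.finite(Pd) || Pd <= 0) stop("Pd must be positive", call. = FALSE)
  .assert_finite(c(A3_signed, kappa), "inputs")
  co <- .lft_coeffs(b2)
  dg <- delta_g(g)
  ## -A3/Pd = K + c_dip*alpha2 - c_g2*Dg2 - c_g1*Dg1 - Dg3
  alpha2 <- (-A3_signed / Pd - kappa + co$c_g2 * dg[2] + co$c_g1 * dg[1] + dg[3]) /
    co$c_dip
  if (!is.finite(alpha2) || alpha2 < 0 || alpha2 > 1.2)
    stop(sprintf("no physical spin density in [0, 1.2] (got %.3f): inconsistent inputs",
                 alpha2), call. = FALSE)
  unname(alpha2)
}

#' Decompose the Cu hyperfine coupling into ligand-field contributions
#'
#' Produces the Fermi-contact, dipolar and orbital contributions in the
#' directions parallel and perpendicular to the unique axis, together with
#' the spin density. The parallel terms are exact within the model (they
#' recompose to the signed A3 by construction); the perpendicular terms use
#' the leading-order expressions (factor +2/7 on the dipolar part, 11/14 on
#' the mean in-plane Delta-g for the orbital part) and are flagged
#' approximate because cross terms are not modelled.
#'
#' @param g `g_tensor` or numeric triple.
#' @param Aiso sign-resolved isotropic coupling, MHz.
#' @param A3_signed signed A3, MHz.
#' @param b2 d(z2) mixing fraction.
#' @param Pd dipolar parameter, MHz.
#' @return object of class `hyperfine_decomposition`: list with fields
#'   `fermi`, `dipolar_para`, `dipolar_perp`, `orbital_para`,
#'   `orbital_perp` (MHz), `alpha2`, `kappa`, `A3_signed`,
#'   `perp_approximate = TRUE`.
#' @export
decompose_hyperfine <- function(g, Aiso, A3_signed, b2 = 0.02, Pd = 1180) {
  fc <- fermi_contact(Aiso, g, Pd)
  alpha2 <- solve_spin_density(A3_signed, g, fc$kappa, b2, Pd)
  co <- .lft_coeffs(b2)
  dg <- delta_g(g)
  dipolar_para <- -Pd * co$c_dip * alpha2
  orbital_para <- A3_signed - fc$fermi - dipolar_para
  dipolar_perp <- +Pd * (2 / 7) * alpha2 * (co$a^2 - co$b^2)
  orbital_perp <- Pd * (11 / 14) * mean(dg[1:2])
  structure(list(fermi = fc$fermi, dipolar_para = dipolar_para,
                 dipolar_perp = dipolar_perp, orbital_para = orbital_para,
                 orbital_perp = orbital_perp, alpha2 = alpha2,
                 kappa = fc$kappa, A3_signed = A3_signed,
                 perp_approximate = TRUE),
            class = "hyperfine_decomposition")
}

#' @export
print.hyperfine_decomposition <- function(x, ...) {
  cat("<hyperfine_decomposition> (MHz)\n")
  cat(sprintf("  Fermi contact : %8.1f\n", x$fermi))
  cat(sprintf("  Dipolar  para : %8.1f   perp: %7.1f (approx.)\n",
              x$dipolar_para, x$dipolar_perp))
  cat(sprintf("  Orbital  para : %8.1f   perp: %7.1f (approx.)\n",
              x$orbital_para, x$orbital_perp))
  cat(sprintf("  Spin density alpha^2 = %.3f (kappa = %.4f)\n", x$alpha2, x$kappa))
  invisible(x)
}

#' Recompose the parallel hyperfine component
#'
#' Consistency check: fermi + dipolar_para + orbital_para, which by
#' construction reproduces the signed A3 fed to [decompose_hyperfine()].
#'
#' @param d `hyperfine_decomposition`.
#' @return signed parallel coupling in MHz.
#' @export
recompose_parallel <- function(d) {
  d$fermi + d$dipolar_para + d$orbital_para
}

#' d(z2) mixing fraction b^2
#'
#' Either a fixed value (default 2\%) or a linear estimate from the in-plane
#' g anisotropy, b^2 = c (g2 - g1). The calibration constant defaults to the
#' value that maps the substrate-free g values (g2 - g1 = 0.068) to 0.02.
#'
#' @param g `g_tensor` or numeric triple.
#' @param mode "fixed" or "estimate".
#' @param fixed_b2 value returned in fixed mode.
#' @param calibration slope of the linear estimate (per unit g2 - g1).
#' @return b^2 (clipped to >= 0 with a warning if the estimate is negative).
#' @export
dz2_mixing <- function(g, mode = c("fixed", "estimate"), fixed_b2 = 0.02,
                       calibration = 0.02 / 0.068) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(fixed_b2)
  gv <- if (inherits(g, "g_tensor")) g$g else sort(g)
  b2 <- calibration * (gv[2] - gv[1])
  if (b2 < 0) {
    warning("negative b^2 estimate clipped to 0", call. = FALSE)
    b2 <- 0
  }
  b2
}

#' Thermodynamic coupling between substrate binding and superoxide affinity
#'
#' Container for the five-/four-coordinate Cu-superoxide point-energy
#' differences and their difference ddE = dE1 - dE2.
#'
#' @param dE1,dE2 point-energy differences in kcal/mol.
#' @param temperature temperature in K (> 0).
#' @return object of class `thermo_coupling`.
#' @export
thermo_coupling <- function(dE1, dE2, temperature = 298) {
  .assert_finite(c(dE1, dE2), "energies")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  structure(list(dE1 = dE1, dE2 = dE2, ddE = dE1 - dE2,
                 temperature = temperature), class = "thermo_coupling")
}

#' Equilibrium stabilization ratio from an energy difference
#'
#' exp(ddE / RT), assuming ddG ~ ddE; R = 1.98720e-3 kcal/(mol K).
#'
#' @param tc a `thermo_coupling`, or a plain ddE in kcal/mol.
#' @param temperature temperature in K (used when `tc` is numeric).
#' @return dimensionless stability ratio.
#' @examples
#' stability_ratio(8.2) # about 1.04e6
#' @export
stability_ratio <- function(tc, temperature = 298) {
  if (inherits(tc, "thermo_coupling")) {
    ddE <- tc$ddE; temperature <- tc$temperature
  } else {
    ddE <- tc
  }
  .assert_finite(ddE, "ddE")
  exp(ddE / (hb_constants$R_kcal * temperature))
}

#' Ligand-field decomposition table for a pair of conditions
#'
#' Convenience wrapper running [decompose_hyperfine()] for the
#' substrate-free and substrate-bound parameter sets (including both A1 sign
#' branches when unresolved), producing a contributions table.
#'
#' @param sys_free,sys_bound `spin_system` objects; signs as stored are used
#'   to enumerate Aiso branches.
#' @param b2 d(z2) mixing fraction: a number applied to both conditions, or
#'   NULL (default) to estimate it per condition from the in-plane g
#'   anisotropy via [dz2_mixing()] (the d(z2) admixture collapses together
#'   with g2 - g1 when the site becomes axial).
#' @param Pd dipolar parameter, MHz.
#' @return data.frame with one row per condition/branch: columns condition,
#'   b2, Aiso, fermi, dipolar_para, dipolar_perp, orbital_para,
#'   orbital_perp, spin_density.
#' @export
delft_table <- function(sys_free, sys_bound, b2 = NULL, Pd = 1180) {
  one <- function(sys, condition) {
    b2c <- if (is.null(b2)) dz2_mixing(sys$g, mode = "estimate") else b2
    br <- enumerate_hyperfine_signs(sys$cuA$absA, sys$cuA$signs)
    do.call(rbind, lapply(seq_len(nrow(br)), function(i) {
      d <- decompose_hyperfine(sys$g, br$Aiso[i], br$A3[i], b2 = b2c, Pd = Pd)
      data.frame(condition = condition, b2 = b2c, Aiso = br$Aiso[i],
                 fermi = d$fermi, dipolar_para = d$dipolar_para,
                 dipolar_perp = d$dipolar_perp, orbital_para = d$orbital_para,
                 orbital_perp = d$orbital_perp, spin_density = d$alpha2)
    }))
  }
  rbind(one(sys_free, "no substrate"), one(sys_bound, "substrate"))
}
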