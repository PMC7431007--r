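## Paramagnetic relaxation enhancement from a structural ensemble carrying
## a Cu(II) centre, comparison against observed HSQC intensity ratios, and
## rotational-correlation-time estimation from 15N relaxation.

#' Read a multi-model structural ensemble with a paramagnetic centre
#'
#' Parses MODEL/ENDMDL records of a PDB file (via bio3d), retaining amide
#' N/H atoms and any copper. The paramagnetic centre is located per model
#' either from an explicit Cu atom or as the midpoint of named atoms.
#'
#' @param pdb path to a (multi-MODEL) PDB file.
#' @param center centre rule: `list(type = "cu")` (default; first Cu
#'   atom) or `list(type = "midpoint", resno = c(..), elety = c(..))`
#'   (parallel vectors selecting the atoms to average).
#' @return object of class `structure_ensemble`: list with `atoms` (long
#'   data.frame: model, resno, resid, elety, x, y, z), `centers`
#'   (n_models x 3), `n_models`, `resno` (residues present).
#' @export
read_ensemble <- function(pdb, center = list(type = "cu")) {
  p <- bio3d::read.pdb(pdb, multi = TRUE, verbose = FALSE)
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  if (n_models < 1 || nrow(p$atom) == 0) stop("no models in PDB", call. = FALSE)
  at <- p$atom
  keep <- (at$elety %in% c("N", "H", "HN")) | grepl("^CU", toupper(at$elety)) |
    toupper(at$resid) == "CU"
  idx <- which(keep)
  rows <- lapply(seq_len(n_models), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    data.frame(model = m, resno = at$resno[idx], resid = at$resid[idx],
               elety = at$elety[idx],
               x = co[idx, 1], y = co[idx, 2], z = co[idx, 3],
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  centers <- matrix(NA_real_, n_models, 3)
  for (m in seq_len(n_models)) {
    am <- atoms[atoms$model == m, ]
    if (identical(center$type, "cu")) {
      cu <- am[grepl("^CU", toupper(am$elety)) | toupper(am$resid) == "CU", ]
      if (nrow(cu) < 1)
        stop("paramagnetic centre unresolvable: no Cu atom in model ", m,
             call. = FALSE)
      centers[m, ] <- as.numeric(cu[1, c("x", "y", "z")])
    } else if (identical(center$type, "midpoint")) {
      sel <- mapply(function(rn, el) {
        r <- am[am$resno == rn & am$elety == el, c("x", "y", "z")]
        if (nrow(r) != 1) stop("centre atom ", el, " of residue ", rn,
                               " missing in model ", m, call. = FALSE)
        as.numeric(r)
      }, center$resno, center$elety)
      centers[m, ] <- rowMeans(matrix(sel, nrow = 3))
    } else stop("unknown center rule", call. = FALSE)
  }
  structure(list(atoms = atoms, centers = centers, n_models = n_models,
                 resno = sort(unique(atoms$resno[atoms$elety %in% c("N", "H", "HN")]))),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d models, %d residues with amide atoms\n",
              x$n_models, length(x$resno)))
  invisible(x)
}

#' Ensemble-averaged effective distances to the paramagnetic centre
#'
#' r_eff = <r^-6>^(-1/6) over models, the PRE-appropriate average, for the
#' selected atom of every residue. Residues missing the atom in any model
#' are skipped (recorded in the `skipped` attribute).
#'
#' @param e a `structure_ensemble`.
#' @param atom atom name, default the amide proton "H" (falls back to "HN").
#' @return data.frame with columns `resno`, `r_eff` (Angstrom).
#' @export
effective_distances <- function(e, atom = "H") {
  stopifnot(inherits(e, "structure_ensemble"))
  sel <- e$atoms$elety == atom
  if (!any(sel) && atom == "H") sel <- e$atoms$elety == "HN"
  at <- e$atoms[sel, ]
  res <- sort(unique(at$resno))
  out <- lapply(res, function(rn) {
    a <- at[at$resno == rn, ]
    if (nrow(a) != e$n_models) return(NULL)  # atom missing in some model
    d2 <- (a$x - e$centers[a$model, 1])^2 + (a$y - e$centers[a$model, 2])^2 +
      (a$z - e$centers[a$model, 3])^2
    data.frame(resno = rn, r_eff = mean(d2^(-3))^(-1 / 6))
  })
  skipped <- res[vapply(out, is.null, TRUE)]
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  attr(df, "skipped") <- skipped
  df
}

#' Solomon-Bloembergen transverse PRE rate
#'
#' Gamma2 = (1/15) (mu0/4pi)^2 gammaH^2 giso^2 muB^2 S(S+1) r^-6
#'          \[4 tau_c + 3 tau_c / (1 + omegaH^2 tau_c^2)\], S = 1/2.
#' tau_c is the effective electron-nucleus correlation time; with the
#' electron relaxation time tau_s finite, 1/tau_c = 1/tau_r + 1/tau_s.
#'
#' @param r_eff_A effective distance(s), Angstrom (> 0).
#' @param tau_c_ns rotational correlation time, ns (> 0).
#' @param proton_frequency_MHz 1H Larmor frequency (default 600).
#' @param g_iso isotropic electron g value.
#' @param tau_s_ns electron relaxation time, ns (default Inf:
#'   rotation-dominated).
#' @return Gamma2 in s^-1 (vectorized over `r_eff_A`).
#' @export
gamma2_sb <- function(r_eff_A, tau_c_ns, proton_frequency_MHz = 600,
                      g_iso = 2.128, tau_s_ns = Inf) {
  if (any(!is.finite(r_eff_A)) || any(r_eff_A <= 0))
    stop("r_eff must be positive", call. = FALSE)
  if (!is.finite(tau_c_ns) || tau_c_ns <= 0 || proton_frequency_MHz <= 0 ||
      g_iso <= 0)
    stop("tau_c, proton frequency and g_iso must be positive", call. = FALSE)
  tc <- 1 / (1 / (tau_c_ns * 1e-9) + 1 / (tau_s_ns * 1e-9))
  wH <- 2 * pi * proton_frequency_MHz * 1e6
  pref <- (1 / 15) * hb_constants$mu0_4pi^2 * hb_constants$gamma_rad[["1H"]]^2 *
    g_iso^2 * hb_constants$muB^2 * 0.5 * 1.5
  spectral <- 4 * tc + 3 * tc / (1 + wH^2 * tc^2)
  pref * (r_eff_A * 1e-10)^(-6) * spectral
}

#' HSQC intensity ratio from a PRE rate
#'
#' Battiste-Wagner-style model: ratio = R2 exp(-Gamma2 t) / (R2 + Gamma2),
#' clipped to \[0, 1\]; t is the total INEPT evolution time.
#'
#' @param gamma2 PRE rate, s^-1 (>= 0).
#' @param R2_dia diamagnetic transverse rate, s^-1 (> 0).
#' @param t_evolution evolution time, s (default 0.010).
#' @return predicted paramagnetic/diamagnetic intensity ratio in \[0, 1\].
#' @export
intensity_ratio <- function(gamma2, R2_dia, t_evolution = 0.010) {
  if (any(R2_dia <= 0)) stop("R2_dia must be positive", call. = FALSE)
  if (t_evolution < 0) stop("t_evolution must be >= 0", call. = FALSE)
  pmin(1, pmax(0, R2_dia * exp(-gamma2 * t_evolution) / (R2_dia + gamma2)))
}

#' Relaxation records table
#'
#' Validates a per-residue relaxation table (T1, T2 in seconds, {1H}-15N
#' heteronuclear NOE).
#'
#' @param residue integer residue numbers.
#' @param T1,T2 relaxation times in s (> 0).
#' @param hetNOE heteronuclear NOE (sanity bound <= 1.2).
#' @return data.frame of class `relaxation_table`.
#' @export
relaxation_table <- function(residue, T1, T2, hetNOE) {
  if (any(T1 <= 0) || any(T2 <= 0)) stop("T1, T2 must be > 0", call. = FALSE)
  if (any(hetNOE > 1.2)) stop("hetNOE above sanity bound 1.2", call. = FALSE)
  structure(data.frame(residue = as.integer(residue), T1 = T1, T2 = T2,
                       hetNOE = hetNOE),
            class = c("relaxation_table", "data.frame"))
}

#' Predict a per-residue PRE intensity-ratio profile
#'
#' Composes [effective_distances()], [gamma2_sb()] and [intensity_ratio()]
#' over an ensemble, using per-residue R2 = 1/T2 from a relaxation table
#' when available and a global default otherwise.
#'
#' @param e a `structure_ensemble`.
#' @param relax optional `relaxation_table` (per-residue R2).
#' @param tau_c_ns rotational correlation time, ns.
#' @param g_iso isotropic electron g value.
#' @param proton_frequency_MHz 1H frequency, MHz.
#' @param R2_default fallback diamagnetic R2, s^-1.
#' @param t_evolution INEPT evolution time, s.
#' @param tau_s_ns electron relaxation time, ns.
#' @return data.frame of class `pre_profile`: resno, r_eff, gamma2,
#'   ratio_pred.
#' @export
predict_pre_profile <- function(e, relax = NULL, tau_c_ns = 10.2,
                                g_iso = 2.128, proton_frequency_MHz = 600,
                                R2_default = 15, t_evolution = 0.010,
                                tau_s_ns = Inf) {
  ed <- effective_distances(e)
  if (!is.null(relax)) {
    if (!length(intersect(ed$resno, relax$residue)))
      stop("no residue overlap between ensemble and relaxation table",
           call. = FALSE)
    R2 <- 1 / relax$T2[match(ed$resno, relax$residue)]
    R2[is.na(R2)] <- R2_default
  } else {
    R2 <- rep(R2_default, nrow(ed))
  }
  g2 <- gamma2_sb(ed$r_eff, tau_c_ns, proton_frequency_MHz, g_iso, tau_s_ns)
  out <- data.frame(resno = ed$resno, r_eff = ed$r_eff, gamma2 = g2,
                    ratio_pred = intensity_ratio(g2, R2, t_evolution))
  attr(out, "settings") <- list(
    model = "R2*exp(-Gamma2*t)/(R2+Gamma2)",
    tau_c_ns = tau_c_ns, tau_s_ns = tau_s_ns, g_iso = g_iso,
    proton_frequency_MHz = proton_frequency_MHz, t_evolution = t_evolution)
  class(out) <- c("pre_profile", "data.frame")
  out
}

#' Rotational correlation time from 15N T1/T2
#'
#' tau_c = (1 / (4 pi nuN)) sqrt(6 <T1/T2> - 7), where <.> is the mean of
#' T1/T2 over records passing the filters (hetNOE >= `min_noe`, then T1/T2
#' within `sd_mult` SD of the median). The uncertainty propagates the SD of
#' the retained T1/T2 values through the formula.
#'
#' @param relax a `relaxation_table` (or data.frame with residue, T1, T2,
#'   hetNOE).
#' @param n15_frequency_MHz 15N Larmor frequency, MHz.
#' @param min_noe hetNOE cutoff (default 0.65).
#' @param sd_mult spread cutoff around the median of T1/T2 (default 1.5).
#' @return list with `tau_c_ns`, `uncertainty_ns`, `n_used`, `mean_ratio`.
#' @export
estimate_tauc <- function(relax, n15_frequency_MHz, min_noe = 0.65,
                          sd_mult = 1.5) {
  df <- as.data.frame(relax)
  df <- df[df$hetNOE >= min_noe, ]
  ratio <- df$T1 / df$T2
  if (length(ratio) >= 3) {
    med <- stats::median(ratio); s <- stats::sd(ratio)
    if (is.finite(s) && s > 0) ratio <- ratio[abs(ratio - med) <= sd_mult * s]
  }
  if (length(ratio) < 3)
    stop("fewer than 3 records survive the filters", call. = FALSE)
  m <- mean(ratio)
  if (m < 7 / 6)
    stop("mean T1/T2 below 7/6: tau_c formula undefined", call. = FALSE)
  wN <- 4 * pi * n15_frequency_MHz * 1e6
  tau_c <- sqrt(6 * m - 7) / wN
  ## d tau / d m = 3 / (wN sqrt(6m - 7))
  unc <- 3 / (wN * sqrt(6 * m - 7)) * stats::sd(ratio) / sqrt(length(ratio))
  list(tau_c_ns = tau_c * 1e9, uncertainty_ns = unc * 1e9,
       n_used = length(ratio), mean_ratio = m)
}
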