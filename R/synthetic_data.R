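## Seeded generators producing every input the pipeline consumes, with
## ground truth emitted alongside, so each stage is testable without
## external data. Each channel draws from its own RNG substream derived
## from the master seed, so adding a channel never perturbs the others.

#' Synthetic-data configuration
#'
#' @param seed master integer seed; every generator is a pure function of
#'   its config.
#' @param n_models number of ensemble conformers.
#' @param n_residues chain length (>= 10).
#' @param cu_attach_residue residue the Cu is placed next to.
#' @param coord_jitter per-model Gaussian coordinate jitter, Angstrom.
#' @param relax_noise fractional (lognormal) noise on T1/T2.
#' @param spectrum_snr peak-to-peak signal to noise-SD ratio; `Inf` for
#'   noiseless.
#' @param ratio_sd SD of the truncated-Gaussian noise on intensity ratios.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, n_models = 10, n_residues = 60,
                         cu_attach_residue = 10, coord_jitter = 0.3,
                         relax_noise = 0.05, spectrum_snr = 50,
                         ratio_sd = 0.05) {
  stopifnot(n_residues >= 10, n_models >= 1,
            cu_attach_residue >= 1, cu_attach_residue <= n_residues,
            coord_jitter >= 0, relax_noise >= 0, ratio_sd >= 0,
            spectrum_snr > 0)
  structure(list(seed = as.integer(seed), n_models = n_models,
                 n_residues = n_residues,
                 cu_attach_residue = cu_attach_residue,
                 coord_jitter = coord_jitter, relax_noise = relax_noise,
                 spectrum_snr = spectrum_snr, ratio_sd = ratio_sd),
            class = "synth_config")
}

## named substream seeds below 2^31
.channel_seed <- function(seed, channel) {
  id <- c(ensemble = 1L, relaxation = 2L, spectrum = 3L, intensities = 4L)[channel]
  (as.integer(seed) * 7919L + id * 104729L) %% 2147483647L
}

.pdb_atom_line <- function(serial, name, resid, resno, xyz, het = FALSE,
                           element = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          resid, resno, xyz[1], xyz[2], xyz[3], element)
}

#' Generate a synthetic multi-model ensemble with a Cu centre
#'
#' Schematic extended-chain backbone (N, H, CA per residue, 3.5 Angstrom
#' rise) with per-model Gaussian coordinate jitter and one Cu atom placed
#' 2.1 Angstrom off the amide nitrogen of `cu_attach_residue`. Writes valid
#' multi-MODEL PDB text that [read_ensemble()] round-trips.
#'
#' @param cfg a `synth_config`.
#' @return list with `ensemble` (a `structure_ensemble`), `pdb_text`
#'   (character vector of PDB lines) and `truth` (generator parameters).
#' @export
synth_ensemble <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(.channel_seed(cfg$seed, "ensemble"))
  nres <- cfg$n_residues
  base_N <- cbind(3.5 * seq_len(nres), 0, 0)
  base_H <- base_N + matrix(rep(c(0, -0.98, 0), each = nres), ncol = 3)
  base_CA <- base_N + matrix(rep(c(1.2, 0.8, 0), each = nres), ncol = 3)
  cu0 <- base_N[cfg$cu_attach_residue, ] + c(0, 2.1, 0)
  lines <- character(0)
  for (m in seq_len(cfg$n_models)) {
    jit <- function(co) co + matrix(stats::rnorm(length(co), 0, cfg$coord_jitter),
                                    ncol = 3)
    N <- jit(base_N); H <- jit(base_H); CA <- jit(base_CA)
    cu <- cu0 + stats::rnorm(3, 0, cfg$coord_jitter)
    lines <- c(lines, sprintf("MODEL     %4d", m))
    serial <- 0L
    for (i in seq_len(nres)) {
      serial <- serial + 1L
      lines <- c(lines, .pdb_atom_line(serial, "N", "ALA", i, N[i, ]))
      serial <- serial + 1L
      lines <- c(lines, .pdb_atom_line(serial, "H", "ALA", i, H[i, ]))
      serial <- serial + 1L
      lines <- c(lines, .pdb_atom_line(serial, "CA", "ALA", i, CA[i, ]))
    }
    lines <- c(lines,
               .pdb_atom_line(serial + 1L, "CU", "CU", nres + 1L, cu,
                              het = TRUE, element = "CU"),
               "ENDMDL")
  }
  lines <- c(lines, "END")
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  ens <- read_ensemble(tf)
  unlink(tf)
  list(ensemble = ens, pdb_text = lines,
       truth = list(seed = cfg$seed, n_models = cfg$n_models,
                    cu_attach_residue = cfg$cu_attach_residue,
                    coord_jitter = cfg$coord_jitter))
}

## Reduced spectral densities for rigid isotropic tumbling. The default
## retains only the J(0) and J(omegaN) terms -- the approximation that
## underlies the tau_c = f(T1/T2) estimator -- so the noise-free round trip
## is exact; include_highfreq adds the J(omegaH +/- omegaN) and J(omegaH)
## dipolar terms of the full expressions.
.n15_relaxation_rates <- function(tau_c_ns, nuH_MHz = 600,
                                  include_highfreq = FALSE) {
  tc <- tau_c_ns * 1e-9
  gH <- hb_constants$gamma_rad[["1H"]]
  gN <- hb_constants$gamma_rad[["15N"]]
  wH <- 2 * pi * nuH_MHz * 1e6
  wN <- wH * gN / gH
  J <- function(w) 0.4 * tc / (1 + (w * tc)^2)
  d <- hb_constants$mu0_4pi * gH * gN * hb_constants$hbar / (1.02e-10)^3
  c2 <- (wN * (-160e-6))^2 / 3           # 15N CSA -160 ppm
  hfR1 <- if (include_highfreq) (d^2 / 4) * (J(wH - wN) + 6 * J(wH + wN)) else 0
  hfR2 <- if (include_highfreq)
    (d^2 / 8) * (J(wH - wN) + 6 * J(wH) + 6 * J(wH + wN)) else 0
  R1 <- (d^2 / 4) * 3 * J(wN) + c2 * J(wN) + hfR1
  R2 <- (d^2 / 8) * (4 * J(0) + 3 * J(wN)) + (c2 / 6) * (4 * J(0) + 3 * J(wN)) + hfR2
  noe <- 1 + (d^2 / 4) * (gH / gN) * (6 * J(wH + wN) - J(wH - wN)) / R1
  list(R1 = R1, R2 = R2, noe = noe, nuN_MHz = abs(wN) / (2 * pi) / 1e6)
}

#' Generate a synthetic 15N relaxation table from a known tau_c
#'
#' T1 and T2 follow rigid isotropic tumbling at the configured field with
#' multiplicative lognormal noise; the last `n_flexible` residues emulate a
#' mobile tail (hetNOE < 0.65, lengthened T2) to exercise the filters of
#' [estimate_tauc()].
#'
#' @param tau_c_ns ground-truth rotational correlation time, ns (> 0).
#' @param cfg a `synth_config` (seed, n_residues, relax_noise).
#' @param nuH_MHz proton frequency, MHz.
#' @param n_flexible number of flexible tail residues.
#' @param include_highfreq include the high-frequency spectral-density
#'   terms (introduces the known percent-level bias of the T1/T2 method).
#' @return list with `table` (a `relaxation_table` plus `flexible` column),
#'   `truth` (tau_c, field, nuN).
#' @export
synth_relaxation <- function(tau_c_ns = 10.2, cfg = synth_config(),
                             nuH_MHz = 600, n_flexible = 8,
                             include_highfreq = FALSE) {
  stopifnot(tau_c_ns > 0)
  set.seed(.channel_seed(cfg$seed, "relaxation"))
  rr <- .n15_relaxation_rates(tau_c_ns, nuH_MHz, include_highfreq)
  n <- cfg$n_residues
  noise <- function() exp(stats::rnorm(n, 0, cfg$relax_noise))
  T1 <- (1 / rr$R1) * noise()
  T2 <- (1 / rr$R2) * noise()
  noe <- pmin(1.0, rr$noe * exp(stats::rnorm(n, 0, cfg$relax_noise / 2)))
  flexible <- seq_len(n) > (n - n_flexible)
  T2[flexible] <- T2[flexible] * stats::runif(sum(flexible), 2, 4)
  noe[flexible] <- stats::runif(sum(flexible), 0.1, 0.6)
  tab <- relaxation_table(seq_len(n), T1, T2, noe)
  tab$flexible <- flexible
  list(table = tab,
       truth = list(tau_c_ns = tau_c_ns, nuH_MHz = nuH_MHz,
                    nuN_MHz = rr$nuN_MHz, include_highfreq = include_highfreq,
                    seed = cfg$seed))
}

#' Generate a noisy synthetic CW-EPR spectrum
#'
#' [simulate_powder()] output plus white Gaussian noise scaled so that the
#' peak-to-peak signal over the noise SD equals `snr`.
#'
#' @param sys a `spin_system` (ground truth).
#' @param snr signal-to-noise ratio; `Inf` returns the noiseless spectrum.
#' @param seed integer seed (independent of the simulation).
#' @param ... passed to [simulate_powder()].
#' @return an `epr_spectrum`; ground truth in `metadata$truth`.
#' @export
synth_spectrum <- function(sys, snr = 50, seed = 1, ...) {
  stopifnot(snr > 0)
  clean <- simulate_powder(sys, ...)
  if (is.finite(snr)) {
    set.seed(.channel_seed(seed, "spectrum"))
    sd_noise <- diff(range(clean$intensity)) / snr
    clean$intensity <- clean$intensity +
      stats::rnorm(length(clean$intensity), 0, sd_noise)
  }
  clean$metadata$truth <- list(label = sys$label, snr = snr, seed = seed,
                               g = sys$g$g, absA = sys$cuA$absA)
  clean
}

#' Generate an observed intensity-ratio table from a PRE profile
#'
#' Adds truncated-Gaussian noise (clipped to \[0, 1.2\]) to the predicted
#' ratios and attaches a per-residue error column equal to `sd`.
#'
#' @param profile a `pre_profile` from [predict_pre_profile()].
#' @param sd noise SD.
#' @param seed integer seed.
#' @return data.frame: resno, ratio_obs, ratio_err.
#' @export
synth_intensity_table <- function(profile, sd = 0.05, seed = 1) {
  stopifnot(sd >= 0)
  set.seed(.channel_seed(seed, "intensities"))
  obs <- profile$ratio_pred + stats::rnorm(nrow(profile), 0, sd)
  obs <- pmin(1.2, pmax(0, obs))
  data.frame(resno = profile$resno, ratio_obs = obs, ratio_err = sd)
}
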