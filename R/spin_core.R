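## Tensor bookkeeping shared by all other modules: principal-value
## containers, sign enumeration, isotropic averages, isotopologue rescaling
## and resonance-field arithmetic.

#' Isotropic average of three principal values
#'
#' The rotational average (v1 + v2 + v3) / 3 used for both g_iso and A_iso.
#' Full precision is returned; presentation layers round (g to 3 decimals,
#' A_iso to integer MHz).
#'
#' @param v1,v2,v3 principal values; alternatively `v1` may be a length-3
#'   vector and `v2`/`v3` omitted.
#' @return scalar mean of the three values.
#' @examples
#' isotropic_average(2.027, 2.095, 2.261) # 2.1277
#' @export
isotropic_average <- function(v1, v2 = NULL, v3 = NULL) {
  v <- if (is.null(v2)) v1 else c(v1, v2, v3)
  if (length(v) != 3L) stop("need exactly three principal values", call. = FALSE)
  .assert_finite(v, "principal values")
  mean(v)
}

#' g tensor principal values
#'
#' Constructs a g-tensor container with the ordering convention
#' g1 <= g2 <= g3. Inputs violating the ordering are re-sorted with a
#' warning; values outside the Cu(II)-plausible window (1.8, 2.6) warn but
#' do not fail.
#'
#' @param g1,g2,g3 dimensionless principal values (or a length-3 vector as
#'   `g1`).
#' @return object of class `g_tensor`: list with `g` (sorted triple) and
#'   `giso`.
#' @export
g_tensor <- function(g1, g2 = NULL, g3 = NULL) {
  g <- if (is.null(g2)) g1 else c(g1, g2, g3)
  if (length(g) != 3L) stop("need exactly three g values", call. = FALSE)
  .assert_finite(g, "g values")
  if (is.unsorted(g)) {
    warning("g values re-sorted to enforce g1 <= g2 <= g3", call. = FALSE)
    g <- sort(g)
  }
  if (any(g <= 1.8 | g >= 2.6))
    warning("g value outside (1.8, 2.6): unusual for Cu(II)", call. = FALSE)
  structure(list(g = unname(g), giso = mean(g)), class = "g_tensor")
}

#' @export
print.g_tensor <- function(x, ...) {
  cat(sprintf("<g_tensor> g = (%.3f, %.3f, %.3f), giso = %.3f\n",
              x$g[1], x$g[2], x$g[3], x$giso))
  invisible(x)
}

#' Delta-g values relative to the free electron
#'
#' @param g a `g_tensor` or numeric triple.
#' @param ge reference g value (free-electron 2.0023).
#' @return numeric triple g_n - ge.
#' @export
delta_g <- function(g, ge = hb_constants$ge) {
  gv <- if (inherits(g, "g_tensor")) g$g else g
  gv - ge
}

#' Copper hyperfine coupling with per-axis sign state
#'
#' CW-EPR determines only |A_n|; signs come from external (quantum-chemical)
#' information and may be unresolved. A_iso is defined only when all three
#' signs are resolved.
#'
#' @param absA length-3 vector of magnitudes in MHz (>= 0).
#' @param signs length-3 character vector, each of "+", "-", "?".
#' @return object of class `cu_hyperfine` with fields `absA`, `signs`, and
#'   `Aiso` (NA unless all signs resolved).
#' @export
cu_hyperfine <- function(absA, signs = c("?", "?", "?")) {
  if (length(absA) != 3L || any(!is.finite(absA)) || any(absA < 0))
    stop("absA must be three finite non-negative magnitudes (MHz)", call. = FALSE)
  signs <- as.character(signs)
  if (length(signs) != 3L || !all(signs %in% c("+", "-", "?")))
    stop('signs must be three of "+", "-", "?"', call. = FALSE)
  Aiso <- NA_real_
  if (!any(signs == "?")) {
    s <- ifelse(signs == "+", 1, -1)
    Aiso <- mean(s * absA)
  }
  structure(list(absA = unname(absA), signs = signs, Aiso = Aiso),
            class = "cu_hyperfine")
}

#' Enumerate hyperfine sign assignments compatible with constraints
#'
#' Lists every assignment of signs to the three |A| magnitudes allowed by the
#' per-axis constraints, with the resulting A_iso. Ordering is lexicographic
#' over (s1, s2, s3) with "+" before "-".
#'
#' @param magnitudes length-3 vector of |A| in MHz.
#' @param constraints length-3 character vector of "+", "-", "?" ("?" =
#'   unknown sign, both branches enumerated).
#' @return data.frame with columns s1, s2, s3 (+1/-1), A1, A2, A3 (signed
#'   MHz) and Aiso.
#' @examples
#' enumerate_hyperfine_signs(c(80, 85, 620), c("?", "-", "-"))
#' @export
enumerate_hyperfine_signs <- function(magnitudes, constraints = c("?", "?", "?")) {
  if (length(magnitudes) != 3L || any(!is.finite(magnitudes)) || any(magnitudes < 0))
    stop("magnitudes must be three finite non-negative values", call. = FALSE)
  constraints <- as.character(constraints)
  if (length(constraints) != 3L || !all(constraints %in% c("+", "-", "?")))
    stop('constraints must be three of "+", "-", "?"', call. = FALSE)
  choices <- lapply(constraints, function(ct)
    switch(ct, "+" = 1, "-" = -1, "?" = c(1, -1)))
  ## expand.grid varies the first factor fastest; build so s1 varies slowest
  ## and "+" (=1) precedes "-" for lexicographic order
  grid <- expand.grid(s3 = choices[[3]], s2 = choices[[2]], s1 = choices[[1]],
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("s1", "s2", "s3")]
  A <- t(t(as.matrix(grid)) * 1) * rep(magnitudes, each = nrow(grid))
  out <- data.frame(grid,
                    A1 = A[, 1], A2 = A[, 2], A3 = A[, 3],
                    Aiso = rowMeans(A))
  rownames(out) <- NULL
  out
}

#' Resonance field for an effective g value
#'
#' Center-field arithmetic: B = h nu / (g mu_B), returned in mT.
#'
#' @param g_eff dimensionless effective g value (> 0).
#' @param frequency_GHz microwave frequency in GHz (> 0).
#' @return field in mT.
#' @examples
#' resonance_field(2.0023, 9.3046) # ~332.0 mT
#' @export
resonance_field <- function(g_eff, frequency_GHz) {
  if (any(!is.finite(g_eff)) || any(g_eff <= 0))
    stop("g_eff must be positive and finite", call. = FALSE)
  if (any(!is.finite(frequency_GHz)) || any(frequency_GHz <= 0))
    stop("frequency must be positive and finite", call. = FALSE)
  ## h*nu/(g*muB) in Tesla, then mT
  hb_constants$h * frequency_GHz * 1e9 / (g_eff * hb_constants$muB) * 1e3
}

#' Rescale a nitrogen coupling between isotopologues
#'
#' Hyperfine couplings scale with the nuclear gyromagnetic ratio;
#' |gamma(15N)/gamma(14N)| = 1.4027.
#'
#' @param value coupling in MHz.
#' @param from_isotope,to_isotope one of "14N", "15N".
#' @return rescaled coupling in MHz.
#' @examples
#' rescale_nitrogen_coupling(43, "14N", "15N") # 60.3
#' @export
rescale_nitrogen_coupling <- function(value, from_isotope, to_isotope) {
  ok <- c("14N", "15N")
  if (!(from_isotope %in% ok) || !(to_isotope %in% ok))
    stop('isotopes must be "14N" or "15N"', call. = FALSE)
  .assert_finite(value, "coupling")
  r <- hb_constants$ratio_15N_14N
  fac <- if (from_isotope == to_isotope) 1 else if (to_isotope == "15N") r else 1 / r
  value * fac
}

#' Superhyperfine-coupled nitrogen nucleus
#'
#' One principal coupling value per nucleus (the component along the Cu-N
#' bond, the only one resolvable from CW powder spectra).
#'
#' @param principal_value coupling in MHz (>= 0).
#' @param isotope "14N" or "15N".
#' @param assignment "His", "NH2" or "unknown".
#' @return object of class `nitrogen_shf`.
#' @export
nitrogen_shf <- function(principal_value, isotope = "14N", assignment = "unknown") {
  if (!is.finite(principal_value) || principal_value < 0)
    stop("principal value must be finite and >= 0", call. = FALSE)
  if (!(isotope %in% c("14N", "15N"))) stop("unknown isotope", call. = FALSE)
  if (!(assignment %in% c("His", "NH2", "unknown")))
    stop("assignment must be His, NH2 or unknown", call. = FALSE)
  structure(list(principal_value = principal_value, isotope = isotope,
                 assignment = assignment), class = "nitrogen_shf")
}

#' Complete CW-EPR model of one Cu(II) species
#'
#' Bundles everything the powder simulator needs: g tensor, 63Cu hyperfine
#' (I = 3/2), nitrogen superhyperfine couplings, g- and A-strains, residual
#' linewidths and microwave frequency. Electron spin is fixed at 1/2.
#'
#' @param g `g_tensor` or numeric triple.
#' @param cuA `cu_hyperfine` or numeric triple of |A| in MHz.
#' @param signs optional sign vector when `cuA` is numeric.
#' @param nitrogens list of `nitrogen_shf` objects (possibly empty).
#' @param g_strain dimensionless triple >= 0 (Gaussian widths of g_n).
#' @param A_strain MHz triple >= 0 (Gaussian widths of A_n).
#' @param linewidths length-2 vector, Gaussian and Lorentzian peak-to-peak
#'   widths in mT.
#' @param mw_frequency_GHz microwave frequency in GHz (> 0).
#' @param label free-form species label.
#' @return object of class `spin_system`.
#' @export
spin_system <- function(g, cuA, signs = NULL, nitrogens = list(),
                        g_strain = c(0, 0, 0), A_strain = c(0, 0, 0),
                        linewidths = c(0.5, 0.5), mw_frequency_GHz = 9.3,
                        label = "") {
  if (!inherits(g, "g_tensor")) g <- g_tensor(g)
  if (!inherits(cuA, "cu_hyperfine"))
    cuA <- cu_hyperfine(cuA, if (is.null(signs)) c("?", "?", "?") else signs)
  stopifnot(length(g_strain) == 3L, length(A_strain) == 3L,
            length(linewidths) == 2L)
  if (any(g_strain < 0) || any(A_strain < 0) || any(linewidths < 0))
    stop("strains and linewidths must be >= 0", call. = FALSE)
  if (!is.finite(mw_frequency_GHz) || mw_frequency_GHz <= 0)
    stop("frequency must be positive", call. = FALSE)
  if (length(nitrogens) && !all(vapply(nitrogens, inherits, TRUE, "nitrogen_shf")))
    stop("nitrogens must be a list of nitrogen_shf objects", call. = FALSE)
  structure(list(electron_spin = 0.5, cu_isotope = "63Cu", cu_I = 1.5,
                 g = g, cuA = cuA, nitrogens = nitrogens,
                 g_strain = unname(g_strain), A_strain = unname(A_strain),
                 linewidths = unname(linewidths),
                 mw_frequency_GHz = mw_frequency_GHz, label = label),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  g      = (%.4f, %.4f, %.4f)  giso = %.4f\n",
              x$g$g[1], x$g$g[2], x$g$g[3], x$g$giso))
  cat(sprintf("  |A|    = (%g, %g, %g) MHz, signs (%s)%s\n",
              x$cuA$absA[1], x$cuA$absA[2], x$cuA$absA[3],
              paste(x$cuA$signs, collapse = " "),
              if (is.na(x$cuA$Aiso)) "" else sprintf(", Aiso = %.1f MHz", x$cuA$Aiso)))
  if (length(x$nitrogens))
    cat(sprintf("  N SHF  = %s MHz\n",
                paste(vapply(x$nitrogens, function(n)
                  sprintf("%g (%s %s)", n$principal_value, n$isotope, n$assignment),
                  character(1)), collapse = ", ")))
  cat(sprintf("  mw     = %.4f GHz; lw (G, L) = (%g, %g) mT\n",
              x$mw_frequency_GHz, x$linewidths[1], x$linewidths[2]))
  invisible(x)
}

## ---- spin-system table I/O -------------------------------------------------

.sys_to_row <- function(sys) {
  data.frame(
    label = sys$label,
    g1 = sys$g$g[1], g2 = sys$g$g[2], g3 = sys$g$g[3],
    absA1 = sys$cuA$absA[1], absA2 = sys$cuA$absA[2], absA3 = sys$cuA$absA[3],
    sA1 = sys$cuA$signs[1], sA2 = sys$cuA$signs[2], sA3 = sys$cuA$signs[3],
    shf_values = paste(vapply(sys$nitrogens, function(n) n$principal_value,
                              numeric(1)), collapse = ";"),
    shf_assignment = paste(vapply(sys$nitrogens, function(n) n$assignment,
                                  character(1)), collapse = ";"),
    g_strain = paste(sys$g_strain, collapse = ";"),
    A_strain = paste(sys$A_strain, collapse = ";"),
    lw_gauss = sys$linewidths[1], lw_lorentz = sys$linewidths[2],
    freq_GHz = sys$mw_frequency_GHz,
    isotope = if (length(sys$nitrogens)) sys$nitrogens[[1]]$isotope else "14N",
    stringsAsFactors = FALSE)
}

.row_to_sys <- function(row) {
  split_num <- function(s) if (is.na(s) || !nzchar(s)) numeric(0) else
    as.numeric(strsplit(as.character(s), ";")[[1]])
  split_chr <- function(s) if (is.na(s) || !nzchar(s)) character(0) else
    strsplit(as.character(s), ";")[[1]]
  shf <- split_num(row$shf_values)
  asg <- split_chr(row$shf_assignment)
  if (!length(asg)) asg <- rep("unknown", length(shf))
  nitrogens <- Map(function(v, a) nitrogen_shf(v, as.character(row$isotope), a),
                   shf, asg)
  spin_system(
    g = c(row$g1, row$g2, row$g3),
    cuA = c(row$absA1, row$absA2, row$absA3),
    signs = c(row$sA1, row$sA2, row$sA3),
    nitrogens = unname(nitrogens),
    g_strain = split_num(row$g_strain),
    A_strain = split_num(row$A_strain),
    linewidths = c(row$lw_gauss, row$lw_lorentz),
    mw_frequency_GHz = row$freq_GHz,
    label = as.character(row$label))
}

#' Read / write spin-system tables
#'
#' CSV (or JSON) tables with one row per species, columns `label, g1, g2,
#' g3, absA1..3, sA1..3, shf_values, shf_assignment, g_strain, A_strain,
#' lw_gauss, lw_lorentz, freq_GHz, isotope`. Triples inside a cell are
#' semicolon-separated.
#'
#' @param path file path; `.json` is auto-detected, everything else is CSV.
#' @return named list of `spin_system` objects.
#' @export
read_spin_systems <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
      shf_values = "character", shf_assignment = "character",
      g_strain = "character", A_strain = "character"))
  }
  out <- lapply(seq_len(nrow(df)), function(i) .row_to_sys(df[i, ]))
  names(out) <- df$label
  out
}

#' @rdname read_spin_systems
#' @param systems list of `spin_system` objects.
#' @export
write_spin_systems <- function(systems, path) {
  df <- do.call(rbind, lapply(systems, .sys_to_row))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Bundled spin-system parameter sets for Cu(II)-LPMO10A
#'
#' The six fitted CW-EPR parameter sets (14N/15N isotopologues at X- and
#' Q-band, with and without beta-chitin) shipped with the package.
#'
#' @return named list of `spin_system` objects.
#' @export
lpmo_spin_systems <- function() {
  read_spin_systems(system.file("extdata", "cu_lpmo_spin_systems.csv",
                                package = "histbrace", mustWork = TRUE))
}
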