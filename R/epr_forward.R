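## Forward simulation of field-swept CW powder EPR spectra for S = 1/2
## coupled to 63Cu (I = 3/2) with nitrogen superhyperfine structure, an
## exact-diagonalization oracle, and bounded least-squares refinement.
##
## The working engine treats the Cu hyperfine to second order in
## A / (g muB B) with the nuclear sub-blocks handled exactly; nitrogen
## couplings enter to first order as equal-amplitude splitting combs.
## g, A(Cu) and A(N) principal frames are taken as coincident.

## ---- spin operators --------------------------------------------------------

.spin_ops <- function(I) {
  m <- seq(I, -I, by = -1); n <- length(m)
  Ip <- matrix(0, n, n)
  if (n > 1) for (k in 2:n) Ip[k - 1, k] <- sqrt(I * (I + 1) - m[k] * (m[k] + 1))
  list(x = (Ip + t(Ip)) / 2, y = (Ip - t(Ip)) / (2i), z = diag(m, n))
}

## ---- orientation grids -----------------------------------------------------

#' Orientation quadrature grid on the unit sphere
#'
#' Product quadrature over one octant (sufficient for coincident
#' orthorhombic tensors): Gauss-Legendre nodes in cos(theta) and a midpoint
#' rule in phi. Weights sum to 1.
#'
#' @param n_theta number of polar knots (default 31, about 3 degrees).
#' @param n_phi number of azimuthal knots (default 16).
#' @return object of class `orientation_grid`: list with `vectors`
#'   (count x 3 matrix of unit vectors) and `weights` (summing to 1).
#' @export
orientation_grid <- function(n_theta = 31, n_phi = 16) {
  stopifnot(n_theta >= 1, n_phi >= 1)
  gl <- .gauss_legendre(n_theta, 0, 1)       # nodes in cos(theta)
  phi <- (seq_len(n_phi) - 0.5) * (pi / 2) / n_phi
  ct <- rep(gl$nodes, each = n_phi)
  st <- sqrt(pmax(0, 1 - ct^2))
  cp <- rep(cos(phi), times = n_theta)
  sp <- rep(sin(phi), times = n_theta)
  vectors <- cbind(st * cp, st * sp, ct)
  weights <- rep(gl$weights, each = n_phi) / n_phi
  structure(list(vectors = vectors, weights = weights / sum(weights),
                 n_theta = n_theta, n_phi = n_phi),
            class = "orientation_grid")
}

## Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenproblem.
.gauss_legendre <- function(n, a = -1, b = 1) {
  if (n == 1) return(list(nodes = (a + b) / 2, weights = b - a))
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta; J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (a + b) / 2 + (b - a) / 2 * x[ord],
       weights = (b - a) / 2 * w[ord])
}

## ---- spectra ---------------------------------------------------------------

#' First-derivative EPR spectrum container
#'
#' @param field_axis strictly increasing uniform grid, mT.
#' @param intensity same length as `field_axis` (derivative lineshape).
#' @param mw_frequency_GHz microwave frequency, GHz.
#' @param metadata free-form list.
#' @return object of class `epr_spectrum`.
#' @export
epr_spectrum <- function(field_axis, intensity, mw_frequency_GHz,
                         metadata = list()) {
  if (length(field_axis) != length(intensity))
    stop("axis and intensity lengths differ", call. = FALSE)
  d <- diff(field_axis)
  if (any(d <= 0) || (max(d) - min(d)) > 1e-9 * max(abs(field_axis)))
    stop("field axis must be a strictly increasing uniform grid", call. = FALSE)
  structure(list(field = field_axis, intensity = intensity,
                 mw_frequency_GHz = mw_frequency_GHz, metadata = metadata),
            class = "epr_spectrum")
}

#' @export
print.epr_spectrum <- function(x, ...) {
  cat(sprintf("<epr_spectrum> %d points, %.2f-%.2f mT @ %.4f GHz\n",
              length(x$field), min(x$field), max(x$field), x$mw_frequency_GHz))
  invisible(x)
}

#' Write / read a spectrum as two-column text plus JSON sidecar
#'
#' @param spec an `epr_spectrum`.
#' @param path data file path; the sidecar is `<path>.json`.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.table(data.frame(field_mT = spec$field, intensity = spec$intensity),
                     path, row.names = FALSE, col.names = TRUE, quote = FALSE)
  jsonlite::write_json(c(list(mw_frequency_GHz = spec$mw_frequency_GHz),
                         spec$metadata),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::fromJSON(side) else list()
  nu <- meta$mw_frequency_GHz
  meta$mw_frequency_GHz <- NULL
  epr_spectrum(df[[1]], df[[2]], nu, meta)
}

## ---- resonance-field engines ----------------------------------------------

## Vectorized second-order resonance fields for the Cu manifold.
## orientations: n x 3 unit vectors. Returns list of matrices (n x 4):
## fields (mT), plus per-orientation geff, K (MHz), u (n x 3).
.cu_resonances <- function(g, A, nu_GHz, orientations) {
  n <- orientations
  if (is.null(dim(n))) n <- matrix(n, 1)
  nu <- nu_GHz * 1e3                      # MHz
  g2 <- n^2 %*% g^2
  geff <- sqrt(g2[, 1])
  u <- n * rep(g, each = nrow(n)) / geff  # electron axis in principal frame
  u2 <- u^2
  K2 <- u2 %*% A^2
  K <- sqrt(K2[, 1])
  alpha <- (u2 %*% A^4)[, 1] / pmax(K2[, 1], .Machine$double.eps) - K2[, 1]
  Ttot <- sum(A^2) - K2[, 1]
  beta <- Ttot - alpha
  conv <- .mhz_per_mT_g1 * geff           # MHz per mT
  Ii <- 1.5
  mI <- seq(-Ii, Ii, by = 1)
  fields <- matrix(NA_real_, nrow(n), length(mI))
  for (j in seq_along(mI)) {
    C <- alpha * mI[j]^2 + beta * (Ii * (Ii + 1) - mI[j]^2) / 2
    bq <- -(nu - K * mI[j])
    disc <- bq^2 - 4 * conv * (C / (2 * conv))
    fields[, j] <- (-bq + sqrt(pmax(disc, 0))) / (2 * conv)
  }
  list(fields = fields, geff = geff, K = K, u = u, mI = mI, conv = conv)
}

#' Second-order perturbative resonance fields
#'
#' Resonance fields and amplitudes for one orientation: Cu hyperfine
#' treated by diagonalizing the second-order effective nuclear Hamiltonian
#' within each electron-spin manifold (second order in A/(g muB B) with
#' nuclear-state mixing retained), nitrogen superhyperfine to first order
#' as equal-amplitude multiplets (1:1:1 per 14N, 1:1 per 15N). A warning is
#' attached when the perturbation parameter max|A|/(h nu) exceeds 0.15.
#'
#' @param sys a `spin_system`.
#' @param orientation unit 3-vector in the tensor principal frame.
#' @param shf include nitrogen superhyperfine splittings.
#' @return data.frame with columns `field` (mT) and `amplitude`; attribute
#'   `warning` carries the perturbation-validity message when triggered.
#' @export
resonance_fields_perturbative <- function(sys, orientation, shf = TRUE) {
  orientation <- orientation / sqrt(sum(orientation^2))
  ref <- .cu_resonances_block(sys$g$g, sys$cuA$absA, sys$mw_frequency_GHz,
                              orientation)
  amp0 <- .transition_amp(sys$g$g, matrix(orientation, 1))[1]
  out <- data.frame(field = ref$fields,
                    amplitude = amp0 * ref$amps / sum(ref$amps))
  res <- list(u = matrix(ref$u, 1), conv = ref$conv)
  if (shf && length(sys$nitrogens)) {
    off <- .shf_offsets(sys, res$u[1, , drop = FALSE], res$conv[1])
    out <- data.frame(
      field = as.vector(outer(off$offsets[1, ], out$field, "+")),
      amplitude = as.vector(outer(rep(1 / ncol(off$offsets), ncol(off$offsets)),
                                  out$amplitude, "*")))
  }
  out <- out[order(out$field), ]
  rownames(out) <- NULL
  pp <- max(sys$cuA$absA) / (sys$mw_frequency_GHz * 1e3)
  if (pp > 0.15)
    attr(out, "warning") <- sprintf(
      "perturbation parameter %.2f > 0.15: second-order treatment may be inaccurate", pp)
  out
}

## Per-orientation Cu resonance fields from the second-order effective
## nuclear Hamiltonian, diagonalized within each mS block (retains the
## nuclear-state mixing the closed-form expectation drops). Fixed-point
## iteration on the field through the 1/(g muB B) denominators.
.cu_resonances_block <- function(g, A, nu_GHz, nvec) {
  nu <- nu_GHz * 1e3
  geff <- sqrt(sum(g^2 * nvec^2)); u <- g * nvec / geff
  v <- if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(0, -u[3], u[2])
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  I <- .spin_ops(1.5)
  dot <- function(p) p[1] * I$x + p[2] * I$y + p[3] * I$z
  Kop <- dot(A * u)
  Fop <- dot(A * v) + 1i * dot(A * w)
  Gop <- dot(A * v) - 1i * dot(A * w)
  GF <- Gop %*% Fop; FG <- Fop %*% Gop
  conv <- .mhz_per_mT_g1 * geff
  solve_one <- function(i) {
    B <- nu / conv; dE <- 0; amp <- 1
    for (it in 1:8) {
      D <- conv * B
      ep <- eigen(0.5 * Kop + GF / (4 * D), symmetric = TRUE)
      em <- eigen(-0.5 * Kop - FG / (4 * D), symmetric = TRUE)
      ov <- abs(Conj(t(em$vectors)) %*% ep$vectors)^2
      pair <- apply(ov, 2, which.max)
      dE_new <- (ep$values - em$values[pair])[i]
      amp <- ov[pair[i], i]
      Bn <- (nu - dE_new) / conv
      if (abs(Bn - B) < 1e-7 && it > 1) { B <- Bn; break }
      B <- Bn
    }
    c(B, amp)
  }
  sol <- vapply(1:4, solve_one, numeric(2))
  ord <- order(sol[1, ])
  list(fields = sol[1, ord], amps = sol[2, ord], u = u, conv = conv,
       geff = geff)
}

## Standard S=1/2 powder transition probability (perpendicular-mode),
## combined with the Aasa-Vanngard 1/g frequency-to-field factor.
.transition_amp <- function(g, orientations) {
  n2 <- orientations^2
  g2 <- (n2 %*% g^2)[, 1]
  gp2 <- (g[1]^2 * g[2]^2 * n2[, 3] + g[2]^2 * g[3]^2 * n2[, 1] +
            g[1]^2 * g[3]^2 * n2[, 2]) / g2
  ## transition moment ~ (g1g2g3/geff)^2-ish; use gp2 (perp g^2) over geff
  gp2 / sqrt(g2) / g2  # includes 1/g Aasa-Vanngard factor and 1/geff dB/dnu
}

## First-order nitrogen superhyperfine field offsets for given electron
## axes u (n x 3). Each nitrogen has tensor (p, f p, f p) with its unique
## axis along an in-plane principal axis (alternating 1, 2, 1, ...).
## Returns offsets matrix n x n_comb and the multiplet size.
.shf_offsets <- function(sys, u, conv, minor_fraction = 2 / 3) {
  stopifnot(length(sys$nitrogens) > 0)
  u2 <- u^2
  combs <- list()
  for (k in seq_along(sys$nitrogens)) {
    nit <- sys$nitrogens[[k]]
    p <- nit$principal_value
    axis <- if (k %% 2 == 1) 1L else 2L
    Av <- rep(minor_fraction * p, 3); Av[axis] <- p
    Aeff <- sqrt((u2 %*% Av^2)[, 1])     # MHz, along electron axis
    mI <- if (nit$isotope == "14N") c(-1, 0, 1) else c(-0.5, 0.5)
    combs[[k]] <- outer(Aeff / conv, mI)  # mT offsets, n x n_mI
  }
  offsets <- combs[[1]]
  if (length(combs) > 1) for (k in 2:length(combs)) {
    offsets <- offsets[, rep(seq_len(ncol(offsets)), times = ncol(combs[[k]])),
                       drop = FALSE] +
      combs[[k]][, rep(seq_len(ncol(combs[[k]])), each = ncol(offsets)),
                 drop = FALSE]
  }
  list(offsets = offsets, n_comb = ncol(offsets))
}

#' Exact-diagonalization resonance fields (oracle engine)
#'
#' Finds resonance fields by bisection on the eigen-energy differences of
#' the full electron-Zeeman + hyperfine Hamiltonian (S = 1/2 coupled to
#' 63Cu I = 3/2; nitrogen nuclei optionally included to first order are
#' excluded here, matching the perturbative Cu comb). Amplitudes come from
#' transition-moment matrix elements of S_x (perpendicular mode).
#'
#' @param sys a `spin_system`.
#' @param orientation unit 3-vector.
#' @param window field search window in mT (default auto from g and A).
#' @param step scan step for bracketing, mT.
#' @return data.frame with columns `field` (mT) and `amplitude`; empty if no
#'   resonance falls inside the window.
#' @export
eigenfields_exact <- function(sys, orientation, window = NULL, step = 0.5) {
  orientation <- orientation / sqrt(sum(orientation^2))
  g <- sys$g$g; A <- sys$cuA$absA
  nu <- sys$mw_frequency_GHz * 1e3       # MHz
  if (is.null(window)) {
    Bc <- resonance_field(c(min(g), max(g)), sys$mw_frequency_GHz)
    spread <- (max(A) * 2.5) / (.mhz_per_mT_g1 * min(g)) + 2
    window <- c(max(min(Bc) - spread, 1), max(Bc) + spread)
  }
  S <- .spin_ops(0.5); I <- .spin_ops(1.5)
  Id4 <- diag(4)
  HZ1 <- .mhz_per_mT_g1 *
    (g[1] * orientation[1] * kronecker(S$x, Id4) +
     g[2] * orientation[2] * kronecker(S$y, Id4) +
     g[3] * orientation[3] * kronecker(S$z, Id4))   # MHz per mT
  HF <- A[1] * kronecker(S$x, I$x) + A[2] * kronecker(S$y, I$y) +
    A[3] * kronecker(S$z, I$z)
  ## perpendicular transition operator: S_x in the lab frame; build a unit
  ## vector perpendicular to the field direction
  perp <- if (abs(orientation[3]) < 0.9) c(-orientation[2], orientation[1], 0) else
    c(0, -orientation[3], orientation[2])
  perp <- perp / sqrt(sum(perp^2))
  Sx_lab <- g[1] * perp[1] * kronecker(S$x, Id4) +
    g[2] * perp[2] * kronecker(S$y, Id4) + g[3] * perp[3] * kronecker(S$z, Id4)
  eigsys <- function(B) eigen(HZ1 * B + HF, symmetric = FALSE)
  diffs <- function(B) {
    ev <- sort(Re(eigen(HZ1 * B + HF, only.values = TRUE)$values))
    as.vector(outer(ev[5:8], ev[1:4], "-")) - nu
  }
  Bs <- seq(window[1], window[2], by = step)
  vals <- vapply(Bs, diffs, numeric(16))
  roots <- numeric(0)
  for (i in seq_len(nrow(vals))) {
    hit <- which(vals[i, ] == 0)          # root exactly on a scan point
    roots <- c(roots, Bs[hit])
    sgn <- vals[i, -1] * vals[i, -ncol(vals)]
    for (k in which(sgn < 0)) {
      lo <- Bs[k]; hi <- Bs[k + 1]; flo <- vals[i, k]
      for (it in 1:50) {
        mid <- (lo + hi) / 2
        fm <- diffs(mid)[i]
        if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  if (!length(roots)) return(data.frame(field = numeric(0), amplitude = numeric(0)))
  roots <- sort(roots)
  amp <- vapply(roots, function(B) {
    es <- eigsys(B)
    ev <- Re(es$values); ord <- order(ev)
    V <- es$vectors[, ord]
    M <- abs(Conj(t(V[, 5:8])) %*% Sx_lab %*% V[, 1:4])^2
    max(Re(M))
  }, numeric(1))
  data.frame(field = roots, amplitude = amp)
}

## ---- powder simulation -----------------------------------------------------

#' Simulate a field-swept CW powder EPR spectrum
#'
#' Orientation-weighted accumulation of second-order Cu resonance lines with
#' first-order nitrogen superhyperfine structure. Each line gets a Gaussian
#' width from the quadrature sum of the residual Gaussian linewidth and the
#' g-/A-strain contributions propagated to field via first-order
#' derivatives; the accumulated absorption is convolved with a Lorentzian of
#' the residual Lorentzian width (pseudo-Voigt) and differentiated.
#' Deterministic for fixed inputs.
#'
#' @param sys a `spin_system`.
#' @param grid an `orientation_grid`.
#' @param field_axis uniform mT grid, or NULL to auto-build one spanning all
#'   resonances.
#' @param n_points axis length when auto-building.
#' @param shf include nitrogen superhyperfine structure.
#' @param scale "number of spins" amplitude factor.
#' @param clip drop lines outside a supplied axis silently instead of
#'   erroring (used internally by the fitter).
#' @return an `epr_spectrum` (first-derivative lineshape).
#' @export
simulate_powder <- function(sys, grid = orientation_grid(),
                            field_axis = NULL, n_points = 1024,
                            shf = TRUE, scale = 1, clip = FALSE) {
  g <- sys$g$g; A <- sys$cuA$absA
  res <- .cu_resonances(g, A, sys$mw_frequency_GHz, grid$vectors)
  fields <- res$fields                          # n x 4
  nOri <- nrow(fields)
  amp0 <- .transition_amp(g, grid$vectors) * grid$weights
  ## strain widths (per orientation, per mI): first-order derivatives
  u2 <- res$u^2
  n2 <- grid$vectors^2
  g2 <- (n2 %*% g^2)[, 1]
  sigB2_g <- matrix(0, nOri, 4)
  sigB2_A <- matrix(0, nOri, 4)
  Kk <- pmax(res$K, 1e-9)
  for (j in 1:4) {
    mI <- res$mI[j]
    dBdg <- -fields[, j] * t(t(n2) * g) / g2    # n x 3
    sigB2_g[, j] <- (dBdg^2 %*% sys$g_strain^2)[, 1]
    dBdA <- -mI * t(t(u2) * A) / (Kk * res$conv)  # mT per MHz
    sigB2_A[, j] <- (dBdA^2 %*% sys$A_strain^2)[, 1]
  }
  sig_res <- sys$linewidths[1] / 2              # pp -> sd for deriv. Gaussian
  sigma <- sqrt(sigB2_g + sigB2_A + sig_res^2)  # n x 4
  ## superhyperfine offsets
  if (shf && length(sys$nitrogens)) {
    off <- .shf_offsets(sys, res$u, res$conv)
    n_comb <- off$n_comb
    centers <- matrix(NA_real_, nOri, 4 * n_comb)
    for (j in 1:4)
      centers[, ((j - 1) * n_comb + 1):(j * n_comb)] <- fields[, j] + off$offsets
    sigma <- sigma[, rep(1:4, each = n_comb), drop = FALSE]
    amps <- matrix(amp0 / (4 * n_comb), nOri, 4 * n_comb)
  } else {
    centers <- fields
    amps <- matrix(amp0 / 4, nOri, 4)
  }
  cvec <- as.vector(centers); svec <- as.vector(sigma); avec <- as.vector(amps)
  if (is.null(field_axis)) {
    pad <- 4 * max(svec) + 2 * sum(sys$linewidths)
    field_axis <- seq(min(cvec) - pad, max(cvec) + pad, length.out = n_points)
  } else {
    outside <- cvec < min(field_axis) | cvec > max(field_axis)
    if (any(outside) && !clip) {
      stop(sprintf("%d resonance lines fall outside the field window [%.1f, %.1f] mT (e.g. %.1f mT); widen the axis or use auto-expansion",
                   sum(outside), min(field_axis), max(field_axis),
                   cvec[which(outside)[1]]), call. = FALSE)
    }
    keep <- !outside
    cvec <- cvec[keep]; svec <- svec[keep]; avec <- avec[keep]
  }
  dB <- field_axis[2] - field_axis[1]
  nb <- length(field_axis)
  ## bin lines by width class, accumulate sticks, convolve per class
  nclass <- 16
  lsv <- log(pmax(svec, dB / 4))
  rng <- range(lsv)
  cls <- if (diff(rng) < 1e-12) rep(1L, length(lsv)) else
    pmin(nclass, 1L + floor((lsv - rng[1]) / diff(rng) * nclass))
  sig_cls <- exp(rng[1] + (seq_len(nclass) - 0.5) * diff(rng) / nclass)
  if (diff(rng) < 1e-12) sig_cls <- rep(exp(rng[1]), nclass)
  ## linear split between adjacent bins keeps the spectrum continuous in
  ## the line positions (the fitter differentiates through this)
  pos <- (cvec - field_axis[1]) / dB
  b0 <- pmin(nb, pmax(1L, floor(pos) + 1L))
  b1 <- pmin(nb, b0 + 1L)
  frac <- pmin(1, pmax(0, pos - (b0 - 1L)))
  M <- Matrix::sparseMatrix(i = c(b0, b1), j = c(cls, cls),
                            x = c(avec * (1 - frac), avec * frac),
                            dims = c(nb, nclass))
  M <- as.matrix(M)
  absorb <- numeric(nb)
  half <- floor(nb / 2)
  for (k in seq_len(nclass)) {
    if (all(M[, k] == 0)) next
    kern <- stats::dnorm(seq(-half, nb - half - 1) * dB, 0, sig_cls[k]) * dB
    absorb <- absorb + .circ_convolve(M[, k], kern, half)
  }
  ## Lorentzian part of the pseudo-Voigt (pp width -> gamma = pp*sqrt(3)/2)
  lwL <- sys$linewidths[2]
  if (lwL > 0) {
    gam <- lwL * sqrt(3) / 2
    kern <- (gam / pi) / (((seq_len(nb) - 1 - half) * dB)^2 + gam^2) * dB
    absorb <- .circ_convolve(absorb, kern, half)
  }
  absorb <- absorb / dB   # per-bin mass -> density, so amplitude and
                          # integrals are independent of the grid spacing
  deriv <- c(0, diff(absorb, lag = 2) / (2 * dB), 0)
  epr_spectrum(field_axis, deriv * scale, sys$mw_frequency_GHz,
               metadata = list(label = sys$label,
                               n_orientations = nOri,
                               shf = shf && length(sys$nitrogens) > 0))
}

## linear convolution via FFT with a kernel centered at index `center+1`
.circ_convolve <- function(x, kern, center) {
  n <- length(x)
  m <- stats::nextn(2 * n, 2)
  xp <- c(x, numeric(m - n))
  kp <- c(kern, numeric(m - length(kern)))
  out <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / m
  out[(center + 1):(center + n)]
}

#' Integrated absorption of a derivative spectrum
#'
#' Double integral of the first-derivative lineshape (proportional to the
#' number of spins).
#'
#' @param spec an `epr_spectrum`.
#' @return scalar absorption integral.
#' @export
absorption_integral <- function(spec) {
  dB <- spec$field[2] - spec$field[1]
  sum(cumsum(spec$intensity) * dB) * dB
}

## ---- fitting ---------------------------------------------------------------

#' Least-squares refinement of spin-Hamiltonian parameters
#'
#' Bounded local least-squares (Levenberg-Marquardt with box constraints)
#' on g values, |A| values and linewidths against one spectrum or jointly
#' against several spectra at different microwave frequencies with shared
#' parameters. The per-spectrum amplitude scale is profiled out
#' analytically. Deterministic start from `initial`.
#'
#' @param observed an `epr_spectrum` or list of them.
#' @param initial starting `spin_system` (frequencies are taken from the
#'   observed spectra).
#' @param vary character vector naming parameter groups to refine, from
#'   `"g"`, `"A"`, `"lw"`, `"g_strain"`, `"A_strain"`.
#' @param rel_bounds fractional half-width of the box around the start for
#'   g and A (absolute bound 0.05 for g is also applied); linewidths/strains
#'   are bounded in \[0, 4x start + 1\].
#' @param grid orientation grid used during refinement (coarser than the
#'   presentation default for speed).
#' @param maxiter maximum LM iterations.
#' @return list with `system` (best fit), `residual` (scale-invariant rms),
#'   `converged`, `diagnostics` (nls.lm info).
#' @export
fit_spectrum <- function(observed, initial, vary = c("g", "A"),
                         rel_bounds = 0.06, grid = orientation_grid(16, 8),
                         maxiter = 30) {
  specs <- if (inherits(observed, "epr_spectrum")) list(observed) else observed
  stopifnot(all(vapply(specs, inherits, TRUE, "epr_spectrum")))
  par0 <- c(); lower <- c(); upper <- c()
  addp <- function(nm, val, lo, hi) {
    par0 <<- c(par0, stats::setNames(val, nm))
    lower <<- c(lower, lo); upper <<- c(upper, hi)
  }
  if ("g" %in% vary) for (i in 1:3)
    addp(paste0("g", i), initial$g$g[i],
         initial$g$g[i] - 0.05, initial$g$g[i] + 0.05)
  if ("A" %in% vary) for (i in 1:3)
    addp(paste0("A", i), initial$cuA$absA[i],
         max(0, initial$cuA$absA[i] * (1 - 4 * rel_bounds)),
         initial$cuA$absA[i] * (1 + 4 * rel_bounds) + 5)
  if ("lw" %in% vary) for (i in 1:2)
    addp(paste0("lw", i), initial$linewidths[i], 0.01,
         4 * initial$linewidths[i] + 1)
  if ("g_strain" %in% vary) for (i in 1:3)
    addp(paste0("gs", i), initial$g_strain[i], 0, 4 * initial$g_strain[i] + 0.05)
  if ("A_strain" %in% vary) for (i in 1:3)
    addp(paste0("As", i), initial$A_strain[i], 0, 4 * initial$A_strain[i] + 50)
  build <- function(p, nu) {
    sys <- initial
    if ("g" %in% vary) sys$g <- suppressWarnings(g_tensor(p[c("g1", "g2", "g3")]))
    if ("A" %in% vary) sys$cuA <- cu_hyperfine(pmax(p[c("A1", "A2", "A3")], 0),
                                               initial$cuA$signs)
    if ("lw" %in% vary) sys$linewidths <- pmax(p[c("lw1", "lw2")], 0)
    if ("g_strain" %in% vary) sys$g_strain <- pmax(p[c("gs1", "gs2", "gs3")], 0)
    if ("A_strain" %in% vary) sys$A_strain <- pmax(p[c("As1", "As2", "As3")], 0)
    sys$mw_frequency_GHz <- nu
    sys
  }
  resid_fun <- function(p) {
    unlist(lapply(specs, function(sp) {
      sys <- build(p, sp$mw_frequency_GHz)
      sim <- tryCatch(
        simulate_powder(sys, grid = grid, field_axis = sp$field, clip = TRUE),
        error = function(e) NULL)
      if (is.null(sim)) return(rep(1e3, length(sp$field)))
      s <- sum(sim$intensity * sp$intensity) /
        max(sum(sim$intensity^2), .Machine$double.eps)
      (s * sim$intensity - sp$intensity) / max(abs(sp$intensity))
    }))
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ptol = 1e-8, ftol = 1e-8,
                              epsfcn = 1e-7))
  best <- build(fit$par, initial$mw_frequency_GHz)
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("fit did not converge; returning best iterate", call. = FALSE)
  list(system = best,
       residual = sqrt(mean(resid_fun(fit$par)^2)),
       converged = converged,
       diagnostics = list(info = fit$info, message = fit$message,
                          niter = fit$niter, par = fit$par))
}
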