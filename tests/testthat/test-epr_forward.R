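test_that("orientation grids have unit weights and unit vectors", {
  for (g in list(orientation_grid(5, 4), orientation_grid(31, 16))) {
    expect_equal(sum(g$weights), 1, tolerance = 1e-12)
    expect_equal(rowSums(g$vectors^2), rep(1, nrow(g$vectors)), tolerance = 1e-12)
  }
})

test_that("hyperfine-free isotropic system resonates at the closed-form field", {
  iso <- spin_system(g = c(2.0023, 2.0023 + 1e-9, 2.0023 + 2e-9),
                     cuA = c(0, 0, 0), mw_frequency_GHz = 9.3046)
  pe <- resonance_fields_perturbative(iso, c(0.3, 0.5, 0.81))
  expect_equal(pe$field, rep(332.0145, 4), tolerance = 1e-4)
  ex <- eigenfields_exact(iso, c(0, 0, 1))
  expect_equal(unique(round(ex$field, 3)), 332.014, tolerance = 1e-3)
})

test_that("first-order comb spacing along the unique axis is A h/(g muB)", {
  s <- lpmo$chitin_14N_X
  pe <- resonance_fields_perturbative(s, c(0, 0, 1), shf = FALSE)
  expect_equal(nrow(pe), 4L)
  spacing <- diff(pe$field)
  ## A = 620 MHz, g3 = 2.205 -> 20.1 mT to first order
  expect_equal(mean(spacing), 20.1, tolerance = 0.02)
})

test_that("perturbative and exact engines agree within 0.1 mT on all parameter sets", {
  ors <- random_orientations(16, seed = 99)
  for (nm in c("apo_14N_X", "apo_15N_Q", "chitin_14N_X", "chitin_15N_Q")) {
    s <- lpmo[[nm]]
    worst <- 0
    for (r in seq_len(nrow(ors))) {
      pe <- resonance_fields_perturbative(s, ors[r, ], shf = FALSE)
      ex <- eigenfields_exact(s, ors[r, ])
      expect_gte(nrow(ex), 4L)
      worst <- max(worst, max(vapply(pe$field, function(b)
        min(abs(ex$field - b)), 0)))
    }
    expect_lt(worst, 0.1)
  }
})

test_that("second-order shifts are non-zero and near-symmetric about the comb", {
  s <- lpmo$apo_14N_X
  pe <- resonance_fields_perturbative(s, c(0, 0, 1), shf = FALSE)$field
  ## first-order comb from the closed-form spacing A h / (g muB)
  conv <- s$g$g[3] * 9.2740100783e-24 * 1e-3 / 6.62607015e-34 * 1e-6
  nu <- s$mw_frequency_GHz * 1e3
  B1 <- sort((nu - 336 * c(-1.5, -0.5, 0.5, 1.5)) / conv)
  shift <- pe - B1
  ## all lines shift downfield at second order, including mI = +/- 3/2
  expect_true(all(shift < -0.05))
  ## outer (and inner) shifts agree pairwise up to higher-order residue
  expect_lt(abs(shift[4] - shift[1]), 0.2 * abs(mean(shift[c(1, 4)])))
  expect_lt(abs(shift[3] - shift[2]), 0.2 * abs(mean(shift[c(2, 3)])))
})

test_that("the large |A3| produces the high-field overshoot at X band", {
  s <- lpmo$chitin_14N_X
  g1_field <- resonance_field(s$g$g[1], s$mw_frequency_GHz)
  pe <- resonance_fields_perturbative(s, c(0, 0, 1), shf = FALSE)
  expect_gt(max(pe$field), g1_field)
})

test_that("powder spectrum of an axial system shows turning points at g-par and g-perp", {
  ax <- spin_system(g = c(2.05, 2.05 + 1e-6, 2.25), cuA = c(0, 0, 0),
                    linewidths = c(1.0, 0.2), mw_frequency_GHz = 9.3)
  sp <- simulate_powder(ax, grid = orientation_grid(40, 4))
  absorb <- cumsum(sp$intensity)
  Bpar <- resonance_field(2.25, 9.3)
  Bperp <- resonance_field(2.05, 9.3)
  ## absorption mass is confined between the two canonical edges
  inside <- sp$field > Bpar - 3 & sp$field < Bperp + 3
  expect_gt(sum(absorb[inside]), 0.98 * sum(absorb))
  ## the perpendicular edge dominates the derivative amplitude
  expect_lt(abs(sp$field[which.min(sp$intensity)] - Bperp), 2)
})

test_that("absorption integral is positive, grid-stable, and linear in scale", {
  s <- lpmo$chitin_14N_X
  sp1 <- simulate_powder(s, grid = orientation_grid(24, 12))
  sp2 <- simulate_powder(s, grid = orientation_grid(48, 24))
  i1 <- absorption_integral(sp1); i2 <- absorption_integral(sp2)
  expect_gt(i1, 0)
  expect_equal(i1, i2, tolerance = 0.01)
  sp4 <- simulate_powder(s, grid = orientation_grid(24, 12), scale = 4)
  expect_equal(absorption_integral(sp4), 4 * i1, tolerance = 1e-9)
})

test_that("doubling all linewidths preserves the absorption integral", {
  s <- lpmo$apo_14N_X
  wide <- s
  wide$linewidths <- s$linewidths * 2
  wide$g_strain <- s$g_strain * 2
  wide$A_strain <- s$A_strain * 2
  grid <- orientation_grid(24, 12)
  ## common generous axis so both tails are captured equally
  ax <- seq(180, 440, length.out = 2048)
  i1 <- absorption_integral(simulate_powder(s, grid = grid, field_axis = ax))
  i2 <- absorption_integral(simulate_powder(wide, grid = grid, field_axis = ax))
  expect_equal(i2, i1, tolerance = 0.01)
  ## amplitude normalization is independent of the grid spacing
  j1 <- absorption_integral(simulate_powder(s, grid = grid, n_points = 1024))
  j2 <- absorption_integral(simulate_powder(s, grid = grid, n_points = 4096))
  expect_equal(j1, j2, tolerance = 0.005)
})

test_that("powder spectrum is invariant under rotation of the tensor frame", {
  ## rotating the molecular frame relative to the lab is equivalent to
  ## rotating the orientation set; with an equal-weight full-sphere
  ## quadrature the powder pattern must not change
  fib <- function(n) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    phi <- pi * (1 + sqrt(5)) * i
    cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  }
  V <- fib(4000)
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, byrow = TRUE)
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)),
                           3, byrow = TRUE)
  Rot <- Rz(0.7) %*% Rx(0.4)
  mk <- function(vec) structure(list(vectors = vec,
                                     weights = rep(1 / nrow(vec), nrow(vec))),
                                class = "orientation_grid")
  s <- lpmo$apo_14N_X
  ax <- seq(240, 380, length.out = 1024)
  i1 <- simulate_powder(s, grid = mk(V), field_axis = ax)$intensity
  i2 <- simulate_powder(s, grid = mk(V %*% t(Rot)), field_axis = ax)$intensity
  expect_lt(sqrt(mean((i1 - i2)^2)) / max(abs(i1)), 0.01)
})

test_that("near-axial spectra converge quickly in azimuthal density", {
  s <- lpmo$chitin_15N_Q
  ax <- NULL
  sp1 <- simulate_powder(s, grid = orientation_grid(31, 4))
  sp2 <- simulate_powder(s, grid = orientation_grid(31, 16),
                         field_axis = sp1$field)
  expect_lt(sqrt(mean((sp1$intensity - sp2$intensity)^2)) /
              max(abs(sp2$intensity)), 0.01)
})

test_that("resonances outside a fixed window raise an informative error", {
  s <- lpmo$chitin_14N_X
  expect_error(simulate_powder(s, field_axis = seq(320, 340, length.out = 128)),
               "outside the field window")
  expect_silent(simulate_powder(s, field_axis = seq(320, 340, length.out = 128),
                                clip = TRUE))
})

test_that("spectrum text round-trips with its frequency sidecar", {
  s <- lpmo$apo_14N_X
  sp <- simulate_powder(s, grid = orientation_grid(8, 4), n_points = 256)
  tf <- tempfile(fileext = ".txt")
  write_spectrum(sp, tf)
  back <- read_spectrum(tf)
  expect_equal(back$field, sp$field, tolerance = 1e-9)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-9)
  expect_equal(back$mw_frequency_GHz, sp$mw_frequency_GHz)
  unlink(c(tf, paste0(tf, ".json")))
})

test_that("noiseless self-fit returns the truth with zero residual", {
  s <- lpmo$chitin_14N_X
  grid <- orientation_grid(16, 8)
  clean <- simulate_powder(s, grid = grid)
  fit <- fit_spectrum(clean, s, vary = c("g", "A"), grid = grid)
  expect_equal(fit$system$g$g, s$g$g, tolerance = 1e-8)
  expect_equal(fit$system$cuA$absA, s$cuA$absA, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-10)
})

test_that("seeded noisy spectrum recovery meets the g3/A3 targets", {
  truth <- lpmo$chitin_14N_X
  grid <- orientation_grid(24, 12)
  obs <- synth_spectrum(truth, snr = 50, seed = 7, grid = grid)
  init <- truth
  init$g <- suppressWarnings(g_tensor(truth$g$g * c(1.01, 0.995, 1.005)))
  init$cuA <- cu_hyperfine(truth$cuA$absA * c(1.01, 0.99, 1.01),
                           truth$cuA$signs)
  fit <- fit_spectrum(obs, init, vary = c("g", "A"), grid = grid)
  expect_lt(abs(fit$system$g$g[3] - truth$g$g[3]), 0.005)
  expect_lt(abs(fit$system$cuA$absA[3] - truth$cuA$absA[3]), 10)
})

test_that("adding the Q-band spectrum sharpens the g2 objective", {
  ## the chi-square profile along g2 must rise faster when the second
  ## frequency is fitted simultaneously: that is the double constraint
  truth <- lpmo$apo_15N_X
  truthQ <- lpmo$apo_15N_Q
  truthQ$g <- truth$g; truthQ$cuA <- truth$cuA
  grid <- orientation_grid(16, 8)
  spX <- simulate_powder(truth, grid = grid)
  spQ <- simulate_powder(truthQ, grid = grid)
  chisq <- function(specs, dg2) {
    sys <- truth
    sys$g <- suppressWarnings(g_tensor(truth$g$g + c(0, dg2, 0)))
    sum(unlist(lapply(specs, function(sp) {
      sys$mw_frequency_GHz <- sp$mw_frequency_GHz
      sim <- simulate_powder(sys, grid = grid, field_axis = sp$field,
                             clip = TRUE)
      sc <- sum(sim$intensity * sp$intensity) / sum(sim$intensity^2)
      ((sc * sim$intensity - sp$intensity) / max(abs(sp$intensity)))^2
    })))
  }
  dg <- 0.003
  curv_x <- chisq(list(spX), dg) + chisq(list(spX), -dg)
  curv_xq <- chisq(list(spX, spQ), dg) + chisq(list(spX, spQ), -dg)
  expect_gt(curv_xq, curv_x)
})
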