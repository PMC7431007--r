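g_free <- c(2.027, 2.095, 2.261)
g_bound <- c(2.042, 2.053, 2.205)
Aiso_free <- 29 / 3          # (+255 + 110 - 336)/3
Aiso_bound <- -625 / 3       # (+80 - 85 - 620)/3

test_that("Fermi contact from the Aiso relation matches the published values", {
  f_free <- fermi_contact(Aiso_free, g_free)
  expect_equal(f_free$fermi, -139, tolerance = 2 / 139)
  f_bound <- fermi_contact(Aiso_bound, g_bound)
  expect_equal(f_bound$fermi, -324, tolerance = 2 / 324)
  expect_equal(f_free$kappa, -f_free$fermi / 1180)
  ## K = 0 case: Aiso equal to the orbital term gives zero Fermi contact
  dg <- g_free - 2.0023
  expect_equal(fermi_contact((1180 / 3) * sum(dg), g_free)$fermi, 0,
               tolerance = 1e-9)
  expect_error(fermi_contact(10, g_free, Pd = -5), "positive")
})

test_that("Fermi contact is linear in Aiso at fixed g and Pd", {
  f <- function(a) fermi_contact(a, g_free)$fermi
  a <- c(-300, -100, 0, 50, 200)
  expect_equal(diff(vapply(a, f, 0)) / diff(a), rep(1, 4))
})

test_that("spin density from the A3 relation gives 0.82 at both bands", {
  kap <- fermi_contact(Aiso_free, g_free)$kappa
  a2_x <- solve_spin_density(-336, g_free, kap, b2 = 0.02)
  a2_q <- solve_spin_density(-340, g_free, kap, b2 = 0.02)
  expect_equal(a2_x, 0.82, tolerance = 0.02 / 0.82)
  expect_equal(a2_q, 0.82, tolerance = 0.02 / 0.82)
  ## trivial case: no orbital terms and kappa chosen to absorb A3 entirely
  expect_equal(solve_spin_density(-118, g_free * 0 + 2.0023, 118 / 1180,
                                  b2 = 0.02), 0, tolerance = 1e-9)
  expect_error(solve_spin_density(+500, g_free, kap), "inconsistent")
})

test_that("spin density agrees with a brute-force grid search of the A3 relation", {
  ## independent oracle: scan alpha2 and evaluate the A3 expression directly
  oracle <- function(A3, g, kap, b2, Pd = 1180) {
    a <- sqrt(1 - b2); b <- sqrt(b2)
    dg <- g - 2.0023
    grid <- seq(0, 1.2, by = 1e-5)
    lhs <- -Pd * (kap + 4 * grid * (a^2 - b^2) / 7 -
                    (3 * a - 3 * b) * dg[2] / (14 * (a + 3 * b)) -
                    (3 * a + 3 * b) * dg[1] / (14 * (a - 3 * b)) - dg[3])
    grid[which.min(abs(lhs - A3))]
  }
  kap <- fermi_contact(Aiso_free, g_free)$kappa
  for (A3 in c(-336, -340)) {
    expect_equal(solve_spin_density(A3, g_free, kap, 0.02),
                 oracle(A3, g_free, kap, 0.02), tolerance = 2e-5)
  }
  kapb <- fermi_contact(Aiso_bound, g_bound)$kappa
  expect_equal(solve_spin_density(-620, g_bound, kapb, 0.003),
               oracle(-620, g_bound, kapb, 0.003), tolerance = 2e-5)
})

test_that("decomposition reproduces the published contribution table", {
  d <- decompose_hyperfine(g_free, Aiso_free, -336, b2 = 0.02)
  expect_equal(d$fermi, -139, tolerance = 5 / 139)
  expect_equal(d$dipolar_para, -533, tolerance = 5 / 533)
  expect_equal(d$orbital_para, 332, tolerance = 5 / 332)
  expect_equal(d$alpha2, 0.82, tolerance = 0.02 / 0.82)
  ## perpendicular entries: leading-order only, assert sign
  expect_gt(d$dipolar_perp, 0)
  expect_gt(d$orbital_perp, 0)
  expect_true(d$perp_approximate)

  db <- decompose_hyperfine(g_bound, Aiso_bound, -620, b2 = 0.003)
  expect_equal(db$fermi, -324, tolerance = 5 / 324)
  expect_equal(db$dipolar_para, -558, tolerance = 5 / 558)
  expect_equal(db$orbital_para, 262, tolerance = 5 / 262)
  expect_equal(db$alpha2, 0.83, tolerance = 0.02 / 0.83)
})

test_that("degenerate decomposition collapses onto pure Fermi contact", {
  g0 <- c(2.0023, 2.0023, 2.0023)
  d <- suppressWarnings(decompose_hyperfine(g0, -150, -150, b2 = 0.02))
  expect_equal(d$fermi, -150)
  expect_equal(d$dipolar_para, 0, tolerance = 1e-9)
  expect_equal(d$orbital_para, 0, tolerance = 1e-9)
  expect_equal(d$alpha2, 0, tolerance = 1e-9)
})

test_that("recompose_parallel is the exact inverse on A3 and matches Table rows", {
  set.seed(3)
  for (i in 1:10) {
    g <- sort(2.0 + stats::runif(3, 0, 0.3))
    A3 <- -stats::runif(1, 200, 700)
    Aiso <- stats::runif(1, -250, 50)
    d <- try(decompose_hyperfine(g, Aiso, A3, b2 = stats::runif(1, 0, 0.05)),
             silent = TRUE)
    if (inherits(d, "try-error")) next
    expect_equal(recompose_parallel(d), A3, tolerance = 1e-12)
  }
  ## printed rows recompose onto the signed |A3| of the matching band
  expect_equal(-139 + -533 + 332, -340)
  expect_equal(-324 + -558 + 262, -620)
})

test_that("delft_table reproduces the signs and parallel magnitudes of every row", {
  tab <- delft_table(lpmo$apo_14N_X, lpmo$chitin_14N_X)
  expect_equal(nrow(tab), 3L)  # one free branch + two bound branches
  free <- tab[tab$condition == "no substrate", ]
  bound <- tab[tab$condition == "substrate", ]
  b208 <- bound[round(bound$Aiso) == -208, ]
  b262 <- bound[round(bound$Aiso) == -262, ]
  published <- rbind(
    c(-139, -533, 281, 332, 70, 0.82),
    c(-324, -558, 279, 262, 53, 0.83),
    c(-380, -504, 252, 264, 50, 0.75))
  got <- rbind(
    unlist(free[c("fermi", "dipolar_para", "dipolar_perp",
                  "orbital_para", "orbital_perp", "spin_density")]),
    unlist(b208[c("fermi", "dipolar_para", "dipolar_perp",
                  "orbital_para", "orbital_perp", "spin_density")]),
    unlist(b262[c("fermi", "dipolar_para", "dipolar_perp",
                  "orbital_para", "orbital_perp", "spin_density")]))
  expect_true(all(sign(got) == sign(published)))
  ## parallel-direction magnitudes within 5 MHz
  expect_true(all(abs(got[, c(1, 2, 4)] - published[, c(1, 2, 4)]) <= 5))
  expect_true(all(abs(got[, 6] - published[, 6]) <= 0.02))
})

test_that("dz2 mixing modes behave as documented", {
  expect_identical(dz2_mixing(g_free, "fixed"), 0.02)
  expect_equal(dz2_mixing(g_tensor(g_free), "estimate"), 0.02, tolerance = 1e-9)
  expect_equal(dz2_mixing(c(2.1, 2.1, 2.3), "estimate"), 0)
  ## monotone in g2 - g1
  gaps <- seq(0, 0.1, by = 0.01)
  vals <- vapply(gaps, function(d) dz2_mixing(c(2.0, 2.0 + d, 2.3), "estimate"), 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("stability ratio converts ddE to the published ~1e6 factor", {
  expect_gt(stability_ratio(8.2), 1e6)
  expect_equal(stability_ratio(8.2), 1.04e6, tolerance = 0.01)
  expect_identical(stability_ratio(0), 1)
  R <- 1.98720e-3
  expect_equal(stability_ratio(R * 298 * log(10)), 10, tolerance = 1e-12)
  ## reciprocal symmetry
  set.seed(4)
  for (x in stats::runif(5, 0, 12))
    expect_equal(stability_ratio(x) * stability_ratio(-x), 1, tolerance = 1e-12)
  tc <- thermo_coupling(dE1 = 10.2, dE2 = 2.0, temperature = 298)
  expect_equal(tc$ddE, 8.2)
  expect_equal(stability_ratio(tc), stability_ratio(8.2))
})
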