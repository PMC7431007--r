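make_pdb_fixture <- function(models) {
  ## models: list of lists with N, H (n x 3) and cu (length 3 or NULL)
  lines <- character(0)
  for (m in seq_along(models)) {
    mo <- models[[m]]
    lines <- c(lines, sprintf("MODEL     %4d", m))
    serial <- 0L
    for (i in seq_len(nrow(mo$N))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  N   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
        serial, i, mo$N[i, 1], mo$N[i, 2], mo$N[i, 3]))
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  H   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           H",
        serial, i, mo$H[i, 1], mo$H[i, 2], mo$H[i, 3]))
    }
    if (!is.null(mo$cu))
      lines <- c(lines, sprintf(
        "HETATM%5d CU    CU A%4d    %8.3f%8.3f%8.3f  1.00  0.00          CU",
        serial + 1L, nrow(mo$N) + 1L, mo$cu[1], mo$cu[2], mo$cu[3]))
    lines <- c(lines, "ENDMDL")
  }
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  tf
}

two_model_fixture <- function(d1 = 8, d2 = 12) {
  N <- rbind(c(0, 1, 0), c(5, 1, 0))
  make_pdb_fixture(list(
    list(N = N, H = rbind(c(d1, 0, 0), c(30, 0, 0)), cu = c(0, 0, 0)),
    list(N = N, H = rbind(c(d2, 0, 0), c(30, 0, 0)), cu = c(0, 0, 0))))
}

test_that("read_ensemble parses multi-model PDB with a Cu centre", {
  tf <- two_model_fixture()
  e <- read_ensemble(tf)
  expect_s3_class(e, "structure_ensemble")
  expect_equal(e$n_models, 2L)
  expect_equal(e$centers, matrix(0, 2, 3))
  unlink(tf)
})

test_that("midpoint centre rule places the centre between named atoms", {
  N <- rbind(c(2, 0, 0), c(4, 0, 0))
  tf <- make_pdb_fixture(list(list(N = N, H = N + 1, cu = NULL)))
  e <- read_ensemble(tf, center = list(type = "midpoint", resno = c(1, 2),
                                       elety = c("N", "N")))
  expect_equal(e$centers[1, ], c(3, 0, 0))
  ## no Cu and default rule -> unresolvable
  expect_error(read_ensemble(tf), "unresolvable")
  unlink(tf)
})

test_that("effective distances use the <r^-6>^(-1/6) average", {
  tf <- two_model_fixture(8, 12)
  e <- read_ensemble(tf)
  ed <- effective_distances(e)
  oracle <- ((8^-6 + 12^-6) / 2)^(-1 / 6)   # 8.85
  expect_equal(ed$r_eff[ed$resno == 1], oracle, tolerance = 1e-9)
  expect_equal(oracle, 8.85, tolerance = 1e-3)
  ## equal distances in all models collapse to that distance
  expect_equal(ed$r_eff[ed$resno == 2], 30, tolerance = 1e-9)
  unlink(tf)
})

test_that("single-model ensembles give plain distances", {
  N <- rbind(c(0, 1, 0))
  tf <- make_pdb_fixture(list(list(N = N, H = rbind(c(10, 0, 0)),
                                   cu = c(0, 0, 0))))
  e <- read_ensemble(tf)
  expect_equal(effective_distances(e)$r_eff, 10, tolerance = 1e-9)
  unlink(tf)
})

test_that("Gamma2 matches an independent constants-assembly oracle", {
  ## oracle assembled from scratch (CODATA values typed independently)
  oracle <- function(r_A, tc_ns, nuH_MHz, giso) {
    mu0 <- 4 * pi * 1e-7
    gH <- 267.52218744e6
    muB <- 9.2740100783e-24
    tc <- tc_ns * 1e-9
    wH <- 2 * pi * nuH_MHz * 1e6
    (1 / 15) * (mu0 / (4 * pi))^2 * gH^2 * giso^2 * muB^2 * (1 / 2) * (3 / 2) *
      (r_A * 1e-10)^-6 * (4 * tc + 3 * tc / (1 + wH^2 * tc^2))
  }
  set.seed(5)
  for (i in 1:100) {
    r <- stats::runif(1, 4, 60)
    tc <- stats::runif(1, 2, 20)
    nu <- stats::runif(1, 400, 950)
    gi <- stats::runif(1, 2.0, 2.3)
    expect_equal(gamma2_sb(r, tc, nu, gi), oracle(r, tc, nu, gi),
                 tolerance = 1e-6)
  }
})

test_that("Gamma2 obeys the r^-6 scaling law and decays at long range", {
  g10 <- gamma2_sb(10, 10.2)
  expect_equal(gamma2_sb(5, 10.2) / g10, 64, tolerance = 1e-9)
  expect_lt(gamma2_sb(60, 10.2), 0.1)
  expect_error(gamma2_sb(-1, 10), "positive")
})

test_that("a finite electron relaxation time shortens the effective tau_c", {
  expect_lt(gamma2_sb(10, 10.2, tau_s_ns = 5), gamma2_sb(10, 10.2))
  expect_equal(gamma2_sb(10, 5), gamma2_sb(10, 10, tau_s_ns = 10),
               tolerance = 1e-12)
})

test_that("intensity ratio model behaves at its limits and spot value", {
  expect_identical(intensity_ratio(0, 20), 1)
  expect_lt(intensity_ratio(1e7, 20), 1e-6)
  expect_equal(intensity_ratio(20, 20, 0.010), 0.5 * exp(-0.2),
               tolerance = 1e-12)
  expect_equal(0.5 * exp(-0.2), 0.409, tolerance = 1e-3)
  ## monotone non-increasing in gamma2
  g <- seq(0, 500, by = 25)
  expect_true(all(diff(intensity_ratio(g, 15)) <= 0))
})

test_that("predicted PRE profile is monotone in r_eff and saturates correctly", {
  se <- synth_ensemble(synth_config(seed = 3))
  prof <- predict_pre_profile(se$ensemble, tau_c_ns = 10.2)
  ord <- order(prof$r_eff)
  expect_true(all(diff(prof$ratio_pred[ord]) >= -1e-12))
  expect_true(all(prof$ratio_pred >= 0 & prof$ratio_pred <= 1))
  expect_true(all(prof$ratio_pred[prof$r_eff >= 40] > 0.9))
  ## removing the paramagnetic contribution restores full intensity
  expect_true(all(intensity_ratio(0 * prof$gamma2, 15) == 1))
})

test_that("paper-regime profile quenches residues within 12 A", {
  se <- synth_ensemble(synth_config(seed = 1))
  rel <- synth_relaxation(10.2, synth_config(seed = 1))
  prof <- predict_pre_profile(se$ensemble, rel$table, tau_c_ns = 10.2)
  near <- prof$ratio_pred[prof$r_eff <= 12]
  expect_gt(length(near), 2)
  expect_true(all(near < 0.2))
  ## Fig-1E-style concordance: strong rank correlation between proximity
  ## and signal reduction
  expect_gte(cor(-prof$r_eff, 1 - prof$ratio_pred, method = "spearman"), 0.95)
})

test_that("tau_c estimation matches the closed form and its domain error", {
  tab <- relaxation_table(1:5, rep(30, 5), rep(1, 5), rep(0.8, 5))
  est <- estimate_tauc(tab, n15_frequency_MHz = 60.8)
  expect_equal(est$tau_c_ns, 17.2, tolerance = 1e-2)
  ## boundary: mean T1/T2 exactly 7/6 gives tau_c = 0
  tab0 <- relaxation_table(1:5, rep(7, 5), rep(6, 5), rep(0.8, 5))
  expect_equal(estimate_tauc(tab0, 60.8)$tau_c_ns, 0)
  tab_bad <- relaxation_table(1:5, rep(1, 5), rep(1, 5), rep(0.8, 5))
  expect_error(estimate_tauc(tab_bad, 60.8), "undefined")
  expect_error(estimate_tauc(tab[1:2, ], 60.8), "fewer than 3")
})

test_that("relaxation-table validation enforces physical bounds", {
  expect_error(relaxation_table(1, -0.1, 0.1, 0.8), "> 0")
  expect_error(relaxation_table(1, 0.5, 0.1, 1.5), "sanity")
})
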