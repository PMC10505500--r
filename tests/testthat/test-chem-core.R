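test_that("elemental composition follows the terminal-water convention", {
  # free glycine vs glycine residue
  on <- aa_to_elements(aa_composition(Gly = 1), terminal_water = TRUE)
  expect_equal(as.numeric(on[, c("C", "H", "N", "O", "S")]),
               c(2, 5, 1, 2, 0))
  off <- aa_to_elements(aa_composition(Gly = 1))
  expect_equal(as.numeric(off[, c("C", "H", "N", "O", "S")]),
               c(2, 3, 1, 1, 0))
  # hand sum of two residues + one terminal H2O
  two <- aa_to_elements(aa_composition(Gly = 1, Ala = 1),
                        terminal_water = TRUE)
  expect_equal(as.numeric(two[, c("C", "H", "N", "O", "S")]),
               c(5, 10, 2, 3, 0))
  expect_error(aa_composition(Gly = 1, Xyz = 2), "Xyz")
  expect_error(aa_to_elements(aa_composition()), "zero total")
})

test_that("carbon oxidation state matches hand-derived values", {
  expect_equal(zc(data.frame(C = 2, H = 5, N = 1, O = 2, S = 0)), 1)
  expect_equal(zc(data.frame(C = 5, H = 11, N = 1, O = 2, S = 1)), -0.4)
  expect_equal(zc(data.frame(C = 1, H = 0, N = 0, O = 2, S = 0)), 4)
  expect_error(zc(data.frame(C = 0, H = 2, N = 0, O = 1, S = 0)),
               "undefined")
})

test_that("basis projection reproduces hand-solved element balances", {
  # glutamine is a basis species: projects onto itself
  gln <- basis_projection(data.frame(C = 5, H = 10, N = 2, O = 3, S = 0), 1)
  expect_equal(gln$nH2O, 0)
  expect_equal(gln$nO2, 0)
  # glycine residue: solved by hand elimination of the 5x5 system
  res <- basis_projection(aa_to_elements(aa_composition(Gly = 1)), 1)
  expect_equal(res$nH2O, -0.6)
  expect_equal(res$nO2, 0.3)
  # free glycine: nH2O shifts by exactly the terminal H2O, nO2 unchanged
  free <- basis_projection(
    aa_to_elements(aa_composition(Gly = 1), terminal_water = TRUE), 1)
  expect_equal(free$nH2O, 0.4)
  expect_equal(free$nO2, 0.3)
  # a singular basis is rejected
  bad <- basis_qec()
  bad[2, c("C", "H", "N", "O", "S")] <- bad[1, c("C", "H", "N", "O", "S")]
  expect_error(basis_projection(data.frame(C = 2, H = 3, N = 1, O = 1,
                                           S = 0), 1, basis = bad),
               "singular")
})

test_that("element balance reconstructs the input composition to 1e-9", {
  set.seed(42)
  m <- t(as.matrix(basis_qec()[, c("C", "H", "N", "O", "S")]))
  for (i in 1:20) {
    counts <- stats::setNames(stats::rgamma(20, 1) * 50, names(aa_composition())[1:20])
    aa <- do.call(aa_composition, as.list(counts))
    elem <- aa_to_elements(aa)
    coef <- as.numeric(basis_coefficients(elem))
    rebuilt <- as.numeric(m %*% coef)
    expect_lt(max(abs(rebuilt -
                        as.numeric(elem[, c("C", "H", "N", "O", "S")]))),
              1e-9)
  }
})

test_that("Zc is exactly invariant to the terminal-water convention", {
  set.seed(7)
  for (i in 1:25) {
    counts <- stats::setNames(stats::rgamma(20, 1) * 100,
                              names(aa_composition())[1:20])
    aa <- do.call(aa_composition, c(as.list(counts), chains = i %% 3 + 1))
    expect_identical(zc(aa_to_elements(aa, terminal_water = TRUE)),
                     zc(aa_to_elements(aa, terminal_water = FALSE)))
  }
})

test_that("GRAVY is the count-weighted Kyte-Doolittle mean", {
  expect_equal(gravy(aa_composition(Ala = 5)), 1.8)
  expect_equal(gravy(aa_composition(Ile = 1, Val = 1)), 4.35)
  expect_equal(gravy(aa_composition(Arg = 2)), -4.5)
})

test_that("isoelectric point solves the charge balance", {
  # single (+,-) pK pair: closed-form midpoint of Nterm/Cterm pKs
  expect_equal(isoelectric_point(aa_composition(Gly = 3)),
               (7.5 + 3.55) / 2, tolerance = 0.005)
  # acidic-dominated: below the Asp side-chain pK, and a true root
  pi_acid <- isoelectric_point(aa_composition(Asp = 4, Gly = 4))
  expect_lt(pi_acid, 4.05)
  expect_lt(abs(net_charge(c(Asp = 4, Gly = 4), 1, pi_acid)), 1e-4)
  # basic-dominated
  pi_base <- isoelectric_point(aa_composition(Lys = 4, Gly = 4))
  expect_gt(pi_base, 10)
  expect_lt(abs(net_charge(c(Lys = 4, Gly = 4), 1, pi_base)), 1e-4)
  expect_error(isoelectric_point(aa_composition(Gly = 1, chains = 0)),
               "ionizable")
})

test_that("pI brackets the charge root for mixed acid/base compositions", {
  set.seed(11)
  for (i in 1:15) {
    counts <- stats::setNames(round(stats::rgamma(20, 1) * 20) + 1,
                              names(aa_composition())[1:20])
    aa <- do.call(aa_composition, as.list(counts))
    p <- isoelectric_point(aa)
    expect_lt(abs(net_charge(as.list(counts), 1, p)), 1e-4)
    expect_gt(net_charge(as.list(counts), 1, p - 1), 0)
    expect_lt(net_charge(as.list(counts), 1, p + 1), 0)
  }
})

test_that("metrics suite computes lengths, masses and ratios", {
  expect_equal(calc_metrics(aa_composition(Gly = 10),
                            metrics = "length")$length, 10)
  r <- calc_metrics(aa_composition(Gly = 1), metrics = c("H/C", "O/C"))
  expect_equal(r$HC, 1.5)
  expect_equal(r$OC, 0.5)
  expect_equal(calc_metrics(aa_composition(Gly = 1), metrics = "MW")$MW,
               57.05, tolerance = 1e-4)
  expect_error(calc_metrics(aa_composition(Gly = 1), metrics = "bogus"),
               "valid names")
  expect_named(calc_metrics(aa_composition(Gly = 1, Ala = 2)),
               c("Zc", "nO2", "nH2O"))
})

test_that("all metrics are invariant to scaling counts and chains", {
  set.seed(3)
  counts <- stats::setNames(stats::rgamma(20, 1) * 30 + 0.5,
                            names(aa_composition())[1:20])
  aa1 <- do.call(aa_composition, c(as.list(counts), chains = 2))
  aa2 <- do.call(aa_composition, c(as.list(counts * 3.7), chains = 2 * 3.7))
  m1 <- calc_metrics(aa1, metrics = c("Zc", "nO2", "nH2O", "length", "MW",
                                      "HC", "NC", "OC", "SC", "GRAVY", "pI"))
  m2 <- calc_metrics(aa2, metrics = names(m1))
  # pI is homogeneous up to the bisection stopping rule (|Q| < 1e-4),
  # whose reached pH depends slightly on the charge scale
  expect_equal(unlist(m1), unlist(m2), tolerance = 1e-5)
})

test_that("Zc and nO2 strongly covary across random compositions", {
  set.seed(101)
  x <- matrix(stats::rgamma(1000 * 20, 1), nrow = 1000)
  comps <- 100 * x / rowSums(x)
  colnames(comps) <- names(aa_composition())[1:20]
  aa <- tibble::as_tibble(comps)
  m <- calc_metrics(aa, metrics = c("Zc", "nO2"))
  expect_gte(stats::cor(m$Zc, m$nO2), 0.8)
})

test_that("sequence-derived and hand-built compositions agree", {
  seq_aa <- aa_from_sequence("GGAKWR")
  hand <- aa_composition(Gly = 2, Ala = 1, Lys = 1, Trp = 1, Arg = 1)
  all_m <- c("Zc", "nO2", "nH2O", "length", "MW", "HC", "NC", "OC", "SC",
             "GRAVY", "pI")
  expect_equal(calc_metrics(seq_aa, metrics = all_m),
               calc_metrics(hand, metrics = all_m))
  expect_error(aa_from_sequence("GAX"), "X")
})
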