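ct2 <- toyClassTable(c("X", "Y"), c("G", "C"), c("C", "G"))

test_that("Boltzmann binding probabilities match closed forms and normalise", {
  expect_equal(bindingProbability(0), 0.5)
  expect_equal(bindingProbability(-log(3)), 0.75, tolerance = 1e-12)
  # two-state form is the competing form with a single competitor
  for (dG in c(-2.3, 0, 1.7))
    expect_equal(bindingProbability(dG),
                 bindingProbability(dG, others = dG), tolerance = 1e-12)
  # full distribution over 24 competitors sums to 1 with the unbound share
  set.seed(4)
  dGs <- stats::rnorm(24, -3, 2)
  ps <- vapply(dGs, bindingProbability, numeric(1), others = dGs)
  unbound <- 1 / (1 + sum(exp(-dGs)))
  expect_equal(sum(ps) + unbound, 1, tolerance = 1e-12)
})

test_that("logit-energy mapping inverts exactly and rejects the boundary", {
  expect_equal(logitEnergy(0.5), 0)
  expect_equal(logitEnergy(exp(1) / (1 + exp(1))), -1, tolerance = 1e-12)
  for (p in c(1e-6, 0.25, 0.5, 0.9, 1 - 1e-6))
    expect_equal(inverseLogitEnergy(logitEnergy(p)), p, tolerance = 1e-12)
  expect_error(logitEnergy(0), "strictly between")
  expect_error(logitEnergy(1), "strictly between")
  # unit scaling is linear
  expect_equal(logitEnergy(0.9, kBT = 2), 2 * logitEnergy(0.9))
})

test_that("strand energies decompose exactly and match the predictor", {
  aln <- toyAlignment(list(s = c(`35` = "G", `36` = "C", `10` = "U")),
                      "X", ct2)
  # bias only
  m0 <- toyModel(c("X", "Y"), c(-1.2, 0))
  e0 <- strandEnergy(m0, aln)
  expect_equal(e0@forward, 1.2)
  expect_equal(e0@reverse, 0)
  expect_equal(e0@total, 1.2)
  # tandem-only coefficients leave the non-tandem reverse at zero
  mt <- toyModel(c("X", "Y"), c(-1, 0),
                 coefDf("X", c("35", "36"), c("G", "C"), c(2, 3)))
  et <- strandEnergy(mt, aln)
  expect_equal(et@reverseTandem, -5)
  expect_equal(et@reverseOther, 0)
  expect_equal(et@total, 1 - 5)
  # sign convention: positive coefficient, negative energy input
  expect_true(all(sign(et@inputs$dG) == -1))
  # doubling the unit doubles every energy
  et2 <- strandEnergy(mt, aln, kBT = 2)
  expect_equal(et2@total, 2 * et@total)
  expect_equal(et2@reverseTandem, 2 * et@reverseTandem)
})

test_that("strand energy equals -kT times the predictor on fitted models", {
  s <- separableFit()
  F <- predictorValues(s$fit, s$aln)
  for (i in c(1, 50, 200, nStrand(s$aln))) {
    prof <- strandEnergy(s$fit, s$aln, strand = i)
    cl <- unname(strandClasses(s$aln)[i])
    expect_equal(prof@total, -F[i, cl], tolerance = 1e-12)
    expect_equal(prof@total, prof@forward + prof@reverse)
    expect_equal(prof@reverse, prof@reverseTandem + prof@reverseOther)
    expect_equal(prof@bias, prof@forward)
  }
})

test_that("class energy summaries match a hand-computed oracle", {
  aln <- toyAlignment(list(a = c(`35` = "G", `36` = "C", `10` = "U"),
                           b = c(`35` = "G", `36` = "C")),
                      c("X", "X"), ct2)
  model <- toyModel(c("X", "Y"), c(-1, 0),
                    coefDf("X", c("35", "36", "10"), c("G", "C", "U"),
                           c(2, 3, 0.5)))
  es <- classEnergySummary(model, aln)
  # strand a: dG = 1 - 5 - 0.5 = -4.5; strand b: dG = 1 - 5 = -4
  expect_equal(es$mean_dG, -4.25)
  expect_equal(es$max_dG, -4)
  expect_equal(es$sd_dG, stats::sd(c(-4.5, -4)))
  expect_equal(es$mean_dG0, 1)
  expect_equal(es$mean_dG_rev_tandem, -5)
  expect_equal(es$mean_dG_rev_other, -0.25)
  # identical strands: sd 0, max = mean
  aln2 <- toyAlignment(list(a = c(`35` = "G"), b = c(`35` = "G")),
                       c("X", "X"), ct2)
  es2 <- classEnergySummary(model, aln2)
  expect_equal(es2$sd_dG, 0)
  expect_equal(es2$max_dG, es2$mean_dG)
  aln3 <- toyAlignment(list(a = c(`35` = "G"), b = c(`35` = "C")),
                       c("X", "Y"), ct2)
  expect_warning(classEnergySummary(toyModel("X", 0), aln3), "omitted")
})

test_that("cross-class energies favour the cognate consensus strand", {
  s <- studyFit()
  cons <- consensusStrands(s$aln)
  cross <- crossClassEnergy(s$fit, cons$alignment)
  es <- classEnergySummary(s$fit, s$aln)
  for (cl in rownames(cross)) {
    # the cognate consensus is the best bound strand in its row
    expect_equal(colnames(cross)[which.min(cross[cl, ])], cl)
    # recognition rule: consensus energy below the class threshold
    expect_lte(cross[cl, cl], es$max_dG[es$class == cl] + 1e-9)
  }
})

test_that("tandem nucleotide energies average the tandem coefficients", {
  model <- toyModel("X", -1, coefDf("X", c("35", "36"), c("G", "C"),
                                    c(2, 3)))
  ct1 <- toyClassTable("X", "G", "C")
  te <- tandemNucleotideEnergy(model, ct1)
  expect_equal(te$mean_dG_rev[te$code == "G"], -2)
  expect_equal(te$mean_dG_rev[te$code == "C"], -3)
  expect_false("A" %in% te$code)  # absent from every tandem
})

test_that("hydrogen-bond counts follow the parent base", {
  ab <- defaultAlphabet()
  expect_identical(hbondCount(c("G", "C"), ab), c(3L, 3L))
  expect_identical(hbondCount(c("A", "U"), ab), c(2L, 2L))
  expect_identical(hbondCount("-", ab), 0L)
  # modified nucleosides inherit from the parent base
  expect_identical(hbondCount(c("D", "P", "Q", "?"), ab),
                   c(2L, 2L, 3L, 3L))
  expect_true(is.na(hbondCount("{", ab)))  # unassignable parent
  expect_error(hbondCount("Z", ab), "not in alphabet")
})

test_that("reverse energy decreases with carried hydrogen bonds", {
  # graded nested subsets of three identity cells
  ov <- list(s0 = c(),
             s1 = c(`10` = "G"),
             s2 = c(`10` = "G", `20` = "C"),
             s3 = c(`10` = "G", `20` = "C", `30` = "U"))
  aln <- toyAlignment(ov, rep("X", 4), toyClassTable("X", "G", "C"),
                      fill = "A")
  model <- toyModel("X", -1, coefDf("X", c("10", "20", "30"),
                                    c("G", "C", "U"), c(1, 2, 0.5)))
  sets <- extractIdentitySets(model)
  prof <- hbondEnergyProfile(model, aln, "X", sets)
  expect_true(any(prof$n_hb == 0 & prof$dG_rev == 0))  # zero point
  expect_equal(max(prof$n_hb), 3 + 3 + 2)              # full set
  expect_true(all(diff(prof$dG_rev[order(prof$n_hb)]) < 0))
})
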