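ct3 <- toyClassTable(c("X", "Y", "Z"), c("G", "C", "U"), c("C", "G", "U"))

test_that("identity sets map coefficients to signed cells", {
  model <- toyModel("X", -1,
                    coefDf("X", c("35", "36", "71", "44"),
                           c("G", "C", "C", "A"), c(2, 3, 1, -1)))
  sets <- extractIdentitySets(model)
  expect_equal(nrow(sets), 4)
  expect_equal(unname(nIP(sets)["X"]), 4L)
  expect_setequal(paste0(sets$position,
                         ifelse(sets$sign == "repel", "~", ""),
                         sets$codes),
                  c("35G", "36C", "71C", "44~A"))
  # empty model, empty sets
  expect_equal(nrow(extractIdentitySets(toyModel("X", 0))), 0)
  # threshold filters by magnitude
  expect_equal(nrow(extractIdentitySets(model, threshold = 1.5)), 2)
})

test_that("degenerate wobble selections merge into one multi-code cell", {
  model <- toyModel("X", -1,
                    coefDf("X", c("34", "34", "35"), c("G", "Q", "G"),
                           c(1, 0.5, 2)))
  sets <- extractIdentitySets(model)
  expect_equal(nrow(sets), 2)
  cell34 <- sets[sets$position == "34", ]
  expect_identical(cell34$codes, "G,Q")
  expect_equal(cell34$value, 1.5)
  expect_equal(unname(nIP(sets)["X"]), 2L)
})

test_that("occurrence statistics count carried non-repelling cells", {
  sets <- data.frame(class = "X",
                     position = c("1", "2", "3", "4", "5", "6", "7", "9"),
                     codes = c("G", "C", "U", "A", "-", "G,Q", "C", "U"),
                     sign = c(rep("attract", 7), "repel"),
                     stringsAsFactors = FALSE)
  # strand carries 5 of the 7 attract cells (multi-code via Q; "-" matches)
  ov <- list(s = c(`1` = "G", `2` = "C", `3` = "U", `5` = "-", `6` = "Q"))
  aln <- toyAlignment(ov, "X", toyClassTable("X", "G", "C"), fill = "D")
  occ <- occurrenceStats(aln, sets)
  expect_equal(occ$max_theor, 7)
  expect_equal(occ$min_real, 5L)
  expect_equal(occ$coverage, 5 / 7)
})

test_that("coverage approaches the penetrance on large samples", {
  ct1 <- toyClassTable("X", "G", "C")
  plants <- data.frame(class = "X", position = c("5", "10", "20"),
                       code = c("G", "C", "U"), theta = 0.7,
                       sign = "attract")
  cfg <- syntheticConfig(ct1, plants, strandsPerClass = 1000, seed = 13)
  aln <- simulateTrnaAlignment(cfg)
  sets <- data.frame(class = "X", position = plants$position,
                     codes = plants$code, sign = "attract",
                     stringsAsFactors = FALSE)
  occ <- occurrenceStats(aln, sets)
  tol <- 3 * sqrt(0.7 * 0.3 / (3 * 1000))
  expect_lt(abs(occ$coverage - 0.7), tol)
  # full penetrance: min = max = theoretical, coverage 1
  cfg1 <- syntheticConfig(ct1, transform(plants, theta = 1),
                          strandsPerClass = 50, seed = 13)
  occ1 <- occurrenceStats(simulateTrnaAlignment(cfg1), sets)
  expect_equal(occ1$min_real, occ1$max_theor)
  expect_equal(occ1$coverage, 1)
})

test_that("consensus strands take the modal code with documented tie-breaks", {
  aln <- toyAlignment(list(a = c(`10` = "G"), b = c(`10` = "G"),
                           c = c(`10` = "C")),
                      rep("X", 3), toyClassTable("X", "G", "C"))
  cons <- consensusStrands(aln)
  m <- strandCodes(cons$alignment)
  expect_identical(unname(m[1, "10"]), "G")
  expect_equal(cons$modalFrequency["X", "10"], 2 / 3)
  # a class of identical strands reproduces the strand
  aln2 <- toyAlignment(list(a = c(`5` = "U"), b = c(`5` = "U")),
                       rep("X", 2), toyClassTable("X", "G", "C"))
  cons2 <- consensusStrands(aln2)
  expect_identical(unname(strandCodes(cons2$alignment)[1, ]),
                   unname(strandCodes(aln2)[1, ]))
  # ties broken by alphabet order (A before U before G) and recorded
  aln3 <- toyAlignment(list(a = c(`7` = "U"), b = c(`7` = "G")),
                       rep("X", 2), toyClassTable("X", "G", "C"))
  cons3 <- consensusStrands(aln3)
  expect_identical(unname(strandCodes(cons3$alignment)[1, "7"]), "U")
  expect_true(any(cons3$ties$position == "7"))
})

test_that("consensus of high-penetrance synthetic data recovers the tandems", {
  cfg <- defaultSyntheticConfig(seed = 6, strandsPerClass = 200,
                                theta = 0.85)
  aln <- simulateTrnaAlignment(cfg)
  cons <- consensusStrands(aln)
  ct <- classTableData(loadFixture("class_table"))
  m <- strandCodes(cons$alignment)
  expect_identical(unname(m[, "35"]), ct$tandem35)
  expect_identical(unname(m[, "36"]), ct$tandem36)
})

test_that("agreement scoring applies the attract and repel rules", {
  cons <- toyAlignment(list(cX = c(`10` = "G", `20` = "C"),
                            cY = c(`10` = "U", `20` = "A")),
                       c("X", "Y"), ct3)
  allMatch <- data.frame(class = c("X", "X"), position = c("10", "20"),
                         codes = c("G", "C"), sign = "attract",
                         stringsAsFactors = FALSE)
  expect_equal(consensusAgreement(allMatch, cons)$percentage, 100)
  allRepel <- data.frame(class = c("Y", "Y"), position = c("10", "20"),
                         codes = c("G", "C"), sign = "repel",
                         stringsAsFactors = FALSE)
  expect_equal(consensusAgreement(allRepel, cons)$percentage, 100)
  mixed <- data.frame(class = c("X", "X"), position = c("10", "20"),
                      codes = c("G", "A"), sign = "attract",
                      stringsAsFactors = FALSE)
  agr <- consensusAgreement(mixed, cons)
  expect_equal(agr$consistent, 1)
  expect_equal(agr$total, 2)
  # degenerate cells are consistent when any member matches
  degen <- data.frame(class = "X", position = "10", codes = "Q,G",
                      sign = "attract", stringsAsFactors = FALSE)
  expect_equal(consensusAgreement(degen, cons)$consistent, 1)
})

test_that("universal markers demand full in-class presence and uniqueness", {
  ct <- toyClassTable(c("X", "Y", "Z"), c("G", "C", "U"),
                      c("C", "G", "U"))
  plants <- rbind(
    data.frame(class = "X", position = c("71", "3"), code = c("C", "G"),
               theta = 1, sign = "attract"),
    data.frame(class = "X", position = "20", code = "G", theta = 0.5,
               sign = "attract"),
    # other classes never show the X cells
    data.frame(class = c("Y", "Z"), position = "71", code = "C",
               theta = 1, sign = "repel"),
    data.frame(class = c("Y", "Z"), position = "3", code = "G",
               theta = 1, sign = "repel"))
  cfg <- syntheticConfig(ct, plants, strandsPerClass = 30, seed = 21)
  aln <- simulateTrnaAlignment(cfg)
  sets <- data.frame(class = "X",
                     position = c("35", "36", "71", "3", "20"),
                     codes = c("G", "C", "C", "G", "G"),
                     sign = "attract", stringsAsFactors = FALSE)
  mk <- universalMarkers(aln, sets)
  expect_equal(mk$class, "X")
  cells <- strsplit(mk$cells, ",", fixed = TRUE)[[1]]
  expect_true(all(c("35:G", "36:C", "71:C", "3:G") %in% cells))
  # the sub-unit-penetrance cell cannot be part of the marker
  expect_false("20:G" %in% cells)
})

test_that("a marker must extend beyond the anticodon tandem", {
  ct <- toyClassTable(c("X", "Y"), c("G", "C"), c("C", "G"))
  cfg <- syntheticConfig(ct, NULL, strandsPerClass = 10, seed = 1)
  aln <- simulateTrnaAlignment(cfg)
  sets <- data.frame(class = "X", position = c("35", "36"),
                     codes = c("G", "C"), sign = "attract",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(universalMarkers(aln, sets)), 0)
})

test_that("unique ensembles exclude the tandem and shared combinations", {
  ct <- toyClassTable(c("X", "Y"), c("G", "C"), c("C", "G"))
  ov <- list(x1 = c(`20` = "G", `50` = "A"),
             x2 = c(`20` = "G", `50` = "A"),
             x3 = c(`20` = "G"),
             x4 = c(),
             y1 = c(`20` = "G"),
             y2 = c(`50` = "A"))
  aln <- toyAlignment(ov, c(rep("X", 4), rep("Y", 2)), ct, fill = "U")
  sets <- data.frame(class = "X", position = c("20", "50", "35"),
                     codes = c("G", "A", "G"), sign = "attract",
                     stringsAsFactors = FALSE)
  ens <- uniqueEnsembles(aln, sets)
  expect_equal(nrow(ens), 1)
  expect_identical(ens$cells, "20G,50A")
  expect_equal(ens$n_strands, 2L)
  # jointly present in another class: excluded
  aln2 <- toyAlignment(c(ov, list(y3 = c(`20` = "G", `50` = "A"))),
                       c(rep("X", 4), rep("Y", 3)), ct, fill = "U")
  expect_equal(nrow(uniqueEnsembles(aln2, sets)), 0)
  # a class with nothing beyond the tandem has no ensembles
  tandemOnly <- sets[sets$position == "35", , drop = FALSE]
  expect_equal(nrow(uniqueEnsembles(aln, tandemOnly)), 0)
})

test_that("universal markers stay unique as extra-anticodon ensembles", {
  ct <- toyClassTable(c("X", "Y", "Z"), c("G", "C", "U"),
                      c("C", "G", "U"))
  plants <- rbind(
    data.frame(class = "X", position = c("71", "3"), code = c("C", "G"),
               theta = 1, sign = "attract"),
    data.frame(class = c("Y", "Z"), position = "71", code = "C",
               theta = 1, sign = "repel"))
  cfg <- syntheticConfig(ct, plants, strandsPerClass = 25, seed = 8)
  aln <- simulateTrnaAlignment(cfg)
  sets <- data.frame(class = "X", position = c("35", "36", "71", "3"),
                     codes = c("G", "C", "C", "G"), sign = "attract",
                     stringsAsFactors = FALSE)
  mk <- universalMarkers(aln, sets)
  expect_equal(nrow(mk), 1)
  ens <- uniqueEnsembles(aln, sets)
  # the marker minus its tandem cells survives as a unique ensemble
  expect_true(any(vapply(strsplit(ens$cells, ","), function(cc)
    all(c("71C", "3G") %in% cc), logical(1))))
})

test_that("the class summary joins counts, masses and families", {
  sets <- loadFixture("identity_table")
  ct <- loadFixture("class_table")
  out <- nipMwSummary(sets, ct)
  expect_equal(nrow(out), 24)
  expect_equal(out$family[out$class == "Gly"], "serine")
  expect_equal(out$family[out$class == "Trp"], "aromatic")
  expect_equal(out$n_ip[out$class == "Gln"], 8L)
  expect_equal(out$n_ip[out$class == "Val"], 2L)
  expect_equal(out$molecular_weight[out$class == "Gly"], 75.07)
})
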