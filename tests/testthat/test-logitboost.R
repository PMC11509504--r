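ct2 <- toyClassTable(c("X", "Y"), c("G", "C"), c("C", "G"))

separableToy <- function(nPer = 10) {
  ov <- c(lapply(seq_len(nPer), function(i) c(`35` = "G")),
          lapply(seq_len(nPer), function(i) c(`35` = "C")))
  names(ov) <- paste0("s", seq_len(2 * nPer))
  toyAlignment(ov, rep(c("X", "Y"), each = nPer), ct2)
}

test_that("a separable two-class toy is driven to zero training error", {
  aln <- separableToy()
  fit <- fitSimpleLogistic(aln, control = boostControl(maxIterations = 60))
  expect_equal(min(fit@errorPath), 0)
  expect_equal(fit@errorPath[fit@iterations], 0)
  # coefficients live only on the discriminating columns
  expect_true(all(fit@coef$position == "35"))
  expect_true(all(fit@coef$code %in% c("G", "C")))
  pr <- predict(fit, aln)
  expect_identical(unname(pr$label), unname(strandClasses(aln)))
  # logistic loss is non-increasing up to the selected iteration
  expect_true(all(diff(fit@lossPath[seq_len(fit@iterations)]) <= 1e-9))
})

test_that("degenerate inputs are rejected", {
  aln <- separableToy(2)
  expect_error(fitSimpleLogistic(encodeFeatures(aln), rep("X", 4)),
               "two classes")
  expect_error(fitSimpleLogistic(encodeFeatures(aln[integer(0)]),
                                 character(0)))
})

test_that("predictor values equal a dense dot-product oracle", {
  set.seed(17)
  coef <- coefDf(class = sample(c("X", "Y"), 12, replace = TRUE),
                 position = sample(canonicalPositions(), 12),
                 code = sample(c("A", "U", "G", "C", "-"), 12,
                               replace = TRUE),
                 value = round(stats::rnorm(12), 3))
  coef <- coef[!duplicated(coef[, 1:3]), ]
  model <- toyModel(c("X", "Y"), c(-0.4, 0.9), coef)
  ov <- lapply(1:6, function(i) {
    s <- sample(c("A", "U", "G", "C", "-"), 77, replace = TRUE)
    stats::setNames(s, canonicalPositions())
  })
  names(ov) <- paste0("r", 1:6)
  aln <- toyAlignment(ov, rep(c("X", "Y"), 3), ct2)
  F <- predictorValues(model, aln)
  m <- strandCodes(aln)
  for (i in 1:6) for (cl in c("X", "Y")) {
    f <- model@bias[cl]
    for (r in which(coef$class == cl))
      f <- f + coef$value[r] * (m[i, coef$position[r]] == coef$code[r])
    expect_equal(F[i, cl], unname(f), tolerance = 1e-12)
  }
  # all-zero coefficients give f_i = b_i
  m0 <- toyModel(c("X", "Y"), c(-1.5, 2))
  F0 <- predictorValues(m0, aln)
  expect_true(all(F0[, "X"] == -1.5 & F0[, "Y"] == 2))
})

test_that("prediction follows the closed-form softmax and tie rule", {
  aln <- toyAlignment(list(s = c(`35` = "G")), "X", ct2)
  tie <- toyModel(c("X", "Y"), c(0, 0))
  pr <- predict(tie, aln)
  expect_equal(unname(pr$probability[1, ]), c(0.5, 0.5))
  expect_identical(unname(pr$label), "X")  # first class wins exact ties
  onez <- toyModel(c("X", "Y"), c(1, 0))
  pr2 <- predict(onez, aln)
  expect_equal(unname(pr2$probability[1, "X"]), exp(1) / (1 + exp(1)),
               tolerance = 1e-12)
  # strand holding exactly one coefficient-bearing code: f = b + c
  one <- toyModel(c("X", "Y"), c(0.25, 0), coefDf("X", "35", "G", 1.75))
  expect_equal(unname(predictorValues(one, aln)[1, "X"]), 2)
})

test_that("every base-learner choice minimises weighted SSE (exhaustive check)", {
  set.seed(23)
  for (rep in 1:3) {
    n <- 12; p <- 3
    Xm <- matrix(rbinom(n * p, 1, 0.5), n, p,
                 dimnames = list(paste0("s", 1:n), NULL))
    y <- sample(c("X", "Y", "Z"), n, replace = TRUE)
    while (length(unique(y)) < 3) y <- sample(c("X", "Y", "Z"), n, TRUE)
    X <- new("TrnaFeatureMatrix", matrix = Xm,
             position = c("1", "2", "3"), code = c("A", "A", "A"))
    fit <- fitSimpleLogistic(X, y, classLevels = c("X", "Y", "Z"),
                             control = boostControl(maxIterations = 8,
                                                    stopWindow = 8))
    chk <- refBoostCheck(X, y, fit)
    expect_true(chk$okPick)
    expect_true(chk$okFit)
    expect_equal(fit@errorPath, chk$errPath, tolerance = 1e-12)
  }
})

test_that("truncating at the selected iteration reproduces the recorded error", {
  s <- studyFit()
  X <- encodeFeatures(s$aln)
  pr <- predict(s$fit, X)
  err <- mean(pr$label != unname(strandClasses(s$aln)))
  expect_identical(err, s$fit@errorPath[s$fit@iterations])
  expect_identical(which.min(s$fit@errorPath), as.integer(s$fit@iterations))
})

test_that("predictions agree with a reference multinomial logistic fit", {
  aln <- separableToy()
  fit <- fitSimpleLogistic(aln, control = boostControl(maxIterations = 40))
  x35 <- as.numeric(strandCodes(aln)[, "35"] == "G")
  y <- factor(unname(strandClasses(aln)), levels = c("X", "Y"))
  ref <- nnet::multinom(y ~ x35, trace = FALSE)
  refLab <- as.character(stats::predict(ref))
  expect_identical(unname(predict(fit, aln)$label), refLab)
})

test_that("a model round-trips through JSON", {
  s <- separableFit()
  tf <- tempfile(fileext = ".json")
  writeModelJson(s$fit, tf)
  back <- readModelJson(tf)
  expect_equal(back@bias, s$fit@bias)
  expect_equal(back@coef, s$fit@coef)
  expect_equal(back@errorPath, s$fit@errorPath)
  expect_identical(back@iterations, s$fit@iterations)
  expect_equal(predictorValues(back, s$aln), predictorValues(s$fit, s$aln))
})
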