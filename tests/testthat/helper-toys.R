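# Shared builders for hand-constructed fixtures (all data built in code).

baseCodes <- function(fill = "A") {
  stats::setNames(rep(fill, 77), canonicalPositions())
}

toyClassTable <- function(labels, t35, t36, mw = 100) {
  new("ClassTable",
      table = data.frame(class = labels, amino_acid = labels,
                         tandem35 = t35, tandem36 = t36, remark = "",
                         molecular_weight = mw, stringsAsFactors = FALSE))
}

# strands: named list of named character overrides applied to a constant
# base strand; names become strand ids
toyAlignment <- function(strands, classes, classTable,
                         alphabet = defaultAlphabet(), fill = "A") {
  m <- do.call(rbind, lapply(strands, function(ov) {
    s <- baseCodes(fill)
    if (length(ov)) s[names(ov)] <- ov
    s
  }))
  rownames(m) <- names(strands)
  trnaAlignment(m, classes, alphabet, classTable)
}

coefDf <- function(class, position, code, value) {
  data.frame(class = class, position = as.character(position),
             code = code, value = value, stringsAsFactors = FALSE)
}

toyModel <- function(classLevels, bias, coef = coefDf(character(),
                                                      character(),
                                                      character(),
                                                      numeric())) {
  new("SimpleLogisticModel", classLevels = classLevels,
      bias = stats::setNames(bias, classLevels), coef = coef,
      errorPath = 0, lossPath = 0, iterations = 1L,
      selectionLog = data.frame(), control = unclass(boostControl()))
}
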