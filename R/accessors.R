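#' @rdname TrnaAlignment-class
setMethod("nStrand", "TrnaAlignment", function(x) nrow(x@codes))

#' @rdname TrnaAlignment-class
setMethod("strandIds", "TrnaAlignment", function(x) rownames(x@codes))

#' @rdname TrnaAlignment-class
setMethod("strandClasses", "TrnaAlignment", function(x) {
  stats::setNames(x@classLabel, rownames(x@codes))
})

#' @rdname TrnaAlignment-class
setMethod("strandCodes", "TrnaAlignment", function(x) x@codes)

#' @rdname TrnaAlignment-class
setMethod("alphabet", "TrnaAlignment", function(x) x@alphabet)

#' @rdname TrnaAlignment-class
setMethod("classTable", "TrnaAlignment", function(x) x@classTable)

#' @rdname ClassTable-class
setMethod("classLabels", "ClassTable", function(x) x@table$class)

#' @rdname ClassTable-class
#' @param object a \code{ClassTable}.
#' @export
#' @describeIn ClassTable-class the underlying data.frame.
classTableData <- function(object) object@table

#' @rdname TrnaFeatureMatrix-class
setMethod("featureMatrix", "TrnaFeatureMatrix", function(x) x@matrix)

#' @rdname TrnaFeatureMatrix-class
setMethod("featureInfo", "TrnaFeatureMatrix", function(x) {
  data.frame(position = x@position, code = x@code,
             stringsAsFactors = FALSE)
})

#' Subset an alignment by strand
#'
#' @param x a [TrnaAlignment].
#' @param i strand indices (numeric, logical or strand ids).
#' @param j,...,drop ignored.
#' @return a [TrnaAlignment] with the selected strands.
#' @export
setMethod("[", "TrnaAlignment", function(x, i, j, ..., drop = FALSE) {
  new("TrnaAlignment",
      codes = x@codes[i, , drop = FALSE],
      classLabel = unname(strandClasses(x)[i]),
      alphabet = x@alphabet, classTable = x@classTable)
})

setMethod("show", "NucleosideAlphabet", function(object) {
  cat("NucleosideAlphabet with", length(object@codes), "codes",
      sprintf("(gap '%s')\n", object@gapCode))
  cat(" ", paste(object@codes, collapse = " "), "\n")
})

setMethod("show", "ClassTable", function(object) {
  cat("ClassTable with", nrow(object@table), "tRNA classes\n")
  print(utils::head(object@table, 5))
  if (nrow(object@table) > 5) cat("  ...", nrow(object@table) - 5, "more\n")
})

setMethod("show", "TrnaAlignment", function(object) {
  cat("TrnaAlignment:", nrow(object@codes), "strands x 77 positions,",
      length(unique(object@classLabel)), "classes\n")
  tb <- sort(table(object@classLabel), decreasing = TRUE)
  cat("  classes:", paste(utils::head(names(tb), 8), utils::head(tb, 8),
                          sep = ":", collapse = " "),
      if (length(tb) > 8) "..." else "", "\n")
})

setMethod("show", "TrnaFeatureMatrix", function(object) {
  cat("TrnaFeatureMatrix:", nrow(object@matrix), "strands x",
      ncol(object@matrix), "Boolean (position, code) attributes\n")
})

setMethod("show", "SimpleLogisticModel", function(object) {
  cat("SimpleLogisticModel:", length(object@classLevels), "classes,",
      object@iterations, "boosting iterations kept\n")
  cat("  sparse coefficients:", nrow(object@coef), "over",
      length(unique(paste(object@coef$position, object@coef$code))),
      "(position, code) attributes\n")
  cat("  final training error:",
      format(object@errorPath[object@iterations], digits = 4), "\n")
})

setMethod("show", "EnergyProfile", function(object) {
  cat(sprintf("EnergyProfile for strand '%s' (class %s), unit %g kT\n",
              object@strandId, object@classLabel, object@kBT))
  cat(sprintf("  dG = %.4f  (forward %.4f + reverse %.4f; tandem %.4f, other %.4f)\n",
              object@total, object@forward, object@reverse,
              object@reverseTandem, object@reverseOther))
})
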