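#' @import methods
NULL

#' Nucleoside alphabet for aligned tRNA strands
#'
#' One-letter codes for the nucleosides (canonical and modified) that may
#' occupy a position of an aligned tRNA strand, plus the code for an empty
#' position. Each modified code carries a \code{parentBase} (one of
#' \code{"A"}, \code{"U"}, \code{"G"}, \code{"C"}, or \code{"none"}) used
#' when counting theoretically possible hydrogen bonds.
#'
#' @slot codes character vector of unique one-letter (or short token) codes.
#' @slot nucleosideNames human-readable names, parallel to \code{codes}.
#' @slot parentBase parent canonical base per code (\code{"none"} when the
#'   nucleoside cannot be assigned to a canonical base).
#' @slot gapCode the code standing for an empty position (default \code{"-"}).
#'   An empty position is a legal attribute value, not missing data.
#'
#' @seealso [defaultAlphabet()], [hbondCount()]
#' @exportClass NucleosideAlphabet
setClass("NucleosideAlphabet",
         representation(codes = "character",
                        nucleosideNames = "character",
                        parentBase = "character",
                        gapCode = "character"))

setValidity("NucleosideAlphabet", function(object) {
  msg <- character()
  if (anyDuplicated(object@codes))
    msg <- c(msg, "codes must be unique")
  if (length(object@codes) != length(object@parentBase) ||
      length(object@codes) != length(object@nucleosideNames))
    msg <- c(msg, "codes, nucleosideNames and parentBase must be parallel")
  if (!all(object@parentBase %in% c("A", "U", "G", "C", "none")))
    msg <- c(msg, "parentBase must be one of A, U, G, C, none")
  if (!(object@gapCode %in% object@codes))
    msg <- c(msg, "gapCode must be listed among the codes")
  else if (object@parentBase[match(object@gapCode, object@codes)] != "none")
    msg <- c(msg, "gapCode must have parentBase 'none'")
  for (b in c("A", "U", "G", "C")) {
    i <- match(b, object@codes)
    if (is.na(i) || object@parentBase[i] != b)
      msg <- c(msg, sprintf("canonical base %s must be present as its own parent", b))
  }
  if (length(msg)) msg else TRUE
})

#' Table of tRNA amino-acid-load classes
#'
#' The ordered list of tRNA classes under analysis. Each class is defined by
#' the amino acid its tRNAs are charged with, the fixed anticodon tandem
#' (the codes at strand positions 35 and 36), a remark distinguishing
#' degenerate-anticodon and synthetase-form classes, and the molecular
#' weight of the charging amino acid in Daltons.
#'
#' Class labels cannot always be derived from the sequence (two lysine
#' classes served by different synthetase forms share the same tandem), so
#' the class is a required annotation on input strands.
#'
#' @slot table data.frame with columns \code{class}, \code{amino_acid},
#'   \code{tandem35}, \code{tandem36}, \code{remark},
#'   \code{molecular_weight}.
#'
#' @seealso [loadFixture()]
#' @exportClass ClassTable
setClass("ClassTable", representation(table = "data.frame"))

setValidity("ClassTable", function(object) {
  tb <- object@table
  need <- c("class", "amino_acid", "tandem35", "tandem36", "remark",
            "molecular_weight")
  msg <- character()
  if (!all(need %in% names(tb)))
    msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(tb$class)) msg <- c(msg, "class labels must be unique")
    if (!all(tb$tandem35 %in% c("A", "U", "G", "C")) ||
        !all(tb$tandem36 %in% c("A", "U", "G", "C")))
      msg <- c(msg, "tandem codes must be canonical bases (A, U, G, C)")
  }
  if (length(msg)) msg else TRUE
})

#' Aligned tRNA strands with class annotation
#'
#' A set of pre-aligned tRNA strands over the 77 canonical positions
#' (labelled \code{"-1"}, \code{"1"} .. \code{"76"}; there is no position 0).
#' Each strand is a row of one-letter nucleoside codes drawn from a
#' [NucleosideAlphabet] and carries one class label from a [ClassTable].
#'
#' @slot codes character matrix, strands x 77 positions; rownames are strand
#'   identifiers, colnames the fixed position labels.
#' @slot classLabel character vector of class labels, one per strand.
#' @slot alphabet the [NucleosideAlphabet] the codes are drawn from.
#' @slot classTable the [ClassTable] the labels refer to.
#'
#' @seealso [readTrnaAlignment()], [simulateTrnaAlignment()]
#' @exportClass TrnaAlignment
setClass("TrnaAlignment",
         representation(codes = "matrix",
                        classLabel = "character",
                        alphabet = "NucleosideAlphabet",
                        classTable = "ClassTable"))

#' Canonical position labels
#'
#' The fixed ordered labels of the 77 alignment positions: \code{"-1"}
#' followed by \code{"1"} .. \code{"76"}.
#'
#' @return character vector of length 77.
#' @export
#' @examples
#' head(canonicalPositions())
canonicalPositions <- function() c("-1", as.character(1:76))

setValidity("TrnaAlignment", function(object) {
  msg <- character()
  m <- object@codes
  if (!is.character(m)) msg <- c(msg, "codes must be a character matrix")
  if (ncol(m) != 77 || !identical(colnames(m), canonicalPositions()))
    msg <- c(msg, "codes must have exactly the 77 canonical position columns")
  if (length(object@classLabel) != nrow(m))
    msg <- c(msg, "one class label per strand required")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "strand ids (rownames) must be present and unique")
  bad <- setdiff(unique(as.vector(m)), object@alphabet@codes)
  if (length(bad))
    msg <- c(msg, paste("codes outside the alphabet:",
                        paste(bad, collapse = " ")))
  badcl <- setdiff(unique(object@classLabel), object@classTable@table$class)
  if (length(badcl))
    msg <- c(msg, paste("unknown class labels:", paste(badcl, collapse = " ")))
  if (length(msg)) msg else TRUE
})

#' Boolean position-by-nucleoside feature matrix
#'
#' One-hot encoding of a [TrnaAlignment]: one indicator column per
#' (position, observed code) pair. Every strand activates exactly one
#' column per position (the empty-position code included), so each row sums
#' to 77.
#'
#' @slot matrix numeric 0/1 matrix, strands x features.
#' @slot position position label of each column.
#' @slot code nucleoside code of each column.
#'
#' @seealso [encodeFeatures()]
#' @exportClass TrnaFeatureMatrix
setClass("TrnaFeatureMatrix",
         representation(matrix = "matrix",
                        position = "character",
                        code = "character"))

setValidity("TrnaFeatureMatrix", function(object) {
  msg <- character()
  if (ncol(object@matrix) != length(object@position) ||
      ncol(object@matrix) != length(object@code))
    msg <- c(msg, "position/code annotations must be parallel to the columns")
  if (length(msg)) msg else TRUE
})

#' Fitted multiclass simple-logistic model
#'
#' The result of [fitSimpleLogistic()]: a sparse multiclass linear logistic
#' model built by LogitBoost with single-attribute weighted least-squares
#' base learners. For each class \eqn{i} the linear predictor is
#' \deqn{f_i = b_i + \sum_{jk} p_{ijk} [pos_j = N_k]}
#' over the Boolean position-by-nucleoside indicators.
#'
#' The collapsed model sums, per class, the intercepts and per-column
#' slopes of that class's own base learners across the kept iterations, so
#' each class's coefficients cover exactly the attributes its learners
#' selected. The recentring applied to the boosting scores during fitting
#' is a positive scale plus a class-common shift, so the raw per-class
#' functions stored here produce the same class ranking (and hence the
#' same training-error path) as the internal boosted scores.
#'
#' @slot classLevels class labels in table order.
#' @slot bias per-class intercept \eqn{b_i}.
#' @slot coef data.frame \code{class}, \code{position}, \code{code},
#'   \code{value}: sparse coefficients \eqn{p_{ijk}}.
#' @slot errorPath training misclassification rate after each boosting
#'   iteration (up to the last iteration actually run).
#' @slot lossPath multinomial negative log-likelihood after each iteration.
#' @slot iterations the selected iteration count (earliest minimum of the
#'   training error path).
#' @slot selectionLog data.frame \code{iteration}, \code{class},
#'   \code{position}, \code{code}, \code{slope}, \code{intercept}: the raw
#'   base-learner choices, one row per class per iteration.
#' @slot control the [boostControl()] list used for fitting.
#'
#' @exportClass SimpleLogisticModel
setClass("SimpleLogisticModel",
         representation(classLevels = "character",
                        bias = "numeric",
                        coef = "data.frame",
                        errorPath = "numeric",
                        lossPath = "numeric",
                        iterations = "integer",
                        selectionLog = "data.frame",
                        control = "list"))

#' Per-strand binding free-energy profile
#'
#' The Gibbs free energy of binding of one strand to its cognate synthetase,
#' in multiples of kT, derived from a fitted [SimpleLogisticModel]. The
#' total \eqn{\Delta G_{ii} = -k_BT f_i} splits exactly into a forward
#' (nucleotide-independent, repulsive) part equal to the bias energy
#' \eqn{\Delta G^0_{ii} = -k_BT b_i} and a reverse (nucleotide-dependent,
#' attractive) part summing the per-position inputs
#' \eqn{\Delta G_{ijk} = -k_BT p_{ijk}}. The reverse part further splits
#' into the anticodon-tandem contribution (positions 35 and 36 only) and
#' the remainder.
#'
#' @slot strandId strand identifier.
#' @slot classLabel the class whose predictor was evaluated.
#' @slot total total \eqn{\Delta G_{ii}} in kT.
#' @slot bias bias energy \eqn{\Delta G^0_{ii}}.
#' @slot forward forward part (equals \code{bias}).
#' @slot reverse reverse part (sum of all active inputs).
#' @slot reverseTandem reverse part restricted to positions 35-36.
#' @slot reverseOther reverse part excluding positions 35-36.
#' @slot inputs data.frame \code{position}, \code{code}, \code{dG} of the
#'   strand's active coefficient-bearing indicators.
#' @slot kBT the energy unit used.
#'
#' @seealso [strandEnergy()]
#' @exportClass EnergyProfile
setClass("EnergyProfile",
         representation(strandId = "character",
                        classLabel = "character",
                        total = "numeric",
                        bias = "numeric",
                        forward = "numeric",
                        reverse = "numeric",
                        reverseTandem = "numeric",
                        reverseOther = "numeric",
                        inputs = "data.frame",
                        kBT = "numeric"))

setValidity("EnergyProfile", function(object) {
  tol <- 1e-9
  msg <- character()
  if (abs(object@total - (object@forward + object@reverse)) > tol)
    msg <- c(msg, "total must equal forward + reverse")
  if (abs(object@reverse - (object@reverseTandem + object@reverseOther)) > tol)
    msg <- c(msg, "reverse must equal tandem + non-tandem parts")
  if (abs(object@bias - object@forward) > tol)
    msg <- c(msg, "forward part must equal the bias energy")
  if (length(msg)) msg else TRUE
})
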