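#' One-hot encode an alignment into Boolean attributes
#'
#' Builds the Boolean explanatory variables of the linear predictor: one
#' indicator column per (position, code) pair observed in the alignment
#' (plus any requested extras). Every strand activates exactly one column
#' per position, the empty-position code included, so each row sums to 77.
#'
#' @param x a [TrnaAlignment].
#' @param extraColumns optional data.frame \code{position}, \code{code} of
#'   additional columns to materialise even if unobserved.
#' @return a [TrnaFeatureMatrix]; rows in strand order.
#' @export
#' @examples
#' aln <- loadFixture("consensus_table")
#' X <- encodeFeatures(aln)
#' all(rowSums(featureMatrix(X)) == 77)
encodeFeatures <- function(x, extraColumns = NULL) {
  m <- strandCodes(x)
  cols <- unique(data.frame(position = rep(canonicalPositions(),
                                           each = nrow(m)),
                            code = as.vector(m),
                            stringsAsFactors = FALSE))
  if (!is.null(extraColumns))
    cols <- unique(rbind(cols, extraColumns[, c("position", "code")]))
  # fixed ordering: position order, then alphabet order of codes
  ord <- order(match(cols$position, canonicalPositions()),
               match(cols$code, x@alphabet@codes))
  cols <- cols[ord, , drop = FALSE]
  X <- matrix(0, nrow(m), nrow(cols),
              dimnames = list(rownames(m),
                              paste(cols$position, cols$code, sep = "|")))
  for (j in seq_len(nrow(cols)))
    X[, j] <- as.numeric(m[, cols$position[j]] == cols$code[j])
  new("TrnaFeatureMatrix", matrix = X, position = cols$position,
      code = cols$code)
}

#' Correlation-based attribute ranking of alignment positions
#'
#' Ranks the 77 positions by association with the class attribute. For each
#' position, the rank value is the frequency-weighted mean over all
#' (code indicator, class indicator) pairs of the absolute Pearson
#' correlation between the two binary vectors, with weights equal to code
#' frequency times class frequency. Undefined correlations (zero-variance
#' indicators) contribute 0. The class attribute itself is not ranked, and
#' the empty-position code participates like any other code.
#'
#' This weighted-mean-of-|r| definition is the package's fixed contract for
#' the ranking; it is order-independent and reproduces the qualitative
#' dominance of the anticodon tandem positions on class-structured data.
#'
#' @param X a [TrnaFeatureMatrix] or a [TrnaAlignment].
#' @param y class labels (taken from the alignment when \code{X} is one).
#' @return data.frame \code{position}, \code{rank_value}, sorted by
#'   decreasing rank value, ties broken by position order.
#' @export
#' @examples
#' aln <- simulateTrnaAlignment(defaultSyntheticConfig(seed = 5,
#'                                                     strandsPerClass = 5))
#' head(correlationRanking(aln))
correlationRanking <- function(X, y = NULL) {
  if (is(X, "TrnaAlignment")) {
    y <- unname(strandClasses(X))
    X <- encodeFeatures(X)
  }
  stopifnot(is(X, "TrnaFeatureMatrix"), !is.null(y))
  m <- X@matrix
  if (length(unique(y)) < 2)
    stop("correlation ranking needs at least two classes")
  classes <- unique(y)
  Y <- vapply(classes, function(cl) as.numeric(y == cl),
              numeric(nrow(m)))
  classFreq <- colMeans(Y)
  codeFreq <- colMeans(m)
  # |cor| between every code column and class column; 0 where undefined
  suppressWarnings(R <- abs(stats::cor(m, Y)))
  R[!is.finite(R)] <- 0
  W <- outer(codeFreq, classFreq)
  num <- rowSums(R * W)
  den <- rowSums(W)
  rank <- vapply(canonicalPositions(), function(pos) {
    j <- X@position == pos
    if (!any(j)) return(0)
    sum(num[j]) / sum(den[j])
  }, numeric(1))
  out <- data.frame(position = canonicalPositions(),
                    rank_value = unname(rank), stringsAsFactors = FALSE)
  out[order(-out$rank_value, match(out$position, canonicalPositions())), ,
      drop = FALSE]
}
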