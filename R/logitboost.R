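#' Control parameters for simple-logistic boosting
#'
#' @param maxIterations maximum number of LogitBoost iterations.
#' @param stopWindow no-improvement window: iteration halts once the
#'   current iteration exceeds the training-error minimum by more than this
#'   many iterations.
#' @param weightTrimBeta weight-trimming fraction; 0 disables trimming and
#'   every instance is used in every iteration (the only supported value).
#' @param useCrossValidation must be \code{FALSE}: the number of iterations
#'   is chosen by the training-error minimum, not by cross-validation, so
#'   the fit does not depend on data order.
#' @param zCap cap on the absolute working response, for numerical
#'   stability.
#' @param probFloor floor applied to class probabilities when forming
#'   working responses and weights.
#' @return a named list of class \code{boostControl}.
#' @export
boostControl <- function(maxIterations = 500L, stopWindow = 50L,
                         weightTrimBeta = 0, useCrossValidation = FALSE,
                         zCap = 3, probFloor = 1e-10) {
  stopifnot(maxIterations >= 1, stopWindow >= 0,
            weightTrimBeta >= 0, weightTrimBeta < 1)
  if (weightTrimBeta != 0)
    stop("weight trimming is not supported; use weightTrimBeta = 0")
  if (useCrossValidation)
    stop("cross-validation-based stopping is not supported")
  structure(list(maxIterations = as.integer(maxIterations),
                 stopWindow = as.integer(stopWindow),
                 weightTrimBeta = weightTrimBeta,
                 useCrossValidation = useCrossValidation,
                 zCap = zCap, probFloor = probFloor),
            class = "boostControl")
}

softmaxRows <- function(F) {
  E <- exp(F - apply(F, 1, max))
  E / rowSums(E)
}

#' Fit a multiclass simple-logistic model by LogitBoost
#'
#' Stagewise additive logistic regression with single-attribute linear base
#' learners. Each iteration computes, per class, working responses and
#' weights from the current class probabilities, fits for every class the
#' single-attribute weighted least-squares line minimising weighted squared
#' error over all columns (ties broken towards the lowest column index),
#' recentres the fitted functions across classes (subtracting their mean
#' and scaling by (J-1)/J), adds them to the additive scores and updates
#' the probabilities by the multinomial softmax. After each iteration the
#' training misclassification rate is recorded; the final model is
#' truncated at the iteration with minimal training error (earliest on
#' ties), and iteration halts early once no new minimum has appeared within
#' \code{stopWindow} iterations. The additive model is then collapsed into
#' per-class biases and sparse per-attribute coefficients.
#'
#' @param X a [TrnaFeatureMatrix], or a [TrnaAlignment] (encoded on the
#'   fly).
#' @param y class labels (taken from the alignment when \code{X} is one).
#' @param control a [boostControl()].
#' @param classLevels class order; defaults to the class-table order when
#'   \code{X} is an alignment, otherwise to first appearance in \code{y}.
#' @return a [SimpleLogisticModel].
#' @export
#' @examples
#' cfg <- defaultSyntheticConfig(seed = 2, strandsPerClass = 4, theta = 1)
#' aln <- simulateTrnaAlignment(cfg)
#' fit <- fitSimpleLogistic(aln, control = boostControl(maxIterations = 30))
#' fit
fitSimpleLogistic <- function(X, y = NULL, control = boostControl(),
                              classLevels = NULL) {
  if (is(X, "TrnaAlignment")) {
    if (is.null(y)) y <- unname(strandClasses(X))
    if (is.null(classLevels))
      classLevels <- intersect(classLabels(classTable(X)), unique(y))
    X <- encodeFeatures(X)
  }
  stopifnot(is(X, "TrnaFeatureMatrix"))
  if (is.null(classLevels)) classLevels <- unique(y)
  Xm <- X@matrix
  n <- nrow(Xm); p <- ncol(Xm)
  if (n == 0) stop("empty training data")
  J <- length(classLevels)
  if (J < 2) stop("at least two classes are required")
  yIdx <- match(y, classLevels)
  if (anyNA(yIdx)) stop("labels outside classLevels")
  Ymat <- matrix(0, n, J); Ymat[cbind(seq_len(n), yIdx)] <- 1

  Fmat <- matrix(0, n, J)
  P <- matrix(1 / J, n, J)
  eps <- control$probFloor
  maxIt <- control$maxIterations
  selCol <- matrix(NA_integer_, maxIt, J)
  selSlope <- matrix(0, maxIt, J)
  selInt <- matrix(0, maxIt, J)
  errPath <- lossPath <- numeric(maxIt)
  mLast <- 0L
  for (m in seq_len(maxIt)) {
    Pc <- pmin(pmax(P, eps), 1 - eps)
    Z <- pmin(pmax((Ymat - Pc) / (Pc * (1 - Pc)),
                   -control$zCap), control$zCap)
    W <- Pc * (1 - Pc)
    CW <- crossprod(Xm, W)        # p x J: sum of w over rows with x = 1
    CWZ <- crossprod(Xm, W * Z)   # p x J: sum of w z over rows with x = 1
    fvals <- matrix(0, n, J)
    for (j in seq_len(J)) {
      w <- W[, j]
      Sw <- sum(w); Swz <- sum(w * Z[, j])
      cw <- CW[, j]; cwz <- CWZ[, j]
      xbar <- cw / Sw
      num <- cwz - xbar * Swz
      den <- cw * (1 - xbar)
      ok <- den > 1e-12
      score <- numeric(p)
      score[ok] <- num[ok]^2 / den[ok]
      if (any(ok) && max(score) > 0) {
        best <- which.max(score)  # earliest index on ties
        b <- num[best] / den[best]
        a <- (Swz - b * cw[best]) / Sw
        fvals[, j] <- a + b * Xm[, best]
        selCol[m, j] <- best; selSlope[m, j] <- b; selInt[m, j] <- a
      } else {
        a <- Swz / Sw             # intercept-only fallback
        fvals[, j] <- a
        selInt[m, j] <- a
      }
    }
    fvals <- ((J - 1) / J) * (fvals - rowMeans(fvals))
    Fmat <- Fmat + fvals
    P <- softmaxRows(Fmat)
    errPath[m] <- mean(max.col(Fmat, ties.method = "first") != yIdx)
    lossPath[m] <- -sum(log(pmax(P[cbind(seq_len(n), yIdx)], eps)))
    mLast <- m
    mStar <- which.min(errPath[seq_len(m)])
    if (m - mStar > control$stopWindow) break
  }
  errPath <- errPath[seq_len(mLast)]
  lossPath <- lossPath[seq_len(mLast)]
  mStar <- which.min(errPath)

  # collapse the additive model at the selected iteration by summing each
  # class's own intercepts and per-column slopes; the recentring transform
  # applied to the boosting scores is a positive scale plus a class-common
  # shift, so the raw per-class functions yield the same class ranking
  bias <- colSums(selInt[seq_len(mStar), , drop = FALSE])
  ownAcc <- new.env(parent = emptyenv())
  for (m in seq_len(mStar)) {
    for (k in seq_len(J)) {
      ck <- selCol[m, k]
      if (is.na(ck)) next
      key <- paste(k, ck)
      cur <- if (is.null(ownAcc[[key]])) 0 else ownAcc[[key]]
      ownAcc[[key]] <- cur + selSlope[m, k]
    }
  }
  unpack <- function(env) {
    keys <- ls(env)
    if (!length(keys))
      return(data.frame(class = character(), position = character(),
                        code = character(), value = numeric(),
                        stringsAsFactors = FALSE))
    parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
    i <- as.integer(parts[, 1]); cix <- as.integer(parts[, 2])
    val <- vapply(keys, function(k) env[[k]], numeric(1))
    out <- data.frame(class = classLevels[i],
                      position = X@position[cix], code = X@code[cix],
                      value = unname(val), stringsAsFactors = FALSE)
    out <- out[abs(out$value) > 0, , drop = FALSE]
    out <- out[order(match(out$class, classLevels),
                     match(out$position, canonicalPositions()), out$code), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  }
  colsUsed <- as.vector(selCol[seq_len(mLast), , drop = FALSE])
  selLog <- data.frame(
    iteration = rep(seq_len(mLast), J),
    class = rep(classLevels, each = mLast),
    position = X@position[colsUsed],
    code = X@code[colsUsed],
    slope = as.vector(selSlope[seq_len(mLast), , drop = FALSE]),
    intercept = as.vector(selInt[seq_len(mLast), , drop = FALSE]),
    stringsAsFactors = FALSE)
  new("SimpleLogisticModel", classLevels = classLevels,
      bias = stats::setNames(bias, classLevels),
      coef = unpack(ownAcc),
      errorPath = errPath, lossPath = lossPath,
      iterations = as.integer(mStar), selectionLog = selLog,
      control = unclass(control))
}

#' Evaluate the per-class linear predictors
#'
#' Computes \eqn{f_i = b_i + \sum p_{ijk} [pos_j = N_k]} for every strand.
#' Codes without a stored coefficient (including codes outside the model's
#' training alphabet) contribute 0.
#'
#' @param model a [SimpleLogisticModel].
#' @param x a [TrnaAlignment] or a [TrnaFeatureMatrix].
#' @return numeric matrix, strands x classes.
#' @export
predictorValues <- function(model, x) {
  co <- model@coef
  if (is(x, "TrnaFeatureMatrix")) {
    n <- nrow(x@matrix)
    key <- paste(x@position, x@code, sep = "|")
    F <- matrix(rep(model@bias, each = n), n, length(model@classLevels),
                dimnames = list(rownames(x@matrix), model@classLevels))
    if (nrow(co)) {
      j <- match(paste(co$position, co$code, sep = "|"), key)
      keep <- !is.na(j)
      for (r in which(keep)) {
        cl <- co$class[r]
        F[, cl] <- F[, cl] + co$value[r] * x@matrix[, j[r]]
      }
    }
    return(F)
  }
  stopifnot(is(x, "TrnaAlignment"))
  m <- strandCodes(x)
  n <- nrow(m)
  F <- matrix(rep(model@bias, each = n), n, length(model@classLevels),
              dimnames = list(rownames(m), model@classLevels))
  for (r in seq_len(nrow(co))) {
    hit <- m[, co$position[r]] == co$code[r]
    if (any(hit))
      F[hit, co$class[r]] <- F[hit, co$class[r]] + co$value[r]
  }
  F
}

#' Predict class labels and probabilities
#'
#' Class probabilities are the multinomial softmax of the linear
#' predictors; the label is the class with the largest predictor, the first
#' class in table order winning exact ties.
#'
#' @param object a [SimpleLogisticModel].
#' @param newdata a [TrnaAlignment] or [TrnaFeatureMatrix].
#' @param ... ignored.
#' @return list with \code{label} (character vector), \code{probability}
#'   (matrix strands x classes) and \code{predictor} (the \eqn{f_i}
#'   matrix).
#' @export
setMethod("predict", "SimpleLogisticModel", function(object, newdata, ...) {
  F <- predictorValues(object, newdata)
  P <- softmaxRows(F)
  lab <- object@classLevels[max.col(F, ties.method = "first")]
  list(label = stats::setNames(lab, rownames(F)), probability = P,
       predictor = F)
})

#' Serialise a fitted model to JSON (and back)
#'
#' The JSON file stores the class order, biases, both sparse coefficient
#' views, the fitting control, the error and loss paths and the
#' base-learner selection log; reading it back reproduces the model
#' exactly.
#'
#' @param model a [SimpleLogisticModel].
#' @param path file path.
#' @return \code{path} invisibly, or the restored model.
#' @export
writeModelJson <- function(model, path) {
  obj <- list(classLevels = model@classLevels,
              bias = as.list(model@bias),
              coef = model@coef,
              errorPath = model@errorPath, lossPath = model@lossPath,
              iterations = model@iterations,
              selectionLog = model@selectionLog,
              control = model@control)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixDf <- function(d, cols) {
    if (is.null(d) || !length(d))
      return(data.frame(class = character(), position = character(),
                        code = character(), value = numeric(),
                        stringsAsFactors = FALSE))
    as.data.frame(d, stringsAsFactors = FALSE)
  }
  new("SimpleLogisticModel",
      classLevels = obj$classLevels,
      bias = stats::setNames(unlist(obj$bias), obj$classLevels),
      coef = fixDf(obj$coef),
      errorPath = as.numeric(obj$errorPath),
      lossPath = as.numeric(obj$lossPath),
      iterations = as.integer(obj$iterations),
      selectionLog = as.data.frame(obj$selectionLog,
                                   stringsAsFactors = FALSE),
      control = obj$control)
}
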