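# Independent LogitBoost replay: recomputes the probability updates from
# scratch and brute-force-checks, at every iteration and for every class,
# that the logged base-learner choice minimises the weighted SSE over all
# columns and that its slope/intercept match the weighted least-squares
# closed form. The replay advances using the logged picks so both
# trajectories stay aligned.
refBoostCheck <- function(X, y, model) {
  Xm <- X@matrix
  colKey <- paste(X@position, X@code)
  ctl <- model@control
  n <- nrow(Xm); p <- ncol(Xm)
  classLevels <- model@classLevels
  J <- length(classLevels)
  yIdx <- match(y, classLevels)
  Ymat <- matrix(0, n, J); Ymat[cbind(seq_len(n), yIdx)] <- 1
  F <- matrix(0, n, J); P <- matrix(1 / J, n, J)
  log <- model@selectionLog
  iters <- max(log$iteration)
  okPick <- okFit <- TRUE
  errPath <- numeric(iters)
  for (m in seq_len(iters)) {
    Pc <- pmin(pmax(P, ctl$probFloor), 1 - ctl$probFloor)
    Z <- pmin(pmax((Ymat - Pc) / (Pc * (1 - Pc)), -ctl$zCap), ctl$zCap)
    W <- Pc * (1 - Pc)
    fv <- matrix(0, n, J)
    for (j in seq_len(J)) {
      w <- W[, j]; z <- Z[, j]
      fits <- lapply(seq_len(p), function(cix) {
        x <- Xm[, cix]
        xb <- sum(w * x) / sum(w)
        den <- sum(w * (x - xb)^2)
        if (den <= 1e-12) return(NULL)
        b <- sum(w * (x - xb) * z) / den
        a <- sum(w * z) / sum(w) - b * xb
        list(a = a, b = b, sse = sum(w * (z - a - b * x)^2))
      })
      sses <- vapply(fits, function(f) if (is.null(f)) Inf else f$sse,
                     numeric(1))
      row <- log[log$iteration == m & log$class == classLevels[j], ]
      if (is.na(row$position)) {
        fv[, j] <- sum(w * z) / sum(w)
      } else {
        cix <- match(paste(row$position, row$code), colKey)
        f <- fits[[cix]]
        okPick <- okPick && f$sse <= min(sses) + 1e-9
        okFit <- okFit && abs(f$a - row$intercept) < 1e-8 &&
          abs(f$b - row$slope) < 1e-8
        fv[, j] <- f$a + f$b * Xm[, cix]
      }
    }
    fv <- ((J - 1) / J) * (fv - rowMeans(fv))
    F <- F + fv
    E <- exp(F - apply(F, 1, max)); P <- E / rowSums(E)
    errPath[m] <- mean(max.col(F, ties.method = "first") != yIdx)
  }
  list(okPick = okPick, okFit = okFit, errPath = errPath)
}
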