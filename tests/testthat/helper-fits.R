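# Fitted models shared across test files (computed once per run).

.fitCache <- new.env(parent = emptyenv())

# fully separable study-like data: penetrance 1, 20 strands/class
separableFit <- function() {
  if (is.null(.fitCache$sep)) {
    cfg <- defaultSyntheticConfig(seed = 42, strandsPerClass = 20,
                                  theta = 1)
    aln <- simulateTrnaAlignment(cfg)
    .fitCache$sep <- list(cfg = cfg, aln = aln,
                          fit = fitSimpleLogistic(aln))
  }
  .fitCache$sep
}

# study-condition data: penetrance 0.85, 50 strands/class
studyFit <- function() {
  if (is.null(.fitCache$study)) {
    cfg <- defaultSyntheticConfig(seed = 1, strandsPerClass = 50,
                                  theta = 0.85)
    aln <- simulateTrnaAlignment(cfg)
    .fitCache$study <- list(cfg = cfg, aln = aln,
                            fit = fitSimpleLogistic(aln))
  }
  .fitCache$study
}

# per-class precision/recall of planted attract cells, averaged over classes
plantRecovery <- function(cfg, sets) {
  pa <- cfg$plants[cfg$plants$sign == "attract", , drop = FALSE]
  prec <- rec <- numeric(0)
  for (cl in classLabels(cfg$classTable)) {
    truth <- paste0(pa$position, pa$code)[pa$class == cl]
    got <- sets[sets$class == cl & sets$sign == "attract", , drop = FALSE]
    gotCells <- unlist(lapply(seq_len(nrow(got)), function(i)
      paste0(got$position[i],
             strsplit(got$codes[i], ",", fixed = TRUE)[[1]])))
    tp <- length(intersect(gotCells, truth))
    prec <- c(prec, if (length(gotCells)) tp / length(gotCells) else NA)
    rec <- c(rec, if (length(truth)) tp / length(truth) else NA)
  }
  tan <- pa[pa$position %in% c("35", "36"), , drop = FALSE]
  att <- sets[sets$sign == "attract", , drop = FALSE]
  tanRecall <- mean(paste(tan$class, tan$position, tan$code) %in%
                      paste(att$class, att$position, att$codes))
  list(precision = mean(prec, na.rm = TRUE),
       recall = mean(rec, na.rm = TRUE), tandemRecall = tanRecall)
}
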