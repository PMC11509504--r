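#' Boltzmann binding probability from free energies
#'
#' With competing energies supplied, the probability of binding the cognate
#' complex is the Boltzmann share
#' \eqn{p = e^{-\Delta G}/(1 + \sum_j e^{-\Delta G_j})}; without
#' competitors it reduces to the two-state form
#' \eqn{p = e^{-\Delta G}/(1 + e^{-\Delta G})}, the limit in which the
#' cognate complex binds much more strongly than all others.
#'
#' @param dG Gibbs free energy of binding the cognate complex, in kT.
#' @param others optional vector of free energies \eqn{\Delta G_j} of
#'   binding the competing complexes (the cognate energy included among
#'   them when the full normalised distribution is wanted).
#' @param kBT energy unit (default 1: energies already in kT multiples).
#' @return binding probability.
#' @export
#' @examples
#' bindingProbability(0)            # 0.5
#' bindingProbability(-log(3))      # 0.75
bindingProbability <- function(dG, others = NULL, kBT = 1) {
  stopifnot(kBT > 0, is.finite(dG))
  if (is.null(others)) return(exp(-dG / kBT) / (1 + exp(-dG / kBT)))
  stopifnot(all(is.finite(others)))
  exp(-dG / kBT) / (1 + sum(exp(-others / kBT)))
}

#' Logit-energy correspondence
#'
#' Maps a binding probability to a Gibbs free energy via
#' \eqn{\Delta G = -k_BT \,\mathrm{logit}(p)} and back. Probabilities of
#' exactly 0 or 1 correspond to infinite energies and are rejected.
#'
#' @param p binding probability strictly between 0 and 1.
#' @param dG free energy in kT.
#' @param kBT energy unit.
#' @return \code{logitEnergy}: the free energy; \code{inverseLogitEnergy}:
#'   the probability.
#' @export
#' @examples
#' logitEnergy(0.5)                       # 0
#' logitEnergy(exp(1) / (1 + exp(1)))     # -1
#' inverseLogitEnergy(logitEnergy(0.73))  # 0.73
logitEnergy <- function(p, kBT = 1) {
  stopifnot(kBT > 0)
  if (any(p <= 0 | p >= 1))
    stop("probability must be strictly between 0 and 1 (infinite energy)")
  -kBT * log(p / (1 - p))
}

#' @rdname logitEnergy
#' @export
inverseLogitEnergy <- function(dG, kBT = 1) {
  stopifnot(kBT > 0)
  1 / (1 + exp(dG / kBT))
}

tandemPositions <- function() c("35", "36")

#' Free-energy profile of one strand
#'
#' Evaluates the thermodynamic mapping of the fitted predictor for a
#' single strand: total \eqn{\Delta G_{ii} = -k_BT f_i}, per-position
#' inputs \eqn{\Delta G_{ijk} = -k_BT p_{ijk}} for every active
#' coefficient-bearing indicator, bias energy
#' \eqn{\Delta G^0_{ii} = -k_BT b_i}, and the exact decomposition into the
#' forward (nucleotide-independent) part, which equals the bias energy, and
#' the reverse (nucleotide-dependent) part, itself split into the
#' anticodon-tandem contribution (positions 35-36) and the rest. A
#' positive coefficient yields a negative, attracting energy input.
#'
#' @param model a [SimpleLogisticModel].
#' @param x a [TrnaAlignment].
#' @param strand strand id or index (default: first strand).
#' @param classLabel class whose predictor to evaluate; defaults to the
#'   strand's own class.
#' @param kBT energy unit.
#' @return an [EnergyProfile].
#' @export
strandEnergy <- function(model, x, strand = 1L, classLabel = NULL,
                         kBT = 1) {
  stopifnot(is(x, "TrnaAlignment"), kBT > 0)
  if (is.character(strand)) strand <- match(strand, strandIds(x))
  codes <- strandCodes(x)[strand, ]
  id <- strandIds(x)[strand]
  if (is.null(classLabel)) classLabel <- unname(strandClasses(x)[strand])
  if (!(classLabel %in% model@classLevels))
    stop("class '", classLabel, "' not present in the model")
  co <- model@coef[model@coef$class == classLabel, , drop = FALSE]
  active <- co[codes[co$position] == co$code, , drop = FALSE]
  inputs <- data.frame(position = active$position, code = active$code,
                       dG = -kBT * active$value, stringsAsFactors = FALSE)
  bias <- -kBT * unname(model@bias[classLabel])
  revTan <- sum(inputs$dG[inputs$position %in% tandemPositions()])
  revOther <- sum(inputs$dG[!(inputs$position %in% tandemPositions())])
  new("EnergyProfile", strandId = id, classLabel = classLabel,
      total = bias + revTan + revOther, bias = bias, forward = bias,
      reverse = revTan + revOther, reverseTandem = revTan,
      reverseOther = revOther, inputs = inputs, kBT = kBT)
}

#' Per-class free-energy summary
#'
#' Evaluates every strand against its own class predictor and summarises
#' per class: mean, standard deviation and maximum of the total
#' \eqn{\Delta G_{ii}} (the maximum is the recognition threshold set by the
#' least bound strand), the mean bias/forward energy, and the mean reverse
#' part split into anticodon-tandem and non-tandem contributions.
#'
#' @param model a [SimpleLogisticModel].
#' @param x a [TrnaAlignment]; classes absent from the model are skipped
#'   with a warning.
#' @param kBT energy unit.
#' @return data.frame with one row per class: \code{class}, \code{n},
#'   \code{mean_dG}, \code{sd_dG}, \code{max_dG}, \code{mean_dG0},
#'   \code{mean_dG_rev}, \code{mean_dG_rev_tandem},
#'   \code{mean_dG_rev_other}.
#' @export
classEnergySummary <- function(model, x, kBT = 1) {
  cls <- unname(strandClasses(x))
  skip <- setdiff(unique(cls), model@classLevels)
  if (length(skip))
    warning("classes without a fitted predictor omitted: ",
            paste(skip, collapse = " "))
  keep <- intersect(intersect(model@classLevels, classLabels(classTable(x))),
                    unique(cls))
  F <- predictorValues(model, x)
  rows <- lapply(keep, function(cl) {
    i <- which(cls == cl)
    dG <- -kBT * F[i, cl]
    # reverse split needs per-strand active tandem inputs
    co <- model@coef[model@coef$class == cl, , drop = FALSE]
    coTan <- co[co$position %in% tandemPositions(), , drop = FALSE]
    m <- strandCodes(x)[i, , drop = FALSE]
    revTan <- numeric(length(i))
    for (r in seq_len(nrow(coTan)))
      revTan <- revTan - kBT * coTan$value[r] *
        (m[, coTan$position[r]] == coTan$code[r])
    dG0 <- -kBT * unname(model@bias[cl])
    dRev <- dG - dG0
    data.frame(class = cl, n = length(i), mean_dG = mean(dG),
               sd_dG = stats::sd(dG), max_dG = max(dG), mean_dG0 = dG0,
               mean_dG_rev = mean(dRev),
               mean_dG_rev_tandem = mean(revTan),
               mean_dG_rev_other = mean(dRev - revTan),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-class consensus free energies
#'
#' Evaluates every class predictor on every supplied strand (typically the
#' per-class consensus strands) and reports the matrix of free energies
#' \eqn{\Delta G''_{ij} = -k_BT f_i(\mathrm{strand}_j)}: rows are predictor
#' classes, columns strand classes. Proper recognition corresponds to the
#' diagonal entry falling below the class's recognition threshold while
#' off-diagonal strands remain weakly bound or repelled.
#'
#' @param model a [SimpleLogisticModel].
#' @param x a [TrnaAlignment] (strand classes label the columns).
#' @param kBT energy unit.
#' @return numeric matrix, classes x strands, in kT.
#' @export
crossClassEnergy <- function(model, x, kBT = 1) {
  F <- predictorValues(model, x)
  out <- -kBT * t(F)
  colnames(out) <- unname(strandClasses(x))
  out
}

#' Mean reverse energy of anticodon-tandem nucleotides
#'
#' For each canonical base, averages over all (class, tandem position)
#' pairs whose class tandem uses that base the single-position reverse
#' energy \eqn{\Delta G^{rev}_n = -k_BT\, p_{i,\mathrm{pos},n}} taken from
#' the fitted coefficients. Classes are weighted equally. Bases absent
#' from every tandem are omitted.
#'
#' @param model a [SimpleLogisticModel].
#' @param classTable a [ClassTable] giving each class's tandem codes.
#' @param kBT energy unit.
#' @return data.frame \code{code}, \code{n}, \code{mean_dG_rev},
#'   \code{sd_dG_rev}.
#' @export
tandemNucleotideEnergy <- function(model, classTable, kBT = 1) {
  tb <- classTable@table
  tb <- tb[tb$class %in% model@classLevels, , drop = FALSE]
  long <- rbind(data.frame(class = tb$class, position = "35",
                           code = tb$tandem35, stringsAsFactors = FALSE),
                data.frame(class = tb$class, position = "36",
                           code = tb$tandem36, stringsAsFactors = FALSE))
  co <- model@coef
  long$dG <- vapply(seq_len(nrow(long)), function(r) {
    v <- co$value[co$class == long$class[r] &
                    co$position == long$position[r] &
                    co$code == long$code[r]]
    if (length(v)) -kBT * sum(v) else 0
  }, numeric(1))
  out <- do.call(rbind, lapply(c("A", "U", "G", "C"), function(nt) {
    d <- long$dG[long$code == nt]
    if (!length(d)) return(NULL)
    data.frame(code = nt, n = length(d), mean_dG_rev = mean(d),
               sd_dG_rev = if (length(d) > 1) stats::sd(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Reverse energy versus possible hydrogen bonds within one class
#'
#' Groups the strands of one class by the subset of (non-repelling)
#' identity nucleotides they actually carry, and reports per subset the
#' total theoretically possible hydrogen bonds of the carried nucleosides
#' and the shared reverse energy (the sum of the carried identity inputs).
#' The a-priori zero point (no identity nucleotides, 0 bonds, 0 energy) and
#' the theoretical full-set point are always included.
#'
#' @param model a [SimpleLogisticModel].
#' @param x a [TrnaAlignment].
#' @param classLabel the class to profile.
#' @param sets identity sets as returned by [extractIdentitySets()];
#'   computed from the model when missing.
#' @param kBT energy unit.
#' @return data.frame \code{subset} (comma-separated position:code cells),
#'   \code{n_cells}, \code{n_hb}, \code{dG_rev}, \code{n_strands}
#'   (\code{n_strands} is \code{NA} for the two theoretical anchor points
#'   unless observed).
#' @export
hbondEnergyProfile <- function(model, x, classLabel, sets = NULL, kBT = 1) {
  if (is.null(sets)) sets <- extractIdentitySets(model)
  cells <- sets[sets$class == classLabel & sets$sign == "attract", ,
                drop = FALSE]
  ab <- alphabet(x)
  m <- strandCodes(x)[unname(strandClasses(x)) == classLabel, ,
                      drop = FALSE]
  carried <- matrix(FALSE, nrow(m), nrow(cells))
  for (j in seq_len(nrow(cells))) {
    codes <- strsplit(cells$codes[j], ",", fixed = TRUE)[[1]]
    carried[, j] <- m[, cells$position[j]] %in% codes
  }
  cellLabel <- paste(cells$position, cells$codes, sep = ":")
  cellHb <- vapply(seq_len(nrow(cells)), function(j) {
    h <- hbondCount(strsplit(cells$codes[j], ",", fixed = TRUE)[[1]], ab)
    if (all(is.na(h))) NA_real_ else max(h, na.rm = TRUE)
  }, numeric(1))
  cellDg <- -kBT * cells$value
  keys <- apply(carried, 1, function(z) paste(which(z), collapse = ","))
  groups <- table(keys)
  rowFor <- function(idx, nStr) {
    data.frame(subset = paste(cellLabel[idx], collapse = ","),
               n_cells = length(idx),
               n_hb = sum(cellHb[idx], na.rm = TRUE),
               dG_rev = sum(cellDg[idx]),
               n_strands = nStr, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(groups), function(g) {
    k <- names(groups)[g]
    idx <- if (nzchar(k)) as.integer(strsplit(k, ",")[[1]]) else integer()
    rowFor(idx, as.integer(groups[g]))
  }))
  # theoretical anchors
  full <- paste(seq_len(nrow(cells)), collapse = ",")
  if (!("" %in% names(groups)))
    out <- rbind(rowFor(integer(), NA_integer_), out)
  if (!(full %in% names(groups)) && nrow(cells))
    out <- rbind(out, rowFor(seq_len(nrow(cells)), NA_integer_))
  out <- out[order(out$n_hb), , drop = FALSE]
  rownames(out) <- NULL
  out
}
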