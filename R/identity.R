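#' Extract per-class identity nucleotides from a fitted model
#'
#' Turns the model's per-class attribute selections into identity cells:
#' every stored coefficient with \code{abs(value) > threshold} becomes one
#' cell, attracting when the coefficient is positive (negative energy
#' input) and repelling when negative. Multiple codes selected at the
#' degenerate wobble position 34 with the same sign are merged into a
#' single multi-code cell. The default threshold of 0 keeps every selected
#' attribute: the booster's own attribute selection is the sparsifier.
#'
#' @param model a [SimpleLogisticModel].
#' @param threshold minimal absolute coefficient magnitude.
#' @return data.frame \code{class}, \code{position}, \code{codes}
#'   (comma-separated for merged wobble cells), \code{sign}, \code{value}
#'   (summed coefficient). The number of identity positions per class,
#'   N_IP, is its number of rows for that class (see [nIP()]).
#' @export
extractIdentitySets <- function(model, threshold = 0) {
  co <- model@coef
  co <- co[abs(co$value) > threshold, , drop = FALSE]
  if (!nrow(co))
    return(data.frame(class = character(), position = character(),
                      codes = character(), sign = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  co$sign <- ifelse(co$value > 0, "attract", "repel")
  merged <- lapply(split(co, list(co$class, co$position, co$sign),
                         drop = TRUE), function(d) {
    if (d$position[1] == "34" && nrow(d) > 1) {
      ord <- order(-abs(d$value))
      data.frame(class = d$class[1], position = "34",
                 codes = paste(d$code[ord], collapse = ","),
                 sign = d$sign[1], value = sum(d$value),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(class = d$class, position = d$position, codes = d$code,
                 sign = d$sign, value = d$value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, merged)
  out <- out[order(match(out$class, model@classLevels),
                   match(out$position, canonicalPositions()), out$codes), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of identity positions per class
#'
#' @param sets identity sets (data.frame with a \code{class} column, one
#'   row per cell).
#' @return named integer vector, one entry per class.
#' @export
nIP <- function(sets) {
  tb <- table(sets$class)
  stats::setNames(as.integer(tb), names(tb))
}

# is each strand of `m` carrying each cell? attract: code present;
# repel: code absent; multi-code cells carried by any member.
carriedMatrix <- function(m, cells) {
  out <- matrix(FALSE, nrow(m), nrow(cells))
  for (j in seq_len(nrow(cells))) {
    codes <- strsplit(cells$codes[j], ",", fixed = TRUE)[[1]]
    present <- m[, cells$position[j]] %in% codes
    out[, j] <- if (cells$sign[j] == "repel") !present else present
  }
  out
}

#' Occurrence and coverage of identity nucleotides
#'
#' Counts, per strand, how many of its class's non-repelling identity
#' cells it actually carries (a multi-code wobble cell counts as carried if
#' any of its codes is present; an empty-position cell counts when the
#' position is empty), and summarises per class the minimum and maximum
#' observed counts, the theoretical maximum (the number of non-repelling
#' cells) and the mean coverage (carried / theoretical maximum).
#'
#' @param x a [TrnaAlignment].
#' @param sets identity sets (from [extractIdentitySets()] or the packaged
#'   identity table). Classes absent from the alignment are omitted.
#' @return data.frame \code{class}, \code{n_strands}, \code{min_real},
#'   \code{max_real}, \code{max_theor}, \code{coverage}.
#' @export
occurrenceStats <- function(x, sets) {
  cls <- unname(strandClasses(x))
  out <- lapply(intersect(unique(sets$class), unique(cls)), function(cl) {
    cells <- sets[sets$class == cl & sets$sign == "attract", , drop = FALSE]
    m <- strandCodes(x)[cls == cl, , drop = FALSE]
    if (!nrow(cells))
      return(data.frame(class = cl, n_strands = nrow(m), min_real = 0L,
                        max_real = 0L, max_theor = 0L, coverage = NA_real_,
                        stringsAsFactors = FALSE))
    hits <- rowSums(carriedMatrix(m, cells))
    data.frame(class = cl, n_strands = nrow(m),
               min_real = as.integer(min(hits)),
               max_real = as.integer(max(hits)),
               max_theor = nrow(cells),
               coverage = mean(hits / nrow(cells)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-class consensus strands
#'
#' Derives, for each class, the consensus strand: at every position the
#' most frequent code among the class's strands. Ties are broken by the
#' fixed alphabet order (canonical bases first, modified codes next, the
#' empty code last) and recorded in the output.
#'
#' @param x a [TrnaAlignment]; every class present must have at least one
#'   strand.
#' @return list with \code{alignment} (a [TrnaAlignment] of one consensus
#'   strand per class, ids \code{consensus_<class>}), \code{modalFrequency}
#'   (matrix class x position of the modal code's relative frequency) and
#'   \code{ties} (data.frame \code{class}, \code{position}, \code{codes}
#'   listing tied modal codes).
#' @export
consensusStrands <- function(x) {
  cls <- unname(strandClasses(x))
  classes <- intersect(classLabels(classTable(x)), unique(cls))
  ab <- alphabet(x)
  cons <- matrix(NA_character_, length(classes), 77,
                 dimnames = list(classes, canonicalPositions()))
  freq <- matrix(NA_real_, length(classes), 77,
                 dimnames = dimnames(cons))
  ties <- list()
  for (cl in classes) {
    m <- strandCodes(x)[cls == cl, , drop = FALSE]
    for (pos in canonicalPositions()) {
      counts <- table(m[, pos])
      top <- names(counts)[counts == max(counts)]
      modal <- top[order(match(top, ab@codes))][1]
      cons[cl, pos] <- modal
      freq[cl, pos] <- max(counts) / nrow(m)
      if (length(top) > 1)
        ties[[length(ties) + 1]] <- data.frame(
          class = cl, position = pos,
          codes = paste(sort(top), collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  rownames(cons) <- paste0("consensus_", classes)
  list(alignment = trnaAlignment(cons, classes, ab, classTable(x)),
       modalFrequency = freq,
       ties = if (length(ties)) do.call(rbind, ties) else
         data.frame(class = character(), position = character(),
                    codes = character(), stringsAsFactors = FALSE))
}

#' Agreement between identity cells and consensus strands
#'
#' Scores every identity cell (one unit each) against the consensus strand
#' of its class. An attracting cell is consistent when the consensus code
#' at its position belongs to the cell's code set (the empty code matching
#' an empty consensus position); a repelling cell is consistent when the
#' consensus code differs from the repelled code — elements differing from
#' attributes of negative impact are treated as consistent.
#'
#' @param sets identity cells: data.frame \code{class}, \code{position},
#'   \code{codes}, \code{sign}.
#' @param consensus a [TrnaAlignment] of consensus strands (one per class,
#'   as from [consensusStrands()] or the packaged consensus table).
#' @return list with \code{consistent}, \code{total}, \code{percentage}
#'   and \code{verdicts} (the cells with a logical \code{consistent}
#'   column and the consensus code seen).
#' @export
#' @examples
#' agr <- consensusAgreement(loadFixture("identity_table"),
#'                           loadFixture("consensus_table"))
#' sprintf("%d/%d (%.0f%%)", agr$consistent, agr$total, agr$percentage)
consensusAgreement <- function(sets, consensus) {
  cls <- unname(strandClasses(consensus))
  m <- strandCodes(consensus)
  sets <- sets[sets$class %in% cls, , drop = FALSE]
  consCode <- character(nrow(sets))
  ok <- logical(nrow(sets))
  for (i in seq_len(nrow(sets))) {
    row <- match(sets$class[i], cls)
    cc <- m[row, sets$position[i]]
    codes <- strsplit(sets$codes[i], ",", fixed = TRUE)[[1]]
    consCode[i] <- cc
    ok[i] <- if (sets$sign[i] == "attract") cc %in% codes else
      !(cc %in% codes)
  }
  verdicts <- cbind(sets[, c("class", "position", "codes", "sign")],
                    consensus_code = consCode, consistent = ok)
  list(consistent = sum(ok), total = length(ok),
       percentage = 100 * sum(ok) / length(ok), verdicts = verdicts)
}

#' Universal class markers
#'
#' A universal marker of a class is an ensemble of its non-repelling
#' identity cells that is entirely present in every strand of that class
#' and never jointly present in any strand of another class. Joint presence
#' is upward-monotone in the ensemble, so the maximal candidate is the set
#' of cells carried by all of the class's strands; it is reported when it
#' is never jointly carried elsewhere and extends beyond the anticodon
#' tandem alone.
#'
#' @param x a clean [TrnaAlignment].
#' @param sets identity sets.
#' @return data.frame \code{class}, \code{cells} (comma-separated
#'   position:codes), \code{size}; empty when no class has a marker.
#' @export
universalMarkers <- function(x, sets) {
  cls <- unname(strandClasses(x))
  out <- list()
  for (cl in intersect(unique(sets$class), unique(cls))) {
    cells <- sets[sets$class == cl & sets$sign == "attract", , drop = FALSE]
    if (!nrow(cells)) next
    own <- carriedMatrix(strandCodes(x)[cls == cl, , drop = FALSE], cells)
    inAll <- which(apply(own, 2, all))
    if (!length(setdiff(cells$position[inAll], c("35", "36")))) next
    cand <- cells[inAll, , drop = FALSE]
    others <- carriedMatrix(strandCodes(x)[cls != cl, , drop = FALSE], cand)
    if (nrow(others) && any(apply(others, 1, all))) next
    out[[cl]] <- data.frame(
      class = cl,
      cells = paste(paste(cand$position, cand$codes, sep = ":"),
                    collapse = ","),
      size = nrow(cand), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(class = character(), cells = character(),
                      size = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Unique extra-anticodon ensembles
#'
#' Enumerates, per class, subsets of its identity cells excluding
#' positions 35 and 36 (repelling and empty-position cells allowed,
#' evaluated by their carrying rule: a repelling cell is carried when the
#' strand does not show the repelled code) that occur in at least one
#' strand of exactly one class. Maximal unique subsets are reported with
#' their in-class occurrence counts.
#'
#' @param x a clean [TrnaAlignment].
#' @param sets identity sets.
#' @param maxSubsetSize enumeration bound on subset size (default 6); a
#'   class with more candidate cells than \code{2^16} subsets within the
#'   bound is truncated with a warning.
#' @param minSubsetSize smallest reported ensemble (default 2).
#' @return data.frame \code{class}, \code{cells}, \code{size},
#'   \code{n_strands}.
#' @export
uniqueEnsembles <- function(x, sets, maxSubsetSize = 6, minSubsetSize = 2) {
  cls <- unname(strandClasses(x))
  results <- list()
  for (cl in intersect(unique(sets$class), unique(cls))) {
    cells <- sets[sets$class == cl &
                    !(sets$position %in% c("35", "36")), , drop = FALSE]
    if (nrow(cells) < minSubsetSize) next
    own <- carriedMatrix(strandCodes(x)[cls == cl, , drop = FALSE], cells)
    oth <- carriedMatrix(strandCodes(x)[cls != cl, , drop = FALSE], cells)
    nc <- nrow(cells)
    sizes <- seq(minSubsetSize, min(maxSubsetSize, nc))
    combos <- unlist(lapply(sizes, function(k)
      utils::combn(nc, k, simplify = FALSE)), recursive = FALSE)
    if (length(combos) > 65536L) {
      warning("ensemble enumeration truncated for class ", cl)
      combos <- combos[seq_len(65536L)]
    }
    uniq <- Filter(function(s) {
      nOwn <- sum(rowSums(own[, s, drop = FALSE]) == length(s))
      if (nOwn == 0) return(FALSE)
      nrow(oth) == 0 ||
        !any(rowSums(oth[, s, drop = FALSE]) == length(s))
    }, combos)
    if (!length(uniq)) next
    maximal <- Filter(function(s) {
      !any(vapply(uniq, function(t)
        length(t) > length(s) && all(s %in% t), logical(1)))
    }, uniq)
    for (s in maximal) {
      nOwn <- sum(rowSums(own[, s, drop = FALSE]) == length(s))
      lab <- paste(cells$position[s],
                   ifelse(cells$sign[s] == "repel", "~", ""),
                   cells$codes[s], sep = "")
      results[[length(results) + 1]] <- data.frame(
        class = cl, cells = paste(lab, collapse = ","),
        size = length(s), n_strands = nOwn, stringsAsFactors = FALSE)
    }
  }
  if (!length(results))
    return(data.frame(class = character(), cells = character(),
                      size = integer(), n_strands = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  out
}

aaFamilies <- c(Ser = "serine", Ser2 = "serine", Gly = "serine",
                Cys = "serine",
                Ala = "pyruvate", Val = "pyruvate", Leu = "pyruvate",
                Leu2 = "pyruvate",
                Asp = "aspartate", Asn = "aspartate", LysI = "aspartate",
                LysII = "aspartate", Met = "aspartate", Thr = "aspartate",
                Ile = "aspartate",
                Glu = "glutamate", Gln = "glutamate", Pro = "glutamate",
                Arg = "glutamate", Arg2 = "glutamate",
                His = "histidine",
                Phe = "aromatic", Trp = "aromatic", Tyr = "aromatic")

#' Identity-count, amino-acid-mass and energy summary
#'
#' Joins, per class, the number of identity positions N_IP, the molecular
#' weight of the charging amino acid, the mean binding free energy and the
#' amino-acid metabolic family (serine, pyruvate, aspartate, glutamate,
#' histidine, aromatic).
#'
#' @param sets identity sets.
#' @param classTable a [ClassTable].
#' @param energies per-class energy summary from [classEnergySummary()]
#'   (optional; \code{mean_dG} is \code{NA} when missing).
#' @return data.frame \code{class}, \code{n_ip}, \code{molecular_weight},
#'   \code{mean_dG}, \code{family}, one row per class present in all
#'   supplied inputs.
#' @export
nipMwSummary <- function(sets, classTable, energies = NULL) {
  tb <- classTable@table
  nip <- nIP(sets)
  keep <- tb$class[tb$class %in% names(nip)]
  if (!is.null(energies)) keep <- intersect(keep, energies$class)
  out <- data.frame(class = keep,
                    n_ip = as.integer(nip[keep]),
                    molecular_weight =
                      tb$molecular_weight[match(keep, tb$class)],
                    mean_dG = if (is.null(energies)) NA_real_ else
                      energies$mean_dG[match(keep, energies$class)],
                    family = unname(aaFamilies[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
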