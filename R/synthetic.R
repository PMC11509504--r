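#' Configuration for the synthetic alignment generator
#'
#' Describes a synthetic study design: a set of tRNA classes, per-class
#' planted identity nucleosides with sub-unit penetrance, and a shared
#' per-position background distribution. The generator emulates the
#' statistical structure of real class-annotated tRNA alignments, where
#' identity attributes may not all be arranged in any single molecule but
#' are comprehensively present within a class.
#'
#' The anticodon tandem (positions 35 and 36) is always planted at
#' penetrance 1 with the class's tandem codes; the constructor adds these
#' plants when missing and rejects conflicting ones.
#'
#' @param classTable a [ClassTable].
#' @param plants data.frame with columns \code{class}, \code{position},
#'   \code{code}, \code{theta} (penetrance in [0,1]) and \code{sign}
#'   (\code{"attract"} or \code{"repel"}). An attract plant places its code
#'   with probability \code{theta} (otherwise a background draw excluding
#'   that code); a repel plant excludes its code from the class entirely.
#' @param strandsPerClass number of strands to generate per class.
#' @param background named list: position label -> named probability vector
#'   over codes. Positions absent from the list default to a uniform draw
#'   over the canonical bases, except positions 74-76 (fixed C, C, A) and
#'   33 (fixed U), mirroring the near-universal alignment consensus.
#' @param seed integer seed; the generator derives one substream per class
#'   from it, so results do not depend on class iteration order.
#' @return a \code{syntheticConfig} list.
#' @seealso [simulateTrnaAlignment()], [defaultSyntheticConfig()]
#' @export
syntheticConfig <- function(classTable, plants = NULL, strandsPerClass = 50,
                            background = list(), seed = 1L) {
  stopifnot(is(classTable, "ClassTable"))
  tb <- classTable@table
  if (is.null(plants))
    plants <- data.frame(class = character(), position = character(),
                         code = character(), theta = numeric(),
                         sign = character(), stringsAsFactors = FALSE)
  plants$position <- as.character(plants$position)
  stopifnot(all(c("class", "position", "code", "theta", "sign") %in%
                  names(plants)),
            all(plants$theta >= 0 & plants$theta <= 1),
            all(plants$sign %in% c("attract", "repel")),
            all(plants$class %in% tb$class))
  bad <- setdiff(unique(plants$position), canonicalPositions())
  if (length(bad))
    stop("plant position(s) outside -1..76: ", paste(bad, collapse = " "))
  # force tandem plants at full penetrance
  for (i in seq_len(nrow(tb))) {
    for (ps in c("35", "36")) {
      code <- if (ps == "35") tb$tandem35[i] else tb$tandem36[i]
      hit <- plants$class == tb$class[i] & plants$position == ps &
        plants$sign == "attract"
      if (any(hit)) {
        if (any(plants$code[hit] != code) || any(plants$theta[hit] != 1))
          stop("tandem plant for class ", tb$class[i], " at position ", ps,
               " must be ", code, " with penetrance 1")
      } else {
        plants <- rbind(plants,
                        data.frame(class = tb$class[i], position = ps,
                                   code = code, theta = 1,
                                   sign = "attract"))
      }
    }
  }
  for (p in names(background)) {
    if (!(p %in% canonicalPositions()))
      stop("background position outside -1..76: ", p)
    if (abs(sum(background[[p]]) - 1) > 1e-8)
      stop("background distribution at position ", p, " must sum to 1")
  }
  structure(list(classTable = classTable, plants = plants,
                 strandsPerClass = as.integer(strandsPerClass),
                 background = background, seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' @export
print.syntheticConfig <- function(x, ...) {
  cat("syntheticConfig:", nrow(x$classTable@table), "classes x",
      x$strandsPerClass, "strands,", nrow(x$plants), "plants, seed",
      x$seed, "\n")
  invisible(x)
}

backgroundFor <- function(cfg, pos) {
  if (!is.null(cfg$background[[pos]])) return(cfg$background[[pos]])
  if (pos %in% c("74", "75", "76"))
    return(stats::setNames(1, c(`74` = "C", `75` = "C", `76` = "A")[pos]))
  if (pos == "33") return(c(U = 1))
  stats::setNames(rep(0.25, 4), c("A", "U", "G", "C"))
}

sampleCodes <- function(n, probs, exclude = character()) {
  p <- probs[setdiff(names(probs), exclude)]
  if (!length(p)) stop("background distribution empty after exclusions")
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate a synthetic aligned tRNA dataset
#'
#' Draws \code{strandsPerClass} strands for every class of the
#' configuration. At an attract plant the planted code appears with
#' probability \code{theta}; otherwise (and at unplanted positions) codes
#' are drawn from the background distribution, with repel-planted codes
#' excluded from the class. The result is fully reproducible from the
#' configuration seed, independently of class iteration order.
#'
#' @param cfg a [syntheticConfig()].
#' @param alphabet a [NucleosideAlphabet]; must cover all plant and
#'   background codes.
#' @return a [TrnaAlignment].
#' @export
#' @examples
#' cfg <- defaultSyntheticConfig(seed = 11, strandsPerClass = 5)
#' aln <- simulateTrnaAlignment(cfg)
#' nStrand(aln)
simulateTrnaAlignment <- function(cfg, alphabet = defaultAlphabet()) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  tb <- cfg$classTable@table
  n <- cfg$strandsPerClass
  out <- vector("list", nrow(tb))
  for (i in seq_len(nrow(tb))) {
    cl <- tb$class[i]
    set.seed((cfg$seed %% 65011) * 32749 + i * 7919)  # per-class substream
    m <- matrix(NA_character_, n, 77,
                dimnames = list(sprintf("%s_%04d", cl, seq_len(n)),
                                canonicalPositions()))
    pl <- cfg$plants[cfg$plants$class == cl, , drop = FALSE]
    for (pos in canonicalPositions()) {
      probs <- backgroundFor(cfg, pos)
      att <- pl[pl$position == pos & pl$sign == "attract", , drop = FALSE]
      repel <- pl$code[pl$position == pos & pl$sign == "repel"]
      if (nrow(att)) {
        hit <- stats::runif(n) < att$theta[1]
        col <- character(n)
        col[hit] <- att$code[1]
        if (any(!hit))
          col[!hit] <- sampleCodes(sum(!hit), probs,
                                   exclude = c(att$code[1], repel))
      } else {
        col <- sampleCodes(n, probs, exclude = repel)
      }
      m[, pos] <- col
    }
    out[[i]] <- m
  }
  codes <- do.call(rbind, out)
  trnaAlignment(codes, rep(tb$class, each = n), alphabet, cfg$classTable)
}

#' Default study-like synthetic configuration
#'
#' Builds the configuration that emulates the packaged class fixtures: the
#' 24 classes with their fixed anticodon tandems, the single-code identity
#' cells of the packaged identity table as plants (attract cells at
#' penetrance \code{theta}, repel cells as exclusions; tandem cells at
#' penetrance 1; degenerate multi-code wobble cells are not planted), and a
#' background derived from the packaged consensus strands: at each position
#' the modal consensus code with probability 0.7, the remaining mass spread
#' uniformly over the canonical bases and the empty code. Modified
#' nucleoside codes therefore appear in the background only where the
#' consensus shows them.
#'
#' @param seed integer seed.
#' @param strandsPerClass strands per class (default 50).
#' @param theta penetrance of non-tandem plants (default 0.85).
#' @return a [syntheticConfig()].
#' @export
#' @examples
#' cfg <- defaultSyntheticConfig(seed = 3)
#' subset(cfg$plants, class == "Gly")
defaultSyntheticConfig <- function(seed = 1L, strandsPerClass = 50,
                                   theta = 0.85) {
  ct <- loadFixture("class_table")
  id <- loadFixture("identity_table")
  single <- !grepl(",", id$codes, fixed = TRUE)
  plants <- data.frame(class = id$class[single],
                       position = id$position[single],
                       code = id$codes[single],
                       theta = ifelse(id$position[single] %in% c("35", "36") &
                                        id$sign[single] == "attract",
                                      1, theta),
                       sign = id$sign[single], stringsAsFactors = FALSE)
  cons <- strandCodes(loadFixture("consensus_table"))
  ab <- defaultAlphabet()
  bg <- list()
  for (pos in canonicalPositions()) {
    counts <- table(cons[, pos])
    # modal code; ties broken by alphabet order
    top <- names(counts)[counts == max(counts)]
    modal <- top[order(match(top, ab@codes))][1]
    rest <- setdiff(c("A", "U", "G", "C", "-"), modal)
    bg[[pos]] <- stats::setNames(c(0.7, rep(0.3 / length(rest),
                                            length(rest))),
                                 c(modal, rest))
  }
  syntheticConfig(ct, plants, strandsPerClass = strandsPerClass,
                  background = bg, seed = seed)
}

#' Write / read a synthetic configuration as JSON
#'
#' @param cfg a [syntheticConfig()].
#' @param path file path.
#' @return \code{path} invisibly, or the restored configuration.
#' @export
writeSyntheticConfig <- function(cfg, path) {
  obj <- list(classTable = cfg$classTable@table, plants = cfg$plants,
              strandsPerClass = cfg$strandsPerClass,
              background = lapply(cfg$background, as.list),  # keep names
              seed = cfg$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSyntheticConfig
#' @export
readSyntheticConfig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bg <- lapply(obj$background, unlist)
  syntheticConfig(new("ClassTable", table = as.data.frame(obj$classTable)),
                  as.data.frame(obj$plants),
                  strandsPerClass = obj$strandsPerClass,
                  background = bg, seed = obj$seed)
}
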