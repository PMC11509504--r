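extdataFile <- function(name) {
  system.file("extdata", name, package = "tRNAidentity", mustWork = TRUE)
}

readTsvRaw <- function(path) {
  # codes include '"' and '#': disable quoting and comments
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

#' Construct an aligned-strand object from parts
#'
#' @param codes character matrix (strands x 77) with the canonical position
#'   labels as colnames and strand ids as rownames, or a data.frame in the
#'   same layout.
#' @param classLabel class label per strand.
#' @param alphabet a [NucleosideAlphabet].
#' @param classTable a [ClassTable].
#' @return a validated [TrnaAlignment].
#' @export
trnaAlignment <- function(codes, classLabel, alphabet = defaultAlphabet(),
                          classTable = loadFixture("class_table")) {
  m <- as.matrix(codes)
  new("TrnaAlignment", codes = m, classLabel = as.character(classLabel),
      alphabet = alphabet, classTable = classTable)
}

#' Read aligned tRNA strands from a file
#'
#' Two plain-text layouts are supported. The tabular layout has a header
#' \code{id}, \code{class}, then the 77 position labels \code{-1},
#' \code{1} .. \code{76}, with one code token per cell. The aligned-FASTA
#' layout has 77-character sequence records with headers
#' \code{>id<delim>class}.
#'
#' Unknown codes, malformed columns and unknown class labels are rejected
#' with informative errors naming the offending strand and position.
#'
#' @param path file path.
#' @param alphabet a [NucleosideAlphabet].
#' @param classTable a [ClassTable].
#' @param format \code{"tsv"} or \code{"fasta"}.
#' @param delim header delimiter between id and class in FASTA input.
#' @return a validated [TrnaAlignment]; strand order as in the file.
#' @export
#' @examples
#' aln <- loadFixture("consensus_table")
#' tf <- tempfile(fileext = ".tsv")
#' writeTrnaAlignment(aln, tf)
#' aln2 <- readTrnaAlignment(tf)
#' identical(strandCodes(aln), strandCodes(aln2))
readTrnaAlignment <- function(path, alphabet = defaultAlphabet(),
                              classTable = loadFixture("class_table"),
                              format = c("tsv", "fasta"), delim = "|") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tb <- readTsvRaw(path)
    need <- c("id", "class", canonicalPositions())
    if (!identical(names(tb), need))
      stop("expected columns 'id', 'class' and the 77 position labels; got ",
           length(names(tb)), " columns")
    ids <- tb$id
    cls <- tb$class
    m <- as.matrix(tb[, canonicalPositions(), drop = FALSE])
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    hd <- grep("^>", lines)
    if (!length(hd)) stop("no FASTA records in ", path)
    ends <- c(hd[-1] - 1L, length(lines))
    ids <- cls <- character(length(hd))
    seqs <- character(length(hd))
    for (k in seq_along(hd)) {
      header <- sub("^>", "", lines[hd[k]])
      parts <- strsplit(header, delim, fixed = TRUE)[[1]]
      if (length(parts) < 2)
        stop("FASTA header without class label: ", lines[hd[k]])
      ids[k] <- parts[1]; cls[k] <- parts[2]
      seqs[k] <- paste(lines[(hd[k] + 1L):ends[k]], collapse = "")
    }
    bad <- which(nchar(seqs) != 77)
    if (length(bad))
      stop("record '", ids[bad[1]], "' has ", nchar(seqs[bad[1]]),
           " characters; 77 expected")
    m <- do.call(rbind, strsplit(seqs, ""))
    colnames(m) <- canonicalPositions()
  }
  rownames(m) <- ids
  # dedicated error messages before formal validity
  bad <- which(!(m %in% alphabet@codes))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf("unknown code '%s' in strand '%s' at position %s",
                 m[bad[1]], ids[rc[1]], canonicalPositions()[rc[2]]))
  }
  badcl <- which(!(cls %in% classTable@table$class))
  if (length(badcl))
    stop(sprintf("unknown class label '%s' for strand '%s'",
                 cls[badcl[1]], ids[badcl[1]]))
  trnaAlignment(m, cls, alphabet, classTable)
}

#' Write aligned tRNA strands
#'
#' @param x a [TrnaAlignment].
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"fasta"}.
#' @param delim FASTA header delimiter.
#' @return \code{path}, invisibly.
#' @export
writeTrnaAlignment <- function(x, path, format = c("tsv", "fasta"),
                               delim = "|") {
  format <- match.arg(format)
  if (format == "tsv") {
    tb <- data.frame(id = strandIds(x), class = unname(strandClasses(x)),
                     strandCodes(x), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(tb, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    seqs <- apply(strandCodes(x), 1, paste, collapse = "")
    multi <- nchar(seqs) != 77  # multi-character tokens cannot round-trip
    if (any(multi))
      stop("strand '", names(seqs)[multi][1],
           "' contains multi-character codes; use the tsv format")
    writeLines(paste0(">", strandIds(x), delim, unname(strandClasses(x)),
                      "\n", seqs), path)
  }
  invisible(path)
}

#' Remove duplicate strands and non-standard anticodon tandems
#'
#' Applies the two cleaning rules used before model fitting: exact
#' duplicates (same class label and the same code at every position) are
#' removed keeping the first occurrence, and strands whose codes at
#' positions 35 or 36 are not canonical bases (A, U, G, C) are excluded.
#'
#' @param x a [TrnaAlignment].
#' @return list with elements \code{alignment} (the cleaned
#'   [TrnaAlignment]) and \code{report} (named integer vector with counts
#'   \code{duplicates} and \code{nonstandard_anticodon}).
#' @export
#' @examples
#' aln <- loadFixture("consensus_table")
#' cleanTrnaAlignment(aln)$report
cleanTrnaAlignment <- function(x) {
  key <- paste(x@classLabel, apply(x@codes, 1, paste, collapse = "\r"))
  dup <- duplicated(key)
  keep1 <- !dup
  std <- x@codes[, "35"] %in% c("A", "U", "G", "C") &
    x@codes[, "36"] %in% c("A", "U", "G", "C")
  keep <- keep1 & std
  report <- c(duplicates = sum(dup),
              nonstandard_anticodon = sum(keep1 & !std))
  list(alignment = x[keep], report = report)
}

#' Load a packaged reference fixture
#'
#' Three fixtures ship with the package, describing the 24-class reference
#' system cell for cell:
#' \describe{
#'   \item{\code{class_table}}{the 24 tRNA amino-acid-load classes with
#'     their fixed anticodon tandems and amino-acid molecular weights
#'     (a [ClassTable]).}
#'   \item{\code{identity_table}}{the 129 identity-nucleoside cells
#'     reported across the 24 classes: a data.frame with columns
#'     \code{class}, \code{position}, \code{codes} (comma-separated for
#'     degenerate wobble cells), \code{sign} (\code{attract}/\code{repel})
#'     and \code{note} (verbatim flags for typographically ambiguous
#'     cells).}
#'   \item{\code{consensus_table}}{the 24 per-class consensus strands as a
#'     [TrnaAlignment] (one strand per class, id \code{consensus_<class>}).}
#' }
#'
#' At load time the consensus fixture is cross-checked against the class
#' table: the consensus codes at positions 35 and 36 must equal each
#' class's tandem codes.
#'
#' @param name one of \code{"class_table"}, \code{"identity_table"},
#'   \code{"consensus_table"}.
#' @return see Description.
#' @export
#' @examples
#' nrow(classTableData(loadFixture("class_table")))
#' nrow(loadFixture("identity_table"))
loadFixture <- function(name = c("class_table", "identity_table",
                                 "consensus_table")) {
  name <- match.arg(name)
  if (name == "class_table") {
    tb <- readTsvRaw(extdataFile("class_table.tsv"))
    tb$molecular_weight <- as.numeric(tb$molecular_weight)
    return(new("ClassTable", table = tb))
  }
  if (name == "identity_table") {
    tb <- readTsvRaw(extdataFile("identity_cells.tsv"))
    tb$note[is.na(tb$note)] <- ""
    return(tb)
  }
  ct <- loadFixture("class_table")
  tb <- readTsvRaw(extdataFile("consensus_strands.tsv"))
  stopifnot(identical(tb$position, canonicalPositions()))
  m <- t(as.matrix(tb[, -1, drop = FALSE]))
  colnames(m) <- canonicalPositions()
  stopifnot(identical(rownames(m), ct@table$class))
  # fixture cross-check: consensus anticodon tandem equals the class tandem
  if (!identical(unname(m[, "35"]), ct@table$tandem35) ||
      !identical(unname(m[, "36"]), ct@table$tandem36))
    stop("consensus fixture disagrees with class-table tandems")
  cls <- rownames(m)
  rownames(m) <- paste0("consensus_", cls)
  trnaAlignment(m, cls, defaultAlphabet(), ct)
}
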