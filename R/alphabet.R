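#' Construct a nucleoside alphabet
#'
#' @param codes character vector of unique codes; must include the four
#'   canonical bases and the gap code.
#' @param nucleosideNames human-readable names (defaults to the codes).
#' @param parentBase parent canonical base per code.
#' @param gapCode code for an empty position.
#' @return a [NucleosideAlphabet].
#' @export
#' @examples
#' nucleosideAlphabet(c("A", "U", "G", "C", "-"),
#'                    parentBase = c("A", "U", "G", "C", "none"))
nucleosideAlphabet <- function(codes, nucleosideNames = codes,
                               parentBase, gapCode = "-") {
  new("NucleosideAlphabet", codes = as.character(codes),
      nucleosideNames = as.character(nucleosideNames),
      parentBase = as.character(parentBase), gapCode = gapCode)
}

#' Read an alphabet from a TSV file
#'
#' The file must have columns \code{code}, \code{name}, \code{parent_base}.
#' Quote and comment interpretation are disabled because several nucleoside
#' codes are punctuation characters.
#'
#' @param path file path.
#' @param gapCode gap code (default \code{"-"}).
#' @return a [NucleosideAlphabet].
#' @export
readAlphabet <- function(path, gapCode = "-") {
  tb <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  stopifnot(all(c("code", "name", "parent_base") %in% names(tb)))
  nucleosideAlphabet(tb$code, tb$name, tb$parent_base, gapCode = gapCode)
}

#' Default nucleoside alphabet
#'
#' The packaged alphabet: the four canonical ribonucleosides, the modified
#' nucleoside codes appearing in the packaged class fixtures (dihydrouridine,
#' pseudouridine, queuosine, inosine, methylated bases, ...), a few
#' typographically ambiguous tokens kept verbatim with no parent base, and
#' the empty-position code \code{"-"}.
#'
#' @return a [NucleosideAlphabet].
#' @export
#' @examples
#' defaultAlphabet()
defaultAlphabet <- function() {
  readAlphabet(system.file("extdata", "alphabet.tsv",
                           package = "tRNAidentity", mustWork = TRUE))
}

#' Theoretically possible hydrogen bonds of a nucleoside
#'
#' Counts the hydrogen bonds a nucleoside could form through its base:
#' 3 for the "strong" bases G and C, 2 for the "weak" bases A and U, and 0
#' for an empty position. Modified nucleosides inherit the count of their
#' parent base; codes with no assignable parent return \code{NA} and are
#' excluded from hydrogen-bond sums.
#'
#' @param code one or more nucleoside codes.
#' @param alphabet a [NucleosideAlphabet].
#' @return integer vector of hydrogen-bond counts (\code{NA} where the
#'   parent base is unknown).
#' @export
#' @examples
#' ab <- defaultAlphabet()
#' hbondCount(c("G", "U", "-", "D"), ab)
hbondCount <- function(code, alphabet = defaultAlphabet()) {
  i <- match(code, alphabet@codes)
  if (anyNA(i))
    stop("code(s) not in alphabet: ",
         paste(unique(code[is.na(i)]), collapse = " "))
  parent <- alphabet@parentBase[i]
  out <- rep(NA_integer_, length(code))
  out[parent %in% c("G", "C")] <- 3L
  out[parent %in% c("A", "U")] <- 2L
  out[code == alphabet@gapCode] <- 0L
  out
}
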