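#' Consensus agreement of the packaged identity and consensus tables
#'
#' Convenience wrapper scoring the packaged identity cells against the
#' packaged consensus strands with [consensusAgreement()]; no model
#' training is involved.
#'
#' @return the [consensusAgreement()] list.
#' @export
#' @examples
#' fixtureAgreement()$percentage
fixtureAgreement <- function() {
  consensusAgreement(loadFixture("identity_table"),
                     loadFixture("consensus_table"))
}

writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the standard stage order on either a synthetic configuration
#' or an aligned-strand input file: clean, one-hot encode, rank attributes,
#' fit the simple-logistic model, derive the free-energy summaries, then
#' the identity, consensus, agreement, marker and summary analyses. All
#' reports are written as TSV/JSON files into \code{outDir} together with
#' a JSON run manifest; given the same inputs and seed the bundle is
#' byte-identical across runs.
#'
#' @param input a [syntheticConfig()], a [TrnaAlignment], or a path to an
#'   aligned-strand TSV file.
#' @param outDir output directory (created if missing).
#' @param control a [boostControl()].
#' @param identityThreshold threshold for [extractIdentitySets()].
#' @param maxSubsetSize bound for [uniqueEnsembles()].
#' @param kBT energy unit.
#' @param verbose log stage progress and counts.
#' @return invisibly, a list with the in-memory results (\code{alignment},
#'   \code{cleanReport}, \code{ranking}, \code{model}, \code{energies},
#'   \code{sets}, \code{consensus}, \code{agreement}, \code{markers},
#'   \code{ensembles}, \code{summary}, \code{files}).
#' @export
runPipeline <- function(input, outDir, control = boostControl(),
                        identityThreshold = 0, maxSubsetSize = 6,
                        kBT = 1, verbose = TRUE) {
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- NA_integer_
  if (inherits(input, "syntheticConfig")) {
    say("simulating ", nrow(input$classTable@table), " classes x ",
        input$strandsPerClass, " strands (seed ", input$seed, ")")
    seed <- input$seed
    aln <- simulateTrnaAlignment(input)
  } else if (is(input, "TrnaAlignment")) {
    aln <- input
  } else {
    say("reading ", input)
    aln <- readTrnaAlignment(input)
  }
  cleaned <- cleanTrnaAlignment(aln)
  aln <- cleaned$alignment
  say("clean: ", nStrand(aln), " strands kept (",
      paste(names(cleaned$report), cleaned$report, sep = "=",
            collapse = ", "), ")")
  files <- character()
  files["dataset"] <- writeTrnaAlignment(aln, file.path(outDir,
                                                        "dataset.tsv"))
  ranking <- correlationRanking(aln)
  files["ranking"] <- writeTsv(ranking, file.path(outDir, "ranking.tsv"))
  say("fitting simple-logistic model (max ", control$maxIterations,
      " iterations)")
  model <- fitSimpleLogistic(aln, control = control)
  say("kept ", model@iterations, " iterations; training error ",
      format(model@errorPath[model@iterations], digits = 4))
  files["model"] <- writeModelJson(model, file.path(outDir, "model.json"))
  energies <- classEnergySummary(model, aln, kBT = kBT)
  files["class_energy"] <- writeTsv(energies,
                                    file.path(outDir, "class_energy.tsv"))
  landscape <- model@coef
  landscape$dG <- -kBT * landscape$value
  files["energy_landscape"] <-
    writeTsv(landscape[, c("class", "position", "code", "dG")],
             file.path(outDir, "energy_landscape.tsv"))
  sets <- extractIdentitySets(model, threshold = identityThreshold)
  files["identity_sets"] <- writeTsv(sets, file.path(outDir,
                                                     "identity_sets.tsv"))
  occ <- occurrenceStats(aln, sets)
  files["occurrence"] <- writeTsv(occ, file.path(outDir, "occurrence.tsv"))
  consensus <- consensusStrands(aln)
  files["consensus"] <- writeTrnaAlignment(consensus$alignment,
                                           file.path(outDir,
                                                     "consensus.tsv"))
  agreement <- consensusAgreement(sets, consensus$alignment)
  say("consensus agreement: ", agreement$consistent, "/",
      agreement$total)
  files["agreement"] <- writeTsv(agreement$verdicts,
                                 file.path(outDir, "agreement.tsv"))
  cross <- crossClassEnergy(model, consensus$alignment, kBT = kBT)
  files["cross_class_energy"] <-
    writeTsv(data.frame(predictor_class = rownames(cross), cross,
                        check.names = FALSE),
             file.path(outDir, "cross_class_energy.tsv"))
  markers <- universalMarkers(aln, sets)
  ensembles <- uniqueEnsembles(aln, sets, maxSubsetSize = maxSubsetSize)
  jsonlite::write_json(list(universal_markers = markers,
                            unique_ensembles = ensembles),
                       file.path(outDir, "markers.json"),
                       auto_unbox = TRUE, digits = NA)
  files["markers"] <- file.path(outDir, "markers.json")
  summary <- nipMwSummary(sets, classTable(aln), energies)
  files["summary"] <- writeTsv(summary, file.path(outDir,
                                                  "nip_mw_summary.tsv"))
  manifest <- list(
    seed = seed,
    n_strands = nStrand(aln),
    n_classes = length(unique(unname(strandClasses(aln)))),
    clean_report = as.list(cleaned$report),
    control = model@control,
    iterations = model@iterations,
    final_training_error = model@errorPath[model@iterations],
    identity_threshold = identityThreshold,
    kBT = kBT,
    consensus_agreement = list(consistent = agreement$consistent,
                               total = agreement$total),
    package_version = as.character(utils::packageVersion("tRNAidentity")),
    files = as.list(vapply(files, basename, character(1))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["manifest"] <- file.path(outDir, "manifest.json")
  invisible(list(alignment = aln, cleanReport = cleaned$report,
                 ranking = ranking, model = model, energies = energies,
                 sets = sets, consensus = consensus,
                 agreement = agreement, markers = markers,
                 ensembles = ensembles, summary = summary,
                 files = files))
}
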