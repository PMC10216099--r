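# Plain-text interchange: subject manifests, ROI time-series TSVs,
# behavioral scores, connectivity CSVs, and report serialization.

#' Write a cohort to disk
#'
#' Produces manifest.csv (subject_id, group, file, fs), one ROI series TSV
#' per subject (one column per ROI, header = labels), scores.csv and a
#' ground-truth JSON.
#'
#' @param cohort output of [generateCohort()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(cohort$recordings, function(r) {
    f <- file.path(dir, paste0(r@subjectID, ".tsv"))
    utils::write.table(r@series, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    data.frame(subject_id = r@subjectID, group = r@group,
               file = basename(f), fs = r@fs, stringsAsFactors = FALSE)
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [writeCohort()] (or assembled by hand)
#'
#' @param dir directory containing manifest.csv, the series TSVs and
#'   optionally scores.csv
#' @return list: recordings, scores (NULL when absent)
#' @export
readCohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  recordings <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    ser <- as.matrix(utils::read.table(file.path(dir, m$file), header = TRUE,
                                       sep = "\t", check.names = FALSE))
    recordings[[m$subject_id]] <- new("SubjectRecording",
                                      subjectID = m$subject_id,
                                      group = m$group, series = ser,
                                      fs = m$fs)
  }
  scoresPath <- file.path(dir, "scores.csv")
  scores <- if (file.exists(scoresPath))
    utils::read.csv(scoresPath, stringsAsFactors = FALSE) else NULL
  list(recordings = recordings, scores = scores)
}

#' Write a connectivity matrix as a square labeled CSV
#'
#' A JSON sidecar (same path with extension .json) records the band and,
#' when available, the Welch parameters.
#'
#' @param cm a [ConnectivityMatrix-class]
#' @param path output CSV path
#' @param welchParams optional list stored in the sidecar
#' @export
writeConnectivityCSV <- function(cm, path, welchParams = NULL) {
  utils::write.csv(cm@values, path, row.names = TRUE)
  jsonlite::write_json(
    list(band = list(name = cm@band@name, fLo = cm@band@fLo,
                     fHi = cm@band@fHi), welch = welchParams),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = 12)
}

#' Read a connectivity CSV written by [writeConnectivityCSV()]
#' @param path CSV path
#' @return a [ConnectivityMatrix-class]
#' @export
readConnectivityCSV <- function(path) {
  C <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  colnames(C) <- rownames(C)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  new("ConnectivityMatrix",
      band = bandSpec(side$band$name, side$band$fLo, side$band$fHi), values = C)
}

#' Structural validation of a study report
#'
#' Checks the report produced by [runFullStudy()] for structural
#' soundness: required sections for every enabled stage, correct column
#' sets, and value ranges for accuracies and Bayes factors.
#'
#' @param report a report list
#' @return TRUE invisibly; errors describe the first violation
#' @export
validateReport <- function(report) {
  need <- function(ok, msg) if (!ok) stop("invalid report: ", msg)
  need(is.list(report$meta) && !is.null(report$meta$seed), "meta$seed missing")
  if (!is.null(report$accuracy)) {
    need(all(c("network", "hemisphere", "band", "accuracy") %in%
               names(report$accuracy$byCell)), "accuracy$byCell columns")
    need(all(report$accuracy$byCell$accuracy >= 0 &
               report$accuracy$byCell$accuracy <= 1), "accuracy range")
  }
  if (!is.null(report$predictions)) {
    need(all(c("roi", "band", "group", "r", "bf10", "evidence") %in%
               names(report$predictions$reported)), "prediction columns")
    if (nrow(report$predictions$reported))
      need(all(report$predictions$reported$r > 0 &
                 report$predictions$reported$bf10 >= 0), "prediction filter")
  }
  if (!is.null(report$graphStats)) {
    need(all(c("bf10", "direction", "tier") %in%
               names(report$graphStats$nodal)), "graph stat columns")
  }
  invisible(TRUE)
}

#' Write a study report bundle
#'
#' Serializes the report to report.json (deterministic formatting) plus
#' per-table TSVs.
#'
#' @param report a report list from [runFullStudy()]
#' @param dir output directory
#' @return the directory, invisibly
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  tsv <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                           row.names = FALSE, quote = FALSE)
  if (!is.null(report$accuracy)) {
    tsv(report$accuracy$byCell, "accuracy_cells.tsv")
    tsv(report$accuracy$byBand, "accuracy_bands.tsv")
  }
  if (!is.null(report$predictions)) {
    tsv(report$predictions$grid, "prediction_grid.tsv")
    tsv(report$predictions$reported, "prediction_report.tsv")
  }
  if (!is.null(report$graphStats)) {
    tsv(report$graphStats$global, "graph_global_bf.tsv")
    tsv(report$graphStats$nodal, "graph_nodal_bf.tsv")
  }
  invisible(dir)
}
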