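# Delimited-text readers and writers for the pipeline artifacts.

#' Write cohort artifacts as CSV
#'
#' Writes animals.csv, mixing_plan.csv and the configuration as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(file.path(dir, "animals.csv"),
             file.path(dir, "mixing_plan.csv"),
             file.path(dir, "config.json"))
  write.csv(cohort$animals, paths[1], row.names = FALSE)
  write.csv(cohort$mixing_plan, paths[2], row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config), paths[3], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Write feeding events with ISO-8601 timestamps
#'
#' @param events a [generate_feeding_events()] result.
#' @param path output CSV path.
#' @export
write_feeding_events <- function(events, path) {
  ev <- events
  ev$start_time <- format(ev$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' Read feeding events (ISO-8601 timestamps)
#'
#' @param path CSV with animal_id, start_time, duration_s, intake_g.
#' @return data.frame with POSIXct start_time (UTC).
#' @export
read_feeding_events <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  assert_has_cols(ev, c("animal_id", "start_time", "duration_s", "intake_g"))
  ev$start_time <- as.POSIXct(ev$start_time, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%OSZ")
  ev
}

#' Write an abundance matrix as TSV (genera x samples) plus metadata CSV
#'
#' @param abundance an `abundance_matrix` (or genera x samples matrix).
#' @param dir output directory.
#' @export
write_abundance <- function(abundance, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as_count_matrix(abundance)
  df <- data.frame(genus = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "abundance.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (inherits(abundance, "abundance_matrix")) {
    write.csv(abundance$samples, file.path(dir, "metadata.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read a genus abundance TSV (genera x samples)
#'
#' The first column holds genus names; a leading BIOM-style `#OTU ID`
#' header is tolerated.
#'
#' @param path TSV path.
#' @return integer matrix, genera x samples.
#' @export
read_abundance <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "# ") && !startsWith(first, "#OTU")) 1 else 0
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
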