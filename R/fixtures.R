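# Packaged fixtures: the per-panel coverage counts, campaign summary counts
# and database-membership flags shipped under inst/extdata. All are plain
# tab-separated text with '#' comment headers.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "mycopanel")
  if (p == "") stop_domain("fixture not found: ", name)
  p
}

#' Packaged per-panel coverage counts
#'
#' Loads the shipped species/isolate counts for all 15 panels of the
#' four-medium study, together with the study totals (152 taxa, 2479
#' analysed isolates) recorded in the file header.
#'
#' @return data.frame (panel, size, species_count, isolate_count) with
#'   attributes `taxa_total` and `isolates_total`.
#' @export
load_table2_counts <- function() {
  path <- fixture_path("table2_counts.tsv")
  hdr <- grep("^#", readLines(path), value = TRUE)
  pick <- function(key) {
    ln <- grep(paste0(key, "="), hdr, value = TRUE)[1]
    as.integer(sub(paste0(".*", key, "="), "", ln))
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  attr(df, "taxa_total") <- pick("taxa_total")
  attr(df, "isolates_total") <- pick("isolates_total")
  df
}

#' Packaged study summary counts
#'
#' @return named list of integer counts (see `study_summary.tsv`).
#' @export
load_study_summary <- function() {
  df <- read.table(fixture_path("study_summary.tsv"), header = TRUE,
                   sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
  as.list(setNames(as.integer(df$value), df$key))
}

#' Packaged database membership flags
#'
#' Loads the per-taxon strain counts and database membership flags for the
#' 30 most common taxa of the study (a patterned reconstruction of the
#' published dot columns; see the file header for the convention).
#'
#' @return data.frame with taxon, per-medium strain counts, isolate count
#'   and logical columns `msi2_initial`, `msi2_supplemented`, `bruker`,
#'   `added_spectra`.
#' @export
load_db_flags <- function() {
  df <- read.table(fixture_path("db_flags.tsv"), header = TRUE, sep = "\t",
                   comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("msi2_initial", "msi2_supplemented", "bruker",
                "added_spectra"))
    df[[col]] <- df[[col]] == 1
  df
}
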