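# Isolate tables: the canonical long format is one row per picked colony
# (isolate) with its provenance (sample, site, date, medium), the strain it
# was assigned to, and the identification outcome (taxon, rank, method,
# status). On disk this is a delimited text table with a fixed header;
# tab-separated is canonical, comma accepted on read.

#' Read an isolate table
#'
#' Reads a delimited isolate table (one row per isolate). The header must name
#' all required columns (`isolate_id, sample_id, site, date, medium,
#' strain_id, taxon, rank, method, status`); extra columns are preserved
#' untouched. The delimiter is sniffed from the header line (tab, else comma)
#' unless given. Dates must be ISO-8601 (`YYYY-MM-DD`); unparsable dates are
#' collected as row-level errors (attached as attribute `row_errors` and
#' re-reported by [validate_records()]) rather than silently dropped.
#'
#' @param path path to a delimited text file.
#' @param sep field separator; `NULL` (default) sniffs tab vs comma.
#' @return a `data.frame` of isolate records, in file order, with `date`
#'   parsed to `Date`. Attribute `row_errors` holds a data.frame
#'   (row, field, message) of parse problems.
#' @export
read_isolate_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  lines <- readLines(path, n = 50L)
  header <- lines[!startsWith(lines, "#")][1]     # '#' comment lines allowed
  if (is.na(header)) stop_domain("empty file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   check.names = FALSE, quote = "", comment.char = "#",
                   na.strings = character(0), stringsAsFactors = FALSE)
  missing <- setdiff(ISOLATE_COLUMNS, names(df))
  if (length(missing) > 0)
    stop_domain("isolate table is missing required column(s): ",
                paste(missing, collapse = ", "))
  row_errors <- data.frame(row = integer(0), field = character(0),
                           message = character(0), stringsAsFactors = FALSE)
  raw_date <- df$date
  parsed <- as.Date(raw_date, format = "%Y-%m-%d", optional = TRUE)
  # strict ISO: the round-trip must reproduce the text
  bad <- which(is.na(parsed) | format(parsed, "%Y-%m-%d") != raw_date)
  if (length(bad) > 0) {
    row_errors <- rbind(row_errors, data.frame(
      row = bad, field = "date",
      message = paste0("not an ISO-8601 date: '", raw_date[bad], "'"),
      stringsAsFactors = FALSE))
    parsed[bad] <- as.Date(NA)
  }
  df$date <- parsed
  attr(df, "row_errors") <- row_errors
  df
}

#' Write an isolate table
#'
#' Inverse of [read_isolate_table()]: tab-separated by default, dates
#' formatted ISO-8601. Writing then re-reading reproduces the records
#' field-for-field, and a read/write cycle on a canonical file is
#' byte-identical.
#'
#' @param records isolate record data.frame.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_isolate_table <- function(records, path, sep = "\t") {
  out <- records
  if (inherits(out$date, "Date")) out$date <- format(out$date, "%Y-%m-%d")
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Validate isolate records
#'
#' Checks every record invariant and reports breaches as data, not
#' exceptions: site and medium must belong to their vocabularies; rank,
#' method and status to theirs; `status = identified` exactly when rank is
#' species or genus; lost/unknown records must carry `rank = none` and
#' `method = none`; dates must be present. Identified records with an empty
#' taxon label draw a warning.
#'
#' @param records isolate record data.frame.
#' @param sites allowed site codes.
#' @param media allowed medium codes.
#' @return a `validation_report`: list with `errors` and `warnings`
#'   data.frames (row, field, message) and `ok` (`TRUE` iff no errors).
#' @export
validate_records <- function(records, sites = DEFAULT_SITES,
                             media = DEFAULT_MEDIA) {
  err <- list(); wrn <- list()
  note <- function(store, rows, field, msg) {
    if (length(rows) == 0) return(store)
    c(store, list(data.frame(row = rows, field = field, message = msg,
                             stringsAsFactors = FALSE)))
  }
  err <- note(err, which(!records$site %in% sites), "site",
              "site code not in site vocabulary")
  err <- note(err, which(!records$medium %in% media), "medium",
              "medium code not in panel vocabulary")
  err <- note(err, which(!records$rank %in% RANK_LEVELS), "rank",
              "rank must be one of species/genus/none")
  err <- note(err, which(!records$method %in% METHOD_LEVELS), "method",
              "unknown identification method")
  err <- note(err, which(!records$status %in% STATUS_LEVELS), "status",
              "status must be one of identified/lost/unknown")
  date_na <- if (inherits(records$date, "Date")) is.na(records$date)
             else is.na(as.Date(records$date, format = "%Y-%m-%d",
                                optional = TRUE))
  err <- note(err, which(date_na), "date", "missing or unparsable date")
  # status <-> rank consistency (only where the levels themselves are valid)
  valid <- records$status %in% STATUS_LEVELS & records$rank %in% RANK_LEVELS
  ident_bad <- valid & records$status == "identified" &
    !(records$rank %in% c("species", "genus"))
  err <- note(err, which(ident_bad), "rank",
              "identified records must have species or genus rank")
  unident <- valid & records$status %in% c("lost", "unknown")
  err <- note(err, which(unident & records$rank != "none"), "rank",
              "lost/unknown records must have rank 'none'")
  err <- note(err, which(unident & records$method != "none"), "method",
              "lost/unknown records must have method 'none'")
  wrn <- note(wrn, which(records$status == "identified" &
                           (is.na(records$taxon) | records$taxon == "")),
              "taxon", "identified record with empty taxon label")
  re <- attr(records, "row_errors")
  if (!is.null(re) && nrow(re) > 0) err <- c(list(re), err)
  empty <- data.frame(row = integer(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE)
  errors <- if (length(err) > 0) do.call(rbind, err) else empty
  errors <- errors[order(errors$row), , drop = FALSE]
  rownames(errors) <- NULL
  warnings <- if (length(wrn) > 0) do.call(rbind, wrn) else empty
  structure(list(errors = errors, warnings = warnings,
                 ok = nrow(errors) == 0),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Isolate table validation:",
      if (x$ok) "OK" else paste0(nrow(x$errors), " error(s)"),
      paste0("(", nrow(x$warnings), " warning(s))"), "\n")
  if (nrow(x$errors) > 0) print(utils::head(x$errors, 20))
  invisible(x)
}

#' Study-level summary of an isolate table
#'
#' Tallies analysed and identified isolates, identified strains (distinct
#' `strain_id` with `status = identified`), species- and genus-rank taxa, and
#' the mean number of identified strains per sample (half-up, 1 decimal).
#'
#' @param records isolate record data.frame.
#' @param n_samples number of water samples the records came from; defaults
#'   to the number of distinct `sample_id` values. Must be >= 1.
#' @return a `study_summary` list with fields `n_isolates`,
#'   `n_identified_isolates`, `n_strains`, `n_samples`,
#'   `n_taxa_species_rank`, `n_taxa_genus_rank`, `n_taxa_total`,
#'   `mean_strains_per_sample`.
#' @export
summarize_study <- function(records,
                            n_samples = length(unique(records$sample_id))) {
  if (!is.numeric(n_samples) || n_samples < 1)
    stop_domain("n_samples must be >= 1")
  ident <- records$status == "identified"
  n_strains <- length(unique(records$strain_id[ident]))
  sp <- unique(records$taxon[ident & records$rank == "species"])
  ge <- unique(records$taxon[ident & records$rank == "genus"])
  structure(list(
    n_isolates = nrow(records),
    n_identified_isolates = sum(ident),
    n_strains = n_strains,
    n_samples = as.integer(n_samples),
    n_taxa_species_rank = length(sp),
    n_taxa_genus_rank = length(ge),
    n_taxa_total = length(sp) + length(ge),
    mean_strains_per_sample = round_half_up(n_strains / n_samples, 1)
  ), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Study summary:\n",
      sprintf("  isolates analysed:  %d (identified: %d)\n",
              x$n_isolates, x$n_identified_isolates),
      sprintf("  identified strains: %d over %d samples (%.1f per sample)\n",
              x$n_strains, x$n_samples, x$mean_strains_per_sample),
      sprintf("  taxa: %d (%d species-rank + %d genus-rank)\n",
              x$n_taxa_total, x$n_taxa_species_rank, x$n_taxa_genus_rank),
      sep = "")
  invisible(x)
}

#' Headline study ratios from summary counts
#'
#' Recomputes the headline percentages and ratios of a sampling campaign from
#' raw summary counts (as shipped in the `study_summary.tsv` fixture):
#' the identified-isolate percentage, mean identified strains per sample,
#' the MALDI-TOF vs sequencing split (computed over identified isolates),
#' the species fraction identifiable by MS, the combined-database isolate
#' percentage (integer precision) and the unidentified percentage.
#'
#' @param counts named list/vector of counts with at least `n_isolates`,
#'   `n_identified_isolates`, `n_strains`, `n_samples`, `n_taxa_total`,
#'   `n_ms_isolates`, `n_ms_species`, `n_seq_isolates`,
#'   `n_combined_db_isolates`, `n_unidentified_isolates`.
#' @return named list of ratios, rounded per package convention.
#' @export
study_ratios <- function(counts) {
  g <- function(k) {
    v <- counts[[k]]
    if (is.null(v) || is.na(v)) stop_domain("missing count: ", k)
    as.numeric(v)
  }
  list(
    pct_isolates_identified   = pct_of(g("n_identified_isolates"), g("n_isolates")),
    strains_per_sample        = round_half_up(g("n_strains") / g("n_samples"), 1),
    pct_isolates_ms           = pct_of(g("n_ms_isolates"), g("n_identified_isolates")),
    pct_species_ms            = pct_of(g("n_ms_species"), g("n_taxa_total")),
    pct_isolates_seq          = pct_of(g("n_seq_isolates"), g("n_identified_isolates")),
    pct_isolates_combined_db  = pct_of(g("n_combined_db_isolates"), g("n_isolates"),
                                       digits = 0),
    pct_isolates_unidentified = pct_of(g("n_unidentified_isolates"), g("n_isolates"))
  )
}
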