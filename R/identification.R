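# The identification cascade: up to two rapid MALDI-TOF MS protocols, up to
# two long (protein-extraction) protocols, then ITS barcode sequencing, then
# the D1/D2 (26S, "NL") region. MS acceptance combines two reference
# libraries ("and/or" of the score criteria); a mismatch between the two
# libraries overrides acceptance and refers the strain to sequencing.
# Catalogs are label sets: a taxon absent from every active database can
# never be MS-identified, whatever its spectra look like.

#' Identification policy
#'
#' Thresholds and attempt budgets of the identification cascade. Defaults:
#' Bruker LogScore >= 1.7 for species-level acceptance; MSI-2 score inside
#' the closed interval \[20, 100\]; percent-identity thresholds 98.41 (ITS)
#' and 99.51 (NL) for species, 96.31 (ITS) and 97.11 (NL) for genus (all
#' inclusive); two short and two long MS attempts.
#'
#' @param bruker_min_logscore,msi_score_range MS acceptance thresholds.
#' @param its_species_min,its_genus_min,nl_species_min,nl_genus_min barcode
#'   percent-identity thresholds.
#' @param max_short_attempts,max_long_attempts MS attempt budgets.
#' @return an `identification_policy` list.
#' @export
identification_policy <- function(bruker_min_logscore = 1.7,
                                  msi_score_range = c(20, 100),
                                  its_species_min = 98.41,
                                  its_genus_min = 96.31,
                                  nl_species_min = 99.51,
                                  nl_genus_min = 97.11,
                                  max_short_attempts = 2L,
                                  max_long_attempts = 2L) {
  if (its_genus_min >= its_species_min || nl_genus_min >= nl_species_min)
    stop_domain("genus threshold must be below the species threshold")
  if (max_short_attempts < 0 || max_long_attempts < 0)
    stop_domain("attempt budgets must be >= 0")
  structure(list(bruker_min_logscore = bruker_min_logscore,
                 msi_score_range = msi_score_range,
                 its_species_min = its_species_min,
                 its_genus_min = its_genus_min,
                 nl_species_min = nl_species_min,
                 nl_genus_min = nl_genus_min,
                 max_short_attempts = as.integer(max_short_attempts),
                 max_long_attempts = as.integer(max_long_attempts)),
            class = "identification_policy")
}

#' MALDI-TOF MS acceptance decision
#'
#' Species-level acceptance if the Bruker LogScore criterion (>= 1.7) or
#' the MSI-2 score criterion (within \[20, 100\]) is met — logical OR —
#' provided the two libraries agree. Met criteria with discordant calls are
#' referred to sequencing; unmet criteria yield `"reject"` (the cascade may
#' retry or move on).
#'
#' @param bruker_logscore Bruker LogScore in \[0, 3\], or `NA` if absent.
#' @param msi_score MSI-2 score (>= 0), or `NA` if absent.
#' @param concordant do the two library calls agree? (Only consulted when a
#'   criterion is met.)
#' @param policy an [identification_policy()].
#' @return `"accept_species"`, `"refer_to_sequencing"` or `"reject"`.
#' @export
accept_ms <- function(bruker_logscore = NA, msi_score = NA,
                      concordant = TRUE,
                      policy = identification_policy()) {
  if (!is.na(bruker_logscore) &&
      (bruker_logscore < 0 || bruker_logscore > 3))
    stop_domain("Bruker LogScore outside plausible range [0, 3]")
  if (!is.na(msi_score) && msi_score < 0)
    stop_domain("MSI score must be non-negative")
  crit_bruker <- !is.na(bruker_logscore) &&
    bruker_logscore >= policy$bruker_min_logscore
  crit_msi <- !is.na(msi_score) &&
    msi_score >= policy$msi_score_range[1] &&
    msi_score <= policy$msi_score_range[2]
  if (!crit_bruker && !crit_msi) return("reject")
  if (isTRUE(concordant)) "accept_species" else "refer_to_sequencing"
}

#' Classify a barcode percent identity
#'
#' Species if the identity reaches the marker's species threshold, genus if
#' it reaches the genus threshold, `none` below; thresholds inclusive.
#'
#' @param identity percent identity in \[0, 100\] (vectorized).
#' @param marker `"ITS"` or `"NL"` (D1/D2 of 26S).
#' @param policy an [identification_policy()].
#' @return character vector of `"species"`, `"genus"`, `"none"`.
#' @export
classify_sequence_identity <- function(identity, marker = c("ITS", "NL"),
                                       policy = identification_policy()) {
  marker <- match.arg(marker)
  if (any(identity < 0 | identity > 100))
    stop_domain("identity must be in [0, 100]")
  sp <- if (marker == "ITS") policy$its_species_min else policy$nl_species_min
  ge <- if (marker == "ITS") policy$its_genus_min else policy$nl_genus_min
  ifelse(identity >= sp, "species", ifelse(identity >= ge, "genus", "none"))
}

#' Database catalog
#'
#' A named snapshot of a reference library, reduced to the set of taxa it
#' can identify.
#'
#' @param name catalog name.
#' @param taxa character vector of taxon labels.
#' @param snapshot free-text version/date tag.
#' @return a `db_catalog` list.
#' @export
db_catalog <- function(name, taxa, snapshot = NA_character_) {
  taxa <- unique(as.character(taxa))
  if (any(is.na(taxa) | taxa == ""))
    stop_domain("catalog taxa must be non-empty labels")
  structure(list(name = name, snapshot = snapshot, taxa = taxa),
            class = "db_catalog")
}

catalog_union <- function(catalogs) {
  unique(unlist(lapply(catalogs, function(c1) c1$taxa)))
}

#' Run the identification cascade for one isolate
#'
#' Stage order: rapid MS protocol (up to `max_short_attempts`), long MS
#' protocol (up to `max_long_attempts`), ITS sequencing, NL sequencing; the
#' first success fixes method and rank, exhaustion yields `status =
#' "unknown"`. MS stages can only succeed when the true taxon is present in
#' the union of the active catalogs; sequencing does not need a catalog. A
#' sequencing success resolves to genus rank (instead of species) with
#' probability `stage_probs$genus_frac`.
#'
#' @param truth_taxon the isolate's true taxon label.
#' @param catalogs list of [db_catalog()] objects active for MS matching.
#' @param stage_probs named list of per-stage success probabilities
#'   `ms_short`, `ms_long`, `seq_its`, `seq_nl`, plus `genus_frac`
#'   (default 0).
#' @param policy an [identification_policy()].
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used, so campaigns remain reproducible end to end).
#' @return list: `method`, `rank`, `status`, `attempts_used` (named counts
#'   for the four stages).
#' @export
run_cascade <- function(truth_taxon, catalogs, stage_probs,
                        policy = identification_policy(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- function(k) { v <- stage_probs[[k]] %||% 0; stopifnot(v >= 0, v <= 1); v }
  genus_frac <- stage_probs$genus_frac %||% 0
  in_catalog <- truth_taxon %in% catalog_union(catalogs)
  attempts <- c(ms_short = 0L, ms_long = 0L, seq_its = 0L, seq_nl = 0L)
  done <- function(method, rank) list(method = method, rank = rank,
                                      status = "identified",
                                      attempts_used = attempts)
  for (stage in c("ms_short", "ms_long")) {
    budget <- if (stage == "ms_short") policy$max_short_attempts
              else policy$max_long_attempts
    for (a in seq_len(budget)) {
      attempts[stage] <- attempts[stage] + 1L
      hit <- runif(1) < p(stage)        # draw consumed even off-catalog,
      if (hit && in_catalog)            # keeping streams comparable
        return(done(stage, "species"))
    }
  }
  for (stage in c("seq_its", "seq_nl")) {
    attempts[stage] <- attempts[stage] + 1L
    if (runif(1) < p(stage)) {
      rank <- if (genus_frac > 0 && runif(1) < genus_frac) "genus"
              else "species"
      return(done(stage, rank))
    }
  }
  list(method = "none", rank = "none", status = "unknown",
       attempts_used = attempts)
}

#' Database coverage of a study
#'
#' For each catalog (and their union): how many of the study's identified
#' taxa the catalog contains, and what percentage of analysed isolates
#' carry a taxon the catalog contains (denominator: all records supplied).
#'
#' @param catalogs list of [db_catalog()] objects.
#' @param records isolate record data.frame.
#' @return a `db_coverage_report` list: `per_catalog` data.frame (catalog,
#'   taxa_count, isolate_pct), `combined` (same fields for the union),
#'   `deltas` data.frame over ordered catalog pairs (from, to, taxa_gained,
#'   isolate_pct_gained), `study_taxa_total`, `isolates_total`.
#' @export
db_coverage <- function(catalogs, records) {
  study_taxa <- unique(records$taxon[records$status == "identified"])
  n_iso <- nrow(records)
  one <- function(name, taxa) {
    hit <- length(intersect(taxa, study_taxa))
    frac <- pct_of(sum(records$taxon %in% taxa), n_iso)
    data.frame(catalog = name, taxa_count = hit, isolate_pct = frac,
               stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(catalogs, function(c1) one(c1$name, c1$taxa)))
  comb <- one("combined", catalog_union(catalogs))
  deltas <- NULL
  if (length(catalogs) > 1) {
    pairs <- utils::combn(length(catalogs), 2)
    deltas <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c1) {
      i <- pairs[1, c1]; j <- pairs[2, c1]
      data.frame(from = per$catalog[i], to = per$catalog[j],
                 taxa_gained = per$taxa_count[j] - per$taxa_count[i],
                 isolate_pct_gained = round_half_up(
                   per$isolate_pct[j] - per$isolate_pct[i], 1),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(per_catalog = per, combined = comb, deltas = deltas,
                 study_taxa_total = length(study_taxa),
                 isolates_total = n_iso),
            class = "db_coverage_report")
}

#' @export
print.db_coverage_report <- function(x, ...) {
  cat(sprintf("Database coverage over %d study taxa, %d isolates:\n",
              x$study_taxa_total, x$isolates_total))
  print(rbind(x$per_catalog, x$combined))
  invisible(x)
}

#' Supplementation delta between two catalog snapshots
#'
#' Gains in identifiable study taxa and isolate percentage when moving from
#' an initial catalog snapshot to its supplemented successor.
#'
#' @param initial,supplemented [db_catalog()] snapshots; the initial taxa
#'   are expected to be a subset of the supplemented ones (warning if not).
#' @param records isolate record data.frame.
#' @return list: `taxa_initial`, `taxa_supplemented`, `taxa_gained`,
#'   `isolate_pct_initial`, `isolate_pct_supplemented`,
#'   `isolate_pct_gained`.
#' @export
supplementation_delta <- function(initial, supplemented, records) {
  if (!all(initial$taxa %in% supplemented$taxa))
    warning("initial catalog is not a subset of the supplemented catalog")
  rep <- db_coverage(list(initial, supplemented), records)
  per <- rep$per_catalog
  list(taxa_initial = per$taxa_count[1],
       taxa_supplemented = per$taxa_count[2],
       taxa_gained = per$taxa_count[2] - per$taxa_count[1],
       isolate_pct_initial = per$isolate_pct[1],
       isolate_pct_supplemented = per$isolate_pct[2],
       isolate_pct_gained = round_half_up(
         per$isolate_pct[2] - per$isolate_pct[1], 1))
}
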