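# Panel evaluation: the taxon x medium incidence matrix and the exhaustive
# coverage scoring of every media subset against the full panel.
#
# Denominator conventions (fixed by the reference study design):
#  * species percentages are relative to the number of taxa recovered by the
#    FULL panel, which is by construction 100% — the full panel is taken as
#    the best achievable, not as truth;
#  * isolate percentages default to the "analysed" denominator (identified +
#    lost + unknown isolates); an "identified"-only denominator is available.
# Genus-rank labels (e.g. "Geotrichum sp.") each count as one taxon.

#' Build a taxon-by-medium incidence matrix
#'
#' The taxa axis is built from identified records only (species-rank and
#' genus-rank labels each count as one taxon); lost and unknown isolates
#' contribute to the per-medium isolate counts but never to the taxa axis.
#'
#' @param records isolate record data.frame (validated).
#' @param media medium codes spanning the panel; defaults to the media
#'   present in `records`, canonically ordered.
#' @return an `incidence_matrix`: list with `taxa`, `media`, `presence`
#'   (logical taxa x media matrix), `isolates_per_medium` (all analysed
#'   isolates), `identified_per_medium`, `taxa_total`, `isolates_total`,
#'   `identified_total`.
#' @export
build_incidence <- function(records, media = NULL) {
  if (is.null(media)) media <- canonical_media(records$medium)
  else media <- canonical_media(media)
  ident <- records$status == "identified"
  if (!any(ident))
    warning("no identified records: incidence matrix has an empty taxa axis")
  taxa <- sort(unique(records$taxon[ident]))
  presence <- matrix(FALSE, nrow = length(taxa), ncol = length(media),
                     dimnames = list(taxa, media))
  if (length(taxa) > 0) {
    idx <- cbind(match(records$taxon[ident], taxa),
                 match(records$medium[ident], media))
    presence[idx[!is.na(idx[, 1]) & !is.na(idx[, 2]), , drop = FALSE]] <- TRUE
  }
  count_by <- function(which_rows) {
    tab <- table(factor(records$medium[which_rows], levels = media))
    setNames(as.integer(tab), media)
  }
  structure(list(
    taxa = taxa, media = media, presence = presence,
    isolates_per_medium = count_by(rep(TRUE, nrow(records))),
    identified_per_medium = count_by(ident),
    taxa_total = length(taxa),
    isolates_total = nrow(records),
    identified_total = sum(ident)
  ), class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("Incidence matrix: %d taxa x %d media (%s); %d analysed isolates\n",
              x$taxa_total, length(x$media), paste(x$media, collapse = ", "),
              x$isolates_total))
  invisible(x)
}

#' Enumerate all non-empty media subsets
#'
#' All `2^k - 1` panels, ordered by size then lexicographically in canonical
#' medium order.
#'
#' @param media medium codes (1 to 12).
#' @return list of character vectors (panels).
#' @export
enumerate_panels <- function(media) {
  media <- canonical_media(media)
  k <- length(media)
  if (k < 1) stop_domain("media list must be non-empty")
  if (k > 12) stop_domain("exhaustive enumeration limited to 12 media")
  panels <- list()
  for (size in seq_len(k)) {
    combos <- utils::combn(k, size, simplify = FALSE)
    panels <- c(panels, lapply(combos, function(i) media[i]))
  }
  panels
}

#' Coverage of one media panel
#'
#' Species coverage is the size of the union of the panel's presence
#' columns; isolate coverage is additive over the panel's media (every
#' isolate belongs to exactly one medium). Percentages are half-up rounded
#' to one decimal.
#'
#' @param incidence an `incidence_matrix`.
#' @param panel subset of `incidence$media`.
#' @param isolate_denominator `"analysed"` (default) or `"identified"`.
#' @return one-row data.frame: panel, size, species_count, species_pct,
#'   isolate_count, isolate_pct.
#' @export
panel_coverage <- function(incidence, panel,
                           isolate_denominator = c("analysed", "identified")) {
  isolate_denominator <- match.arg(isolate_denominator)
  panel <- canonical_media(panel)
  if (length(panel) == 0) stop_domain("panel must be non-empty")
  unknown <- setdiff(panel, incidence$media)
  if (length(unknown) > 0)
    stop_domain("unknown medium in panel: ", paste(unknown, collapse = ", "))
  sp <- if (incidence$taxa_total == 0) 0L else
    sum(rowSums(incidence$presence[, panel, drop = FALSE]) > 0)
  counts <- if (isolate_denominator == "analysed")
    incidence$isolates_per_medium else incidence$identified_per_medium
  total <- if (isolate_denominator == "analysed")
    incidence$isolates_total else incidence$identified_total
  iso <- sum(counts[panel])
  data.frame(
    panel = panel_label(panel), size = length(panel),
    species_count = as.integer(sp),
    species_pct = if (incidence$taxa_total > 0)
      pct_of(sp, incidence$taxa_total) else NA_real_,
    isolate_count = as.integer(iso),
    isolate_pct = pct_of(iso, total),
    stringsAsFactors = FALSE)
}

#' Coverage table over all panels
#'
#' One row per enumerated panel (all non-empty media subsets, by size then
#' canonical order). The full panel has species coverage 100% by
#' construction.
#'
#' @inheritParams panel_coverage
#' @return data.frame of [panel_coverage()] rows with attributes
#'   `taxa_total` and `isolates_total` (the denominators used).
#' @export
coverage_table <- function(incidence,
                           isolate_denominator = c("analysed", "identified")) {
  isolate_denominator <- match.arg(isolate_denominator)
  rows <- lapply(enumerate_panels(incidence$media), function(p)
    panel_coverage(incidence, p, isolate_denominator))
  out <- do.call(rbind, rows)
  attr(out, "taxa_total") <- incidence$taxa_total
  attr(out, "isolates_total") <- if (isolate_denominator == "analysed")
    incidence$isolates_total else incidence$identified_total
  out
}

#' Coverage table from pre-tabulated counts
#'
#' Computes the percentage columns from per-panel species/isolate counts
#' (e.g. the packaged study counts) without needing an incidence matrix.
#'
#' @param counts data.frame with columns `panel`, `species_count`,
#'   `isolate_count` (a `size` column is recomputed from the panel labels).
#' @param taxa_total species denominator.
#' @param isolates_total isolate denominator.
#' @return data.frame as from [coverage_table()].
#' @export
coverage_from_counts <- function(counts,
                                 taxa_total = attr(counts, "taxa_total"),
                                 isolates_total = attr(counts, "isolates_total")) {
  if (is.null(taxa_total) || is.null(isolates_total))
    stop_domain("taxa_total and isolates_total are required")
  if (any(counts$species_count > taxa_total))
    stop_domain("species_count exceeds taxa_total")
  panels <- lapply(counts$panel, parse_panel)
  sizes <- lengths(panels)
  full <- which(sizes == max(sizes))
  if (!any(vapply(panels[full], function(p)
    setequal(p, canonical_media(unlist(panels))), logical(1))))
    stop_domain("the full panel must be present in the counts")
  out <- data.frame(
    panel = vapply(panels, panel_label, character(1)),
    size = sizes,
    species_count = as.integer(counts$species_count),
    species_pct = pct_of(counts$species_count, taxa_total),
    isolate_count = as.integer(counts$isolate_count),
    isolate_pct = pct_of(counts$isolate_count, isolates_total),
    stringsAsFactors = FALSE)
  out <- out[order(out$size, out$panel), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxa_total") <- taxa_total
  attr(out, "isolates_total") <- isolates_total
  out
}

#' Panel-size group summary
#'
#' Groups a coverage table by panel size and reports mean/min/max species
#' and isolate counts. Mean counts are half-up rounded to two decimals;
#' mean percentages are computed from the unrounded means, then half-up
#' rounded to one decimal (so that the exact k/|media| symmetry of the mean
#' isolate coverage survives rounding).
#'
#' @param coverages a coverage table carrying `taxa_total`/`isolates_total`
#'   attributes, or supplied explicitly.
#' @param taxa_total,isolates_total denominators (default: attributes).
#' @return data.frame: panel_size, n_panels, mean_species,
#'   mean_species_pct, min_species, max_species, mean_isolates,
#'   mean_isolate_pct, min_isolates, max_isolates.
#' @export
group_summary <- function(coverages,
                          taxa_total = attr(coverages, "taxa_total"),
                          isolates_total = attr(coverages, "isolates_total")) {
  if (nrow(coverages) == 0) stop_domain("coverage table is empty")
  sizes <- sort(unique(coverages$size))
  rows <- lapply(sizes, function(s) {
    g <- coverages[coverages$size == s, , drop = FALSE]
    msp <- mean(g$species_count); mis <- mean(g$isolate_count)
    data.frame(
      panel_size = s, n_panels = nrow(g),
      mean_species = round_half_up(msp, 2),
      mean_species_pct = if (!is.null(taxa_total))
        pct_of(msp, taxa_total) else NA_real_,
      min_species = min(g$species_count),
      max_species = max(g$species_count),
      mean_isolates = round_half_up(mis, 2),
      mean_isolate_pct = if (!is.null(isolates_total))
        pct_of(mis, isolates_total) else NA_real_,
      min_isolates = min(g$isolate_count),
      max_isolates = max(g$isolate_count),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank panels of a given size
#'
#' Descending by species or isolate count; ties broken lexicographically by
#' panel label (canonical medium order), for determinism.
#'
#' @param coverages coverage table.
#' @param size panel size to rank.
#' @param key `"species"` or `"isolates"`.
#' @return the matching coverage rows, best first.
#' @export
rank_panels <- function(coverages, size, key = c("species", "isolates")) {
  key <- match.arg(key)
  g <- coverages[coverages$size == size, , drop = FALSE]
  if (nrow(g) == 0) stop_domain("no panel of size ", size)
  val <- if (key == "species") g$species_count else g$isolate_count
  g <- g[order(-val, g$panel), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Smallest panel reaching a target species coverage
#'
#' Exhaustive search over all panels for up to 6 media (guaranteed optimum:
#' smallest panel whose species count reaches `target_fraction` of the
#' full-panel taxa; ties broken by higher species count, then
#' lexicographically); greedy set cover beyond 6 media (best marginal gain
#' per step, documented non-optimality).
#'
#' @param incidence an `incidence_matrix`.
#' @param target_fraction fraction of `taxa_total` to cover, in \[0, 1\].
#' @return list: `panel` (character vector, empty for target 0), `coverage`
#'   (one-row data.frame or NULL), `reachable`, `method`
#'   (`"exhaustive"`/`"greedy"`).
#' @export
minimal_panel <- function(incidence, target_fraction) {
  if (!is.numeric(target_fraction) || target_fraction < 0 ||
      target_fraction > 1)
    stop_domain("target_fraction must be in [0, 1]")
  if (target_fraction == 0)
    return(list(panel = character(0), coverage = NULL, reachable = TRUE,
                method = "trivial"))
  need <- target_fraction * incidence$taxa_total - 1e-9
  full_cov <- panel_coverage(incidence, incidence$media)
  if (full_cov$species_count < need)
    return(list(panel = incidence$media, coverage = full_cov,
                reachable = FALSE, method = "exhaustive"))
  if (length(incidence$media) <= 6) {
    tab <- coverage_table(incidence)
    ok <- tab[tab$species_count >= need, , drop = FALSE]
    ok <- ok[order(ok$size, -ok$species_count, ok$panel), , drop = FALSE]
    best <- ok[1, , drop = FALSE]; rownames(best) <- NULL
    return(list(panel = parse_panel(best$panel), coverage = best,
                reachable = TRUE, method = "exhaustive"))
  }
  # greedy set cover: add the medium with the largest marginal species gain
  chosen <- character(0)
  covered <- rep(FALSE, incidence$taxa_total)
  repeat {
    if (sum(covered) >= need) break
    rest <- setdiff(incidence$media, chosen)
    gain <- vapply(rest, function(m)
      sum(incidence$presence[, m] & !covered), numeric(1))
    pick <- rest[order(-gain, match(rest, incidence$media))][1]
    chosen <- c(chosen, pick)
    covered <- covered | incidence$presence[, pick]
  }
  cov <- panel_coverage(incidence, chosen)
  list(panel = canonical_media(chosen), coverage = cov, reachable = TRUE,
       method = "greedy")
}

#' Per-taxon isolation profiles
#'
#' For each identified taxon: distinct strains (`n_strains`), distinct
#' strains seen per medium, and isolate count; sorted by `n_strains`
#' descending, ties by taxon label. Optionally joins database membership
#' flags.
#'
#' @param records isolate record data.frame.
#' @param db_flags optional data.frame with a `taxon` column plus logical
#'   membership columns to join.
#' @param media medium codes (default: canonical media in `records`).
#' @return data.frame: taxon, n_strains, one `strains_<medium>` column per
#'   medium, n_isolates, plus any joined flag columns.
#' @export
taxon_profiles <- function(records, db_flags = NULL, media = NULL) {
  if (is.null(media)) media <- canonical_media(records$medium)
  id <- records[records$status == "identified", , drop = FALSE]
  taxa <- sort(unique(id$taxon))
  prof <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  prof$n_strains <- vapply(taxa, function(t)
    length(unique(id$strain_id[id$taxon == t])), numeric(1))
  for (m in media)
    prof[[paste0("strains_", m)]] <- vapply(taxa, function(t)
      length(unique(id$strain_id[id$taxon == t & id$medium == m])),
      numeric(1))
  prof$n_isolates <- vapply(taxa, function(t) sum(id$taxon == t), numeric(1))
  prof <- prof[order(-prof$n_strains, prof$taxon), , drop = FALSE]
  rownames(prof) <- NULL
  if (!is.null(db_flags)) {
    flags <- db_flags[, c("taxon", setdiff(names(db_flags),
                                           c("taxon", "n_strains", "n_isolates",
                                             paste0("strains_", media),
                                             "ch", "dg", "dr", "sy"))),
                      drop = FALSE]
    prof <- merge(prof, flags, by = "taxon", all.x = TRUE, sort = FALSE)
    prof <- prof[order(-prof$n_strains, prof$taxon), , drop = FALSE]
    rownames(prof) <- NULL
  }
  prof
}
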