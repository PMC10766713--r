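# In-code fixtures: generators of valid isolate tables and small incidence
# instances used across the suite.

SITES <- c("ARC", "CRE", "FSA", "PER", "PSC", "RUI")
MEDIA <- c("CH", "DG", "DR", "SY")

random_records <- function(n, seed = 1, n_taxa = 12,
                           sites = SITES, media = MEDIA,
                           p_status = c(identified = 0.9, lost = 0.05,
                                        unknown = 0.05)) {
  set.seed(seed)
  taxa <- sprintf("Genus%02d species%03d", ((seq_len(n_taxa) - 1) %% 5) + 1,
                  seq_len(n_taxa))
  status <- sample(names(p_status), n, replace = TRUE, prob = p_status)
  ident <- status == "identified"
  rank <- ifelse(ident, sample(c("species", "genus"), n, replace = TRUE,
                               prob = c(0.95, 0.05)), "none")
  taxon <- character(n)
  ti <- sample.int(n_taxa, n, replace = TRUE)
  taxon[ident & rank == "species"] <- taxa[ti[ident & rank == "species"]]
  taxon[ident & rank == "genus"] <-
    sub("^(\\S+).*", "\\1 sp.", taxa[ti[ident & rank == "genus"]])
  method <- ifelse(ident,
                   sample(c("ms_short", "ms_long", "seq_its", "seq_nl"), n,
                          replace = TRUE, prob = c(0.6, 0.2, 0.15, 0.05)),
                   "none")
  data.frame(
    isolate_id = sprintf("I%05d", seq_len(n)),
    sample_id = sprintf("S%03d", sample.int(max(2, n %/% 4), n, TRUE)),
    site = sample(sites, n, replace = TRUE),
    date = as.Date("2020-06-01") + sample.int(500, n, TRUE),
    medium = sample(media, n, replace = TRUE),
    strain_id = sprintf("ST%04d", sample.int(max(2, n %/% 2), n, TRUE)),
    taxon = taxon, rank = rank, method = method, status = status,
    stringsAsFactors = FALSE)
}

# random incidence instance built directly (taxa x media presence with a
# guaranteed non-empty row, plus per-medium isolate counts)
random_incidence <- function(n_taxa, media, seed) {
  set.seed(seed)
  presence <- matrix(runif(n_taxa * length(media)) < 0.4, nrow = n_taxa,
                     dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                     media))
  empty <- rowSums(presence) == 0
  presence[cbind(which(empty),
                 sample.int(length(media), sum(empty), TRUE))] <- TRUE
  iso <- stats::setNames(sample.int(50, length(media), TRUE), media)
  structure(list(taxa = rownames(presence), media = media,
                 presence = presence, isolates_per_medium = iso,
                 identified_per_medium = iso, taxa_total = n_taxa,
                 isolates_total = sum(iso), identified_total = sum(iso)),
            class = "incidence_matrix")
}

# brute-force coverage of a panel: explicit set union over taxa
brute_panel_species <- function(incidence, panel) {
  hit <- character(0)
  for (m in panel)
    hit <- union(hit, incidence$taxa[incidence$presence[, m]])
  length(hit)
}

expect_no_error <- function(expr) expect_error(expr, NA)
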