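# Incidence construction and subset-coverage evaluation.

test_that("incidence separates taxa (identified only) from isolate counts", {
  rec <- data.frame(
    isolate_id = c("I1", "I2", "I3"), sample_id = "S1", site = "ARC",
    date = as.Date("2020-06-01"), medium = c("CH", "DG", "SY"),
    strain_id = c("ST1", "ST1", "ST2"),
    taxon = c("Pichia fermentans", "Pichia fermentans", ""),
    rank = c("species", "species", "none"),
    method = c("ms_short", "ms_short", "none"),
    status = c("identified", "identified", "lost"),
    stringsAsFactors = FALSE)
  inc <- build_incidence(rec)
  expect_equal(inc$taxa_total, 1)
  expect_true(all(inc$presence["Pichia fermentans", c("CH", "DG")]))
  expect_false(inc$presence["Pichia fermentans", "SY"])
  # the lost isolate counts towards SY's isolate total but not the taxa axis
  expect_equal(unname(inc$isolates_per_medium[c("CH", "DG", "SY")]),
               c(1L, 1L, 1L))
  expect_equal(unname(inc$identified_per_medium["SY"]), 0L)
  expect_equal(inc$isolates_total, 3)

  none <- rec[3, ]
  expect_warning(inc0 <- build_incidence(none), "no identified")
  expect_equal(inc0$taxa_total, 0)
})

test_that("incidence presence equals brute-force set construction", {
  for (seed in 1:10) {
    rec <- random_records(120, seed = seed)
    inc <- build_incidence(rec)
    id <- rec[rec$status == "identified", ]
    for (m in inc$media) {
      expect_setequal(inc$taxa[inc$presence[, m]],
                      unique(id$taxon[id$medium == m]))
    }
    expect_setequal(inc$taxa, unique(id$taxon))
  }
})

test_that("panel enumeration is exhaustive, unique and canonically ordered", {
  p4 <- enumerate_panels(MEDIA)
  expect_length(p4, 15)
  expect_equal(vapply(p4[1:4], panel_label, ""), c("CH", "DG", "DR", "SY"))
  expect_equal(panel_label(p4[[5]]), "CH + DG")
  expect_length(enumerate_panels("CH"), 1)
  p5 <- enumerate_panels(c(MEDIA, "XX"))
  expect_length(p5, 31)
  labs <- vapply(p5, panel_label, "")
  expect_equal(anyDuplicated(labs), 0)
  expect_setequal(unique(unlist(p5)), c(MEDIA, "XX"))
  expect_error(enumerate_panels(character(0)), "non-empty")
})

test_that("isolate coverage is additive over panel members", {
  # reconstruct the study's per-medium isolate totals as records
  counts <- c(CH = 659, DG = 556, DR = 699, SY = 565)
  n <- sum(counts)
  rec <- data.frame(
    isolate_id = sprintf("I%04d", 1:n), sample_id = "S1", site = "ARC",
    date = as.Date("2020-06-01"),
    medium = rep(names(counts), counts),
    strain_id = sprintf("ST%04d", 1:n), taxon = "Pichia fermentans",
    rank = "species", method = "ms_short", status = "identified",
    stringsAsFactors = FALSE)
  inc <- build_incidence(rec)
  cov <- panel_coverage(inc, c("CH", "DG"))
  expect_equal(cov$isolate_count, 1215L)
  expect_equal(cov$isolate_pct, 49.0)
  single <- panel_coverage(inc, "DR")
  expect_equal(single$isolate_count, 699L)
  expect_error(panel_coverage(inc, c("CH", "QQ")), "unknown medium")
})

test_that("coverage equals brute-force set union on random instances", {
  for (seed in 1:15) {
    inc <- random_incidence(10, MEDIA, seed = seed)
    tab <- coverage_table(inc)
    expect_equal(nrow(tab), 15)
    for (i in seq_len(nrow(tab))) {
      panel <- parse_panel(tab$panel[i])
      expect_equal(tab$species_count[i], brute_panel_species(inc, panel))
      expect_equal(tab$isolate_count[i],
                   sum(inc$isolates_per_medium[panel]))
    }
    # monotone under subset inclusion + union bounds
    for (i in seq_len(nrow(tab))) for (j in seq_len(nrow(tab))) {
      pi <- parse_panel(tab$panel[i]); pj <- parse_panel(tab$panel[j])
      if (all(pi %in% pj)) {
        expect_lte(tab$species_count[i], tab$species_count[j])
        expect_lte(tab$isolate_count[i], tab$isolate_count[j])
      }
    }
    singles <- tab$species_count[tab$size == 1]
    for (i in which(tab$size > 1)) {
      members <- match(parse_panel(tab$panel[i]), inc$media)
      expect_gte(tab$species_count[i], max(singles[members]))
      expect_lte(tab$species_count[i],
                 min(sum(singles[members]), inc$taxa_total))
    }
  }
})

test_that("a medium recovering every taxon scores 100% alone", {
  inc <- random_incidence(8, MEDIA, seed = 2)
  inc$presence[, "DR"] <- TRUE
  tab <- coverage_table(inc)
  expect_equal(tab$species_pct[tab$panel == "DR"], 100.0)
})

test_that("coverage from counts matches an independent rounding oracle", {
  counts <- load_table2_counts()
  tab <- coverage_from_counts(counts)
  dg <- tab[tab$panel == "DG", ]
  expect_equal(dg$species_pct, 48.0)
  expect_equal(dg$isolate_pct, 22.4)
  full <- tab[tab$size == 4, ]
  expect_equal(full$species_pct, 100.0)
  expect_error(
    coverage_from_counts(data.frame(panel = "CH", species_count = 200,
                                    isolate_count = 1),
                         taxa_total = 152, isolates_total = 2479),
    "exceeds")
  # random counts vs an independent half-up oracle written with integer
  # floor/modulo arithmetic rather than the package's rounding helper
  set.seed(9)
  for (i in 1:50) {
    sc <- sample.int(152, 1); tot <- 152
    p <- coverage_from_counts(
      data.frame(panel = c("CH", "CH + DG + DR + SY"),
                 species_count = c(sc, tot), isolate_count = c(1, 2)),
      taxa_total = tot, isolates_total = 2)$species_pct[1]
    x <- 1000 * sc / tot
    oracle <- (x %/% 1 + (x %% 1 >= 0.5 - 1e-9)) / 10
    expect_equal(p, oracle)
  }
})

test_that("group summary reproduces printed means and the size symmetry", {
  tab <- coverage_from_counts(load_table2_counts())
  gs <- group_summary(tab)
  expect_equal(gs$mean_species[gs$panel_size == 1], 89.5)
  expect_equal(gs$mean_species_pct[gs$panel_size == 1], 58.9)
  expect_equal(gs$mean_isolates[gs$panel_size == 1], 619.75)
  # single-panel group: mean equals the panel itself
  expect_equal(gs$mean_species[gs$panel_size == 4], 152)
  # mean isolate count of the size-k group = k/|media| x isolates_total
  inc <- random_incidence(10, MEDIA, seed = 5)
  gi <- group_summary(coverage_table(inc))
  for (k in 1:4)
    expect_equal(gi$mean_isolates[gi$panel_size == k],
                 k / 4 * inc$isolates_total)
})

test_that("panel ranking agrees with a brute-force sort", {
  tab <- coverage_from_counts(load_table2_counts())
  top2 <- rank_panels(tab, 2, "species")
  expect_equal(top2$panel[1], "CH + DR")
  expect_equal(top2$species_count[1], 126)
  expect_equal(rank_panels(tab, 4, "species")$panel, "CH + DG + DR + SY")
  expect_error(rank_panels(tab, 7, "species"), "no panel")
  inc <- random_incidence(9, MEDIA, seed = 3)
  ti <- coverage_table(inc)
  r <- rank_panels(ti, 2, "isolates")
  brute <- ti[ti$size == 2, ]
  brute <- brute[order(-brute$isolate_count, brute$panel), ]
  expect_equal(r$panel, brute$panel)
})

test_that("minimal panel finds the guaranteed optimum", {
  inc <- random_incidence(8, MEDIA, seed = 2)
  inc$presence[, "DR"] <- TRUE
  got <- minimal_panel(inc, 1.0)
  expect_equal(got$panel, "DR")
  expect_true(got$reachable)
  expect_equal(minimal_panel(inc, 0)$panel, character(0))

  # exhaustive answer vs an independent brute force over all subsets
  for (seed in 1:10) {
    inc5 <- random_incidence(12, c(MEDIA, "XX"), seed = seed)
    for (target in c(0.5, 0.8, 1.0)) {
      got <- minimal_panel(inc5, target)
      best_size <- Inf; best_count <- -1
      for (p in enumerate_panels(inc5$media)) {
        cnt <- brute_panel_species(inc5, p)
        if (cnt >= target * inc5$taxa_total - 1e-9 &&
            (length(p) < best_size ||
             (length(p) == best_size && cnt > best_count))) {
          best_size <- length(p); best_count <- cnt
        }
      }
      expect_equal(length(got$panel), best_size)
      expect_equal(got$coverage$species_count, best_count)
      expect_gte(got$coverage$species_count,
                 target * inc5$taxa_total - 1e-9)
    }
  }
})

test_that("greedy set cover is used beyond 6 media and never beats optimum", {
  media7 <- c(MEDIA, "M5", "M6", "M7")
  for (seed in 1:5) {
    inc7 <- random_incidence(14, media7, seed = seed)
    got <- minimal_panel(inc7, 0.9)
    expect_equal(got$method, "greedy")
    # independent exhaustive optimum
    best <- Inf
    for (p in enumerate_panels(media7))
      if (brute_panel_species(inc7, p) >= 0.9 * inc7$taxa_total - 1e-9)
        best <- min(best, length(p))
    expect_gte(length(got$panel), best)
    expect_gte(got$coverage$species_count, 0.9 * inc7$taxa_total - 1e-9)
  }
})

test_that("unreachable targets are reported, not raised", {
  inc <- random_incidence(10, MEDIA, seed = 4)
  inc$taxa_total <- 20L  # pretend half the taxa were never recovered
  got <- minimal_panel(inc, 1.0)
  expect_false(got$reachable)
  expect_equal(got$panel, inc$media)
})

test_that("taxon profiles equal a brute-force group-by", {
  rec <- data.frame(
    isolate_id = c("I1", "I2"), sample_id = "S1", site = "ARC",
    date = as.Date("2020-06-01"), medium = c("CH", "DR"),
    strain_id = "ST1", taxon = "Pichia fermentans", rank = "species",
    method = "ms_short", status = "identified", stringsAsFactors = FALSE)
  p <- taxon_profiles(rec)
  expect_equal(p$n_strains, 1)
  expect_equal(p$strains_CH, 1)
  expect_equal(p$strains_DR, 1)
  expect_equal(p$n_isolates, 2)

  r <- random_records(250, seed = 13)
  prof <- taxon_profiles(r, media = MEDIA)
  id <- r[r$status == "identified", ]
  expect_setequal(prof$taxon, unique(id$taxon))
  for (i in sample(nrow(prof), 8)) {
    t1 <- prof$taxon[i]
    expect_equal(prof$n_strains[i],
                 length(unique(id$strain_id[id$taxon == t1])))
    expect_equal(prof$n_isolates[i], sum(id$taxon == t1))
    expect_equal(prof$strains_CH[i],
                 length(unique(id$strain_id[id$taxon == t1 &
                                              id$medium == "CH"])))
  }
  expect_true(all(diff(prof$n_strains) <= 0))
  expect_true(all(prof$n_strains <= prof$n_isolates))
})

test_that("profiles are consistent with incidence marginals", {
  rec <- simulate_campaign(
    build_community(30, seed = 4),
    campaign_config(n_sessions = 3, sites = c("ARC", "CRE"), seed = 9))
  prof <- taxon_profiles(rec, media = MEDIA)
  inc <- build_incidence(rec, media = MEDIA)
  for (m in MEDIA)
    expect_equal(sum(prof[[paste0("strains_", m)]] > 0),
                 sum(inc$presence[, m]))
  expect_equal(nrow(prof), inc$taxa_total)
})
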