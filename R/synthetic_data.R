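# Synthetic communities and sampling campaigns. The generator emulates the
# statistical structure the analysis assumes: a strongly skewed
# rank-abundance distribution (a few dominant species, a long tail),
# medium-specific detection probabilities, censoring of late-emerging
# colonies by filamentous overgrowth, and the multi-stage identification
# cascade. Two independent seed phases (physical campaign, then cascade)
# keep the produced isolates identical when only identification settings
# change, and make censoring monotone pathwise per seed.

#' Build a community model
#'
#' Ranked relative abundances from a named family, with per-taxon x medium
#' detection probabilities and per-taxon colony-emergence time parameters.
#' Families: `"lognormal"` — quantile-based lognormal rank-abundance
#' `a_i ∝ exp(sigma * z_i)` with `z_i` the (1-(i-0.5)/n) normal quantile
#' (default, calibrated to a top-3 strain share of 0.25 and top-30 of 0.75
#' when `params` is omitted); `"geometric"` — `a_i ∝ theta (1-theta)^(i-1)`;
#' `"uniform"`. Everything is deterministic given `seed`.
#'
#' @param n_taxa species-pool size (>= 1).
#' @param family abundance family.
#' @param params family parameters: `list(sigma = ...)` for lognormal,
#'   `list(theta = ...)` for geometric; `NULL` calibrates the default skew
#'   (lognormal) or errors (geometric requires `theta`).
#' @param seed integer seed driving the detection matrix.
#' @param media medium codes.
#' @param detection optional taxa x media matrix of detection probabilities
#'   in \[0, 1\]; by default each medium gets a baseline detectability in
#'   \[0.45, 0.75\] with per-taxon jitter, drawn from `seed`.
#' @param emergence per-taxon lognormal emergence-time parameters (hours),
#'   `list(meanlog, sdlog)`; medium-independent.
#' @return a `community_model` list: `n_taxa`, `taxa`, `abundance`,
#'   `detection`, `emergence`, `family`, `params`, `seed`, `media`.
#' @export
build_community <- function(n_taxa,
                            family = c("lognormal", "geometric", "uniform"),
                            params = NULL, seed = 1L,
                            media = DEFAULT_MEDIA, detection = NULL,
                            emergence = list(meanlog = log(40), sdlog = 0.5)) {
  family <- match.arg(family)
  if (n_taxa < 1) stop_domain("n_taxa must be >= 1")
  if (family == "lognormal" && is.null(params)) {
    # default skew: top-3 taxa hold 25% of strains, top-30 hold 75%; for
    # pools too small to express the targets, keep the shape calibrated on
    # the 152-taxon reference pool
    targets <- Filter(function(t) t[1] < n_taxa,
                      list(c(3, 0.25), c(30, 0.75)))
    params <- if (length(targets) > 0)
      calibrate_skew(targets, "lognormal", n_taxa)$params
    else list(sigma = 1.52)
  }
  abundance <- rank_abundance(family, n_taxa, params)
  taxa <- sprintf("Genus%02d species%03d",
                  ((seq_len(n_taxa) - 1) %% 20) + 1, seq_len(n_taxa))
  if (is.null(detection)) {
    set.seed(seed)
    base <- runif(length(media), 0.45, 0.75)
    detection <- sapply(seq_along(media), function(j)
      pmin(pmax(base[j] + runif(n_taxa, -0.25, 0.25), 0.05), 0.95))
    dim(detection) <- c(n_taxa, length(media))
  }
  dimnames(detection) <- list(taxa, media)
  if (any(detection < 0 | detection > 1))
    stop_domain("detection probabilities must be in [0, 1]")
  structure(list(n_taxa = as.integer(n_taxa), taxa = taxa,
                 abundance = abundance, detection = detection,
                 emergence = emergence, family = family, params = params,
                 seed = as.integer(seed), media = media),
            class = "community_model")
}

# ranked relative-abundance vector for a named family (sums to 1,
# non-increasing)
rank_abundance <- function(family, n_taxa, params) {
  a <- switch(family,
    uniform = rep(1, n_taxa),
    geometric = {
      theta <- params$theta
      if (is.null(theta) || theta <= 0 || theta >= 1)
        stop_domain("geometric family requires theta in (0, 1)")
      theta * (1 - theta)^(seq_len(n_taxa) - 1)
    },
    lognormal = {
      sigma <- params$sigma
      if (is.null(sigma) || sigma <= 0)
        stop_domain("lognormal family requires sigma > 0")
      exp(sigma * qnorm(1 - (seq_len(n_taxa) - 0.5) / n_taxa))
    },
    stop_domain("unknown abundance family: ", family))
  a / sum(a)
}

cumulative_share <- function(abundance, cutoff) sum(abundance[seq_len(cutoff)])

#' Calibrate community skew to cumulative-share targets
#'
#' Finds the family parameter that best matches one or two targets of the
#' form (rank cutoff, cumulative abundance share) — e.g. "the top 3 taxa
#' hold 25% of strains, the top 30 hold 75%" — by bounded 1-D minimization
#' of the squared share deviations (for a single geometric target, exact
#' root finding on the closed-form share). Infeasible targets are never a
#' silent success: the best fit is returned with `flagged = TRUE` whenever
#' the worst achieved-vs-target deviation exceeds 0.02, and targets with
#' `cutoff == n_taxa` are flagged degenerate (their share is 1 by
#' construction).
#'
#' @param targets list of `c(cutoff, share)` pairs (1 or 2).
#' @param family `"geometric"` or `"lognormal"`.
#' @param n_taxa species-pool size.
#' @return list: `family`, `params`, `achieved` (shares at the target
#'   cutoffs), `residual` (max absolute deviation), `flagged`,
#'   `degenerate`.
#' @export
calibrate_skew <- function(targets, family = c("geometric", "lognormal"),
                           n_taxa) {
  family <- match.arg(family)
  if (length(targets) < 1 || length(targets) > 2)
    stop_domain("1 or 2 targets required")
  cuts <- vapply(targets, `[`, numeric(1), 1)
  shares <- vapply(targets, `[`, numeric(1), 2)
  if (any(cuts < 1 | cuts > n_taxa))
    stop_domain("cutoffs must lie in [1, n_taxa]")
  degenerate <- any(cuts == n_taxa)
  achieved_at <- function(par) {
    a <- rank_abundance(family, n_taxa,
                        if (family == "geometric") list(theta = par)
                        else list(sigma = par))
    vapply(cuts, function(c1) cumulative_share(a, c1), numeric(1))
  }
  loss <- function(par) sum((achieved_at(par) - shares)^2)
  if (family == "geometric") {
    bounds <- c(1e-6, 1 - 1e-6)
    par <- if (length(targets) == 1 && !degenerate) {
      # share is strictly increasing in theta: invert by root finding
      g <- function(th) achieved_at(th)[1] - shares[1]
      if (g(bounds[1]) > 0 || g(bounds[2]) < 0)
        optimize(loss, bounds, tol = 1e-12)$minimum
      else uniroot(g, bounds, tol = 1e-12)$root
    } else optimize(loss, bounds, tol = 1e-12)$minimum
    params <- list(theta = par)
  } else {
    par <- optimize(loss, c(0.01, 10), tol = 1e-12)$minimum
    params <- list(sigma = par)
  }
  achieved <- achieved_at(par)
  residual <- max(abs(achieved - shares))
  list(family = family, params = params,
       achieved = setNames(achieved, paste0("top", cuts)),
       residual = residual,
       flagged = residual > 0.02 || degenerate, degenerate = degenerate)
}

#' Campaign configuration
#'
#' Study-design parameters of a simulated sampling campaign. Defaults are
#' the reference study conditions: 6 sites, 29 sampling sessions, the
#' four-medium panel, about 10 strain deposits per filtered sample,
#' per-medium logistic invasion parameters matched to the reported
#' overgrowth percentages at 40 h and 66 h (CH/SY fast, DR intermediate,
#' DG slow), colonies countable until 95% membrane overgrowth, and cascade
#' success probabilities giving a realistically high MS identification
#' rate.
#'
#' @param sites site codes.
#' @param n_sessions number of sampling sessions (>= 0).
#' @param media medium codes.
#' @param strains_per_sample_rate Poisson rate of strain deposits per
#'   filtered sample.
#' @param invasion_params named list per medium: `c(t50 = hours,
#'   rate = per hour)`.
#' @param countable_threshold percent membrane overgrowth beyond which new
#'   colonies are censored, in (0, 100].
#' @param cascade_probs per-stage success probabilities (see
#'   [run_cascade()]).
#' @param loss_prob probability a deposited strain dies before
#'   identification (recorded as `status = "lost"`).
#' @param catalogs list of [db_catalog()]s active for MS identification;
#'   `NULL` builds a default reference catalog holding the top 75% of taxon
#'   ranks (databases are biased towards common species).
#' @param seed integer seed of the campaign stream.
#' @param start_date date of the first session; sessions follow every
#'   `session_interval_days`.
#' @param session_interval_days days between sessions.
#' @param horizon incubation horizon in hours.
#' @return a `campaign_config` list.
#' @export
campaign_config <- function(sites = DEFAULT_SITES, n_sessions = 29L,
                            media = DEFAULT_MEDIA,
                            strains_per_sample_rate = 10,
                            invasion_params = list(
                              CH = c(t50 = 45.7, rate = 0.108),
                              DG = c(t50 = 67.6, rate = 0.126),
                              DR = c(t50 = 59.6, rate = 0.097),
                              SY = c(t50 = 45.7, rate = 0.108)),
                            countable_threshold = 95,
                            cascade_probs = list(ms_short = 0.7,
                                                 ms_long = 0.6,
                                                 seq_its = 0.8,
                                                 seq_nl = 0.75,
                                                 genus_frac = 0.025),
                            loss_prob = 0.04,
                            catalogs = NULL, seed = 1L,
                            start_date = as.Date("2020-06-01"),
                            session_interval_days = 18,
                            horizon = 168) {
  if (n_sessions < 0) stop_domain("n_sessions must be >= 0")
  if (strains_per_sample_rate < 0) stop_domain("rate must be >= 0")
  if (countable_threshold <= 0 || countable_threshold > 100)
    stop_domain("countable_threshold must be in (0, 100]")
  missing_m <- setdiff(media, names(invasion_params))
  if (length(missing_m) > 0)
    stop_domain("invasion_params missing for media: ",
                paste(missing_m, collapse = ", "))
  structure(list(sites = sites, n_sessions = as.integer(n_sessions),
                 media = canonical_media(media),
                 strains_per_sample_rate = strains_per_sample_rate,
                 invasion_params = invasion_params,
                 countable_threshold = countable_threshold,
                 cascade_probs = cascade_probs, loss_prob = loss_prob,
                 catalogs = catalogs, seed = as.integer(seed),
                 start_date = as.Date(start_date),
                 session_interval_days = session_interval_days,
                 horizon = horizon),
            class = "campaign_config")
}

#' Simulate a sampling campaign
#'
#' For every session x site, a Poisson number of strains is deposited on
#' the membranes; each strain draws a taxon from the community's abundances
#' and a colony-emergence time. On each medium of the panel the strain
#' yields an isolate when an independent detection draw succeeds AND the
#' colony emerges inside the medium's usable window (the time at which the
#' medium's logistic invasion curve crosses the countable threshold,
#' clipped to the horizon). Produced isolates are then pushed through the
#' identification cascade (or recorded as lost strains). Fully reproducible
#' from `config$seed`; the physical campaign and the cascade use separate
#' seed phases (`seed`, `seed + 1`).
#'
#' @param model a [build_community()] model.
#' @param config a [campaign_config()].
#' @return an isolate record data.frame (see [read_isolate_table()] for
#'   the columns), with attribute `n_samples` (sessions x sites).
#' @export
simulate_campaign <- function(model, config) {
  media <- config$media
  if (!all(media %in% model$media))
    stop_domain("config media absent from the community model")
  windows <- vapply(media, function(m) {
    p <- config$invasion_params[[m]]
    w <- if (config$countable_threshold == 100) Inf
         else p["t50"] - log(100 / config$countable_threshold - 1) / p["rate"]
    min(max(w, 0), config$horizon)
  }, numeric(1))

  empty <- data.frame(isolate_id = character(0), sample_id = character(0),
                      site = character(0), date = as.Date(character(0)),
                      medium = character(0), strain_id = character(0),
                      taxon = character(0), rank = character(0),
                      method = character(0), status = character(0),
                      stringsAsFactors = FALSE)
  if (config$n_sessions == 0 || length(config$sites) == 0) {
    attr(empty, "n_samples") <- 0L
    return(empty)
  }

  # phase 1: the physical campaign (deposits, emergence, detection, loss)
  set.seed(config$seed)
  dep <- list(); strain_no <- 0L
  for (session in seq_len(config$n_sessions)) {
    date <- config$start_date +
      (session - 1) * config$session_interval_days
    for (site in config$sites) {
      sample_id <- sprintf("S%02d-%s", session, site)
      n_dep <- rpois(1, config$strains_per_sample_rate)
      if (n_dep == 0) next
      for (d in seq_len(n_dep)) {
        strain_no <- strain_no + 1L
        taxon_i <- sample.int(model$n_taxa, 1, prob = model$abundance)
        emerge <- rlnorm(1, model$emergence$meanlog, model$emergence$sdlog)
        lost <- runif(1) < config$loss_prob
        det <- runif(length(media))
        produced <- det < model$detection[taxon_i, media] &
          emerge < windows
        if (!any(produced)) next
        dep[[length(dep) + 1L]] <- list(
          sample_id = sample_id, site = site, date = date,
          strain_id = sprintf("ST%05d", strain_no),
          taxon_i = taxon_i, lost = lost, media = media[produced])
      }
    }
  }
  if (length(dep) == 0) {
    attr(empty, "n_samples") <- length(config$sites) * config$n_sessions
    return(empty)
  }

  # phase 2: identification cascade over produced isolates
  set.seed(config$seed + 1L)
  catalogs <- config$catalogs
  if (is.null(catalogs))
    catalogs <- list(db_catalog(
      "reference", model$taxa[seq_len(max(1, ceiling(0.75 * model$n_taxa)))],
      snapshot = "default"))
  rows <- vector("list", sum(vapply(dep, function(d) length(d$media),
                                    integer(1))))
  iso_no <- 0L
  for (d in dep) {
    truth <- model$taxa[d$taxon_i]
    for (m in d$media) {
      iso_no <- iso_no + 1L
      if (d$lost) {
        out <- list(method = "none", rank = "none", status = "lost")
        taxon <- ""
      } else {
        out <- run_cascade(truth, catalogs, config$cascade_probs)
        taxon <- switch(out$rank,
                        species = truth,
                        genus = sub("^(\\S+).*", "\\1 sp.", truth),
                        "")
      }
      rows[[iso_no]] <- data.frame(
        isolate_id = sprintf("I%06d", iso_no), sample_id = d$sample_id,
        site = d$site, date = d$date, medium = m,
        strain_id = d$strain_id, taxon = taxon, rank = out$rank,
        method = out$method, status = out$status, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "n_samples") <- length(config$sites) * config$n_sessions
  res
}
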