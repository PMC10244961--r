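# Synthetic landscapes, occupancy dynamics and opportunistic recording with
# known ground truth. The generator emulates the data-generating process the
# occupancy-detection model assumes: latent Bernoulli occupancy per site and
# year with region-specific logit-linear trends and site random effects, and
# presence-only recording whose detection probability depends on the visit's
# list-length category.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults describe the reference simulation scenario used throughout the
#' package's validation: three cropland regions of 60 one-kilometre sites
#' each followed for 20 years, 15 focal species, true annual occupancy
#' growth of -5%% in the high-, -2%% in the low- and 0%% in the no-cropland
#' region.
#'
#' @param n_sites named integer vector of sites per region.
#' @param n_species number of focal species.
#' @param first_year,last_year study window (inclusive).
#' @param psi0 named vector of initial mean occupancy per region.
#' @param growth named vector of true annual occupancy growth (%% per year)
#'   per region.
#' @param sigma_u standard deviation of the site random effect (logit scale).
#' @param species_sd standard deviation of species-level offsets added to
#'   the shared regional year-effect trajectory (logit scale).
#' @param p_single detection probability on a single-species list.
#' @param beta1,beta2 logit-scale detection offsets for short (2-3 species)
#'   and long (4+) lists.
#' @param visit_rate mean visits per site and year (Poisson).
#' @param list_probs probabilities of the `single`/`short`/`long` list
#'   categories per visit.
#' @param n_fillers size of the non-focal ("filler") species pool used to
#'   pad recorded lists to their assigned length.
#' @param n_violation_change,n_violation_class extra landscape cells built
#'   to violate the cropland-change / incomparable-class filters.
#' @param seed mandatory integer seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = c(high = 60, low = 60, none = 60),
                            n_species = 15,
                            first_year = 1990, last_year = 2009,
                            psi0 = c(high = 0.4, low = 0.4, none = 0.4),
                            growth = c(high = -5, low = -2, none = 0),
                            sigma_u = 0.5,
                            species_sd = 0.5,
                            p_single = 0.25,
                            beta1 = 0.7, beta2 = 1.4,
                            visit_rate = 3,
                            list_probs = c(single = 0.3, short = 0.4,
                                           long = 0.3),
                            n_fillers = 30,
                            n_violation_change = 0,
                            n_violation_class = 0,
                            seed) {
  if (missing(seed)) stop("a seed is mandatory for scenario generation")
  stopifnot(all(psi0 > 0), all(psi0 < 1), all(growth > -100),
            p_single > 0, p_single < 1, visit_rate > 0,
            abs(sum(list_probs) - 1) < 1e-8, last_year > first_year,
            identical(names(n_sites), names(psi0)),
            identical(names(n_sites), names(growth)))
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate a synthetic landscape of classified 1 km cells
#'
#' Emits a two-epoch long-format cover table whose [classify_sites()] output
#' reproduces the requested per-region cell counts, plus (optionally) cells
#' deliberately violating the change and incomparable-class filters.
#'
#' @param cfg a [scenario_config()].
#' @return list with `cover` (long table `site,epoch,class,percent`) and
#'   `sites` (data.frame `site`, `region` of the valid cells).
#' @export
gen_landscape <- function(cfg) {
  set.seed(cfg$seed + 1L)
  regions <- names(cfg$n_sites)
  n_total <- sum(cfg$n_sites) + cfg$n_violation_change +
    cfg$n_violation_class
  side <- ceiling(sqrt(n_total))
  ids <- sprintf("%d_%d", rep(seq_len(side), each = side),
                 rep(seq_len(side), side))[seq_len(n_total)]
  region <- c(rep(regions, times = cfg$n_sites),
              rep("viol_change", cfg$n_violation_change),
              rep("viol_class", cfg$n_violation_class))

  crop_late <- numeric(n_total)
  crop_late[region == "high"] <- stats::runif(sum(region == "high"), 51, 95)
  crop_late[region == "low"] <- stats::runif(sum(region == "low"), 1, 50)
  crop_late[region == "none"] <- 0
  crop_late[region == "viol_change"] <-
    stats::runif(cfg$n_violation_change, 30, 60)
  crop_late[region == "viol_class"] <-
    stats::runif(cfg$n_violation_class, 1, 40)
  crop_early <- pmin(100, pmax(0, crop_late +
                                 stats::runif(n_total, -8, 8)))
  crop_early[region == "none"] <- 0
  crop_early[region == "viol_change"] <-
    pmax(0, crop_late[region == "viol_change"] - 20)

  wetland <- stats::runif(n_total, 0, 8)
  wetland[region == "viol_class"] <- stats::runif(cfg$n_violation_class,
                                                  30, 45)
  built_up <- stats::runif(n_total, 0, 5)
  other <- stats::runif(n_total, 0, 3)
  rest <- pmax(0, 100 - crop_late - wetland - built_up - other)
  grass_frac <- stats::runif(n_total, 0.3, 0.7)

  mk <- function(epoch, crop) {
    rest_e <- pmax(0, 100 - crop - wetland - built_up - other)
    data.frame(
      site = rep(ids, 6),
      epoch = epoch,
      class = rep(c("cropland", "grassland", "woodland", "wetland",
                    "built_up", "other"), each = n_total),
      percent = c(crop, rest_e * grass_frac, rest_e * (1 - grass_frac),
                  wetland, built_up, other),
      stringsAsFactors = FALSE)
  }
  cover <- rbind(mk("early", crop_early), mk("late", crop_late))
  cover <- cover[order(cover$site, cover$epoch, cover$class), ]
  rownames(cover) <- NULL
  valid <- region %in% regions
  list(cover = cover,
       sites = data.frame(site = ids[valid], region = region[valid],
                          stringsAsFactors = FALSE))
}

solve_year_effect <- function(target, sigma_u) {
  # b such that E over u~N(0,sigma_u^2) of plogis(b + u) equals target
  if (sigma_u == 0) return(stats::qlogis(target))
  f <- function(b) {
    stats::integrate(function(x) stats::plogis(b + x) *
                       stats::dnorm(x, 0, sigma_u),
                     lower = -10 * sigma_u, upper = 10 * sigma_u,
                     rel.tol = 1e-10)$value - target
  }
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}

#' Generate latent occupancy dynamics with known ground truth
#'
#' Solves the regional year-effect trajectories so that mean occupancy (the
#' average of inverse-logit state over the site-effect distribution) follows
#' the requested geometric growth, adds species-level offsets, draws site
#' effects and latent occupancy states, and records everything in a truth
#' ledger.
#'
#' @param cfg a [scenario_config()].
#' @param sites data.frame `site`, `region` (from [gen_landscape()]); when
#'   omitted a minimal landscape is generated internally.
#' @return list of class `truth_ledger`: `b` (species x regions x years),
#'   `u` (sites x species), `z` (sites x years x species), `psi_expected`
#'   (species x regions x years target mean occupancy), `occ_true`
#'   (species x regions x years realised occupancy = mean of z), `sites`,
#'   `species`, `region_levels`, `years`.
#' @export
gen_dynamics <- function(cfg, sites = NULL) {
  if (is.null(sites)) sites <- gen_landscape(cfg)$sites
  set.seed(cfg$seed + 2L)
  regions <- names(cfg$n_sites)
  years <- cfg$first_year:cfg$last_year
  Tn <- length(years)
  mult <- 1 + cfg$growth / 100
  sp <- sprintf("sp_%02d", seq_len(cfg$n_species))
  offsets <- stats::rnorm(cfg$n_species, 0, cfg$species_sd)
  # every species shares the region's relative (geometric) trajectory but
  # starts from its own offset baseline, so the configured growth rate is
  # also the exact group-level geometric-mean growth
  path <- array(NA_real_, c(cfg$n_species, length(regions), Tn),
                dimnames = list(sp, regions, years))
  growth_curve <- outer(mult, seq_len(Tn) - 1L, `^`)   # regions x years
  for (s in seq_len(cfg$n_species)) {
    psi0_s <- stats::plogis(stats::qlogis(cfg$psi0) + offsets[s])
    path[s, , ] <- psi0_s * growth_curve
  }
  if (any(path <= 0) || any(path >= 1)) {
    stop("requested growth drives mean occupancy outside (0, 1)")
  }
  b <- array(NA_real_, dim(path), dimnames = dimnames(path))
  for (s in seq_len(cfg$n_species)) {
    for (r in seq_along(regions)) {
      for (t in seq_len(Tn)) {
        b[s, r, t] <- solve_year_effect(path[s, r, t], cfg$sigma_u)
      }
    }
  }

  n <- nrow(sites)
  reg_i <- match(sites$region, regions)
  u <- matrix(stats::rnorm(n * cfg$n_species, 0, cfg$sigma_u), n,
              dimnames = list(sites$site, sp))
  z <- array(0L, c(n, Tn, cfg$n_species),
             dimnames = list(sites$site, years, sp))
  occ_true <- array(NA_real_, c(cfg$n_species, length(regions), Tn),
                    dimnames = list(sp, regions, years))
  for (s in seq_len(cfg$n_species)) {
    psi <- stats::plogis(matrix(b[s, reg_i, ], n, Tn) + u[, s])
    z[, , s] <- stats::rbinom(n * Tn, 1L, psi)
    for (r in seq_along(regions)) {
      occ_true[s, r, ] <- colMeans(z[reg_i == r, , s, drop = FALSE])
    }
  }
  structure(list(b = b, u = u, z = z,
                 psi_expected = path, occ_true = occ_true,
                 sites = sites, species = sp, region_levels = regions,
                 years = years, species_offsets = offsets),
            class = "truth_ledger")
}

#' Generate presence-only occurrence records from a truth ledger
#'
#' For every site and year a Poisson number of recording visits is drawn on
#' distinct dates; each visit is assigned a list-length category from the
#' configured distribution and a concrete list length. Focal species that
#' are present (z = 1) are detected with the category-dependent probability
#' and written as presence-only records; non-detections are never written.
#' Non-focal "filler" species records pad the list to its assigned length,
#' so the visit exists in the output even when no focal species was detected
#' (as in real opportunistic recording, where a visit is observable only
#' through what was recorded) and the target-group approach can infer
#' non-detections from it.
#'
#' @param truth a `truth_ledger` from [gen_dynamics()].
#' @param cfg the same [scenario_config()].
#' @return data.frame of records: `species`, `group`, `site`, `date`,
#'   `spatial_precision_m`, `temporal_precision`.
#' @export
gen_records <- function(truth, cfg) {
  set.seed(cfg$seed + 3L)
  n <- nrow(truth$sites)
  Tn <- length(truth$years)
  a_base <- stats::qlogis(cfg$p_single)
  p_cat <- stats::plogis(a_base + c(single = 0, short = cfg$beta1,
                                    long = cfg$beta2))
  fillers <- sprintf("filler_%02d", seq_len(cfg$n_fillers))

  nv <- matrix(stats::rpois(n * Tn, cfg$visit_rate), n, Tn)
  sp_l <- list(); site_l <- list(); date_l <- list(); cat_l <- list()
  j <- 0L
  for (i in seq_len(n)) {
    for (t in seq_len(Tn)) {
      m <- min(nv[i, t], 300L)
      if (m == 0L) next
      days <- sample.int(365, m)
      dates <- as.Date(sprintf("%d-01-01", truth$years[t])) + days - 1L
      cat_i <- sample.int(3L, m, replace = TRUE, prob = cfg$list_probs)
      L <- ifelse(cat_i == 1L, 1L,
                  ifelse(cat_i == 2L, sample(2:3, m, replace = TRUE),
                         sample(4:6, m, replace = TRUE)))
      present <- which(truth$z[i, t, ] == 1L)
      for (v in seq_len(m)) {
        det <- present[stats::runif(length(present)) < p_cat[cat_i[v]]]
        sp_det <- truth$species[det]
        pad <- max(0L, L[v] - length(sp_det))
        if (pad > 0L) {
          sp_det <- c(sp_det, sample(fillers, min(pad, cfg$n_fillers)))
        }
        j <- j + 1L
        sp_l[[j]] <- sp_det
        site_l[[j]] <- truth$sites$site[i]
        date_l[[j]] <- dates[v]
        cat_l[[j]] <- cat_i[v]
      }
    }
  }
  nrec <- lengths(sp_l)
  out <- data.frame(
    species = unlist(sp_l, use.names = FALSE),
    group = "synthgroup",
    site = rep(unlist(site_l, use.names = FALSE), nrec),
    date = rep(do.call(c, date_l), nrec),
    spatial_precision_m = 1000L,
    temporal_precision = "day",
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  # visit-level truth: the effort category that drove detection, part of
  # the ground-truth ledger for validation
  attr(out, "visit_truth") <- data.frame(
    site = rep(unlist(site_l, use.names = FALSE), 1L),
    date = do.call(c, date_l),
    datatype_assigned = c("single", "short", "long")[
      unlist(cat_l, use.names = FALSE)],
    stringsAsFactors = FALSE)
  out
}

#' Generate a complete synthetic scenario
#'
#' Runs [gen_landscape()], [gen_dynamics()] and [gen_records()] and
#' optionally writes the records table, cover table and truth ledger to an
#' output directory as plain-text files.
#'
#' @param cfg a [scenario_config()].
#' @param dir optional output directory.
#' @return list with `records`, `cover`, `sites`, `truth`, `config`.
#' @export
simulate_scenario <- function(cfg, dir = NULL) {
  land <- gen_landscape(cfg)
  truth <- gen_dynamics(cfg, land$sites)
  records <- gen_records(truth, cfg)
  out <- list(records = records, cover = land$cover, sites = land$sites,
              truth = truth, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(land$cover, file.path(dir, "cover.csv"),
                     row.names = FALSE)
    occ <- as.data.frame.table(truth$occ_true, stringsAsFactors = FALSE)
    names(occ) <- c("species", "region", "year", "occupancy")
    utils::write.csv(occ, file.path(dir, "truth_occupancy.csv"),
                     row.names = FALSE)
  }
  out
}

#' True group-level growth rates and effect size of a scenario
#'
#' Recomputes the quantities the pipeline estimates in two forms: the
#' generating ("expected") truth, i.e. the growth of the group geometric
#' mean of the species' expected occupancy paths — by construction equal to
#' the configured regional growth rates — and the realised finite-sample
#' version computed from the latent states actually drawn, which fluctuates
#' around the generating truth with the binomial noise of the site sample.
#' Credible-interval coverage is assessed against the generating truth (the
#' parameter of the data-generating process); the realised values document
#' one particular draw.
#'
#' @param truth a `truth_ledger`.
#' @return list with `group_growth` (realised, named per region, % per
#'   year), `group_growth_expected` (generating truth),
#'   `effect_size_high_low` and `effect_size_high_low_expected`.
#' @export
true_group_growth <- function(truth) {
  Tn <- length(truth$years)
  y <- Tn - 1L
  regions <- truth$region_levels
  gg <- vapply(seq_along(regions), function(r) {
    s <- geometric_mean(truth$occ_true[, r, 1L],
                        floor_at = 1 / (2 * sum(truth$sites$region ==
                                                  regions[r])))
    f <- geometric_mean(truth$occ_true[, r, Tn],
                        floor_at = 1 / (2 * sum(truth$sites$region ==
                                                  regions[r])))
    growth_rate(s, f, y)
  }, numeric(1))
  names(gg) <- regions
  gge <- vapply(seq_along(regions), function(r) {
    s <- geometric_mean(truth$psi_expected[, r, 1L])
    f <- geometric_mean(truth$psi_expected[, r, Tn])
    growth_rate(s, f, y)
  }, numeric(1))
  names(gge) <- regions
  es <- es_e <- NA_real_
  if (all(c("high", "low") %in% regions)) {
    es <- gg[["high"]] - gg[["low"]]
    es_e <- gge[["high"]] - gge[["low"]]
  }
  list(group_growth = gg, group_growth_expected = gge,
       effect_size_high_low = es, effect_size_high_low_expected = es_e)
}
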