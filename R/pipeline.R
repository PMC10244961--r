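# End-to-end orchestration: cleaning -> visits -> stratification ->
# per-species occupancy model fits -> convergence report -> multi-species
# indicators, with a machine-readable run report.

#' Default run configuration
#'
#' Returns the full configuration tree with package defaults; values can be
#' overridden by a named list or loaded from a YAML file with
#' [read_run_config()].
#'
#' @param ... named overrides of top-level entries (partial lists are merged
#'   into the defaults).
#' @return nested list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    first_year = 1990,
    last_year = 2019,
    cleaning = list(max_precision_m = 1000,
                    exclude_species = character(),
                    aggregate_map = character()),
    stratify = list(change_threshold = 10,
                    incomparable_threshold = 25,
                    incomparable_classes = c("wetland", "built_up", "other")),
    rule_of_thumb = list(min_records = 50, min_sites = 10, min_years = 5),
    mcmc = list(chains = 3, iterations = 32000, burnin = 30000, thin = 6),
    convergence = list(threshold = 1.1, apply_filter = FALSE),
    indicators = list(n_draws = 999, hdi_mass = 0.95),
    seed = 1)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; keys mirror [run_config()].
#' @return `run_config` list (file values merged over defaults).
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Join visits to site classifications
#'
#' Attaches region labels to visits and drops (with a message) visits at
#' sites excluded by the stratification filters. Visits at sites absent from
#' the classification table are an error.
#'
#' @param visits output of [build_visits()].
#' @param classifications output of [classify_sites()] (or any data.frame
#'   with `site` and `region`).
#' @return visits with a `region` column; excluded-site visits removed.
#' @export
species_visit_join <- function(visits, classifications) {
  reg <- stats::setNames(as.character(classifications$region),
                         classifications$site)
  hit <- reg[visits$site]
  if (anyNA(hit)) {
    bad <- unique(visits$site[is.na(hit)])
    stop("unclassified site(s) in visits: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  drop <- hit == "excluded"
  if (any(drop)) {
    message(sum(drop), " visits at ", length(unique(visits$site[drop])),
            " excluded sites dropped")
  }
  out <- visits[!drop, , drop = FALSE]
  out$region <- unname(hit[!drop])
  rownames(out) <- NULL
  out
}

species_seed <- function(master_seed, species) {
  # deterministic per-species seed independent of fitting order
  h <- sum(utf8ToInt(species) * seq_along(utf8ToInt(species)))
  as.integer((as.numeric(master_seed) * 1009 + h) %% 2147483587)
}

#' Run the full occupancy-trend pipeline
#'
#' Executes record cleaning, visit construction, land-cover stratification,
#' the per-species rule-of-thumb filter, independent per-species model fits
#' (seeded deterministically from the master seed and the species name, so
#' results do not depend on fitting order), the convergence report, and the
#' multi-species indicators: geometric-mean occupancy indices, annual growth
#' rates per region and the high-minus-low effect size, all propagated
#' draw-wise.
#'
#' @param records raw records data.frame (or path to a records CSV).
#' @param cover long-format cover table (or path to a cover CSV).
#' @param config a [run_config()].
#' @param species optional subset of species to fit (default: all that pass
#'   the rule-of-thumb filter).
#' @param output optional directory; when given, stage tables and a
#'   `report.json` are written.
#' @return list of class `occ_run`: `classifications`, `visits`,
#'   `species_fits` (per species `occ_draws`), `convergence`, `indicators`
#'   (per-region index/growth summaries, effect size), and `report`.
#' @export
run_pipeline <- function(records, cover, config = run_config(),
                         species = NULL, output = NULL) {
  if (is.character(records)) records <- read_records(records)
  if (is.character(cover)) cover <- utils::read.csv(cover,
                                                    stringsAsFactors = FALSE)
  report <- list(seed = config$seed)

  ## stage 1: clean ----------------------------------------------------
  cleaned <- standardize_records(
    records, config$first_year, config$last_year,
    exclude_species = config$cleaning$exclude_species,
    aggregate_map = config$cleaning$aggregate_map,
    max_precision_m = config$cleaning$max_precision_m)
  report$n_records_raw <- nrow(records)
  report$n_records_clean <- nrow(cleaned)
  report$cleaning_log <- cleaning_log(cleaned)
  report$n_species_clean <- length(unique(cleaned$species))

  ## stage 2: stratify -------------------------------------------------
  cls <- classify_sites(
    cover,
    change_threshold = config$stratify$change_threshold,
    incomparable_classes = config$stratify$incomparable_classes,
    incomparable_threshold = config$stratify$incomparable_threshold)
  report$region_summary <- region_summary(cls)
  report$n_sites_excluded <- sum(cls$region == "excluded")

  ## stage 3: visits + join --------------------------------------------
  visits <- build_visits(cleaned, config$first_year)
  visits <- species_visit_join(visits, cls)
  n_years <- config$last_year - config$first_year + 1
  report$n_visits <- nrow(visits)

  ## stage 4: rule-of-thumb filter -------------------------------------
  sums <- species_summaries(cleaned[cleaned$site %in% visits$site, ,
                                    drop = FALSE])
  rot <- rule_of_thumb_filter(sums,
                              min_records = config$rule_of_thumb$min_records,
                              min_sites = config$rule_of_thumb$min_sites,
                              min_years = config$rule_of_thumb$min_years)
  fit_species <- rot$species[rot$retained]
  if (!is.null(species)) fit_species <- intersect(fit_species, species)
  report$n_species_rule_of_thumb <- length(fit_species)
  if (length(fit_species) == 0L) stop("no species pass the filters")

  ## stage 5: per-species fits -----------------------------------------
  site_regions <- cls[cls$region != "excluded", c("site", "region")]
  fits <- list()
  conv <- data.frame(species = character(), rhat_first = numeric(),
                     rhat_last = numeric())
  for (sp in fit_species) {
    hist <- detection_history(visits, sp)
    md <- occ_model_data(hist, site_regions, n_years = n_years)
    dr <- sample_posterior(
      md, chains = config$mcmc$chains,
      iterations = config$mcmc$iterations,
      burnin = config$mcmc$burnin, thin = config$mcmc$thin,
      seed = species_seed(config$seed, sp))
    fits[[sp]] <- dr
    rep_sp <- convergence_report(dr, config$convergence$threshold)
    occ_rh <- rep_sp[grepl("^occ\\[", rep_sp$quantity), ]
    first_rh <- occ_rh$rhat[grepl("first", occ_rh$quantity)]
    last_rh <- occ_rh$rhat[grepl("last", occ_rh$quantity)]
    conv <- rbind(conv, data.frame(
      species = sp,
      rhat_first = if (all(is.na(first_rh))) NA_real_ else
        max(first_rh, na.rm = TRUE),
      rhat_last = if (all(is.na(last_rh))) NA_real_ else
        max(last_rh, na.rm = TRUE)))
  }

  ## stage 6: convergence filter ---------------------------------------
  cf <- convergence_filter(conv, config$convergence$threshold)
  keep <- if (isTRUE(config$convergence$apply_filter)) {
    cf$species[cf$retained]
  } else fit_species
  report$n_species_converged <- sum(cf$retained)
  report$n_species_indicator <- length(keep)
  if (length(keep) == 0L) stop("no species retained after convergence filter")

  ## stage 7: indicators -----------------------------------------------
  ind <- compute_indicators(fits[keep], n_draws = config$indicators$n_draws,
                            hdi_mass = config$indicators$hdi_mass,
                            seed = config$seed,
                            first_year = config$first_year)
  report$indicators <- ind$summary
  if (!is.null(ind$effect_size)) {
    report$effect_size_high_low <- list(
      median = ind$effect_size$median,
      hdi = unname(ind$effect_size$hdi),
      prob_below_zero = ind$effect_size$prob_below_zero)
  }

  out <- list(classifications = cls, visits = visits, species_fits = fits,
              convergence = cf, convergence_rhats = conv, indicators = ind,
              report = report, config = config)
  class(out) <- "occ_run"
  if (!is.null(output)) write_run(out, output)
  out
}

#' Derive multi-species indicators from a set of fitted species
#'
#' Aligns per-species posterior occupancy draws (subsampling each species'
#' chains to a common draw count), computes the geometric-mean occupancy
#' index per region and year, per-region group growth rates between the
#' first and last year, and the high-minus-low effect size, each with
#' draw-wise medians and HDIs.
#'
#' @param fits named list of `occ_draws` (one per species) over the same
#'   regions and years.
#' @param n_draws number of aligned posterior draws used for the derived
#'   parameters (default 999).
#' @param hdi_mass credible mass of the reported intervals.
#' @param seed seed for the draw subsampling.
#' @param first_year first calendar year (for labelling).
#' @return list: `psi` (draws x species x regions x years), `index` (draws x
#'   regions x years), `growth` (draws x regions, % per year),
#'   `effect_size` (when both `high` and `low` regions are present),
#'   `summary` (long data.frame of medians and HDIs).
#' @export
compute_indicators <- function(fits, n_draws = 999, hdi_mass = 0.95,
                               seed = 1, first_year = NULL) {
  stopifnot(length(fits) >= 1L)
  regions <- fits[[1L]]$region_levels
  Tn <- fits[[1L]]$n_years
  for (f in fits) {
    if (!identical(f$region_levels, regions) || f$n_years != Tn) {
      stop("species fits cover different regions or years")
    }
  }
  set.seed(seed)
  nsp <- length(fits)
  psi <- array(NA_real_, c(n_draws, nsp, length(regions), Tn),
               dimnames = list(NULL, names(fits), regions, NULL))
  for (s in seq_len(nsp)) {
    S <- length(fits[[s]]$chain)
    idx <- if (S >= n_draws) sample.int(S, n_draws) else
      sample.int(S, n_draws, replace = TRUE)
    psi[, s, , ] <- fits[[s]]$occ[idx, , , drop = FALSE]
  }
  nsr <- fits[[1L]]$n_sites_region
  index <- occupancy_index(psi, n_sites_region = nsr)

  y <- Tn - 1L
  growth <- matrix(NA_real_, n_draws, length(regions),
                   dimnames = list(NULL, regions))
  for (r in seq_along(regions)) {
    gr_sp <- matrix(NA_real_, n_draws, nsp)
    fl <- 1 / (2 * nsr[r])
    for (s in seq_len(nsp)) {
      s0 <- pmax(psi[, s, r, 1L], fl)
      f0 <- pmax(psi[, s, r, Tn], fl)
      gr_sp[, s] <- growth_rate(s0, f0, y)
    }
    growth[, r] <- multi_species_growth(gr_sp)
  }

  es <- if (all(c("high", "low") %in% regions)) {
    effect_size(growth[, "high"], growth[, "low"], mass = hdi_mass)
  } else NULL

  summ <- do.call(rbind, lapply(seq_along(regions), function(r) {
    cbind(data.frame(quantity = "group_growth", region = regions[r]),
          summarise_draws(growth[, r], hdi_mass))
  }))
  if (!is.null(es)) {
    summ <- rbind(summ, cbind(
      data.frame(quantity = "effect_size_high_low", region = "high-low"),
      summarise_draws(es$draws, hdi_mass)))
  }
  list(psi = psi, index = index, growth = growth, effect_size = es,
       summary = summ, first_year = first_year)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$classifications,
                   file.path(dir, "classifications.csv"), row.names = FALSE)
  v <- run$visits
  v$species <- NULL
  utils::write.csv(v, file.path(dir, "visits.csv"), row.names = FALSE)
  utils::write.csv(run$indicators$summary,
                   file.path(dir, "indicator_summary.csv"),
                   row.names = FALSE)
  gr <- as.data.frame.table(run$indicators$growth,
                            stringsAsFactors = FALSE)
  names(gr) <- c("draw", "region", "growth_rate")
  gr$draw <- as.integer(factor(gr$draw, levels = unique(gr$draw)))
  utils::write.csv(gr, file.path(dir, "growth_draws.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(dir)
}

#' @export
print.occ_run <- function(x, ...) {
  r <- x$report
  cat("occupancy-trend run:", r$n_records_clean, "cleaned records,",
      r$n_visits, "visits,", r$n_species_indicator, "species in indicators\n")
  print(r$indicators, row.names = FALSE)
  invisible(x)
}
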