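#' Read an occurrence-record table
#'
#' Reads comma-separated presence-only records with the canonical header
#' `species,group,site,date,spatial_precision_m,temporal_precision`.
#' Dates are ISO-8601 (`YYYY-MM-DD`); rows whose date fails to parse are kept
#' here (with `NA` date) and rejected, with a log entry, by
#' [standardize_records()].
#'
#' @param path path to a CSV file.
#' @return a data.frame of raw records.
#' @export
read_records <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species", "group", "site", "date",
              "spatial_precision_m", "temporal_precision")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stop("records file lacks column(s): ", paste(missing, collapse = ", "))
  }
  raw$date <- as.Date(raw$date, format = "%Y-%m-%d")
  raw
}

#' Clean raw occurrence records
#'
#' Standardises presence-only records to the minimum precision required for
#' visit-based occupancy modelling: 1 km spatial precision, daily dates inside
#' the study window, species-level identifications only. Optionally relabels
#' species to configured aggregates (taxonomic changes over the study period)
#' before filtering, drops species on an exclusion list, and collapses exact
#' duplicates (same species, site and date). Counts dropped per rule are
#' attached as the `"cleaning_log"` attribute (see [cleaning_log()]).
#'
#' Cleaning is idempotent: re-applying it to its own output changes nothing.
#'
#' @param records data.frame with columns `species`, `group`, `site`, `date`
#'   (`Date` or ISO-8601 string), `spatial_precision_m`, `temporal_precision`.
#'   An optional logical column `species_level` marks rows identified to
#'   species level (default: all `TRUE`).
#' @param first_year,last_year study window; records dated outside
#'   `[first_year, last_year]` are dropped.
#' @param groups character vector of recognised taxon groups. Records with a
#'   group outside this set raise an error (they indicate a mis-assembled
#'   input, not noise).
#' @param exclude_species species dropped outright (e.g. a rapidly invading
#'   alien whose trend reflects invasion, not habitat management).
#' @param aggregate_map named character vector mapping raw species names to
#'   aggregate names; applied before all filters. Default empty.
#' @param max_precision_m maximum allowed spatial precision in metres
#'   (default 1000 = 1 km grid cell).
#' @return the cleaned data.frame, ordered as received, with attribute
#'   `"cleaning_log"` (a data.frame of `rule`, `n_dropped`).
#' @export
standardize_records <- function(records, first_year, last_year,
                                groups = NULL,
                                exclude_species = character(),
                                aggregate_map = character(),
                                max_precision_m = 1000) {
  stopifnot(is.data.frame(records), first_year <= last_year)
  if (!inherits(records$date, "Date")) {
    records$date <- as.Date(as.character(records$date), format = "%Y-%m-%d")
  }
  if (!is.null(groups)) {
    bad <- setdiff(unique(records$group), groups)
    if (length(bad) > 0L) {
      stop("unknown taxon group(s): ", paste(bad, collapse = ", "))
    }
  }
  if (length(aggregate_map) > 0L) {
    hit <- records$species %in% names(aggregate_map)
    records$species[hit] <- unname(aggregate_map[records$species[hit]])
  }

  log <- list()
  drop_rule <- function(df, keep, rule) {
    keep[is.na(keep)] <- FALSE
    log[[rule]] <<- sum(!keep)
    df[keep, , drop = FALSE]
  }

  records <- drop_rule(records, !is.na(records$date), "unparseable_date")
  records <- drop_rule(records,
                       records$spatial_precision_m <= max_precision_m,
                       "coarse_spatial_precision")
  records <- drop_rule(records, records$temporal_precision == "day",
                       "coarse_temporal_precision")
  yr <- as.integer(format(records$date, "%Y"))
  records <- drop_rule(records, yr >= first_year & yr <= last_year,
                       "outside_study_window")
  if ("species_level" %in% names(records)) {
    records <- drop_rule(records, as.logical(records$species_level),
                         "above_species_level")
    records$species_level <- NULL
  } else {
    log[["above_species_level"]] <- 0L
  }
  records <- drop_rule(records, !(records$species %in% exclude_species),
                       "excluded_species")
  dup <- duplicated(records[, c("species", "group", "site", "date")])
  records <- drop_rule(records, !dup, "duplicate_record")

  rownames(records) <- NULL
  attr(records, "cleaning_log") <- data.frame(
    rule = names(log), n_dropped = unlist(log, use.names = FALSE),
    row.names = NULL)
  records
}

#' Retrieve the cleaning log of a standardized record table
#' @param records output of [standardize_records()].
#' @return data.frame with columns `rule` and `n_dropped`.
#' @export
cleaning_log <- function(records) {
  lg <- attr(records, "cleaning_log")
  if (is.null(lg)) stop("no cleaning log: was standardize_records() applied?")
  lg
}

#' List-length category of a visit
#'
#' Recorder effort is proxied by the number of species recorded on a visit,
#' collapsed into three data-type categories: single-species lists, short
#' lists of 2-3 species and long lists of at least 4 species.
#'
#' @param list_length positive integer vector.
#' @return factor with levels `single`, `short`, `long`.
#' @export
datatype_of <- function(list_length) {
  if (any(is.na(list_length)) || any(list_length < 1) ||
      any(list_length != as.integer(list_length))) {
    stop("list_length must be a positive integer")
  }
  factor(ifelse(list_length == 1, "single",
                ifelse(list_length <= 3, "short", "long")),
         levels = c("single", "short", "long"))
}

#' Build visits from cleaned records of one taxon group
#'
#' A visit is a unique combination of 1 km site and calendar date. Each visit
#' carries the set of species detected (deduplicated), its list length and
#' list-length category, and a 0-based year index relative to `first_year`.
#'
#' @param records cleaned records (one taxon group).
#' @param first_year first year of the study window (year index origin).
#' @return data.frame with columns `site`, `date`, `year_index`,
#'   `list_length`, `datatype` and a list column `species` holding the
#'   detected-species set; sorted by site then date.
#' @export
build_visits <- function(records, first_year) {
  if (nrow(records) == 0L) {
    return(data.frame(site = character(), date = as.Date(character()),
                      year_index = integer(), list_length = integer(),
                      datatype = factor(character(),
                                        levels = c("single", "short", "long")),
                      species = I(list())))
  }
  if (length(unique(records$group)) > 1L) {
    stop("build_visits expects records of a single taxon group; got: ",
         paste(unique(records$group), collapse = ", "))
  }
  key <- paste(records$site, format(records$date, "%Y-%m-%d"), sep = "\r")
  sp <- lapply(split(records$species, key), function(s) sort(unique(s)))
  first <- !duplicated(key)
  out <- data.frame(site = records$site[first], date = records$date[first],
                    stringsAsFactors = FALSE)
  out <- out[order(out$site, out$date), , drop = FALSE]
  okey <- paste(out$site, format(out$date, "%Y-%m-%d"), sep = "\r")
  out$year_index <- as.integer(format(out$date, "%Y")) - as.integer(first_year)
  out$list_length <- lengths(sp)[okey]
  out$datatype <- datatype_of(out$list_length)
  out$species <- I(unname(sp[okey]))
  rownames(out) <- NULL
  out
}

#' Detection history of a focal species (target-group approach)
#'
#' Because records are presence-only, non-detections are inferred from visits
#' on which other species of the same taxon group were recorded: if a visit's
#' list does not include the focal species, the focal species is scored as
#' not detected (0) on that visit. Every visit of the group appears exactly
#' once.
#'
#' @param visits output of [build_visits()].
#' @param focal_species species identifier.
#' @return data.frame `site`, `date`, `year_index`, `list_length`,
#'   `datatype`, `detected` (0/1); one row per visit.
#' @export
detection_history <- function(visits, focal_species) {
  stopifnot(length(focal_species) == 1L)
  det <- vapply(visits$species, function(s) focal_species %in% s, logical(1))
  if (nrow(visits) > 0L && !any(det)) {
    warning("focal species '", focal_species,
            "' never detected: all-zero detection history")
  }
  out <- visits[, c("site", "date", "year_index", "list_length", "datatype")]
  out$detected <- as.integer(det)
  rownames(out) <- NULL
  out
}

#' Per-species record summaries for rule-of-thumb filtering
#'
#' @param records cleaned records of one taxon group.
#' @return data.frame `species`, `n_records`, `n_sites`, `n_years`.
#' @export
species_summaries <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(species = character(), n_records = integer(),
                      n_sites = integer(), n_years = integer()))
  }
  yr <- as.integer(format(records$date, "%Y"))
  agg <- function(x, f) vapply(split(x, records$species), f, integer(1))
  out <- data.frame(
    species = sort(unique(records$species)),
    stringsAsFactors = FALSE)
  out$n_records <- agg(records$species, length)[out$species]
  out$n_sites <- agg(records$site, function(s) length(unique(s)))[out$species]
  out$n_years <- vapply(split(yr, records$species),
                        function(y) length(unique(y)), integer(1))[out$species]
  rownames(out) <- NULL
  out
}
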