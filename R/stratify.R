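#' Aggregate fine-grid land-cover labels to cell percentages
#'
#' Computes the percentage cover of each land class within every 1 km cell
#' from a table of labelled subcells (e.g. 25 m pixels, 1600 per cell).
#'
#' @param subcells data.frame with columns `site` and `class`, one row per
#'   subcell, each carrying exactly one class label.
#' @param classes optional character vector of all class names; classes never
#'   observed in a cell get an explicit 0% row.
#' @return long-format data.frame `site`, `class`, `percent`.
#' @export
aggregate_cover <- function(subcells, classes = NULL) {
  stopifnot(is.data.frame(subcells),
            all(c("site", "class") %in% names(subcells)))
  if (nrow(subcells) == 0L) stop("no subcells supplied")
  if (is.null(classes)) classes <- sort(unique(as.character(subcells$class)))
  tab <- table(factor(subcells$site),
               factor(as.character(subcells$class), levels = classes))
  pct <- sweep(tab, 1L, rowSums(tab), "/") * 100
  out <- as.data.frame(as.table(pct), stringsAsFactors = FALSE)
  names(out) <- c("site", "class", "percent")
  out <- out[order(out$site, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stability and comparability exclusions for one cell
#'
#' A cell is excluded when cropland cover changed by more than
#' `change_threshold` percentage points between the two epochs
#' (`cover_change`), or when any of the land classes not directly comparable
#' with cropland (by default wetland, built-up areas and "other") exceeds
#' `incomparable_threshold`% in the late epoch (`incomparable_class`).
#'
#' @param early,late named numeric vectors of percentage cover per class for
#'   the early and late epoch of one cell.
#' @param change_threshold maximum tolerated absolute cropland change in
#'   percentage points (default 10).
#' @param incomparable_classes classes checked against
#'   `incomparable_threshold` (default `c("wetland", "built_up", "other")`).
#' @param incomparable_threshold percentage above which an incomparable class
#'   excludes the cell (default 25).
#' @param cropland_class name of the cropland class (default `"cropland"`).
#' @param both_epochs if `TRUE`, the incomparable-class rule is evaluated on
#'   both epochs rather than the late epoch only.
#' @return list with `keep` (logical) and `reason` (`NA`, `"cover_change"` or
#'   `"incomparable_class"`).
#' @export
apply_exclusions <- function(early, late,
                             change_threshold = 10,
                             incomparable_classes = c("wetland", "built_up",
                                                      "other"),
                             incomparable_threshold = 25,
                             cropland_class = "cropland",
                             both_epochs = FALSE) {
  if (is.null(early) || is.null(late) || anyNA(c(early, late))) {
    stop("both epochs must be present for exclusion filtering")
  }
  pc <- function(cover, cls) if (cls %in% names(cover)) cover[[cls]] else 0
  crop_e <- pc(early, cropland_class)
  crop_l <- pc(late, cropland_class)
  if (abs(crop_l - crop_e) > change_threshold) {
    return(list(keep = FALSE, reason = "cover_change"))
  }
  bad_l <- vapply(incomparable_classes, pc, numeric(1), cover = late)
  bad <- max(bad_l)
  if (both_epochs) {
    bad <- max(bad, vapply(incomparable_classes, pc, numeric(1),
                           cover = early))
  }
  if (bad > incomparable_threshold) {
    return(list(keep = FALSE, reason = "incomparable_class"))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Cropland region of a cell
#'
#' Classifies a cell by its late-epoch cropland percentage: exactly 0% is
#' `none`, above 0 up to and including 50% is `low`, strictly above 50% is
#' `high` (majority cropland).
#'
#' @param cropland_late numeric vector of percentages in \[0, 100\].
#' @return factor with levels `high`, `low`, `none`.
#' @export
classify_region <- function(cropland_late) {
  if (any(is.na(cropland_late)) || any(cropland_late < 0) ||
      any(cropland_late > 100)) {
    stop("cropland percentage must lie in [0, 100]")
  }
  factor(ifelse(cropland_late == 0, "none",
                ifelse(cropland_late <= 50, "low", "high")),
         levels = c("high", "low", "none"))
}

#' Classify all sites from a long-format cover table
#'
#' Runs [apply_exclusions()] and [classify_region()] over every site of a
#' two-epoch cover table.
#'
#' @param cover long-format data.frame `site`, `epoch` (`early`/`late`),
#'   `class`, `percent`.
#' @param ... passed on to [apply_exclusions()].
#' @return data.frame `site`, `cropland_early`, `cropland_late`, `region`
#'   (levels `high`, `low`, `none`, `excluded`), `exclusion_reason`.
#' @export
classify_sites <- function(cover, ...) {
  stopifnot(all(c("site", "epoch", "class", "percent") %in% names(cover)))
  sites <- sort(unique(cover$site))
  wide <- function(site, epoch) {
    sub <- cover[cover$site == site & cover$epoch == epoch, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    stats::setNames(sub$percent, sub$class)
  }
  res <- lapply(sites, function(s) {
    e <- wide(s, "early"); l <- wide(s, "late")
    if (is.null(e) || is.null(l)) {
      stop("site '", s, "' lacks cover for one epoch")
    }
    excl <- apply_exclusions(e, l, ...)
    crop_e <- if ("cropland" %in% names(e)) e[["cropland"]] else 0
    crop_l <- if ("cropland" %in% names(l)) l[["cropland"]] else 0
    data.frame(site = s, cropland_early = crop_e, cropland_late = crop_l,
               region = if (excl$keep)
                 as.character(classify_region(crop_l)) else "excluded",
               exclusion_reason = excl$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$region <- factor(out$region,
                       levels = c("high", "low", "none", "excluded"))
  rownames(out) <- NULL
  out
}

#' Region counts and percentage shares
#'
#' Shares are computed over non-excluded cells only and sum to 100% before
#' rounding.
#'
#' @param classifications output of [classify_sites()], or any data.frame
#'   with a `region` column.
#' @return data.frame `region`, `n_cells`, `share_percent`.
#' @export
region_summary <- function(classifications) {
  reg <- as.character(classifications$region)
  kept <- reg[reg != "excluded"]
  if (length(kept) == 0L) stop("all cells excluded: no regions to summarise")
  n <- table(factor(kept, levels = c("high", "low", "none")))
  data.frame(region = names(n),
             n_cells = as.integer(n),
             share_percent = 100 * as.integer(n) / sum(n),
             stringsAsFactors = FALSE)
}
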