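# Multi-species indicators derived from posterior occupancy draws.
# All summaries are computed draw-wise: a derived quantity gets its own
# vector of posterior draws first, and medians / credible intervals are
# taken from that vector, never from summarised inputs.

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param floor_at optional positive floor applied to zero values (with a
#'   message the first time); without it any non-positive value is an error.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x, floor_at = NULL) {
  if (!is.null(floor_at)) {
    stopifnot(floor_at > 0)
    x[x == 0] <- floor_at
  }
  if (any(x <= 0)) {
    stop("geometric mean needs positive values (supply floor_at for zeros)")
  }
  exp(mean(log(x)))
}

#' Annualised growth rate between first- and last-year occupancy
#'
#' `((f / s)^(1/y) - 1) * 100`, the constant annual percentage change that
#' compounds first-year occupancy `s` to last-year occupancy `f` over `y`
#' annual steps. Vectorised over posterior draws.
#'
#' @param s first-year occupancy (> 0; 0 gives `NA` with a warning).
#' @param f last-year occupancy (>= 0; 0 gives -100).
#' @param y number of annual steps, i.e. `last_year - first_year`.
#' @return percentage growth per year.
#' @export
growth_rate <- function(s, f, y) {
  stopifnot(y >= 1, all(f >= 0))
  if (any(s == 0)) {
    warning("growth rate undefined for zero first-year occupancy")
  }
  out <- ((f / s)^(1 / y) - 1) * 100
  out[s == 0] <- NA_real_
  out
}

#' Multi-species geometric-mean occupancy index
#'
#' Collapses per-species regional occupancy draws into one indicator per
#' region and year: the geometric mean across species, computed within every
#' posterior draw. Zero draws (possible with a finite site set) are floored
#' at half the smallest observable non-zero occupancy,
#' `1 / (2 * n_sites_region)`, before the logarithm.
#'
#' @param psi 4-d array of occupancy draws, `draws x species x regions x
#'   years`.
#' @param n_sites_region integer vector (length = regions) used for the zero
#'   floor; alternatively pass `floor_at` directly.
#' @param floor_at optional explicit floor (overrides `n_sites_region`).
#' @return array `draws x regions x years` of index values, with the number
#'   of floored draws in attribute `"n_floored"`.
#' @export
occupancy_index <- function(psi, n_sites_region = NULL, floor_at = NULL) {
  stopifnot(length(dim(psi)) == 4L)
  d <- dim(psi)
  if (is.null(floor_at)) {
    if (is.null(n_sites_region)) stop("supply n_sites_region or floor_at")
    stopifnot(length(n_sites_region) == d[3L])
    fl <- 1 / (2 * n_sites_region)
    floor_arr <- aperm(array(fl, c(d[3L], d[1L], d[2L], d[4L])),
                       c(2L, 3L, 1L, 4L))
  } else {
    floor_arr <- array(floor_at, d)
  }
  n_floored <- sum(psi == 0)
  psi <- pmax(psi, floor_arr)
  if (any(psi <= 0)) stop("occupancy draws must be non-negative")
  out <- exp(apply(log(psi), c(1L, 3L, 4L), mean))
  attr(out, "n_floored") <- n_floored
  out
}

#' Multi-species growth rate across species
#'
#' Per posterior draw, summarises per-species annual growth rates as the
#' geometric mean of their annual multipliers `1 + gr/100`, reported back as
#' a percentage. A species whose multiplier is non-positive in a draw
#' (gr <= -100) is excluded from that draw with a warning.
#'
#' @param gr matrix of growth-rate draws, `draws x species`, in % per year.
#' @return vector of group-level growth-rate draws (% per year).
#' @export
multi_species_growth <- function(gr) {
  gr <- as.matrix(gr)
  mult <- 1 + gr / 100
  bad <- !is.finite(mult) | mult <= 0
  if (any(bad)) {
    warning(sum(bad), " draw x species multipliers <= 0 excluded")
    mult[bad] <- NA_real_
  }
  (exp(rowMeans(log(mult), na.rm = TRUE)) - 1) * 100
}

#' Between-region effect size on growth rates
#'
#' Draw-wise (paired) difference between the multi-species growth rates of
#' two regions, typically high- minus low-cropland. Negative values mean the
#' decline is stronger in the first region.
#'
#' @param gr_high,gr_low aligned growth-rate draw vectors (% per year).
#' @param mass credible-interval mass for the summary (default 0.95).
#' @return list with `draws`, `median`, `hdi` and `prob_below_zero` (strict
#'   posterior mass below 0).
#' @export
effect_size <- function(gr_high, gr_low, mass = 0.95) {
  if (length(gr_high) != length(gr_low)) {
    stop("draw vectors must be paired: lengths differ")
  }
  d <- gr_high - gr_low
  list(draws = d, median = stats::median(d), hdi = hdi(d, mass),
       prob_below_zero = mean(d < 0))
}

#' Highest-density interval of empirical draws
#'
#' The shortest interval containing the requested posterior mass: among all
#' windows of `ceiling(mass * n)` consecutive sorted draws, the narrowest.
#'
#' @param draws numeric vector (>= 20 draws).
#' @param mass interval mass in (0, 1), default 0.95.
#' @return named vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  n <- length(draws)
  if (n < 20L) stop("need >= 20 draws for an empirical HDI")
  x <- sort(draws)
  m <- ceiling(mass * n)
  widths <- x[m:n] - x[seq_len(n - m + 1L)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Draw-vector summary (median and HDI)
#'
#' @param draws numeric vector of posterior draws.
#' @param mass credible mass (default 0.95).
#' @return data.frame `median`, `hdi_lower`, `hdi_upper`.
#' @export
summarise_draws <- function(draws, mass = 0.95) {
  h <- hdi(draws, mass)
  data.frame(median = stats::median(draws),
             hdi_lower = unname(h[1L]), hdi_upper = unname(h[2L]))
}

#' Rule-of-thumb species filter
#'
#' Excludes species whose data volume is too small to support a reliable
#' trend, using configurable minima on record count, number of distinct
#' sites and number of years with records. The default thresholds are
#' package choices; set them from your own calibration.
#'
#' @param summaries data.frame with columns `species`, `n_records`,
#'   `n_sites`, `n_years` (see [species_summaries()]).
#' @param min_records,min_sites,min_years minima (a species is retained iff
#'   all are met).
#' @return data.frame `species`, `retained`.
#' @export
rule_of_thumb_filter <- function(summaries, min_records = 50,
                                 min_sites = 10, min_years = 5) {
  needed <- c("species", "n_records", "n_sites", "n_years")
  missing <- setdiff(needed, names(summaries))
  if (length(missing) > 0L) {
    stop("summaries lack column(s): ", paste(missing, collapse = ", "))
  }
  data.frame(species = summaries$species,
             retained = summaries$n_records >= min_records &
               summaries$n_sites >= min_sites &
               summaries$n_years >= min_years)
}
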