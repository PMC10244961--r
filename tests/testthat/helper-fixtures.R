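# Shared in-code fixtures. Everything is generated at test time; the small
# scenario is built once per test run and reused across files.

tiny_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_config(
        n_sites = c(high = 12, low = 12, none = 12), n_species = 4,
        first_year = 2000, last_year = 2005,
        n_violation_change = 2, n_violation_class = 2, seed = 5)
      sim <- simulate_scenario(cfg)
      cl <- standardize_records(sim$records, 2000, 2005)
      cls <- classify_sites(sim$cover)
      visits <- species_visit_join(build_visits(cl, 2000), cls)
      cache <<- list(cfg = cfg, sim = sim, cleaned = cl, cls = cls,
                     visits = visits,
                     site_regions = cls[cls$region != "excluded",
                                        c("site", "region")])
    }
    cache
  }
})

# records table built by hand for the cleaning tests
make_raw_records <- function() {
  data.frame(
    species = c("A", "A", "B", "C", "Harmonia axyridis", "D", "D", "E"),
    group = "ladybirds",
    site = c("s1", "s1", "s1", "s2", "s2", "s3", "s3", "s4"),
    date = c("1995-06-01", "1995-06-01", "1995-06-01", "1985-05-10",
             "1996-07-02", "1995-06-01", "1995-08-09", "2001-03-03"),
    spatial_precision_m = c(1000, 1000, 1000, 1000, 1000, 10000, 1000, 1000),
    temporal_precision = c("day", "day", "day", "day", "day", "day", "day",
                           "month"),
    stringsAsFactors = FALSE)
}

logsum2 <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log(exp(a - m) + exp(b - m))
}

# running log-sum-exp over all z configurations of the augmented kernel
enumerate_augmented <- function(params, data, priors) {
  n <- data$n_sites; Tn <- data$n_years
  total <- -Inf
  grid <- as.matrix(expand.grid(rep(list(0:1), n * Tn)))
  for (g in seq_len(nrow(grid))) {
    z <- matrix(as.integer(grid[g, ]), n, Tn)
    lp <- log_posterior_kernel(c(params, list(z = z)), data, priors,
                               form = "augmented")
    total <- logsum2(total, lp)
  }
  total
}

# random small model instance (sites x years, a few visits) with valid params
random_instance <- function(n_sites, n_years, n_visits, seed,
                            regions = c("high", "low")) {
  set.seed(seed)
  hist <- data.frame(
    site = sprintf("s%d", sample.int(n_sites, n_visits, replace = TRUE)),
    year_index = sample.int(n_years, n_visits, replace = TRUE) - 1L,
    datatype = sample(c("single", "short", "long"), n_visits,
                      replace = TRUE),
    detected = stats::rbinom(n_visits, 1L, 0.4))
  # make sure every site appears
  hist$site[seq_len(n_sites)] <- sprintf("s%d", seq_len(n_sites))
  sr <- data.frame(site = sprintf("s%d", seq_len(n_sites)),
                   region = rep(regions, length.out = n_sites))
  data <- occ_model_data(hist, sr, n_years = n_years)
  params <- list(
    b = matrix(stats::rnorm(data$n_regions * n_years, 0, 1),
               data$n_regions, n_years),
    u = stats::rnorm(data$n_sites, 0, 0.5),
    a = stats::rnorm(n_years, -0.5, 0.5),
    beta1 = 0.4, beta2 = 0.9, sigma_u = 0.8, sigma_rw = 0.6,
    mu_a = -0.5, sigma_a = 0.8)
  list(data = data, params = params)
}
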