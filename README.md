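# occtrend

Long-term occupancy trends of invertebrates from opportunistic,
presence-only biological records, compared across regions of cropland
cover.

Volunteer recording schemes produce millions of verified "species X was
seen at 1 km cell Y on day Z" records — and no record of absences. This
package is for ecologists and biodiversity analysts who want to turn such
data into defensible multi-species trend estimates: it cleans records into
visit-level detection histories (inferring non-detections from other
species of the same taxonomic group recorded on the same visit), stratifies
sites by cropland cover, fits a hierarchical Bayesian occupancy-detection
model per species, and aggregates posterior draws into multi-species
indicators, annual growth rates and between-region effect sizes with full
uncertainty propagation.

## The model

For site *i* in region *r(i)*, year *t* and visit *v*:

    z_it  ~ Bernoulli(psi_it)        logit(psi_it) = b_{t,r(i)} + u_i
    y_itv ~ Bernoulli(p_itv * z_it)  logit(p_itv)  = a_t + beta1*[2-3 species list]
                                                         + beta2*[4+ species list]

with a first-order random-walk prior `b_{t,r} ~ N(b_{t-1,r}, sigma_rw^2)`
per region, site random effects `u_i ~ N(0, sigma_u^2)`, and list length
(the number of species recorded on the visit) as a categorical proxy for
recorder effort. Regional occupancy per posterior draw is the proportion of
occupied modelled sites; species are combined by geometric means, growth
rates are `((f/s)^(1/y) - 1) * 100` % per year between the first and last
year, and the high-minus-low effect size is computed draw-wise. The MCMC
sampler is part of the package (Metropolis-within-Gibbs with exact latent-z
conditionals) and is validated in the test suite against exact kernel
enumeration, a Beta-Bernoulli closed form and an independent JAGS fit.

## Worked example

Every stage runs on synthetic data with known truth, so the whole pipeline
can be exercised without access to any recording-scheme data:

```r
library(occtrend)

cfg <- scenario_config(
  n_sites = c(high = 25, low = 25, none = 25), n_species = 6,
  first_year = 2000, last_year = 2011, seed = 42)
sim <- simulate_scenario(cfg)
nrow(sim$records)
#> [1] 7401

run <- run_pipeline(
  sim$records, sim$cover,
  run_config(first_year = 2000, last_year = 2011,
             rule_of_thumb = list(min_records = 20, min_sites = 5,
                                  min_years = 3),
             mcmc = list(chains = 3, iterations = 1500, burnin = 750,
                         thin = 3),
             indicators = list(n_draws = 500), seed = 42),
  species = sim$truth$species)
run
#> occupancy-trend run: 7401 cleaned records, 2614 visits, 6 species in indicators
#>              quantity   region     median hdi_lower  hdi_upper
#>          group_growth     high -3.3588552 -6.697587 -0.1595098
#>          group_growth      low -0.3652294 -2.812498  2.5880737
#>          group_growth     none -0.6799071 -3.048144  1.2639035
#>  effect_size_high_low high-low -2.9833714 -6.883556  1.5051841
```

The `group_growth` rows are posterior medians and 95% highest-density
intervals of the annual percentage change in the multi-species
geometric-mean occupancy of each cropland region; `effect_size_high_low` is
the draw-wise difference between the high- and low-region growth rates
(negative means declines are stronger where cropland dominates). This demo
is deliberately small — 25 sites per region and six species give wide
intervals; the generating truth here was −5 (high), −2 (low) and 0 (none)
% per year, realised as

```r
true_group_growth(sim$truth)$group_growth
#>      high       low      none
#> -4.079415 -2.409050 -1.063694
```

The package's reference validation (60 sites per region, 20 years, 15
species) is run by the test suite and the acceptance script.

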