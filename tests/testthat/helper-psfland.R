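# shared fixtures, all generated in code

# noise-free experiment: every plot equals its treatment mean
noise_free_plots <- function() {
  generate_experiment(experiment_config(dispersion = 0))
}

# minimal wide experiment table built by hand (2 plots per cell)
tiny_plots <- function(native_total = c(20, 40), nonnative_total = c(10, 30)) {
  split <- default_split()
  rows <- list()
  id <- 0
  for (soil in psf_soil_types()) {
    for (com in c("native", "nonnative")) {
      totals <- if (com == "native") native_total else nonnative_total
      for (tot in totals) {
        id <- id + 1
        fr <- split[split$community == com, ]
        cover <- setNames(rep(NA_real_, 6), psf_species()$code)
        cover[fr$code] <- tot * fr$fraction
        rows[[id]] <- tibble::tibble(
          plot_id = sprintf("T%03d", id), soil_type = soil, community = com,
          !!!as.list(cover)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# uniform rate table for simulator unit tests
flat_rate_table <- function(rate = 1.05, steps = 55, initial = 0.004) {
  m <- matrix(rate, 6, 5,
              dimnames = list(psf_species()$code, psf_soil_types()))
  rate_table(m, steps_per_season = steps, initial_cover = initial)
}

# rate table with one nonzero species, chosen per-step rate r
single_species_table <- function(species = "PSSP", r = 1.05, steps = 55,
                                 initial = 0.004) {
  m <- matrix(1, 6, 5, dimnames = list(psf_species()$code, psf_soil_types()))
  m[species, ] <- r
  rate_table(m, steps_per_season = steps, initial_cover = initial)
}

unbounded_capacities <- function() capacities(1, 1)
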