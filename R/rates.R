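#' Per-time-step multiplicative growth rate from initial and final cover
#'
#' A plant growing from seed (ground-cover fraction `initial_cover`) to
#' `final_cover` over `steps` equal multiplicative steps grows by
#' `(F/I)^(1/steps)` per step; applying the rate for `steps` steps maps
#' I exactly back to F. The default 55 steps represent roughly two-day
#' time steps over a 110-day growing season.
#'
#' @param final_cover Final ground-cover fraction (> 0). Vectorised.
#' @param initial_cover Initial ground-cover fraction (> 0); the default
#'   0.004 is the assumed cover of a seed.
#' @param steps Number of time steps in the growth interval (>= 1).
#' @return Per-step multiplicative growth rate(s); > 1 iff
#'   `final_cover > initial_cover`.
#' @examples
#' step_rate(0.42) # exp(log(105) / 55)
#' step_rate(0.004) # 1: no net growth
#' @export
step_rate <- function(final_cover, initial_cover = 0.004, steps = 55) {
  if (any(final_cover <= 0) || any(initial_cover <= 0)) {
    abort("Covers must be positive; floor zero observations before calling.")
  }
  if (steps < 1) abort("`steps` must be >= 1.")
  (final_cover / initial_cover)^(1 / steps)
}

#' Derive the soil-specific growth-rate table from experiment plots
#'
#' For every (species, soil type) cell, the seasonal final cover F is
#' the mean of that species' percent cover (as a ground fraction) across
#' all plots of its community on that soil; the per-step rate is
#' `step_rate(F, initial_cover, steps_per_season)`. Cell means of zero
#' are floored at `initial_cover` (rate exactly 1), so species absent
#' from a soil are static rather than instantaneously extinct. The null
#' model's single rate per species is its rate on its "self" soil.
#'
#' @param plots Experiment table as returned by [generate_experiment()].
#' @param steps_per_season Steps over which each seasonal rate is
#'   defined (default 55).
#' @param initial_cover Seed ground-cover fraction (default 0.004).
#' @param self_soil Named character vector mapping each species to its
#'   self soil; defaults to [self_soil_default()].
#' @return An object of class `psf_rate_table`: a list with `rates`
#'   (tibble: `species`, `soil_type`, `f_mean` ground fraction, `rate`),
#'   `null_rates` (tibble: `species`, `self_soil`, `rate`),
#'   `steps_per_season` and `initial_cover`.
#' @examples
#' plots <- generate_experiment(experiment_config(dispersion = 0))
#' rt <- derive_rate_table(plots)
#' rate_matrix(rt)
#' @export
derive_rate_table <- function(plots, steps_per_season = 55,
                              initial_cover = 0.004,
                              self_soil = self_soil_default()) {
  long <- experiment_long(plots)
  soils <- unique(long$soil_type)
  cells <- long |>
    summarise(f_mean = mean(.data$cover) / 100,
              .by = c("species", "soil_type"))
  full <- expand_grid(species = psf_species()$code, soil_type = soils)
  missing <- anti_join(full, cells, by = c("species", "soil_type"))
  if (nrow(missing) > 0) {
    abort(paste0(
      "Empty (species, soil) cells with no imputation rule: ",
      paste(missing$species, missing$soil_type, sep = "/", collapse = ", ")
    ))
  }
  rates <- cells |>
    mutate(
      f_mean = ifelse(.data$f_mean <= 0, initial_cover, .data$f_mean),
      rate = step_rate(.data$f_mean, initial_cover, steps_per_season)
    ) |>
    arrange(match(.data$species, psf_species()$code),
            match(.data$soil_type, psf_soils))
  if (!all(names(self_soil) %in% rates$species) ||
      !all(unique(rates$species) %in% names(self_soil))) {
    abort("`self_soil` must map every species in the table.")
  }
  null_rates <- tibble(species = unique(rates$species)) |>
    mutate(self_soil = unname(self_soil[.data$species])) |>
    left_join(rates, by = c("species", self_soil = "soil_type")) |>
    select("species", "self_soil", "rate")

  structure(
    list(rates = rates, null_rates = null_rates,
         steps_per_season = steps_per_season, initial_cover = initial_cover),
    class = "psf_rate_table"
  )
}

#' Construct a growth-rate table directly
#'
#' Builds the object [derive_rate_table()] returns from a species-by-soil
#' matrix of per-step rates, for simulations parameterised by hand.
#'
#' @param rates_matrix Numeric matrix of per-step multiplicative rates;
#'   species codes as rownames, soil types as colnames.
#' @param null_rates Named numeric vector of single per-species rates
#'   for the null model; defaults to each species' rate on its
#'   [self_soil_default()] soil when those soils are present, otherwise
#'   required.
#' @param steps_per_season,initial_cover Rate definition (see
#'   [step_rate()]).
#' @return A `psf_rate_table` object.
#' @examples
#' m <- matrix(1.05, 6, 5, dimnames = list(psf_species()$code,
#'                                         psf_soil_types()))
#' rate_table(m)
#' @export
rate_table <- function(rates_matrix, null_rates = NULL,
                       steps_per_season = 55, initial_cover = 0.004) {
  if (is.null(rownames(rates_matrix)) || is.null(colnames(rates_matrix))) {
    abort("`rates_matrix` needs species rownames and soil-type colnames.")
  }
  if (any(rates_matrix <= 0)) abort("All rates must be positive.")
  species <- rownames(rates_matrix)
  if (is.null(null_rates)) {
    self <- self_soil_default()
    if (!all(species %in% names(self)) ||
        !all(self[species] %in% colnames(rates_matrix))) {
      abort("Supply `null_rates` when default self soils are not in the matrix.")
    }
    null_rates <- setNames(
      rates_matrix[cbind(species, self[species])], species
    )
    self_used <- unname(self[species])
  } else {
    if (!all(species %in% names(null_rates))) {
      abort("`null_rates` must name every species in the matrix.")
    }
    null_rates <- null_rates[species]
    self_used <- NA_character_
  }
  rates <- as_tibble(rates_matrix, rownames = "species") |>
    pivot_longer(-"species", names_to = "soil_type", values_to = "rate") |>
    mutate(f_mean = initial_cover * .data$rate^steps_per_season,
           .before = "rate")
  structure(
    list(
      rates = rates,
      null_rates = tibble(species = species, self_soil = self_used,
                          rate = unname(null_rates)),
      steps_per_season = steps_per_season, initial_cover = initial_cover
    ),
    class = "psf_rate_table"
  )
}

#' Species-by-soil matrix view of a rate table
#'
#' @param rate_table A [derive_rate_table()] object.
#' @return Numeric matrix, species rows by soil-type columns.
#' @export
rate_matrix <- function(rate_table) {
  stopifnot(inherits(rate_table, "psf_rate_table"))
  wide <- rate_table$rates |>
    select("species", "soil_type", "rate") |>
    pivot_wider(names_from = "soil_type", values_from = "rate")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$species
  m
}

#' Group-level carrying capacities from experiment plots
#'
#' The carrying capacity of each plant group (all natives, all
#' non-natives) is the mean plus two standard deviations of plot-level
#' community-total cover (as a ground fraction), pooled over all soil
#' treatments.
#'
#' @param plots Experiment table as returned by [generate_experiment()].
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n).
#' @return An object of class `psf_capacities`: a list with `k_native`
#'   and `k_nonnative` (ground fractions) and `sd_type`.
#' @examples
#' plots <- generate_experiment(seed = 1)
#' derive_capacities(plots)
#' @export
derive_capacities <- function(plots, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  totals <- community_totals(plots)
  ks <- totals |>
    summarise(
      n = n(),
      mean = mean(.data$total) / 100,
      s = if (sd_type == "sample") sd(.data$total) / 100 else
        sqrt(mean((.data$total - mean(.data$total))^2)) / 100,
      .by = "community"
    )
  if (any(ks$n < 2)) {
    abort("At least 2 plots per community are required.")
  }
  k <- setNames(ks$mean + 2 * ks$s, ks$community)
  structure(
    list(k_native = unname(k["native"]), k_nonnative = unname(k["nonnative"]),
         sd_type = sd_type),
    class = "psf_capacities"
  )
}

#' Construct carrying capacities directly
#'
#' @param k_native,k_nonnative Group carrying capacities as ground
#'   fractions in (0, 1].
#' @return A `psf_capacities` object.
#' @export
capacities <- function(k_native, k_nonnative) {
  if (k_native <= 0 || k_native > 1 || k_nonnative <= 0 || k_nonnative > 1) {
    abort("Capacities must be ground fractions in (0, 1].")
  }
  structure(list(k_native = k_native, k_nonnative = k_nonnative,
                 sd_type = "given"),
            class = "psf_capacities")
}

#' @export
print.psf_rate_table <- function(x, ...) {
  cat(sprintf("Growth-rate table: %d steps/season, seed cover %.4g\n",
              x$steps_per_season, x$initial_cover))
  print(rate_matrix(x))
  cat("Null (self-soil) rates:\n")
  print(x$null_rates)
  invisible(x)
}

#' @export
print.psf_capacities <- function(x, ...) {
  cat(sprintf("Carrying capacities (%s SD): native %.4f, non-native %.4f\n",
              x$sd_type, x$k_native, x$k_nonnative))
  invisible(x)
}
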