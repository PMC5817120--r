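#' Soil-weighted effective growth rates
#'
#' With feedback on, a species' growth rate in a given soil state is the
#' additive (proportion-weighted) combination of its soil-specific
#' rates: `sum_s soil[s] * rate(species, s)`. With feedback off every
#' species uses its single null (self-soil) rate regardless of the soil
#' state. When a species' rates are identical on every soil the common
#' value is returned exactly, so the feedback model reduces bit-for-bit
#' to the null model for soil-invariant rate rows.
#'
#' @param rate_table A [derive_rate_table()] object.
#' @param soil Named numeric vector of soil proportions (must cover the
#'   soils in the rate table and sum to 1 within 1e-6).
#' @param feedback Logical; `FALSE` selects the null model rates.
#' @return Named numeric vector of per-step rates, one per species.
#' @examples
#' plots <- generate_experiment(experiment_config(dispersion = 0))
#' rt <- derive_rate_table(plots)
#' effective_rates(rt, c(PSSP = 1, BRTE = 0, CEDI = 0, SILO = 0, Mixed = 0))
#' @export
effective_rates <- function(rate_table, soil, feedback = TRUE) {
  stopifnot(inherits(rate_table, "psf_rate_table"))
  if (!feedback) {
    return(setNames(rate_table$null_rates$rate, rate_table$null_rates$species))
  }
  m <- rate_matrix(rate_table)
  if (!all(colnames(m) %in% names(soil))) {
    abort("`soil` must name a proportion for every soil type in the rate table.")
  }
  w <- soil[colnames(m)]
  if (abs(sum(w) - 1) > 1e-6 || any(w < 0)) {
    abort("Soil proportions must be non-negative and sum to 1.")
  }
  eff <- vapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    if (max(r) == min(r)) r[[1]] else sum(w * r) / sum(w)
  }, numeric(1))
  setNames(eff, rownames(m))
}

#' Cap proposed covers at the group carrying capacities
#'
#' Carrying capacity binds at the level of a whole plant group: if a
#' group's proposed total exceeds its K, every species in that group is
#' rescaled by `K / total` so the group total equals K exactly and
#' within-group relative abundance is preserved. The two groups are
#' capped independently; totals at or below K pass through unchanged.
#'
#' @param cover Named numeric vector of proposed ground-cover fractions
#'   (species codes as names, all >= 0).
#' @param capacities A [capacities()] or [derive_capacities()] object.
#' @param origin Named character vector mapping species to
#'   `"native"`/`"nonnative"`; defaults to the package species table.
#' @return Named numeric vector of capped covers.
#' @examples
#' apply_capacity(c(PSSP = 0.4, FEID = 0.15, KOCR = 0.05),
#'                capacities(0.42, 0.41))
#' @export
apply_capacity <- function(cover, capacities, origin = species_origin()) {
  stopifnot(inherits(capacities, "psf_capacities"))
  if (any(cover < 0)) abort("Proposed covers must be non-negative.")
  k <- c(native = capacities$k_native, nonnative = capacities$k_nonnative)
  grp <- origin[names(cover)]
  for (g in unique(grp)) {
    idx <- which(grp == g)
    tot <- sum(cover[idx])
    if (tot > k[[g]]) cover[idx] <- cover[idx] * (k[[g]] / tot)
  }
  cover
}

#' Soil proportions implied by current plant cover
#'
#' The proportion of each soil type equals the relative abundance of the
#' plants that cultivate it: `soil[s] = sum_{i: cultivates s} cover[i] /
#' sum_i cover[i]`. If total cover is zero the previous proportions are
#' retained (with a warning).
#'
#' @param cover Named numeric vector of ground-cover fractions.
#' @param species_to_soil Named character vector mapping each species to
#'   the soil it cultivates; defaults to [species_to_soil_default()].
#' @param previous Named numeric vector of the previous soil
#'   proportions, returned unchanged when total cover is zero; also
#'   defines the full set of soil types in the output (soils cultivated
#'   by no present species get proportion 0).
#' @return Named numeric vector of soil proportions summing to 1.
#' @examples
#' update_soils(c(PSSP = 0.1, CEDI = 0.3),
#'              previous = c(PSSP = 0.5, BRTE = 0, CEDI = 0.5,
#'                           SILO = 0, Mixed = 0))
#' @export
update_soils <- function(cover, species_to_soil = species_to_soil_default(),
                         previous = NULL) {
  soils <- if (!is.null(previous)) names(previous) else psf_soils
  tot <- sum(cover)
  if (tot <= 0) {
    if (is.null(previous)) {
      abort("Total cover is zero and no previous soil state was given.")
    }
    warn("Total cover is zero; soil proportions held at their previous value.")
    return(previous)
  }
  out <- setNames(numeric(length(soils)), soils)
  for (sp in names(cover)) {
    s <- species_to_soil[[sp]]
    if (!s %in% soils) abort(paste0("Unknown soil type for species ", sp))
    out[s] <- out[s] + cover[[sp]]
  }
  out / tot
}

# one capacity pass for the simulator, by mode
cap_state <- function(cover, capacities, mode, origin) {
  if (mode == "pot") {
    # single ceiling on total cover: the cover-share-weighted mean of the
    # two group capacities; rescaling all species preserves every
    # relative abundance, after which the group caps are enforced too
    tot <- sum(cover)
    if (tot > 0) {
      nat <- sum(cover[origin[names(cover)] == "native"])
      k_tot <- (nat * capacities$k_native +
                  (tot - nat) * capacities$k_nonnative) / tot
      if (tot > k_tot) cover <- cover * (k_tot / tot)
    }
  }
  apply_capacity(cover, capacities, origin)
}

#' Simulate community growth on feedback-coupled soils
#'
#' Discrete-time community growth model ("Pot-Level-K"): at every step
#' each species' cover is multiplied by its soil-weighted effective rate
#' ([effective_rates()]), covers are capped at the carrying capacities,
#' and soil proportions are then updated to the relative abundance of
#' the plants that grew in that step ([update_soils()]). The model is
#' fully deterministic. With `feedback = FALSE` the same machinery runs
#' with each species' single null rate (soil state still tracked, but
#' inert).
#'
#' Three capacity modes are available. `"pot"` (default) caps TOTAL
#' cover at the cover-share-weighted mean of the two group capacities,
#' so the two groups compete for the same ground and the faster-growing
#' group displaces the slower one; group caps are additionally enforced.
#' `"group"` caps each group independently at its own K (pure
#' [apply_capacity()] semantics): groups do not interact and each
#' saturates at its own capacity. `"damped"` multiplies each species'
#' growth increment by `max(0, 1 - G/K_g)` where G is its group's total,
#' a classical logistic damping provided for sensitivity analysis (it
#' systematically undershoots the seasonal final covers the rates were
#' derived from).
#'
#' @param rate_table A [derive_rate_table()] object.
#' @param capacities A [capacities()] or [derive_capacities()] object.
#' @param initial_soil Named numeric vector of initial soil proportions
#'   (summing to 1). Missing soils default to 0.
#' @param n_steps Number of steps (default 165 = three 55-step growing
#'   seasons).
#' @param feedback Logical; `FALSE` runs the null model.
#' @param initial_cover Either a single ground fraction applied to every
#'   species (default 0.004, the seed cover) or a named vector.
#' @param capacity_mode `"pot"`, `"group"` or `"damped"` (see Details).
#' @param soil_update `"season"` (default) or `"step"`. Soil legacies
#'   develop over a growing season, not between two-day growth steps:
#'   with `"season"` the soil state is held fixed within each
#'   `season_length`-step season and reset to plant relative abundance
#'   between seasons, so the initial landscape soil composition governs
#'   the whole first season. With `"step"` soils track the previous
#'   step's relative abundance; because every species starts at the same
#'   propagule cover, this erases the initial soil composition after a
#'   single step and all scenarios collapse onto one trajectory.
#' @param season_length Steps per growing season (defaults to the rate
#'   table's `steps_per_season`).
#' @param species_to_soil Named character vector mapping species to the
#'   soil they cultivate.
#' @return An object of class `psf_trajectory`: a tibble in long form
#'   with columns `step` (0..n_steps), `quantity` (`"cover"` or
#'   `"soil"`), `name` (species or soil type) and `value`; the run
#'   configuration is attached as attributes.
#' @examples
#' plots <- generate_experiment(experiment_config(dispersion = 0))
#' rt <- derive_rate_table(plots)
#' k <- derive_capacities(plots)
#' traj <- simulate_community(rt, k, c(PSSP = 0.25, BRTE = 0.27,
#'                                     CEDI = 0.30, SILO = 0.18))
#' final_cover(traj)
#' @export
simulate_community <- function(rate_table, capacities, initial_soil,
                               n_steps = 165, feedback = TRUE,
                               initial_cover = 0.004,
                               capacity_mode = c("pot", "group", "damped"),
                               soil_update = c("season", "step"),
                               season_length = rate_table$steps_per_season,
                               species_to_soil = species_to_soil_default()) {
  stopifnot(inherits(rate_table, "psf_rate_table"),
            inherits(capacities, "psf_capacities"))
  capacity_mode <- match.arg(capacity_mode)
  soil_update <- match.arg(soil_update)
  if (n_steps < 1) abort("`n_steps` must be >= 1.")
  if (is.null(season_length) || season_length < 1) {
    abort("`season_length` must be >= 1.")
  }

  m <- rate_matrix(rate_table)
  species <- rownames(m)
  soils <- colnames(m)
  origin <- species_origin()
  if (!all(species %in% names(origin))) {
    abort("Rate table contains species with unknown origin.")
  }

  soil <- setNames(numeric(length(soils)), soils)
  known <- intersect(names(initial_soil), soils)
  if (length(setdiff(names(initial_soil), soils)) > 0) {
    abort("`initial_soil` names unknown soil types.")
  }
  soil[known] <- initial_soil[known]
  if (abs(sum(soil) - 1) > 1e-6 || any(soil < 0)) {
    abort("`initial_soil` proportions must be non-negative and sum to 1.")
  }
  soil <- soil / sum(soil)

  cover <- if (length(initial_cover) == 1 && is.null(names(initial_cover))) {
    setNames(rep(initial_cover, length(species)), species)
  } else {
    cv <- setNames(numeric(length(species)), species)
    cv[names(initial_cover)] <- initial_cover
    cv
  }
  if (any(cover < 0)) abort("Initial covers must be non-negative.")

  null_r <- setNames(rate_table$null_rates$rate, rate_table$null_rates$species)
  null_r <- null_r[species]
  row_const <- apply(m, 1, function(r) max(r) == min(r))
  k_g <- c(native = capacities$k_native, nonnative = capacities$k_nonnative)
  grp <- origin[species]

  cover_hist <- matrix(NA_real_, n_steps + 1, length(species),
                       dimnames = list(NULL, species))
  soil_hist <- matrix(NA_real_, n_steps + 1, length(soils),
                      dimnames = list(NULL, soils))
  cover_hist[1, ] <- cover
  soil_hist[1, ] <- soil

  for (t in seq_len(n_steps)) {
    if (feedback) {
      eff <- m %*% soil
      eff <- eff[, 1] / sum(soil)
      eff[row_const] <- m[row_const, 1]
    } else {
      eff <- null_r
    }
    if (capacity_mode == "damped") {
      g_tot <- c(native = sum(cover[grp == "native"]),
                 nonnative = sum(cover[grp == "nonnative"]))
      damp <- pmax(0, 1 - g_tot[grp] / k_g[grp])
      cover <- cover * (1 + (eff - 1) * damp)
      cover <- apply_capacity(cover, capacities, origin)
    } else {
      cover <- cover * eff
      cover <- cap_state(cover, capacities, capacity_mode, origin)
    }
    if (soil_update == "step" || t %% season_length == 0) {
      tot <- sum(cover)
      if (tot > 0) {
        new_soil <- setNames(numeric(length(soils)), soils)
        for (i in seq_along(species)) {
          s <- species_to_soil[[species[i]]]
          new_soil[s] <- new_soil[s] + cover[i]
        }
        soil <- new_soil / tot
      } else {
        warn("Total cover reached zero; soil proportions held constant.")
      }
    }
    cover_hist[t + 1, ] <- cover
    soil_hist[t + 1, ] <- soil
  }

  traj <- bind_rows(
    as_tibble(cover_hist) |>
      mutate(step = 0:n_steps) |>
      pivot_longer(-"step", names_to = "name", values_to = "value") |>
      mutate(quantity = "cover"),
    as_tibble(soil_hist) |>
      mutate(step = 0:n_steps) |>
      pivot_longer(-"step", names_to = "name", values_to = "value") |>
      mutate(quantity = "soil")
  ) |>
    select("step", "quantity", "name", "value") |>
    arrange(.data$step)

  structure(
    traj,
    class = c("psf_trajectory", class(traj)),
    feedback = feedback,
    capacity_mode = capacity_mode,
    soil_update = soil_update,
    season_length = season_length,
    n_steps = n_steps,
    capacities = capacities,
    species_to_soil = species_to_soil
  )
}

#' Final species covers of a trajectory
#'
#' @param trajectory A [simulate_community()] result.
#' @return Named numeric vector of ground-cover fractions at the last
#'   step.
#' @export
final_cover <- function(trajectory) {
  stopifnot(inherits(trajectory, "psf_trajectory"))
  last <- trajectory |>
    filter(.data$step == max(.data$step), .data$quantity == "cover")
  setNames(last$value, last$name)
}

#' Native and non-native group totals over a trajectory
#'
#' @param trajectory A [simulate_community()] result.
#' @return A tibble with columns `step`, `origin`, `total` (ground
#'   fraction).
#' @export
group_totals <- function(trajectory) {
  stopifnot(inherits(trajectory, "psf_trajectory"))
  origin <- species_origin()
  trajectory |>
    filter(.data$quantity == "cover") |>
    mutate(origin = origin[.data$name]) |>
    summarise(total = sum(.data$value), .by = c("step", "origin")) |>
    as_tibble()
}
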