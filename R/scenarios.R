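#' Build landscape soil scenarios from native soil fractions
#'
#' One scenario per distance class from the historical tillage boundary.
#' The native soil fraction (taken from landscape relative abundance of
#' native plants) is assigned wholly to the PSSP-type native soil -- all
#' native soils are assumed cultivated by the dominant native -- and the
#' remainder is distributed among the three non-native soils according
#' to `nonnative_split`. The Mixed soil has no landscape analogue and
#' gets proportion 0.
#'
#' @param native_fractions Named numeric vector, distance class (m) ->
#'   fraction of soil that is native; defaults to the landscape values
#'   0.25, 0.36, 0.86, 0.94 at -50, -5, +5, +50 m.
#' @param nonnative_split Either a named numeric vector of weights for
#'   BRTE/CEDI/SILO (normalised internally; default proportional to the
#'   non-native species' landscape covers 4.5 : 5.1 : 3.0) or the string
#'   `"equal"` for equal thirds.
#' @param propagule_cover Seed ground-cover fraction attached to each
#'   scenario (default 0.004).
#' @return A tibble with columns `distance_m`, `soil_type`, `proportion`
#'   (proportions sum to 1 within each distance class) and attribute
#'   `propagule_cover`.
#' @examples
#' build_scenarios()
#' @export
build_scenarios <- function(native_fractions = c(`-50` = 0.25, `-5` = 0.36,
                                                 `5` = 0.86, `50` = 0.94),
                            nonnative_split = c(BRTE = 4.5, CEDI = 5.1,
                                                SILO = 3.0),
                            propagule_cover = 0.004) {
  if (any(native_fractions < 0 | native_fractions > 1)) {
    abort("`native_fractions` must lie in [0, 1].")
  }
  if (propagule_cover <= 0) abort("`propagule_cover` must be positive.")
  if (identical(nonnative_split, "equal")) {
    nonnative_split <- c(BRTE = 1, CEDI = 1, SILO = 1)
  }
  if (!setequal(names(nonnative_split), c("BRTE", "CEDI", "SILO")) ||
      any(nonnative_split < 0) || sum(nonnative_split) <= 0) {
    abort("`nonnative_split` must give non-negative weights for BRTE, CEDI, SILO.")
  }
  split <- nonnative_split / sum(nonnative_split)

  out <- imap(native_fractions, function(fn, d) {
    tibble(
      distance_m = as.numeric(d),
      soil_type = psf_soils,
      proportion = c(fn, unname(split[c("BRTE", "CEDI", "SILO")]) * (1 - fn), 0)
    )
  }) |>
    list_rbind()
  attr(out, "propagule_cover") <- propagule_cover
  out
}

#' Compare PSF and null model predictions with survey observations
#'
#' Runs the feedback model and the feedback-free null model for every
#' scenario, aggregates final native and non-native cover, attaches the
#' observed transect means from the survey, and flags rank-order
#' agreement (does each model place the same group on top as the
#' observations?) per distance class.
#'
#' @param scenarios Scenario table from [build_scenarios()].
#' @param rate_table A [derive_rate_table()] object.
#' @param capacities A [capacities()] or [derive_capacities()] object.
#' @param survey Survey table as returned by [generate_survey()]; must
#'   cover every scenario distance class.
#' @param n_steps Simulation length (default 165).
#' @param capacity_mode Passed to [simulate_community()].
#' @param ... Further arguments passed to [simulate_community()]
#'   (e.g. `soil_update`, `season_length`).
#' @return An object of class `psf_comparison`: a tibble with one row
#'   per distance class and columns `distance_m`, `observed_native`,
#'   `observed_nonnative`, `psf_native`, `psf_nonnative`, `null_native`,
#'   `null_nonnative` (all percent cover), `psf_agrees`, `null_agrees`.
#' @examples
#' plots <- generate_experiment(experiment_config(dispersion = 0))
#' rt <- derive_rate_table(plots)
#' k <- derive_capacities(plots)
#' sv <- generate_survey(seed = 1)
#' run_comparison(build_scenarios(), rt, k, sv)
#' @export
run_comparison <- function(scenarios, rate_table, capacities, survey,
                           n_steps = 165,
                           capacity_mode = c("pot", "group", "damped"), ...) {
  capacity_mode <- match.arg(capacity_mode)
  survey <- as_tibble(survey)
  distances <- sort(unique(scenarios$distance_m))
  if (!all(distances %in% survey$distance_m)) {
    abort("`survey` must cover every scenario distance class.")
  }
  propagule <- attr(scenarios, "propagule_cover") %||% 0.004

  observed <- survey |>
    summarise(observed_native = mean(.data$native_cover),
              observed_nonnative = mean(.data$nonnative_cover),
              .by = "distance_m")

  run_one <- function(d, feedback) {
    sc <- scenarios |> filter(.data$distance_m == d)
    init <- setNames(sc$proportion, sc$soil_type)
    traj <- simulate_community(
      rate_table, capacities, init, n_steps = n_steps, feedback = feedback,
      initial_cover = propagule, capacity_mode = capacity_mode, ...
    )
    gt <- group_totals(traj) |> filter(.data$step == n_steps)
    setNames(gt$total, gt$origin) * 100
  }

  pred <- purrr::map(distances, function(d) {
    psf <- run_one(d, TRUE)
    nul <- run_one(d, FALSE)
    tibble(
      distance_m = d,
      psf_native = psf[["native"]], psf_nonnative = psf[["nonnative"]],
      null_native = nul[["native"]], null_nonnative = nul[["nonnative"]]
    )
  }) |>
    list_rbind()

  out <- pred |>
    left_join(observed, by = "distance_m") |>
    mutate(
      psf_agrees = sign(.data$psf_native - .data$psf_nonnative) ==
        sign(.data$observed_native - .data$observed_nonnative),
      null_agrees = sign(.data$null_native - .data$null_nonnative) ==
        sign(.data$observed_native - .data$observed_nonnative)
    ) |>
    select("distance_m", "observed_native", "observed_nonnative",
           "psf_native", "psf_nonnative", "null_native", "null_nonnative",
           "psf_agrees", "null_agrees") |>
    arrange(.data$distance_m)

  structure(out, class = c("psf_comparison", class(out)),
            capacity_mode = capacity_mode, n_steps = n_steps)
}
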