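#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a soil-treatment ANOVA
#'
#' @param x A `psf_anova` object.
#' @param ... Unused.
#' @return One row per soil type: back-transformed mean cover, SE on the
#'   transformed scale, n and compact letters.
#' @export
tidy.psf_anova <- function(x, ...) {
  x$group_means |> mutate(community = x$community, .before = 1)
}

#' @rdname tidy.psf_anova
#' @export
glance.psf_anova <- function(x, ...) {
  tibble(
    community = x$community, f_statistic = x$f_statistic,
    df_num = x$df_num, df_den = x$df_den, p_value = x$p_value
  )
}

#' Tidy a survey origin-by-distance test
#'
#' @param x A `psf_survey_test` object.
#' @param ... Unused.
#' @return `tidy()`: the per-distance paired contrasts; `glance()`: one
#'   row with the interaction F test.
#' @export
tidy.psf_survey_test <- function(x, ...) x$contrasts

#' @rdname tidy.psf_survey_test
#' @export
glance.psf_survey_test <- function(x, ...) {
  tibble(
    interaction_f = x$interaction_f,
    df_num = x$interaction_df[1], df_den = x$interaction_df[2],
    interaction_p = x$interaction_p, n_sites = x$n_sites
  )
}

#' Tidy a growth-rate table
#'
#' @param x A `psf_rate_table` object.
#' @param ... Unused.
#' @return Long tibble of soil-specific rates with each species' null
#'   (self-soil) rate joined on.
#' @export
tidy.psf_rate_table <- function(x, ...) {
  x$rates |>
    left_join(
      x$null_rates |> select("species", null_rate = "rate"),
      by = "species"
    )
}

#' @rdname tidy.psf_rate_table
#' @export
glance.psf_rate_table <- function(x, ...) {
  tibble(
    n_species = length(unique(x$rates$species)),
    n_soils = length(unique(x$rates$soil_type)),
    steps_per_season = x$steps_per_season,
    initial_cover = x$initial_cover
  )
}
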