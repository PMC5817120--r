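#' Bar chart of community cover by soil treatment
#'
#' Mirrors the standard presentation of a soil-conditioning experiment:
#' back-transformed mean percent cover per cultivated soil with +-1 SE
#' (delta-method on the transformed scale) and compact letters; bars
#' sharing no letter differ at the fitted alpha.
#'
#' @param object A `psf_anova` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psf_anova <- function(object, ...) {
  gm <- object$group_means |>
    mutate(
      lo = back_transform_cover(.data$mean_transformed - .data$se_transformed),
      hi = back_transform_cover(.data$mean_transformed + .data$se_transformed),
      soil_type = factor(.data$soil_type, levels = .data$soil_type)
    )
  ggplot2::ggplot(gm, ggplot2::aes(x = .data$soil_type, y = .data$mean_cover)) +
    ggplot2::geom_col(fill = "grey65", colour = "grey20") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(y = .data$hi, label = .data$letters),
                       vjust = -0.6) +
    ggplot2::labs(
      x = "Cultivated soil", y = "Cover (%)",
      title = sprintf("%s community cover by soil treatment",
                      if (object$community == "native") "Native" else "Non-native")
    ) +
    ggplot2::theme_minimal()
}

#' Cover and soil trajectories of a simulation
#'
#' @param object A `psf_trajectory` object.
#' @param ... Unused.
#' @return A ggplot faceted into species cover and soil proportion
#'   panels.
#' @export
autoplot.psf_trajectory <- function(object, ...) {
  dat <- as_tibble(object) |>
    mutate(quantity = factor(.data$quantity, c("cover", "soil"),
                             c("Species cover (fraction)",
                               "Soil proportion")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$step, y = .data$value,
                                    colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Time step", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Observed vs predicted dominance across the tillage boundary
#'
#' Grouped bars of native and non-native percent cover per distance
#' class in three panels: survey observations, the feedback model and
#' the feedback-free null model.
#'
#' @param object A `psf_comparison` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psf_comparison <- function(object, ...) {
  dat <- as_tibble(object) |>
    select(-"psf_agrees", -"null_agrees") |>
    pivot_longer(-"distance_m", names_to = c("panel", "origin"),
                 names_sep = "_", values_to = "cover") |>
    mutate(
      panel = factor(.data$panel, c("observed", "psf", "null"),
                     c("Observed", "PSF model", "Null model")),
      origin = factor(.data$origin, c("native", "nonnative"),
                      c("Native", "Non-native")),
      distance_m = factor(.data$distance_m, sort(unique(.data$distance_m)))
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$distance_m, y = .data$cover,
                                    fill = .data$origin)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_manual(values = c(Native = "#2b8cbe",
                                          `Non-native` = "#e34a33")) +
    ggplot2::labs(x = "Distance from tillage boundary (m)",
                  y = "Cover (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
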