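#' Read and write the package's CSV tables
#'
#' Plain-CSV interchange for the experiment table (one row per plot,
#' one column per species code), the survey table and the rate table
#' (species-by-soil matrix plus the null-rate column). The rate-table
#' reader restores `steps_per_season` and `initial_cover` from the
#' arguments, which must match the values used at derivation.
#'
#' @param x Object to write.
#' @param path File path.
#' @param steps_per_season,initial_cover Rate definition carried by a
#'   rate-table CSV.
#' @return Readers return the corresponding tibble/object; writers
#'   return `x` invisibly.
#' @name psf_io
NULL

#' @rdname psf_io
#' @export
write_experiment_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname psf_io
#' @export
read_experiment_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname psf_io
#' @export
write_survey_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname psf_io
#' @export
read_survey_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname psf_io
#' @export
write_rate_table_csv <- function(x, path) {
  stopifnot(inherits(x, "psf_rate_table"))
  wide <- x$rates |>
    select("species", "soil_type", "rate") |>
    pivot_wider(names_from = "soil_type", values_from = "rate") |>
    left_join(
      x$null_rates |> select("species", "self_soil", null_rate = "rate"),
      by = "species"
    )
  readr::write_csv(wide, path)
  invisible(x)
}

#' @rdname psf_io
#' @export
read_rate_table_csv <- function(path, steps_per_season = 55,
                                initial_cover = 0.004) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  soils <- setdiff(names(wide), c("species", "self_soil", "null_rate"))
  rates <- wide |>
    select("species", all_of(soils)) |>
    pivot_longer(all_of(soils), names_to = "soil_type", values_to = "rate") |>
    mutate(f_mean = initial_cover * .data$rate^steps_per_season)
  null_rates <- wide |> select("species", "self_soil", rate = "null_rate")
  structure(
    list(rates = rates, null_rates = null_rates,
         steps_per_season = steps_per_season, initial_cover = initial_cover),
    class = "psf_rate_table"
  )
}
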