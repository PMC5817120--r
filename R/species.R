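#' Target species of the shrub-steppe study system
#'
#' The six focal species: three long-lived native bunchgrasses
#' (*Pseudoroegneria spicata* PSSP, *Festuca idahoensis* FEID,
#' *Koeleria cristata* KOCR) and three short-lived non-natives
#' (*Bromus tectorum* BRTE, *Centaurea diffusa* CEDI,
#' *Sisymbrium loeselii* SILO). `landscape_cover` is the fraction of
#' ground each species covers in its origin's home field type
#' (never-tilled fields for natives, abandoned-agricultural fields for
#' non-natives).
#'
#' @return A tibble with columns `code`, `origin`
#'   (`"native"`/`"nonnative"`) and `landscape_cover`.
#' @examples
#' psf_species()
#' @export
psf_species <- function() {
  tibble(
    code = c("PSSP", "FEID", "KOCR", "BRTE", "CEDI", "SILO"),
    origin = rep(c("native", "nonnative"), each = 3),
    landscape_cover = c(0.189, 0.029, 0.002, 0.045, 0.051, 0.030)
  )
}

#' Soil types cultivated in the common-garden experiment
#'
#' One native soil (cultivated by *P. spicata*), three non-native soils
#' (BRTE, CEDI, SILO) and one "mixed" soil cultivated by a mix of target
#' natives and naturally recruiting non-natives.
#'
#' @return Character vector of the five soil type labels.
#' @export
psf_soil_types <- function() psf_soils

#' Default soil cultivated by each species in the simulator
#'
#' All three natives are mapped to the single PSSP-type native soil
#' (growth rates on FEID- and KOCR-cultivated soils were never measured,
#' and the dominant native is assumed to cultivate all native soil);
#' each non-native cultivates its own soil. No species cultivates the
#' Mixed soil, so its proportion decays once soil composition starts
#' tracking plant relative abundance.
#'
#' @return Named character vector, species code -> soil type.
#' @export
species_to_soil_default <- function() {
  c(PSSP = "PSSP", FEID = "PSSP", KOCR = "PSSP",
    BRTE = "BRTE", CEDI = "CEDI", SILO = "SILO")
}

#' Default "self" soil of each species for the null model
#'
#' Species whose monocultures successfully cultivated a soil are mapped
#' to it. FEID and KOCR monocultures failed during the conditioning
#' phase, so no conspecific soil exists for them; they default to the
#' Mixed soil, consistent with the community-level reading of "self"
#' (soil cultivated by any member of the focal community).
#'
#' @return Named character vector, species code -> soil type.
#' @export
self_soil_default <- function() {
  c(PSSP = "PSSP", BRTE = "BRTE", CEDI = "CEDI", SILO = "SILO",
    FEID = "Mixed", KOCR = "Mixed")
}

# origin lookup as a named vector
species_origin <- function() {
  sp <- psf_species()
  setNames(sp$origin, sp$code)
}
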