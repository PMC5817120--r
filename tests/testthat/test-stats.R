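test_that("arcsine square-root transform matches its closed form", {
  expect_equal(transform_cover(0), 0)
  expect_equal(transform_cover(100), pi / 2)
  expect_equal(transform_cover(25), pi / 6)
  # strictly monotone, hence rank-preserving
  x <- seq(0, 100, by = 0.5)
  expect_true(all(diff(transform_cover(x)) > 0))
  expect_error(transform_cover(-1), "\\[0, 100\\]")
  expect_error(transform_cover(101), "\\[0, 100\\]")
})

test_that("one-way F matches the hand-computed sums of squares", {
  # two groups, n = 2: {0.1, 0.2} vs {0.3, 0.4} on the transformed scale
  # SSB = 0.04 (df 1), SSW = 0.01 (df 2) -> F = 8
  split <- default_split()
  fr <- split[split$community == "native", ]
  # choose totals whose transformed values are 0.1, 0.2, 0.3, 0.4
  totals <- 100 * sin(c(0.1, 0.2, 0.3, 0.4))^2
  rows <- purrr::imap(totals, function(tot, i) {
    cover <- setNames(rep(NA_real_, 6), psf_species()$code)
    cover[fr$code] <- tot * fr$fraction
    tibble::tibble(plot_id = paste0("p", i),
                   soil_type = if (i <= 2) "PSSP" else "CEDI",
                   community = "native", !!!as.list(cover))
  }) |> dplyr::bind_rows()
  fit <- soil_treatment_anova(rows, "native")
  expect_equal(fit$f_statistic, 8, tolerance = 1e-10)
  expect_equal(fit$df_num, 1L)
  expect_equal(fit$df_den, 2L)
  # cross-check against stats::aov as an independent route
  y <- c(0.1, 0.2, 0.3, 0.4)
  g <- factor(c("a", "a", "b", "b"))
  ref <- summary(stats::aov(y ~ g))[[1]]
  expect_equal(fit$f_statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(fit$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("identical observations give F = 0 and a single shared letter", {
  plots <- tiny_plots(native_total = c(30, 30), nonnative_total = c(30, 30))
  fit <- soil_treatment_anova(plots, "native")
  expect_equal(fit$f_statistic, 0)
  expect_equal(fit$p_value, 1)
  expect_length(unique(fit$group_means$letters), 1)
})

test_that("zero within-group variance with distinct means is an error", {
  plots <- noise_free_plots()
  expect_error(soil_treatment_anova(plots, "native"), "within-group variance")
})

test_that("soil types need at least two plots", {
  plots <- generate_experiment(seed = 1)
  cell <- plots$soil_type == "CEDI" & plots$community == "native"
  keep_id <- plots$plot_id[cell][1]
  one <- plots[!cell | plots$plot_id == keep_id, ]
  expect_error(soil_treatment_anova(one, "native"), "at least 2 plots")
})

test_that("suppressed soils earn their own letter on the default fixture", {
  plots <- generate_experiment(seed = 21)
  nat <- soil_treatment_anova(plots, "native")
  gm <- nat$group_means
  cedi <- gm$letters[gm$soil_type == "CEDI"]
  others <- gm$letters[gm$soil_type != "CEDI"]
  # CEDI shares no letter with any other soil
  expect_true(all(!purrr::map_lgl(
    others, ~ any(strsplit(cedi, "")[[1]] %in% strsplit(.x, "")[[1]])
  )))
  expect_lt(nat$p_value, 0.001)
  expect_equal(nat$df_num, 4L)
  expect_equal(nat$df_den, 120L)
  # and the suppressed soil has the smallest back-transformed mean
  expect_equal(gm$soil_type[which.min(gm$mean_cover)], "CEDI")
})

test_that("compact letters are maximal cliques of the non-significance graph", {
  p <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p["A", "B"] <- p["B", "A"] <- 0.30
  p["B", "C"] <- p["C", "B"] <- 0.20
  p["A", "C"] <- p["C", "A"] <- 0.01
  letts <- cld_letters(p, c(A = 3, B = 2, C = 1), alpha = 0.05)
  expect_equal(letts, c(A = "a", B = "ab", C = "b"))
  # all pairwise significant -> all distinct letters
  p2 <- matrix(0.001, 3, 3, dimnames = dimnames(p))
  diag(p2) <- 1
  expect_equal(unname(cld_letters(p2, c(A = 3, B = 2, C = 1))),
               c("a", "b", "c"))
  # nothing significant -> one shared letter
  p3 <- matrix(0.9, 3, 3, dimnames = dimnames(p))
  expect_equal(unname(cld_letters(p3, c(A = 3, B = 2, C = 1))),
               c("a", "a", "a"))
})

test_that("two-way interaction F matches an independent ANOVA", {
  sv <- generate_survey(n_sites = 6, years = 3, seed = 2)
  res <- survey_origin_by_distance(sv)
  # independent route: stats::aov on the same site x distance means
  transect <- sv |>
    dplyr::summarise(native = mean(native_cover),
                     nonnative = mean(nonnative_cover),
                     .by = c(site_id, distance_m)) |>
    tidyr::pivot_longer(c(native, nonnative), names_to = "origin",
                        values_to = "cover") |>
    dplyr::mutate(y = transform_cover(cover),
                  origin = factor(origin),
                  distance = factor(distance_m),
                  site = factor(site_id))
  ref <- summary(stats::aov(y ~ site + origin * distance, data = transect))[[1]]
  expect_equal(res$interaction_f, ref["origin:distance", "F value"],
               tolerance = 1e-10)
  expect_equal(res$interaction_p, ref["origin:distance", "Pr(>F)"],
               tolerance = 1e-10)
  expect_equal(res$interaction_df[1], ref["origin:distance", "Df"])
  expect_equal(res$interaction_df[2], ref["Residuals", "Df"])
})

test_that("identical origins give a null interaction and no contrasts", {
  sv <- generate_survey(n_sites = 4, years = 2, dispersion = 0, seed = 1,
                        means = tibble::tibble(
                          distance_m = c(-50, -5, 5, 50),
                          native_mean = c(10, 20, 30, 40),
                          nonnative_mean = c(10, 20, 30, 40)
                        ))
  res <- survey_origin_by_distance(sv)
  expect_equal(res$interaction_f, 0)
  expect_false(any(res$contrasts$significant))
})

test_that("default survey yields the interaction and dominance switch", {
  sv <- generate_survey(seed = 9)
  res <- survey_origin_by_distance(sv)
  expect_lt(res$interaction_p, 0.001)
  ct <- res$contrasts
  expect_true(all(ct$significant))
  # difference is native - non-native on the transformed scale
  expect_lt(ct$difference[ct$distance_m == -50], 0)
  expect_gt(ct$difference[ct$distance_m == 5], 0)
  expect_gt(ct$difference[ct$distance_m == 50], 0)
})

test_that("sites missing a distance class are dropped with a warning", {
  sv <- generate_survey(n_sites = 5, years = 2, seed = 3)
  sv <- sv[!(sv$site_id == "S001" & sv$distance_m == -5), ]
  expect_warning(res <- survey_origin_by_distance(sv), "S001")
  expect_equal(res$n_sites, 4)
})

test_that("tidiers expose the fitted quantities", {
  plots <- generate_experiment(seed = 1)
  fit <- soil_treatment_anova(plots, "nonnative")
  td <- generics::tidy(fit)
  gl <- generics::glance(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  expect_named(gl, c("community", "f_statistic", "df_num", "df_den", "p_value"))
  sv <- generate_survey(seed = 1)
  st <- survey_origin_by_distance(sv)
  expect_equal(nrow(generics::tidy(st)), 4)
  expect_equal(generics::glance(st)$n_sites, 25)
})
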