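test_that("effective rates are the soil-weighted average of the row", {
  m <- matrix(1, 6, 5, dimnames = list(psf_species()$code, psf_soil_types()))
  m["PSSP", ] <- c(1.2, 0.8, 1.0, 1.0, 1.0)
  m["CEDI", ] <- c(1.01, 1.02, 1.03, 1.04, 1.05)
  rt <- rate_table(m)

  # single soil at proportion 1 -> that cell's rate exactly
  soil1 <- c(PSSP = 1, BRTE = 0, CEDI = 0, SILO = 0, Mixed = 0)
  expect_identical(effective_rates(rt, soil1)[["PSSP"]], 1.2)

  # 0.5/0.5 mix of rates 1.2 and 0.8 -> 1.0
  soil2 <- c(PSSP = 0.5, BRTE = 0.5, CEDI = 0, SILO = 0, Mixed = 0)
  expect_equal(effective_rates(rt, soil2)[["PSSP"]], 1.0)

  # arbitrary mix equals the explicit dot product
  w <- c(PSSP = 0.25, BRTE = 0.30, CEDI = 0.25, SILO = 0.20, Mixed = 0)
  eff <- effective_rates(rt, w)
  for (sp in rownames(m)) {
    expect_equal(eff[[sp]], sum(w[colnames(m)] * m[sp, ]), tolerance = 1e-12)
  }

  # feedback off returns the null rates regardless of soil
  off <- effective_rates(rt, w, feedback = FALSE)
  expect_identical(off, setNames(rt$null_rates$rate, rt$null_rates$species))

  expect_error(effective_rates(rt, w[1:3]), "every soil type")
})

test_that("group capacity caps rescale proportionally and independently", {
  k <- capacities(0.42, 0.41)
  # native proposals total 0.6 -> rescaled by 0.7
  prop <- c(PSSP = 0.4, FEID = 0.15, KOCR = 0.05)
  expect_equal(apply_capacity(prop, k),
               c(PSSP = 0.28, FEID = 0.105, KOCR = 0.035), tolerance = 1e-15)
  # below both caps -> identity
  small <- c(PSSP = 0.1, BRTE = 0.2)
  expect_identical(apply_capacity(small, k), small)
  # groups capped independently: non-natives untouched while natives rescale
  both <- c(PSSP = 0.5, FEID = 0.1, BRTE = 0.2, CEDI = 0.1)
  capped <- apply_capacity(both, k)
  expect_equal(sum(capped[c("PSSP", "FEID")]), 0.42, tolerance = 1e-12)
  expect_identical(capped[c("BRTE", "CEDI")], both[c("BRTE", "CEDI")])
  # rescaling preserves within-group ratios
  expect_equal(capped[["PSSP"]] / capped[["FEID"]], 5, tolerance = 1e-12)
  expect_error(apply_capacity(c(PSSP = -0.1), k), "non-negative")
})

test_that("soil proportions equal cultivating-plant relative abundance", {
  prev <- c(PSSP = 0.2, BRTE = 0.2, CEDI = 0.2, SILO = 0.2, Mixed = 0.2)
  # one species present -> its soil gets everything
  s1 <- update_soils(c(PSSP = 0.3, BRTE = 0, CEDI = 0, SILO = 0, FEID = 0,
                       KOCR = 0), previous = prev)
  expect_equal(s1[["PSSP"]], 1)
  expect_equal(sum(s1), 1, tolerance = 1e-12)
  # normalisation arithmetic
  s2 <- update_soils(c(PSSP = 0.1, CEDI = 0.3), previous = prev)
  expect_equal(s2[["PSSP"]], 0.25, tolerance = 1e-15)
  expect_equal(s2[["CEDI"]], 0.75, tolerance = 1e-15)
  # FEID and KOCR cultivate the PSSP-type native soil by default
  s3 <- update_soils(c(FEID = 0.1, KOCR = 0.1, BRTE = 0.2), previous = prev)
  expect_equal(s3[["PSSP"]], 0.5, tolerance = 1e-15)
  expect_equal(s3[["BRTE"]], 0.5, tolerance = 1e-15)
  # zero total holds the previous state, with a warning
  expect_warning(s4 <- update_soils(c(PSSP = 0), previous = prev), "zero")
  expect_identical(s4, prev)
})

test_that("all rates 1 is a fixed point of the simulation", {
  rt <- flat_rate_table(rate = 1)
  traj <- simulate_community(rt, capacities(0.42, 0.41),
                             c(PSSP = 0.5, CEDI = 0.5), n_steps = 30)
  cov <- dplyr::filter(traj, quantity == "cover")
  expect_true(all(cov$value == 0.004))
})

test_that("single-soil growth matches the exponential closed form", {
  r <- step_rate(0.3, 0.004, 55)
  rt <- single_species_table("PSSP", r)
  traj <- simulate_community(
    rt, unbounded_capacities(), c(PSSP = 1),
    n_steps = 55, initial_cover = c(PSSP = 0.004)
  )
  cov <- dplyr::filter(traj, quantity == "cover", name == "PSSP")
  expect_equal(cov$value, 0.004 * r^(0:55), tolerance = 1e-9)
  expect_equal(final_cover(traj)[["PSSP"]], 0.3, tolerance = 1e-9)
})

test_that("soil-invariant rate rows make the feedback model equal the null", {
  rt <- derive_rate_table(
    tiny_plots(native_total = c(25, 35), nonnative_total = c(20, 30))
  )
  init <- c(PSSP = 0.25, BRTE = 0.25, CEDI = 0.25, SILO = 0.25)
  k <- capacities(0.42, 0.41)
  a <- simulate_community(rt, k, init, n_steps = 165, feedback = TRUE)
  b <- simulate_community(rt, k, init, n_steps = 165, feedback = FALSE)
  expect_identical(a$value, b$value)
})

test_that("simulations are bit-reproducible and respect all invariants", {
  plots <- generate_experiment(seed = 31)
  rt <- derive_rate_table(plots)
  k <- derive_capacities(plots)
  init <- c(PSSP = 0.36, BRTE = 0.2286, CEDI = 0.2591, SILO = 0.1523)
  for (mode in c("pot", "group", "damped")) {
    t1 <- simulate_community(rt, k, init, capacity_mode = mode)
    t2 <- simulate_community(rt, k, init, capacity_mode = mode)
    expect_identical(t1$value, t2$value)
    soil_sums <- t1 |>
      dplyr::filter(quantity == "soil") |>
      dplyr::summarise(s = sum(value), .by = step)
    expect_true(all(abs(soil_sums$s - 1) <= 1e-9))
    cov <- dplyr::filter(t1, quantity == "cover")
    expect_true(all(cov$value >= 0))
    gt <- group_totals(t1)
    expect_true(all(gt$total[gt$origin == "native"] <= k$k_native + 1e-9))
    expect_true(all(gt$total[gt$origin == "nonnative"] <= k$k_nonnative + 1e-9))
  }
})

test_that("a uniformly faster species never falls behind an equal start", {
  m <- matrix(1, 6, 5, dimnames = list(psf_species()$code, psf_soil_types()))
  m["PSSP", ] <- c(1.06, 1.05, 1.04, 1.05, 1.06) # strictly above FEID
  m["FEID", ] <- c(1.05, 1.04, 1.03, 1.04, 1.05)
  rt <- rate_table(m)
  for (mode in c("pot", "group", "damped")) {
    traj <- simulate_community(rt, capacities(0.3, 0.3),
                               c(PSSP = 0.5, CEDI = 0.5),
                               capacity_mode = mode, n_steps = 165)
    wide <- traj |>
      dplyr::filter(quantity == "cover", name %in% c("PSSP", "FEID")) |>
      tidyr::pivot_wider(names_from = name, values_from = value)
    expect_true(all(wide$PSSP >= wide$FEID))
  }
})

test_that("seasonal soil updates hold soils fixed within a season", {
  plots <- noise_free_plots()
  rt <- derive_rate_table(plots)
  k <- derive_capacities(plots)
  init <- c(PSSP = 0.25, BRTE = 0.2679, CEDI = 0.3036, SILO = 0.1785)
  traj <- simulate_community(rt, k, init, n_steps = 165,
                             soil_update = "season")
  soils <- traj |>
    dplyr::filter(quantity == "soil") |>
    tidyr::pivot_wider(names_from = name, values_from = value)
  # constant over steps 0..54, then updated
  first_season <- soils[soils$step <= 54, psf_soil_types()]
  expect_true(all(vapply(first_season, function(x) max(x) - min(x) == 0,
                         logical(1))))
  expect_false(isTRUE(all.equal(unlist(soils[soils$step == 55, psf_soil_types()]),
                                unlist(soils[soils$step == 54, psf_soil_types()]))))
  # per-step updates change soils from the first step
  traj2 <- simulate_community(rt, k, init, n_steps = 2, soil_update = "step")
  s2 <- traj2 |>
    dplyr::filter(quantity == "soil") |>
    tidyr::pivot_wider(names_from = name, values_from = value)
  expect_false(isTRUE(all.equal(unlist(s2[s2$step == 1, psf_soil_types()]),
                                unlist(s2[s2$step == 0, psf_soil_types()]))))
})

test_that("simulator validates its configuration", {
  rt <- flat_rate_table()
  k <- capacities(0.42, 0.41)
  expect_error(simulate_community(rt, k, c(PSSP = 0.5)), "sum to 1")
  expect_error(simulate_community(rt, k, c(XXXX = 1)), "unknown soil")
  expect_error(simulate_community(rt, k, c(PSSP = 1), n_steps = 0), ">= 1")
  expect_error(capacities(0, 0.4), "\\(0, 1\\]")
})
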