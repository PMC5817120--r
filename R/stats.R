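#' Arcsine square-root transform for percent cover
#'
#' The variance-stabilising transform applied to all percent-cover
#' responses before ANOVA: `asin(sqrt(cover/100))`, in radians. Strictly
#' monotone on \[0, 100\], so group rank order is preserved.
#'
#' @param cover_percent Numeric vector of percent cover values in
#'   \[0, 100\].
#' @return Numeric vector of transformed values in \[0, pi/2\].
#' @examples
#' transform_cover(c(0, 25, 100)) # 0, pi/6, pi/2
#' @export
transform_cover <- function(cover_percent) {
  if (any(is.na(cover_percent))) {
    abort("`cover_percent` must not contain missing values.")
  }
  if (any(cover_percent < 0 | cover_percent > 100)) {
    abort("`cover_percent` must lie in [0, 100].")
  }
  asin(sqrt(cover_percent / 100))
}

# inverse of transform_cover, back to percent
back_transform_cover <- function(x) 100 * sin(x)^2

# long (plot, species, cover) view of a wide experiment table
experiment_long <- function(plots) {
  sp <- intersect(psf_species()$code, names(plots))
  plots |>
    pivot_longer(all_of(sp), names_to = "species", values_to = "cover") |>
    filter(!is.na(.data$cover))
}

# per-plot community totals on the percent scale
community_totals <- function(plots) {
  experiment_long(plots) |>
    summarise(total = sum(.data$cover),
              .by = c("plot_id", "soil_type", "community"))
}

#' Compact letter display from a matrix of pairwise p-values
#'
#' Groups sharing a letter are not significantly different at `alpha`.
#' Letters are the maximal cliques of the non-significance graph
#' (computed exactly by subset enumeration; group counts here are <= 5),
#' so every non-significant pair shares at least one letter and no
#' significant pair shares any. Cliques are lettered in order of their
#' best (largest) group mean, and groups are reported in descending mean
#' order.
#'
#' @param p_matrix Symmetric matrix of pairwise p-values with group
#'   names as dimnames.
#' @param means Named vector of group means (same groups), used only for
#'   ordering.
#' @param alpha Significance level, default 0.05.
#' @return Named character vector of letter strings, in descending mean
#'   order.
#' @export
cld_letters <- function(p_matrix, means, alpha = 0.05) {
  groups <- names(sort(means, decreasing = TRUE))
  k <- length(groups)
  nonsig <- function(a, b) p_matrix[a, b] >= alpha
  # all maximal cliques of the non-significance graph
  cliques <- list()
  for (bits in seq_len(2^k) - 1L) {
    members <- groups[bitwAnd(bits, 2^(seq_len(k) - 1L)) > 0]
    if (length(members) == 0) next
    ok <- TRUE
    if (length(members) > 1) {
      prs <- utils::combn(members, 2)
      ok <- all(apply(prs, 2, function(p) nonsig(p[1], p[2])))
    }
    if (!ok) next
    # maximal: no outside group compatible with all members
    outside <- setdiff(groups, members)
    extendable <- any(vapply(
      outside,
      function(o) all(vapply(members, function(m) nonsig(o, m), logical(1))),
      logical(1)
    ))
    if (!extendable) cliques[[length(cliques) + 1]] <- members
  }
  # letter cliques by the rank of their best member
  best <- vapply(cliques, function(cl) min(match(cl, groups)), numeric(1))
  cliques <- cliques[order(best)]
  letters_out <- setNames(rep("", k), groups)
  for (i in seq_along(cliques)) {
    for (g in cliques[[i]]) {
      letters_out[g] <- paste0(letters_out[g], letters[i])
    }
  }
  letters_out
}

#' One-way ANOVA of community cover across soil treatments
#'
#' Tests whether a community's total percent cover differs among the
#' five cultivated-soil treatments: plot-level community totals are
#' arcsine square-root transformed and analysed as a completely
#' randomised one-way fixed-effects design, followed by pairwise
#' comparisons (Tukey HSD by default) summarised as a compact letter
#' display at `alpha`.
#'
#' @param plots Experiment table as returned by [generate_experiment()].
#' @param community `"native"` or `"nonnative"`.
#' @param adjust `"tukey"` (Tukey HSD, default) or `"none"` (unadjusted
#'   pairwise t-tests on the pooled residual variance).
#' @param alpha Significance level for the letter display.
#' @return An object of class `psf_anova`: a list with elements
#'   `f_statistic`, `df_num`, `df_den`, `p_value`, `group_means`
#'   (tibble of per-soil back-transformed means, SE on the transformed
#'   scale, n, letters) and `community`. Has [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @examples
#' plots <- generate_experiment(seed = 1)
#' fit <- soil_treatment_anova(plots, "native")
#' generics::glance(fit)
#' @export
soil_treatment_anova <- function(plots, community = c("native", "nonnative"),
                                 adjust = c("tukey", "none"), alpha = 0.05) {
  community <- match.arg(community)
  adjust <- match.arg(adjust)
  dat <- community_totals(plots) |>
    filter(.data$community == !!community) |>
    mutate(y = transform_cover(.data$total),
           soil_type = factor(.data$soil_type, levels = psf_soils))
  counts <- count(dat, .data$soil_type, .drop = TRUE)
  if (any(counts$n < 2)) {
    abort("Each soil type needs at least 2 plots for the chosen community.")
  }
  dat$soil_type <- droplevels(dat$soil_type)
  k <- nlevels(dat$soil_type)
  n_tot <- nrow(dat)

  grand <- mean(dat$y)
  cell <- dat |>
    summarise(m = mean(.data$y), n = n(), s2 = stats::var(.data$y),
              .by = "soil_type")
  ss_between <- sum(cell$n * (cell$m - grand)^2)
  ss_within <- sum((cell$n - 1) * cell$s2)
  df_num <- k - 1L
  df_den <- n_tot - k

  if (ss_within <= 0 && ss_between <= 0) {
    # degenerate: every observation identical
    f <- 0
    p <- 1
    pmat <- matrix(1, k, k, dimnames = list(levels(dat$soil_type),
                                            levels(dat$soil_type)))
  } else if (ss_within <= 0) {
    abort("Zero within-group variance: F statistic undefined.")
  } else {
    f <- (ss_between / df_num) / (ss_within / df_den)
    p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
    pmat <- pairwise_p(dat, adjust)
  }

  means <- setNames(cell$m, as.character(cell$soil_type))
  letts <- cld_letters(pmat, means, alpha)
  mse <- if (df_den > 0 && ss_within > 0) ss_within / df_den else 0
  group_means <- cell |>
    mutate(
      soil_type = as.character(.data$soil_type),
      mean_cover = back_transform_cover(.data$m),
      se_transformed = sqrt(mse / .data$n),
      letters = unname(letts[.data$soil_type])
    ) |>
    arrange(desc(.data$m)) |>
    select("soil_type", "mean_cover", mean_transformed = "m",
           "se_transformed", "n", "letters")

  structure(
    list(f_statistic = f, df_num = df_num, df_den = df_den, p_value = p,
         group_means = group_means, community = community,
         adjust = adjust, alpha = alpha),
    class = "psf_anova"
  )
}

# pairwise p-value matrix on the transformed scale
pairwise_p <- function(dat, adjust) {
  fit <- aov(y ~ soil_type, data = dat)
  lev <- levels(dat$soil_type)
  pmat <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  diag(pmat) <- 1
  if (adjust == "tukey") {
    tk <- TukeyHSD(fit, "soil_type")$soil_type
    for (nm in rownames(tk)) {
      ab <- strsplit(nm, "-", fixed = TRUE)[[1]]
      pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- tk[nm, "p adj"]
    }
  } else {
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    cell <- dat |> summarise(m = mean(.data$y), n = n(), .by = "soil_type")
    for (i in seq_along(lev)) {
      for (j in seq_along(lev)) {
        if (i >= j) next
        a <- cell[cell$soil_type == lev[i], ]
        b <- cell[cell$soil_type == lev[j], ]
        se <- sqrt(mse * (1 / a$n + 1 / b$n))
        tval <- (a$m - b$m) / se
        pv <- 2 * stats::pt(abs(tval), fit$df.residual, lower.tail = FALSE)
        pmat[lev[i], lev[j]] <- pmat[lev[j], lev[i]] <- pv
      }
    }
  }
  pmat
}

#' @export
print.psf_anova <- function(x, ...) {
  cat(sprintf(
    "One-way soil-treatment ANOVA (%s community, arcsine sqrt scale)\n",
    x$community
  ))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df_num, x$df_den,
              x$f_statistic, x$p_value))
  print(x$group_means)
  invisible(x)
}

#' Origin-by-distance analysis of the landscape survey
#'
#' Reproduces the survey analysis: records are averaged across years
#' within each site x distance transect, transformed, and analysed as a
#' two-way fixed-effects factorial (plant origin x distance from tillage
#' boundary) with site as a blocking factor. The origin effect within
#' each distance class is then tested with paired (by site) contrasts.
#'
#' @param records Survey table as returned by [generate_survey()].
#' @param alpha Significance level for the per-distance contrasts.
#' @return An object of class `psf_survey_test`: a list with
#'   `interaction_f`, `interaction_df`, `interaction_p`, and `contrasts`
#'   (a tibble with one row per distance class: difference of
#'   transformed means (native - non-native), `p_value`, `significant`).
#' @examples
#' sv <- generate_survey(seed = 1)
#' survey_origin_by_distance(sv)
#' @export
survey_origin_by_distance <- function(records, alpha = 0.05) {
  needed <- c(-50, -5, 5, 50)
  records <- as_tibble(records)
  if (length(unique(records$site_id)) < 2 ||
      !all(needed %in% records$distance_m)) {
    abort("`records` must span at least 2 sites and all four distance classes.")
  }
  transect <- records |>
    summarise(native = mean(.data$native_cover),
              nonnative = mean(.data$nonnative_cover),
              .by = c("site_id", "distance_m"))
  complete_sites <- transect |>
    count(.data$site_id) |>
    filter(.data$n == length(needed))
  dropped <- setdiff(unique(transect$site_id), complete_sites$site_id)
  if (length(dropped) > 0) {
    warn(paste0("Dropping site(s) missing a distance class: ",
                paste(dropped, collapse = ", ")))
    transect <- filter(transect, .data$site_id %in% complete_sites$site_id)
  }

  long <- transect |>
    pivot_longer(c("native", "nonnative"),
                 names_to = "origin", values_to = "cover") |>
    mutate(
      y = transform_cover(.data$cover),
      origin = factor(.data$origin, levels = c("native", "nonnative")),
      distance = factor(.data$distance_m, levels = needed),
      site = factor(.data$site_id)
    )

  ss <- two_way_blocked_ss(long)
  if (ss$ss_res <= 0 && ss$ss_int <= 0) {
    f_int <- 0
    p_int <- 1
  } else if (ss$ss_res <= 0) {
    abort("Zero residual variance: interaction F undefined.")
  } else {
    f_int <- (ss$ss_int / ss$df_int) / (ss$ss_res / ss$df_res)
    p_int <- stats::pf(f_int, ss$df_int, ss$df_res, lower.tail = FALSE)
  }

  contrasts <- purrr::map(needed, function(d) {
    sub <- transect |> filter(.data$distance_m == d)
    dn <- transform_cover(sub$native)
    dx <- transform_cover(sub$nonnative)
    diffs <- dn - dx
    if (stats::sd(diffs) == 0) {
      pv <- if (all(diffs == 0)) 1 else 0
    } else {
      pv <- t.test(dn, dx, paired = TRUE)$p.value
    }
    tibble(distance_m = d, difference = mean(diffs), p_value = pv,
           significant = pv < alpha)
  }) |>
    list_rbind()

  structure(
    list(interaction_f = f_int, interaction_df = c(ss$df_int, ss$df_res),
         interaction_p = p_int, contrasts = contrasts,
         n_sites = length(unique(long$site)), alpha = alpha),
    class = "psf_survey_test"
  )
}

# classical sums of squares for the balanced site-blocked two-way design
two_way_blocked_ss <- function(long) {
  grand <- mean(long$y)
  n <- nrow(long)
  m_o <- long |> summarise(m = mean(.data$y), n = n(), .by = "origin")
  m_d <- long |> summarise(m = mean(.data$y), n = n(), .by = "distance")
  m_s <- long |> summarise(m = mean(.data$y), n = n(), .by = "site")
  m_od <- long |> summarise(m = mean(.data$y), n = n(),
                            .by = c("origin", "distance"))
  ss_o <- sum(m_o$n * (m_o$m - grand)^2)
  ss_d <- sum(m_d$n * (m_d$m - grand)^2)
  ss_s <- sum(m_s$n * (m_s$m - grand)^2)
  cell <- m_od |>
    left_join(m_o, by = "origin", suffix = c("", "_o")) |>
    left_join(m_d, by = "distance", suffix = c("", "_d"))
  ss_int <- sum(cell$n * (cell$m - cell$m_o - cell$m_d + grand)^2)
  ss_tot <- sum((long$y - grand)^2)
  ss_res <- ss_tot - ss_o - ss_d - ss_s - ss_int
  a <- nlevels(long$origin)
  b <- nlevels(long$distance)
  s <- nlevels(long$site)
  list(
    ss_int = ss_int, ss_res = max(ss_res, 0),
    df_int = (a - 1) * (b - 1),
    df_res = n - 1 - (a - 1) - (b - 1) - (s - 1) - (a - 1) * (b - 1)
  )
}

#' @export
print.psf_survey_test <- function(x, ...) {
  cat("Origin x distance analysis of transect means (arcsine sqrt scale)\n")
  cat(sprintf("  interaction F(%d, %d) = %.4g, p = %.4g  [%d sites]\n",
              x$interaction_df[1], x$interaction_df[2], x$interaction_f,
              x$interaction_p, x$n_sites))
  print(x$contrasts)
  invisible(x)
}
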