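# The statistical layer: per-trait three-way ANOVA with block, the sector
# mixed model with contrasts, and their supporting tables.

#' Per-plant sector aggregates for the mixed model
#'
#' Long table of sector responses per plant, compartment scope and variable:
#' shares of volume, length and axis number (%), plus per-sector axis means
#' (diameter, length, volume, angle to soil surface, branching angle) and
#' the mean branching order. Scopes are `all` laterals, the pooled
#' compartments, and `shallow` (ZRT + beyond combined, the classical
#' horizontal shallow group).
#'
#' @param cohort A [generate_cohort()] result or list of root systems.
#' @param ... Passed to [classify_compartments()] via [sector_shares()].
#' @return A tibble: `plant_id`, `group`, `compartment`, `variable`,
#'   `sector`, `value`.
#' @export
sector_table <- function(cohort, ...) {
  systems <- if (!is.null(cohort$systems)) cohort$systems else cohort
  rows <- purrr::map(systems, function(rs) {
    grp <- paste0(ifelse(rs$slope_deg > 0, "slope", "flat"), "_",
                  ifelse(rs$flexed, "flexed", "unflexed"))
    ss <- sector_shares(rs, ...)
    shares <- tidyr::pivot_longer(
      ss[, c("compartment", "sector", "volume_share", "length_share", "n_share")],
      cols = c("volume_share", "length_share", "n_share"),
      names_to = "variable", values_to = "value"
    )
    # per-sector axis means over lateral axes
    ag <- axis_geometry(rs)
    lat <- dplyr::filter(ag, .data$order > 1L, !is.na(.data$sector))
    ax_means <- if (nrow(lat) > 0) {
      comp_of <- function(d) {
        dplyr::bind_rows(
          dplyr::mutate(d, compartment = "all"),
          dplyr::mutate(d, compartment = dplyr::case_when(
            .data$depth_class == "shallow" ~ "shallow",
            .data$depth_class == "intermediate" ~ "intermediate",
            TRUE ~ "deep"
          ))
        )
      }
      long <- tidyr::pivot_longer(
        dplyr::transmute(comp_of(lat),
          compartment = .data$compartment, sector = .data$sector,
          mean_axis_diameter_cm = .data$mean_diameter * 100,
          mean_axis_length_cm = .data$length * 100,
          mean_axis_volume_cm3 = .data$volume * 1e6,
          angle_to_soil_deg = .data$angle_to_soil,
          branching_angle_deg = .data$branching_angle
        ),
        cols = -c("compartment", "sector"),
        names_to = "variable", values_to = "value"
      )
      dplyr::summarise(
        dplyr::group_by(long, .data$compartment, .data$variable, .data$sector),
        value = mean(.data$value, na.rm = TRUE), .groups = "drop"
      )
    } else NULL
    mbo_rows <- purrr::map(c("us", "pp", "ds"), function(sec) {
      tibble::tibble(compartment = "all", variable = "mbo", sector = sec,
                     value = mbo(rs, "total", TRUE, sector = sec))
    })
    out <- dplyr::bind_rows(shares, ax_means, dplyr::bind_rows(mbo_rows))
    dplyr::mutate(out, plant_id = rs$plant_id, group = grp, .before = 1)
  })
  dplyr::bind_rows(rows)
}

stars_at <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 1e-4 ~ "****", p < 1e-3 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Three-way ANOVA (slope, flexing, their interaction, block) per trait
#'
#' For every trait column a linear model
#' `trait ~ slope + flexing + slope:flexing + block` is fitted. Residual
#' normality is checked with the Shapiro test at `alpha_shapiro`; on
#' failure the trait is log-transformed (when strictly positive) and then
#' rank-transformed if residuals are still non-normal. Significance is
#' taken from sequential (Type I) sums of squares in the stated model
#' order, appropriate for balanced cohorts; `ss_type = "II"` switches to
#' Type II for unbalanced ones. Group means and the % variation relative
#' to the control are always computed from the untransformed variable.
#'
#' @param tt A trait table from [build_trait_table()] (metadata columns
#'   `slope`, `flexing`, `block`).
#' @param traits Character vector of trait columns (default: all numeric
#'   non-metadata columns).
#' @param alpha_shapiro Normality threshold for the transform ladder.
#' @param ss_type `"I"` (sequential, default) or `"II"`.
#' @return A tibble with one row per analysed trait: transform used,
#'   p-values and stars for Slope, Flexing, Slope x Flexing and Block,
#'   per-group means and % variation vs control. Constant or all-missing
#'   traits are skipped with `note = "skipped"`.
#' @export
anova_by_trait <- function(tt, traits = NULL, alpha_shapiro = 0.05,
                           ss_type = c("I", "II")) {
  ss_type <- match.arg(ss_type)
  meta_cols <- c("plant_id", "slope", "flexing", "block")
  if (!all(meta_cols %in% names(tt))) {
    rlang::abort("trait table must carry plant_id, slope, flexing, block")
  }
  if (is.null(traits)) {
    traits <- setdiff(names(tt)[vapply(tt, is.numeric, logical(1))], meta_cols)
  }
  cells <- table(tt$slope, tt$flexing)
  if (any(cells < 2)) {
    rlang::warn("fewer than 2 plants in at least one slope x flexing cell")
  }
  rows <- purrr::map(traits, function(tr) {
    d <- tt[, c(meta_cols, tr)]
    names(d)[5] <- "y"
    d <- d[stats::complete.cases(d$y), ]
    base <- tibble::tibble(trait = tr, n = nrow(d))
    if (nrow(d) < 8 || dplyr::n_distinct(d$y) < 2) {
      return(dplyr::mutate(base, transform = NA_character_, note = "skipped"))
    }
    fit_one <- function(y_val) {
      d2 <- d
      d2$y <- y_val
      stats::lm(y ~ slope + flexing + slope:flexing + block, data = d2)
    }
    transform <- "none"
    fit <- fit_one(d$y)
    sw <- function(f) {
      r <- stats::residuals(f)
      if (dplyr::n_distinct(r) < 3) return(0)
      stats::shapiro.test(r)$p.value
    }
    shapiro_p <- sw(fit)
    if (shapiro_p < alpha_shapiro && all(d$y > 0)) {
      transform <- "log"
      fit <- fit_one(log(d$y))
      shapiro_p <- sw(fit)
    }
    if (shapiro_p < alpha_shapiro) {
      transform <- "rank"
      fit <- fit_one(rank(d$y))
      shapiro_p <- sw(fit)
    }
    pv <- if (ss_type == "I") {
      a <- suppressWarnings(stats::anova(fit))
      stats::setNames(a[["Pr(>F)"]], rownames(a))
    } else {
      # Type II: each term against the model dropping it (main effects
      # adjusted for each other, interaction last)
      a <- stats::drop1(stats::update(fit, . ~ slope + flexing + block),
                        scope = ~ slope + flexing + block, test = "F")
      ia <- stats::anova(fit)
      c(slope = a["slope", "Pr(>F)"], flexing = a["flexing", "Pr(>F)"],
        block = a["block", "Pr(>F)"],
        `slope:flexing` = ia["slope:flexing", "Pr(>F)"])
    }
    gm <- dplyr::summarise(
      dplyr::group_by(d, .data$slope, .data$flexing),
      m = mean(.data$y), .groups = "drop"
    )
    cell <- function(s, f) {
      x <- gm$m[gm$slope == s & gm$flexing == f]
      if (length(x) == 0) NA_real_ else x
    }
    m_ctl <- cell("0", "no"); m_slp <- cell("45", "no")
    m_flx <- cell("0", "yes"); m_sf <- cell("45", "yes")
    pct <- function(m) if (!is.na(m_ctl) && m_ctl != 0) 100 * (m - m_ctl) / m_ctl else NA_real_
    tibble::tibble(
      trait = tr, n = nrow(d), transform = transform, note = "",
      shapiro_p = shapiro_p,
      p_slope = pv[["slope"]], p_flexing = pv[["flexing"]],
      p_interaction = pv[["slope:flexing"]], p_block = pv[["block"]],
      stars_slope = stars_at(pv[["slope"]]),
      stars_flexing = stars_at(pv[["flexing"]]),
      stars_interaction = stars_at(pv[["slope:flexing"]]),
      mean_control = m_ctl, mean_slope = m_slp,
      mean_flexing = m_flx, mean_slope_flexed = m_sf,
      pct_var_slope = pct(m_slp), pct_var_flexing = pct(m_flx),
      pct_var_slope_flexed = pct(m_sf)
    )
  })
  dplyr::bind_rows(rows)
}

# compact letter display from a matrix of pairwise p-values (small k)
letter_display <- function(levels, p_pairs, alpha = 0.05) {
  k <- length(levels)
  sig <- function(i, j) {
    p <- p_pairs[[paste(sort(c(levels[i], levels[j])), collapse = "|")]]
    !is.na(p) && p < alpha
  }
  sets <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (all(!vapply(sets[[s]], function(j) sig(i, j), logical(1)))) {
        sets[[s]] <- c(sets[[s]], i)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- i
  }
  # fix-up: every non-significant pair must share a set
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j && !sig(i, j) &&
        !any(vapply(sets, function(s) all(c(i, j) %in% s), logical(1)))) {
      sets[[length(sets) + 1]] <- c(i, j)
    }
  }
  # drop sets wholly contained in another (redundant letters)
  keep <- vapply(seq_along(sets), function(s) {
    !any(vapply(seq_along(sets), function(t) {
      t != s && all(sets[[s]] %in% sets[[t]]) &&
        (length(sets[[t]]) > length(sets[[s]]) || t < s)
    }, logical(1)))
  }, logical(1))
  sets <- sets[keep]
  out <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  stats::setNames(out, levels)
}

#' Sector mixed model with contrasts
#'
#' For each treatment group, compartment scope and variable, fits the mixed
#' model `value ~ sector + (1 | tree)` (REML, Satterthwaite tests) on the
#' per-plant sector responses, reports the fixed-factor test of `sector`
#' and the unadjusted pairwise sector contrasts as a compact letter
#' display. For volume, length and number shares the perpendicular sector
#' value is divided by 2 before testing, since `pp` spans two quadrants
#' while `us` and `ds` span one each. A compartment present in half the
#' plants or fewer is reported `NA`.
#'
#' @param st A [sector_table()].
#' @param alpha Significance level for the letter display.
#' @param halve_pp Halve `pp` for share variables (default TRUE).
#' @return A tibble per group x compartment x variable: `n_plants`,
#'   `p_sector`, sector estimates (`est_us`, `est_pp`, `est_ds`), letters
#'   and pairwise contrast p-values.
#' @export
sector_mixed_model <- function(st, alpha = 0.05, halve_pp = TRUE) {
  share_vars <- c("volume_share", "length_share", "n_share")
  combos <- dplyr::distinct(st, .data$group, .data$compartment, .data$variable)
  n_group <- dplyr::summarise(
    dplyr::group_by(st, .data$group),
    n_total = dplyr::n_distinct(.data$plant_id), .groups = "drop"
  )
  rows <- purrr::pmap(combos, function(group, compartment, variable) {
    d <- st[st$group == group & st$compartment == compartment &
              st$variable == variable, ]
    d <- d[!is.na(d$value), ]
    n_tot <- n_group$n_total[n_group$group == group]
    base <- tibble::tibble(group = group, compartment = compartment,
                           variable = variable,
                           n_plants = dplyr::n_distinct(d$plant_id))
    if (halve_pp && variable %in% share_vars) {
      d$value[d$sector == "pp"] <- d$value[d$sector == "pp"] / 2
    }
    ok <- dplyr::summarise(dplyr::group_by(d, .data$plant_id),
                           full = dplyr::n() == 3, .groups = "drop")
    d <- d[d$plant_id %in% ok$plant_id[ok$full], ]
    n_ok <- dplyr::n_distinct(d$plant_id)
    if (n_ok <= n_tot / 2 || n_ok < 3) {
      return(dplyr::mutate(base, p_sector = NA_real_, note = "NA: too few trees"))
    }
    d$sector <- factor(d$sector, levels = c("us", "pp", "ds"))
    if (stats::sd(d$value) < 1e-12) {
      est <- mean(d$value)
      return(dplyr::mutate(base,
        p_sector = 1, note = "constant",
        est_us = est, est_pp = est, est_ds = est,
        letters_us = "a", letters_pp = "a", letters_ds = "a",
        p_us_pp = 1, p_us_ds = 1, p_pp_ds = 1
      ))
    }
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(value ~ sector + (1 | plant_id), data = d)
    ))
    an <- suppressWarnings(stats::anova(fit))
    p_sector <- an[["Pr(>F)"]][1]
    em <- suppressWarnings(suppressMessages(
      emmeans::emmeans(fit, "sector", lmer.df = "satterthwaite")
    ))
    pr <- as.data.frame(summary(
      emmeans::contrast(em, "pairwise", adjust = "none")
    ))
    emd <- as.data.frame(summary(em))
    getp <- function(a, b) {
      hit <- grepl(a, pr$contrast) & grepl(b, pr$contrast)
      if (any(hit)) pr$p.value[hit][1] else NA_real_
    }
    p_pairs <- list(
      "pp|us" = getp("us", "pp"),
      "ds|us" = getp("us", "ds"),
      "ds|pp" = getp("pp", "ds")
    )
    lett <- if (!is.na(p_sector) && p_sector < alpha) {
      letter_display(c("us", "pp", "ds"), p_pairs, alpha)
    } else {
      c(us = "a", pp = "a", ds = "a")
    }
    dplyr::mutate(base,
      p_sector = p_sector, note = "",
      est_us = emd$emmean[emd$sector == "us"],
      est_pp = emd$emmean[emd$sector == "pp"],
      est_ds = emd$emmean[emd$sector == "ds"],
      letters_us = lett[["us"]], letters_pp = lett[["pp"]],
      letters_ds = lett[["ds"]],
      p_us_pp = p_pairs[["pp|us"]], p_us_ds = p_pairs[["ds|us"]],
      p_pp_ds = p_pairs[["ds|pp"]]
    )
  })
  dplyr::bind_rows(rows)
}
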