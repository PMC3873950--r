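# Per-plant trait assembly: the full architectural trait battery, one row
# per plant, feeding the ANOVA / PCA layer.

# fine roots per segment with the depth group they belong to (order-1 fines
# classified by the bearing segment's tip depth; lateral fines inherit the
# arborescence's origin depth class)
fine_root_table <- function(rs, paths = axis_paths(rs)) {
  cls <- axis_classes(rs, paths)
  rows <- purrr::map(paths, function(p) {
    n <- length(p$segment_ids)
    if (n == 0) return(NULL)
    depth_class <- if (p$order == 1L) {
      classify_depth(p$verts[-1, 3])
    } else {
      rep(cls$depth_class[cls$axis_id == p$axis_id], n)
    }
    tibble::tibble(
      axis_id = p$axis_id, order = p$order,
      segment_id = p$segment_ids,
      count = p$fine_root_count,
      length = p$fine_root_count * p$fine_root_mean_length,
      depth_class = depth_class
    )
  })
  dplyr::bind_rows(rows)
}

# branch positions along the order-1 axis (measured laterals and,
# optionally, fine roots at their bearing segment's tip)
order1_branch_positions <- function(rs, include_fine_roots = TRUE,
                                    paths = axis_paths(rs)) {
  o1 <- order1_axis(paths)
  pos <- purrr::map_dbl(
    purrr::keep(paths, ~ identical(.x$parent_axis, o1$axis_id)), "attach_s"
  )
  pos <- unname(pos)
  if (include_fine_roots) {
    pos <- c(pos, rep(o1$s_bounds[-1], o1$fine_root_count))
  }
  sort(pos)
}

#' Root counts, specific traits and partitioning coefficients
#'
#' Root number (with and without unmeasured fine roots), total root length
#' and volume, specific root length (length / volume), specific root number
#' (number / root dry weight), root density (root dry weight / total
#' volume) and partitioning coefficients. Following the standard convention
#' for container seedlings the stump (first 45 mm of the order-1 root) is
#' excluded from total root volume; root density keeps the full volume
#' since the dry weight includes the stump. Volume-based partitioning
#' coefficients are compartment volume shares scaled by the biomass root
#' partitioning coefficient.
#'
#' @param rs A [root_system()].
#' @param stump_length Stump length, m.
#' @return A one-row tibble of traits (lengths cm, volumes cm^3, density
#'   g cm^-3, coefficients %); mass-based traits are `NA` without dry
#'   weights.
#' @export
counts_and_specifics <- function(rs, stump_length = 0.045) {
  paths <- axis_paths(rs)
  o1 <- order1_axis(paths)
  frt <- fine_root_table(rs, paths)
  lat <- purrr::keep(paths, ~ .x$order > 1L)
  st <- split_stump(rs, stump_length)
  stump_vol <- sum(st$volume[st$part == "stump"]) * 1e6
  o1_vol <- o1$volume * 1e6
  lat_vol <- sum(purrr::map_dbl(lat, "volume")) * 1e6
  lat_len <- sum(purrr::map_dbl(lat, "length")) * 100
  fine_len <- sum(frt$length) * 100
  total_vol_incl <- o1_vol + lat_vol
  total_vol <- total_vol_incl - stump_vol
  total_len <- o1$length * 100 + lat_len
  n_meas <- length(lat)
  n_fine <- sum(frt$count)
  rdw <- rs$root_dry_weight_g
  sdw <- rs$shoot_dry_weight_g
  rpc <- if (!is.na(rdw) && !is.na(sdw)) 100 * rdw / (rdw + sdw) else NA_real_
  tibble::tibble(
    root_number = n_meas,
    root_number_iafr = n_meas + n_fine,
    total_length_cm = total_len,
    total_length_iafr_cm = total_len + fine_len,
    total_volume_cm3 = total_vol,
    total_volume_incl_stump_cm3 = total_vol_incl,
    stump_volume_cm3 = stump_vol,
    srl_cm_cm3 = if (total_vol > 0) total_len / total_vol else NA_real_,
    srl_iafr_cm_cm3 = if (total_vol > 0) (total_len + fine_len) / total_vol else NA_real_,
    srn_n_g = if (!is.na(rdw) && rdw > 0) (n_meas + n_fine) / rdw else NA_real_,
    root_density_g_cm3 = if (!is.na(rdw) && total_vol_incl > 0)
      rdw / total_vol_incl else NA_real_,
    rpc_biomass_pct = rpc,
    rpc_without_order1_pct = if (!is.na(rpc) && total_vol_incl > 0)
      rpc * lat_vol / total_vol_incl else NA_real_,
    taproot_pc_pct = if (!is.na(rpc) && total_vol_incl > 0)
      rpc * (o1_vol - stump_vol) / total_vol_incl else NA_real_,
    stump_pc_pct = if (!is.na(rpc) && total_vol_incl > 0)
      rpc * stump_vol / total_vol_incl else NA_real_
  )
}

#' Full trait battery for one plant
#'
#' Runs the whole per-plant pipeline (wall correction, axis geometry,
#' compartment and sector classification, topology, fractal branching,
#' counts) and returns one wide row. Missing values stay `NA`, never 0.
#'
#' @param rs A [root_system()].
#' @param zrt_limit,stump_length See [classify_compartments()].
#' @param correct_walls Apply [extend_wall_roots()] first (default TRUE).
#' @param include_fine_roots Include fine roots in length/number/topology
#'   traits marked `iafr`.
#' @return A one-row tibble (~70 trait columns).
#' @export
phenotype <- function(rs, zrt_limit = 0.050, stump_length = 0.045,
                      correct_walls = TRUE, include_fine_roots = TRUE) {
  if (correct_walls) rs <- suppressWarnings(extend_wall_roots(rs))
  paths <- axis_paths(rs)
  o1 <- order1_axis(paths)
  ag <- axis_geometry(rs)
  vs <- classify_compartments(rs, zrt_limit = zrt_limit,
                              stump_length = stump_length)
  cs <- counts_and_specifics(rs, stump_length)
  fr <- fractal_params(rs, stump_length = stump_length)
  frt <- fine_root_table(rs, paths)
  ta <- taproot_angle(rs)

  lat <- dplyr::filter(ag, .data$order > 1L)
  o2 <- dplyr::filter(lat, .data$order == 2L)
  fp <- function(scope, var) fr[[var]][fr$scope == scope]

  # compartment volume shares (stump excluded, pooled six-compartment table)
  vol_by <- dplyr::summarise(dplyr::group_by(vs, .data$pooled),
                             v = sum(.data$volume), .groups = "drop")
  vtot_incl <- sum(vol_by$v)
  vstump <- sum(vol_by$v[vol_by$pooled == "stump"])
  vtot <- vtot_incl - vstump
  rv <- function(comp) {
    x <- sum(vol_by$v[vol_by$pooled == comp])
    if (vtot > 0) 100 * x / vtot else NA_real_
  }

  # length / number shares by depth group, fine roots included
  lat_tbl <- dplyr::mutate(lat,
    depth_group = .data$depth_class,
    len_iafr = .data$raw_length +
      if (include_fine_roots) .data$fine_root_length else 0
  )
  fine_o1 <- dplyr::filter(frt, .data$order == 1L)
  grp_len <- function(g) {
    x <- sum(lat_tbl$len_iafr[lat_tbl$depth_group == g]) +
      if (include_fine_roots) sum(fine_o1$length[fine_o1$depth_class == g]) else 0
    x
  }
  grp_n <- function(g) {
    sum(lat_tbl$depth_group == g) +
      if (include_fine_roots) sum(fine_o1$count[fine_o1$depth_class == g]) else 0
  }
  lens <- vapply(c("shallow", "intermediate", "deep"), grp_len, numeric(1))
  ns <- vapply(c("shallow", "intermediate", "deep"), grp_n, numeric(1))
  rl <- if (sum(lens) > 0) 100 * lens / sum(lens) else rep(NA_real_, 3)
  rn <- if (sum(ns) > 0) 100 * ns / sum(ns) else rep(NA_real_, 3)

  # mean axis dimensions by depth group (horizontal laterals, classical
  # compartment tables)
  dim_by <- function(g, var) {
    x <- lat[[var]][lat$depth_class == g & lat$direction_class == "horizontal"]
    if (length(x) == 0) NA_real_ else mean(x, na.rm = TRUE)
  }

  # inter-branch distances on the order-1 axis, split at the stump limit
  bp <- order1_branch_positions(rs, include_fine_roots, paths)
  gap_mean <- function(pos) if (length(pos) >= 2) mean(diff(pos)) else NA_real_
  ill_o2 <- inter_lateral_length(rs, include_fine_roots)
  ill_o2 <- dplyr::filter(ill_o2, .data$order == 2L)

  # sector shares for specific scopes used in multivariate analyses
  ss <- sector_shares(rs, zrt_limit = zrt_limit, stump_length = stump_length)
  pick <- function(comp, sec, var) {
    x <- ss[[var]][ss$compartment == comp & ss$sector == sec]
    if (length(x) == 0) NA_real_ else x
  }
  shallow_vs <- dplyr::filter(vs, .data$pooled %in% c("zrt", "shallow_beyond"),
                              !is.na(.data$sector))
  shallow_pp <- if (nrow(shallow_vs) > 0 && sum(shallow_vs$volume) > 0) {
    100 * sum(shallow_vs$volume[shallow_vs$sector == "pp"]) / sum(shallow_vs$volume)
  } else NA_real_

  muaxe_vol_zrt <- {
    zv <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(vs, .data$pooled == "zrt"), .data$axis_id),
      v = sum(.data$volume), .groups = "drop"
    )
    if (nrow(zv) == 0) NA_real_ else mean(zv$v) * 1e6
  }

  sub_mean <- function(tbl, cond, var) {
    x <- tbl[[var]][cond]
    if (all(is.na(x)) || length(x) == 0) NA_real_ else mean(x, na.rm = TRUE)
  }
  lat_vol <- sum(lat$volume) * 1e6
  lat_len_iafr <- sum(lat_tbl$len_iafr) * 100 +
    if (include_fine_roots) sum(fine_o1$length) * 100 else 0

  tibble::tibble(
    plant_id = rs$plant_id,
    root_dw_g = rs$root_dry_weight_g,
    shoot_dw_g = rs$shoot_dry_weight_g,
    total_dw_g = rs$root_dry_weight_g + rs$shoot_dry_weight_g,
    dw1d = (rs$root_dry_weight_g + rs$shoot_dry_weight_g)^(1 / 3),
    collar_diameter_cm = o1$d_bounds[1] * 100,
    max_radial_distance_cm = max(sqrt(vs$mid_x^2 + vs$mid_y^2)) * 100,
    max_depth_cm = min(vs$mid_z) * 100,
    order1_length_cm = o1$length * 100,
    srl_order1_cm_cm3 = if (o1$volume > 0) o1$length / (o1$volume * 1e6) * 100 else NA_real_,
    srl_laterals_iafr_cm_cm3 = if (lat_vol > 0) lat_len_iafr / lat_vol else NA_real_,
    mean_tip_diameter_cm = sub_mean(lat, lat$order > 1L, "tip_diameter") * 100,
    cs,
    stump_rv_incl_pct = if (vtot_incl > 0) 100 * vstump / vtot_incl else NA_real_,
    rv_taproot_pct = rv("taproot"),
    rv_zrt_pct = rv("zrt"),
    rv_shallow_beyond_pct = rv("shallow_beyond"),
    rv_intermediate_pct = rv("intermediate"),
    rv_deep_pct = rv("deep"),
    rl_shallow_iafr_pct = rl[["shallow"]],
    rl_intermediate_iafr_pct = rl[["intermediate"]],
    rl_deep_iafr_pct = rl[["deep"]],
    rn_shallow_iafr_pct = rn[["shallow"]],
    rn_intermediate_iafr_pct = rn[["intermediate"]],
    rn_deep_iafr_pct = rn[["deep"]],
    mean_axis_length_shallow_cm = dim_by("shallow", "length") * 100,
    mean_axis_length_intermediate_cm = dim_by("intermediate", "length") * 100,
    mean_axis_length_deep_cm = dim_by("deep", "length") * 100,
    mean_axis_diameter_shallow_cm = dim_by("shallow", "mean_diameter") * 100,
    mean_axis_diameter_intermediate_cm = dim_by("intermediate", "mean_diameter") * 100,
    mean_axis_diameter_deep_cm = dim_by("deep", "mean_diameter") * 100,
    mean_axis_volume_shallow_cm3 = dim_by("shallow", "volume") * 1e6,
    mean_axis_volume_intermediate_cm3 = dim_by("intermediate", "volume") * 1e6,
    mean_axis_volume_deep_cm3 = dim_by("deep", "volume") * 1e6,
    muaxe_vol_zrt_cm3 = muaxe_vol_zrt,
    qb_total_iafr = qb(rs, "total", include_fine_roots),
    qb_shallow_iafr = qb(rs, "shallow", include_fine_roots),
    qb_intermediate_iafr = qb(rs, "intermediate", include_fine_roots),
    qb_deep_iafr = qb(rs, "deep", include_fine_roots),
    mbo_total_iafr = mbo(rs, "total", include_fine_roots),
    p_branch_stump = fp("stump", "p_branch"),
    p_branch_taproot = fp("taproot", "p_branch"),
    p_branch_laterals = fp("laterals", "p_branch"),
    p_within_stump_pct_cm = fp("stump", "p_within"),
    p_within_taproot_pct_cm = fp("taproot", "p_within"),
    p_within_laterals_pct_cm = fp("laterals", "p_within"),
    q_stump = fp("stump", "q"),
    q_taproot = fp("taproot", "q"),
    q_laterals = fp("laterals", "q"),
    ill_stump_iafr_cm = gap_mean(bp[bp <= stump_length]) * 100,
    ill_taproot_iafr_cm = gap_mean(bp[bp > stump_length]) * 100,
    ill_order2_iafr_cm = mean(ill_o2$inter_lateral_length, na.rm = TRUE) * 100,
    apical_unbranched_cm = sub_mean(lat, rep(TRUE, nrow(lat)),
                                    "apical_unbranched_length") * 100,
    taproot_angle_deg = ta$angle_deg,
    taproot_reached_deep_limit = ta$reached_limit,
    taper_order1_pct_cm = ag$proximal_taper[ag$order == 1L],
    taper_o2_stump_pct_cm = sub_mean(o2, o2$on_stump, "proximal_taper"),
    taper_o2_below_pct_cm = sub_mean(o2, !o2$on_stump, "proximal_taper"),
    branching_angle_o2_stump_deg = sub_mean(o2, o2$on_stump, "branching_angle"),
    branching_angle_o2_below_deg = sub_mean(o2, !o2$on_stump, "branching_angle"),
    angle_surface_o2_stump_deg = sub_mean(
      o2, o2$on_stump & o2$direction_class == "horizontal", "angle_to_soil"),
    angle_surface_o2_below_deg = sub_mean(
      o2, !o2$on_stump & o2$direction_class == "horizontal", "angle_to_soil"),
    rdd_o2_deg = sub_mean(o2, rep(TRUE, nrow(o2)), "rdd"),
    winding_o2_stump = sub_mean(o2, o2$on_stump, "winding"),
    winding_o2_below = sub_mean(o2, !o2$on_stump, "winding"),
    vol_share_us_pct = pick("all", "us", "volume_share"),
    vol_share_pp_pct = pick("all", "pp", "volume_share"),
    vol_share_ds_pct = pick("all", "ds", "volume_share"),
    len_share_us_pct = pick("all", "us", "length_share"),
    n_share_us_pct = pick("all", "us", "n_share"),
    vol_reinforcement_us_pct = pick("all", "us", "volume_reinforcement"),
    vol_share_us_zrt_pct = pick("zrt", "us", "volume_share"),
    vol_share_pp_shallow_pct = shallow_pp
  )
}

#' Build the plant-by-trait table for a cohort
#'
#' @param cohort A list as returned by [generate_cohort()] (elements
#'   `systems`, `meta`) or a plain list of [root_system()] objects.
#' @param ... Passed to [phenotype()].
#' @return A tibble with one row per plant: metadata columns `plant_id`,
#'   `slope`, `flexing`, `block`, then the trait battery.
#' @export
build_trait_table <- function(cohort, ...) {
  systems <- if (!is.null(cohort$systems)) cohort$systems else cohort
  ids <- purrr::map_chr(systems, "plant_id")
  if (anyDuplicated(ids)) {
    rlang::abort(paste0("duplicate plant id(s): ",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  traits <- dplyr::bind_rows(purrr::map(systems, phenotype, ...))
  meta <- tibble::tibble(
    plant_id = ids,
    slope = factor(purrr::map_dbl(systems, "slope_deg")),
    flexing = factor(ifelse(purrr::map_lgl(systems, "flexed"), "yes", "no")),
    block = factor(purrr::map_chr(systems, "block"))
  )
  dplyr::left_join(meta, traits, by = "plant_id")
}
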