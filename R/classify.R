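# Architectural compartments and slope-oriented circular sectors.
#
# Eight compartments: (1) stump, (2) taproot, (3) zone of rapid taper (ZRT),
# (4) horizontal shallow beyond ZRT, (5) sinkers, (6) deep, (7) intermediate
# depth, (8) oblique. Lateral roots are classified by the depth of the
# initial branching point of their arborescence on the order-1 root plus
# their own direction class; the ZRT/beyond split is spatial, on 10 mm
# virtual segments, using the relative radial distance from the bearing
# point. Sinkers are pooled to the taproot and oblique roots to the
# intermediate compartment for the six-compartment tables.

compartment_names <- c(
  "1" = "stump", "2" = "taproot", "3" = "zrt", "4" = "shallow_beyond",
  "5" = "sinker", "6" = "deep", "7" = "intermediate", "8" = "oblique"
)
pooled_names <- c(
  "1" = "stump", "2" = "taproot", "3" = "zrt", "4" = "shallow_beyond",
  "5" = "taproot", "6" = "deep", "7" = "intermediate", "8" = "intermediate"
)

#' Depth class of a point below the soil surface
#'
#' Limits between shallow, intermediate-depth and deep roots are -35 and
#' -70 mm; boundary depths are assigned to the deeper class.
#'
#' @param depth_m Depth in metres (non-positive; vectorised).
#' @return Character vector: "shallow", "intermediate" or "deep".
#' @export
classify_depth <- function(depth_m) {
  dplyr::case_when(
    depth_m > -0.035 ~ "shallow",
    depth_m > -0.070 ~ "intermediate",
    TRUE ~ "deep"
  )
}

#' Direction class from the angle toward the soil surface
#'
#' Limits between horizontal, oblique and vertical roots are 30 and 60
#' degrees toward the soil surface; boundary angles are assigned to the
#' steeper class.
#'
#' @param angle_deg Angle to the soil surface in degrees (vectorised; the
#'   sign is ignored).
#' @return Character vector: "horizontal", "oblique" or "vertical".
#' @export
classify_direction <- function(angle_deg) {
  a <- abs(angle_deg)
  dplyr::case_when(a < 30 ~ "horizontal", a < 60 ~ "oblique", TRUE ~ "vertical")
}

#' Slope-oriented circular sector of an azimuth
#'
#' Half-open 90-degree bins: upslope `us` = [315, 45), downslope `ds` =
#' [135, 225), perpendicular `pp` = the two remaining quadrants.
#'
#' @param azimuth_deg Azimuth in degrees (vectorised).
#' @return Character vector: "us", "pp" or "ds" (`NA` for `NA` azimuths).
#' @export
classify_sector <- function(azimuth_deg) {
  a <- azimuth_deg %% 360
  dplyr::case_when(
    is.na(a) ~ NA_character_,
    a >= 315 | a < 45 ~ "us",
    a >= 135 & a < 225 ~ "ds",
    TRUE ~ "pp"
  )
}

#' Split the order-1 root into stump and taproot
#'
#' The stump is the first `stump_length` (45 mm) of curvilinear length of the
#' order-1 path; the remainder is the taproot. A segment straddling the limit
#' is split into two virtual parts. When the order-1 path is shorter than the
#' stump length the whole path is stump and the result is flagged.
#'
#' @param rs A [root_system()].
#' @param stump_length Standard stump length in metres (default 0.045).
#' @return A tibble with one row per order-1 segment part: `segment_id`,
#'   `part` ("stump"/"taproot"), `s_from`, `s_to`, `length`, `volume`;
#'   `attr(, "short_order1")` flags an order-1 path shorter than the limit.
#' @export
split_stump <- function(rs, stump_length = 0.045) {
  p <- order1_axis(axis_paths(rs))
  short <- p$length < stump_length - 1e-12
  rows <- purrr::map(seq_along(p$segment_ids), function(i) {
    a <- p$s_bounds[i]; b <- p$s_bounds[i + 1]
    cuts <- c(a, if (stump_length > a + 1e-12 && stump_length < b - 1e-12) stump_length, b)
    tibble::tibble(
      segment_id = p$segment_ids[i],
      s_from = cuts[-length(cuts)],
      s_to = cuts[-1]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$part <- ifelse(out$s_to <= stump_length + 1e-12, "stump", "taproot")
  out$length <- out$s_to - out$s_from
  out$volume <- purrr::map2_dbl(out$s_from, out$s_to, ~ profile_volume(p, .x, .y))
  attr(out, "short_order1") <- short
  out
}

# Per-axis classification: origin depth class of the arborescence's initial
# branching point on the order-1 root, own direction class, compartment,
# bearing point and sector. Internal; exposed through axis_geometry() and
# classify_compartments().
axis_classes <- function(rs, paths = axis_paths(rs), stump_length = 0.045) {
  o1 <- order1_axis(paths)
  # walk each axis up to its order-2 ancestor (arborescence root)
  arbo_of <- function(aid) {
    p <- paths[[aid]]
    while (!is.na(p$parent_axis) && paths[[p$parent_axis]]$order >= 2L) {
      p <- paths[[p$parent_axis]]
    }
    p$axis_id
  }
  rows <- purrr::map(paths, function(p) {
    if (p$order == 1L) {
      return(tibble::tibble(
        axis_id = p$axis_id, order = p$order, arbo = NA_character_,
        bearing_s = NA_real_, bearing_x = NA_real_, bearing_y = NA_real_,
        bearing_z = NA_real_, depth_class = NA_character_,
        direction_class = NA_character_, compartment_axis = NA_integer_,
        sector_azimuth = NA_real_, sector = NA_character_, on_stump = NA
      ))
    }
    arbo <- arbo_of(p$axis_id)
    pa <- paths[[arbo]]
    bearing <- pa$attach_xyz
    bearing_s <- pa$attach_s
    chord <- p$verts[nrow(p$verts), ] - p$verts[1, ]
    dir_cls <- classify_direction(surface_angle_of(chord[1], chord[2], chord[3]))
    depth_cls <- classify_depth(bearing[3])
    comp <- if (depth_cls == "deep") 6L
      else if (depth_cls == "intermediate") 7L
      else switch(dir_cls, horizontal = 3L, oblique = 8L, vertical = 5L)
    # sector from the azimuth, about the bearing point, of the point at 1 cm
    pt1 <- drop(interp_point(p, min(0.01, p$length)))
    az <- azimuth_of(pt1[1] - bearing[1], pt1[2] - bearing[2])
    tibble::tibble(
      axis_id = p$axis_id, order = p$order, arbo = arbo,
      bearing_s = bearing_s,
      bearing_x = bearing[1], bearing_y = bearing[2], bearing_z = bearing[3],
      depth_class = depth_cls, direction_class = dir_cls,
      compartment_axis = comp,
      sector_azimuth = az, sector = classify_sector(az),
      on_stump = bearing_s <= stump_length + 1e-12
    )
  })
  dplyr::bind_rows(rows)
}

#' Classify virtual segments into the eight architectural compartments
#'
#' Runs the full spatial classification: 10 mm virtual segmentation (with the
#' 45 mm stump cut on the order-1 axis), per-axis origin/direction classes,
#' relative radial distance from the bearing point on the order-1 root, the
#' ZRT limit, and the slope-oriented sector of every virtual segment.
#'
#' @param rs A [root_system()].
#' @param zrt_limit Relative radial distance bounding the zone of rapid
#'   taper, metres. The classical analysis leaves this limit implicit; the
#'   default of 0.050 m corresponds to the taproot-proximal zone of a 0.30 m
#'   container and is deliberately prominent because ZRT shares depend on it.
#' @param stump_length Standard stump length, metres (default 0.045).
#' @param step Virtual segment length, metres (default 0.010).
#' @return A tibble of labelled virtual segments with columns `compartment`
#'   (1-8), `compartment_name`, `pooled` (six-class label), `rrd` (relative
#'   radial distance, m), `azimuth` and `sector` (`NA` for stump/taproot,
#'   which are the centre of the circular analysis).
#' @export
classify_compartments <- function(rs, zrt_limit = 0.050, stump_length = 0.045,
                                  step = 0.010) {
  paths <- axis_paths(rs)
  o1 <- order1_axis(paths)
  vs <- virtualize(rs, step = step,
                   axis_breaks = stats::setNames(list(stump_length), o1$axis_id))
  cls <- axis_classes(rs, paths, stump_length = stump_length)
  vs <- dplyr::left_join(
    vs,
    cls[, c("axis_id", "depth_class", "direction_class", "compartment_axis",
            "bearing_x", "bearing_y", "bearing_z", "on_stump")],
    by = "axis_id"
  )
  vs <- dplyr::mutate(vs,
    rrd = sqrt((.data$mid_x - .data$bearing_x)^2 + (.data$mid_y - .data$bearing_y)^2),
    azimuth = azimuth_of(.data$mid_x - .data$bearing_x, .data$mid_y - .data$bearing_y),
    compartment = dplyr::case_when(
      order == 1L & s_axis <= stump_length ~ 1L,
      order == 1L ~ 2L,
      compartment_axis == 3L & rrd <= zrt_limit ~ 3L,
      compartment_axis == 3L ~ 4L,
      TRUE ~ compartment_axis
    )
  )
  if (any(is.na(vs$compartment))) {
    rlang::abort("internal error: unlabelled virtual segment (classification must be total)")
  }
  dplyr::mutate(vs,
    compartment_name = unname(compartment_names[as.character(.data$compartment)]),
    pooled = unname(pooled_names[as.character(.data$compartment)]),
    sector = dplyr::if_else(.data$order == 1L, NA_character_,
                            classify_sector(.data$azimuth))
  )
}

#' Sector shares of volume, length and number
#'
#' Shares (%) of root volume, root length and axis number falling in the
#' upslope (`us`), perpendicular (`pp`) and downslope (`ds`) sectors, per
#' pooled compartment and for all lateral roots together (`compartment =
#' "all"`). Stump and taproot are excluded: they are the centre of the
#' circular analysis. Axis counts use the sector of the axis (azimuth at
#' 1 cm about the bearing point); measured axes only, since the sector of
#' additional fine roots is not recorded.
#'
#' Reinforcements use the quadrant-equivalent share (the `pp` share is halved
#' because that sector spans two quadrants), so an even circular distribution
#' scores 0 in every sector.
#'
#' @param rs A [root_system()].
#' @param ... Passed to [classify_compartments()].
#' @return A tibble: `compartment`, `sector`, raw totals (`volume` m^3,
#'   `length` m, `n` axes), `volume_share`, `length_share`, `n_share`
#'   (percent; `NA` when the compartment total is zero) and the
#'   reinforcement of each share.
#' @export
sector_shares <- function(rs, ...) {
  vs <- classify_compartments(rs, ...)
  acl <- axis_classes(rs)
  lat <- dplyr::filter(vs, .data$order > 1L, !is.na(.data$sector))
  if (nrow(lat) == 0) {
    return(tibble::tibble(
      compartment = character(), sector = character(),
      volume = numeric(), length = numeric(), n = numeric(),
      volume_share = numeric(), length_share = numeric(), n_share = numeric()
    ))
  }
  lat <- dplyr::left_join(
    lat, stats::setNames(acl[, c("axis_id", "sector")], c("axis_id", "axis_sector")),
    by = "axis_id"
  )
  share_tbl <- function(v, comp_label) {
    agg <- dplyr::summarise(
      dplyr::group_by(v, .data$sector),
      volume = sum(.data$volume), length = sum(.data$length), .groups = "drop"
    )
    agg <- tidyr::complete(agg, sector = c("us", "pp", "ds"),
                           fill = list(volume = 0, length = 0))
    axn <- dplyr::count(dplyr::distinct(v, .data$axis_id, .data$axis_sector),
                        .data$axis_sector, name = "n")
    agg$n <- axn$n[match(agg$sector, axn$axis_sector)]
    agg$n[is.na(agg$n)] <- 0
    dplyr::mutate(agg,
      compartment = comp_label,
      volume_share = if (sum(.data$volume) > 0) 100 * .data$volume / sum(.data$volume) else NA_real_,
      length_share = if (sum(.data$length) > 0) 100 * .data$length / sum(.data$length) else NA_real_,
      n_share = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else NA_real_
    )
  }
  out <- dplyr::bind_rows(
    share_tbl(lat, "all"),
    dplyr::bind_rows(purrr::map(
      split(lat, lat$pooled), ~ share_tbl(.x, .x$pooled[1])
    ))
  )
  quad <- function(share, sector) ifelse(sector == "pp", share / 2, share)
  out <- dplyr::mutate(out,
    volume_reinforcement = reinforcement(quad(.data$volume_share, .data$sector)),
    length_reinforcement = reinforcement(quad(.data$length_share, .data$sector)),
    n_reinforcement = reinforcement(quad(.data$n_share, .data$sector))
  )
  dplyr::relocate(out, "compartment", "sector")
}

#' Sector reinforcement
#'
#' The excess of a 90-degree sector's share over the uniform expectation of
#' 25%: `(share - 25) / 25`, expressed in percent. An even circular
#' distribution gives 25% in the upslope and downslope sectors and so a
#' reinforcement of 0; a sector holding everything scores +300%.
#'
#' @param share_pct Sector share in percent (vectorised).
#' @return Reinforcement in percent.
#' @export
reinforcement <- function(share_pct) {
  100 * (share_pct - 25) / 25
}
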