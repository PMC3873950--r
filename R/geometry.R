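# Axis- and segment-level geometry: lengths, Eq-style mean diameters, tapers,
# angles, azimuths, straightness measures and the 10 mm virtual segmentation.

deg <- function(rad) rad * 180 / pi

# Compass azimuth of a horizontal displacement: 0 = +x (north/upslope),
# 90 = +y, in [0, 360). Undefined (NA) for a zero horizontal projection.
azimuth_of <- function(dx, dy, tol = 1e-12) {
  h <- sqrt(dx^2 + dy^2)
  out <- (deg(atan2(dy, dx))) %% 360
  out[h < tol] <- NA_real_
  out
}

# Angle of a displacement to the soil-surface plane, degrees in [-90, 90],
# negative when descending into the soil.
surface_angle_of <- function(dx, dy, dz) {
  len <- sqrt(dx^2 + dy^2 + dz^2)
  ifelse(len == 0, NA_real_, deg(asin(pmin(pmax(dz / len, -1), 1))))
}

# Fold an azimuth difference to [0, 180] (wrap-around absolute change).
fold_angle <- function(a) {
  a <- abs(a) %% 360
  ifelse(a > 180, 360 - a, a)
}

#' Mean root diameter from volume and length
#'
#' The diameter of the cylinder with the same volume and length as the root:
#' `2 * sqrt(volume / (pi * length))`.
#'
#' @param volume Root volume, m^3 (vectorised).
#' @param length Root length, m.
#' @return Mean diameter in metres; errors when `length` is zero.
#' @export
mean_diameter <- function(volume, length) {
  if (any(length <= 0)) {
    rlang::abort("mean_diameter is undefined for zero or negative length")
  }
  2 * sqrt(volume / (pi * length))
}

#' 3D branching angle between two direction vectors
#'
#' Angle in `[0, 180]` degrees between a daughter axis' first-segment vector
#' and the bearing segment's vector.
#'
#' @param v_child,v_mother Numeric length-3 direction vectors.
#' @return Angle in degrees.
#' @export
branching_angle <- function(v_child, v_mother) {
  nc <- sqrt(sum(v_child^2)); nm <- sqrt(sum(v_mother^2))
  if (nc == 0 || nm == 0) rlang::abort("branching_angle: zero-length vector")
  deg(acos(pmin(pmax(sum(v_child * v_mother) / (nc * nm), -1), 1)))
}

#' Taproot angle toward the soil surface
#'
#' Angle to the soil-surface plane of the straight line running from the
#' collar to the point where the order-1 root crosses the deep-root limit
#' (70 mm depth). A perfectly vertical taproot scores -90 degrees. When the
#' taproot never reaches the limit its deepest point is used and the result
#' is flagged.
#'
#' @param rs A [root_system()].
#' @param deep_limit Depth of the deep-root limit in metres (positive value;
#'   default 0.070).
#' @return A one-row tibble: `angle_deg`, `reached_limit`.
#' @export
taproot_angle <- function(rs, deep_limit = 0.070) {
  p <- order1_axis(axis_paths(rs))
  z <- p$verts[, 3]
  collar <- p$verts[1, ]
  below <- which(z <= -deep_limit)
  if (length(below) == 0) {
    pt <- p$verts[which.min(z), ]
    reached <- FALSE
  } else {
    k <- below[1]
    if (k == 1) {
      pt <- p$verts[1, ]
    } else {
      f <- (-deep_limit - z[k - 1]) / (z[k] - z[k - 1])
      pt <- p$verts[k - 1, ] + f * (p$verts[k, ] - p$verts[k - 1, ])
    }
    reached <- TRUE
  }
  d <- pt - collar
  ang <- if (sqrt(sum(d[1:2]^2)) < 1e-12) -90 else surface_angle_of(d[1], d[2], d[3])
  tibble::tibble(angle_deg = ang, reached_limit = reached)
}

#' Per-axis geometric traits
#'
#' One row per axis with the standard architectural measures: length
#' (including the mother-root radius for laterals, accounting for primary
#' growth from the mother's centre), volume, mean diameter, proximal taper
#' over the first 3.5 cm, branching angle, chord angle to the soil surface,
#' azimuth at 1 cm from the base, root directional deviation (RDD), winding,
#' and apical unbranched length.
#'
#' Short-axis fallbacks: axes shorter than 1 cm take their azimuth at the
#' tip, axes shorter than 3.5 cm get `NA` proximal taper, and axes shorter
#' than 10 mm take their RDD at the tip; each case sets the corresponding
#' quality flag instead of dropping the axis.
#'
#' @param rs A [root_system()].
#' @return A tibble with one row per axis.
#' @export
axis_geometry <- function(rs) {
  paths <- axis_paths(rs)
  cls <- tryCatch(axis_classes(rs, paths), error = function(e) NULL)

  # attach positions of children on each axis, for apical unbranched length
  kids_s <- purrr::map(paths, ~ numeric(0))
  for (p in paths) {
    if (!is.na(p$parent_axis)) {
      kids_s[[p$parent_axis]] <- c(kids_s[[p$parent_axis]], p$attach_s)
    }
  }

  rows <- purrr::map(paths, function(p) {
    n <- nrow(p$verts)
    base <- p$verts[1, ]
    tip <- p$verts[n, ]
    chord <- tip - base
    # mother radius: diameter of the bearing axis at the attachment point
    mother_radius <- 0
    bang <- NA_real_
    if (!is.na(p$parent_axis)) {
      pp <- paths[[p$parent_axis]]
      mother_radius <- interp_diameter(pp, p$attach_s) / 2
      k <- match(p$parent_segment, pp$segment_ids)
      v_mother <- pp$verts[k + 1, ] - pp$verts[k, ]
      v_child <- p$verts[2, ] - p$verts[1, ]
      bang <- tryCatch(branching_angle(v_child, v_mother), error = function(e) NA_real_)
    }
    raw_len <- p$length
    # azimuth at the point 1 cm along the axis (tip for shorter axes)
    az_s <- min(0.01, raw_len)
    pt1 <- drop(interp_point(p, az_s))
    az <- azimuth_of(pt1[1] - base[1], pt1[2] - base[2])
    # RDD: azimuth change about the axis origin between 10 mm and the tip
    rdd_s <- min(0.01, raw_len)
    pt10 <- drop(interp_point(p, rdd_s))
    az10 <- azimuth_of(pt10[1] - base[1], pt10[2] - base[2])
    az_tip <- azimuth_of(chord[1], chord[2])
    rdd <- fold_angle(az_tip - az10)
    chord_len <- sqrt(sum(chord^2))
    winding <- if (chord_len > 0) raw_len / chord_len else NA_real_
    d0 <- p$d_bounds[1]
    taper <- if (raw_len >= 0.035 && d0 > 0) {
      d35 <- interp_diameter(p, 0.035)
      100 * (d0 - d35) / d0 / 3.5
    } else NA_real_
    ks <- kids_s[[p$axis_id]]
    apical <- if (length(ks) > 0) raw_len - max(ks) else raw_len
    tibble::tibble(
      axis_id = p$axis_id, order = p$order,
      parent_axis = p$parent_axis, attach_s = p$attach_s,
      origin_depth = if (is.na(p$parent_axis)) 0 else p$attach_xyz[3],
      raw_length = raw_len,
      length = raw_len + mother_radius,
      volume = p$volume,
      basal_diameter = d0,
      tip_diameter = p$d_bounds[length(p$d_bounds)],
      mean_diameter = if (raw_len > 0) mean_diameter(p$volume, raw_len) else NA_real_,
      proximal_taper = taper,
      branching_angle = bang,
      angle_to_soil = surface_angle_of(chord[1], chord[2], chord[3]),
      azimuth_1cm = az,
      rdd = rdd,
      winding = winding,
      apical_unbranched_length = apical,
      n_branches = length(ks),
      fine_root_count = sum(p$fine_root_count),
      fine_root_length = sum(p$fine_root_count * p$fine_root_mean_length),
      azimuth_flag = raw_len < 0.01,
      rdd_flag = raw_len < 0.01,
      taper_flag = raw_len < 0.035
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, plant_id = rs$plant_id, .before = 1)
  if (!is.null(cls)) {
    out <- dplyr::left_join(
      out,
      cls[, c("axis_id", "depth_class", "direction_class", "compartment_axis",
              "bearing_s", "bearing_x", "bearing_y", "bearing_z",
              "sector_azimuth", "sector", "on_stump")],
      by = "axis_id"
    )
  }
  out
}

#' Split root segments into 10 mm virtual segments
#'
#' Every segment is divided into slices of at most `step` (10 mm) measured
#' from the segment base; total length and volume are conserved exactly.
#' Volume is apportioned by the frustum integral of the linearly
#' interpolated diameter profile (or proportionally to slice length in
#' cylinder mode). Additional axis-level breakpoints (e.g. the 45 mm stump
#' limit on the order-1 axis) split the straddling slice in two.
#'
#' @param rs A [root_system()].
#' @param step Slice length in metres (default 0.010).
#' @param axis_breaks Named list: axis id -> numeric curvilinear positions at
#'   which slices must additionally be cut.
#' @return A tibble of virtual segments with midpoint coordinates, depth,
#'   axis-curvilinear midpoint position `s_axis`, length and volume.
#' @export
virtualize <- function(rs, step = 0.010, axis_breaks = list()) {
  paths <- axis_paths(rs)
  rows <- purrr::map(paths, function(p) {
    per_seg <- purrr::map(seq_along(p$segment_ids), function(i) {
      L <- p$seg_lengths[i]
      if (L <= 0) return(NULL)
      s0 <- p$s_bounds[i]
      cuts <- seq(0, L, by = step)
      if (cuts[length(cuts)] < L - 1e-12) cuts <- c(cuts, L) else cuts[length(cuts)] <- L
      extra <- axis_breaks[[p$axis_id]]
      if (!is.null(extra)) {
        loc <- extra - s0
        loc <- loc[loc > 1e-12 & loc < L - 1e-12]
        cuts <- sort(unique(c(cuts, loc)))
      }
      a <- s0 + cuts[-length(cuts)]
      b <- s0 + cuts[-1]
      vol <- if (rs$volume_mode == "frustum") {
        # the diameter profile is linear within one segment
        d0 <- p$d_bounds[i]; d1 <- p$d_bounds[i + 1]
        da <- d0 + (a - s0) / L * (d1 - d0)
        db <- d0 + (b - s0) / L * (d1 - d0)
        frustum_volume(da, db, b - a)
      } else {
        pi / 4 * p$d_bounds[i]^2 * (b - a)
      }
      mid <- interp_point(p, (a + b) / 2)
      tibble::tibble(
        segment_id = p$segment_ids[i],
        slice = seq_along(a),
        s_axis = (a + b) / 2,
        length = b - a,
        volume = vol,
        mid_x = mid[, 1], mid_y = mid[, 2], mid_z = mid[, 3]
      )
    })
    out <- dplyr::bind_rows(per_seg)
    if (nrow(out) == 0) return(out)
    dplyr::mutate(out, axis_id = p$axis_id, order = p$order, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out,
    plant_id = rs$plant_id,
    depth = .data$mid_z,
    .before = 1
  )
}
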