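# Internal machinery: per-axis polyline paths, diameter profiles and
# interpolation. Diameters are measured at segment bases; the diameter at the
# boundary between consecutive segments on an axis is therefore the basal
# diameter of the downstream segment, and the distal segment of an axis is
# treated as a cylinder of its own basal diameter. Everything downstream
# (volumes, tapers, 2 cm CSA interpolation, stump split) reads this profile.

# Order the segments of one axis from base to tip by following parent links.
order_axis_segments <- function(seg, ids) {
  sub <- seg[seg$segment_id %in% ids, , drop = FALSE]
  first <- sub$segment_id[is.na(sub$parent_id) | !(sub$parent_id %in% ids)]
  if (length(first) != 1) {
    rlang::abort(sprintf(
      "axis %s does not have a unique base segment", sub$axis_id[1]
    ))
  }
  nxt <- stats::setNames(sub$segment_id, sub$parent_id)
  out <- character(nrow(sub))
  out[1] <- first
  i <- 1L
  while (i < nrow(sub)) {
    succ <- sub$segment_id[!is.na(sub$parent_id) & sub$parent_id == out[i]]
    if (length(succ) == 0) break
    if (length(succ) > 1) {
      rlang::abort(sprintf("segment %s has two successors on its own axis", out[i]))
    }
    i <- i + 1L
    out[i] <- succ
  }
  if (i != nrow(sub)) {
    rlang::abort(sprintf("axis %s is not a single chain", sub$axis_id[1]))
  }
  out
}

# Full per-axis decomposition of a root system. Returns a named list (one
# element per axis) with the ordered segment ids, vertex matrix, curvilinear
# boundaries, boundary diameters, per-segment volumes, parent attachment and
# order. Used by every geometric and topological operation.
axis_paths <- function(rs) {
  seg <- rs$segments
  mode <- rs$volume_mode
  axes <- split(seg$segment_id, seg$axis_id)
  rowof <- stats::setNames(seq_len(nrow(seg)), seg$segment_id)

  out <- purrr::imap(axes, function(ids, aid) {
    ord <- order_axis_segments(seg, ids)
    r <- rowof[ord]
    n <- length(ord)
    verts <- rbind(
      c(seg$base_x[r[1]], seg$base_y[r[1]], seg$base_z[r[1]]),
      cbind(seg$tip_x[r], seg$tip_y[r], seg$tip_z[r])
    )
    lens <- sqrt(rowSums((verts[-1, , drop = FALSE] - verts[-(n + 1), , drop = FALSE])^2))
    s_bounds <- c(0, cumsum(lens))
    # boundary diameters: basal diameters plus a repeated distal diameter
    d_bounds <- c(seg$diameter[r], seg$diameter[r[n]])
    vols <- if (mode == "frustum") {
      frustum_volume(d_bounds[-(n + 1)], d_bounds[-1], lens)
    } else {
      pi / 4 * d_bounds[-(n + 1)]^2 * lens
    }
    first_parent <- seg$parent_id[r[1]]
    list(
      axis_id = aid,
      segment_ids = ord,
      order = seg$order[r[1]],
      verts = verts,
      seg_lengths = lens,
      s_bounds = s_bounds,
      d_bounds = d_bounds,
      seg_volumes = vols,
      length = s_bounds[n + 1],
      volume = sum(vols),
      fine_root_count = seg$fine_root_count[r],
      fine_root_mean_length = seg$fine_root_mean_length[r],
      parent_segment = first_parent
    )
  })

  # attachment of each axis on its parent axis (curvilinear position + point)
  segaxis <- stats::setNames(seg$axis_id, seg$segment_id)
  for (aid in names(out)) {
    p <- out[[aid]]
    if (is.na(p$parent_segment)) {
      out[[aid]]$parent_axis <- NA_character_
      out[[aid]]$attach_s <- NA_real_
      out[[aid]]$attach_xyz <- p$verts[1, ]
      next
    }
    paxis <- segaxis[[p$parent_segment]]
    pp <- out[[paxis]]
    k <- match(p$parent_segment, pp$segment_ids)
    out[[aid]]$parent_axis <- paxis
    out[[aid]]$attach_s <- pp$s_bounds[k + 1]  # child attaches at parent tip
    out[[aid]]$attach_xyz <- pp$verts[k + 1, ]
  }
  out
}

# Volume of a conical frustum with end diameters d1, d2 and length L.
frustum_volume <- function(d1, d2, L) {
  pi * L / 12 * (d1^2 + d1 * d2 + d2^2)
}

# Linear interpolation of the 3D point at curvilinear distance s along a path.
interp_point <- function(path, s) {
  s <- pmin(pmax(s, 0), path$length)
  i <- findInterval(s, path$s_bounds, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(path$s_bounds) - 1L)
  t0 <- path$s_bounds[i]
  seglen <- path$s_bounds[i + 1] - t0
  f <- ifelse(seglen > 0, (s - t0) / seglen, 0)
  path$verts[i, , drop = FALSE] * (1 - f) + path$verts[i + 1, , drop = FALSE] * f
}

# Linear interpolation of the diameter profile at curvilinear distance s.
interp_diameter <- function(path, s) {
  s <- pmin(pmax(s, 0), path$length)
  stats::approx(path$s_bounds, path$d_bounds, xout = s,
                method = "linear", ties = "ordered")$y
}

# CSA (m^2) from a diameter.
csa <- function(d) pi / 4 * d^2

# Volume of the slice of an axis/segment with linearly varying diameter
# between curvilinear positions s0 and s1 (frustum integral).
profile_volume <- function(path, s0, s1) {
  d0 <- interp_diameter(path, s0)
  d1 <- interp_diameter(path, s1)
  # the profile is piecewise linear; integrate knot interval by interval
  knots <- sort(unique(c(s0, s1, path$s_bounds[path$s_bounds > s0 & path$s_bounds < s1])))
  if (length(knots) == 2) {
    return(frustum_volume(d0, d1, s1 - s0))
  }
  dd <- interp_diameter(path, knots)
  sum(frustum_volume(dd[-length(dd)], dd[-1], diff(knots)))
}

# Rebuild all segment coordinates from per-segment chord vectors, keeping the
# collar fixed. `vectors` is a named list/matrix of tip - base displacement
# per segment id. Children automatically follow their parents because every
# base is its parent's tip.
rebuild_coordinates <- function(rs, vectors) {
  seg <- rs$segments
  rowof <- stats::setNames(seq_len(nrow(seg)), seg$segment_id)
  collar <- seg$segment_id[is.na(seg$parent_id)]
  kid_of <- split(seg$segment_id, seg$parent_id)
  base <- matrix(NA_real_, nrow(seg), 3)
  tip <- matrix(NA_real_, nrow(seg), 3)
  cr <- rowof[[collar]]
  base[cr, ] <- c(seg$base_x[cr], seg$base_y[cr], seg$base_z[cr])
  frontier <- collar
  while (length(frontier)) {
    nxt <- character()
    for (id in frontier) {
      r <- rowof[[id]]
      tip[r, ] <- base[r, ] + vectors[[id]]
      kids <- kid_of[[id]]
      if (!is.null(kids)) {
        for (k in kids) base[rowof[[k]], ] <- tip[r, ]
        nxt <- c(nxt, kids)
      }
    }
    frontier <- nxt
  }
  seg$base_x <- base[, 1]; seg$base_y <- base[, 2]; seg$base_z <- base[, 3]
  seg$tip_x <- tip[, 1]; seg$tip_y <- tip[, 2]; seg$tip_z <- tip[, 3]
  rs$segments <- seg
  rs
}

# The order-1 axis (stump + taproot) of a root system.
order1_axis <- function(paths) {
  o1 <- purrr::keep(paths, ~ .x$order == 1L)
  if (length(o1) != 1) {
    rlang::abort(sprintf("expected exactly one order-1 axis, found %d", length(o1)))
  }
  o1[[1]]
}
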