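# Fractal branching analysis: per-branch-event cross-sectional-area (CSA)
# scaling. At every branch point on a bearing axis:
#   p_branch = CSA before the branch / sum of CSA after (continuing segment
#              plus all daughters); > 1 when tapering occurs, 1 under CSA
#              conservation.
#   q        = largest post-branch CSA / sum of post-branch CSA; 0.5 for an
#              equal dichotomous split, close to 1 in a herringbone pattern.
#   p_within = % CSA decrease per cm between consecutive branch points on
#              the same axis.
# Diameters are digitized just before a branch point but not directly after,
# so when the continuing segment is longer than 2 cm its post-branch CSA is
# taken 2 cm after the branching point by linear interpolation of the
# diameter profile; shorter continuing segments use the diameter at their
# distal end.

#' Branch-event table
#'
#' One row per branch event (coincident daughters are one event), with the
#' CSA bookkeeping of the fractal branching analysis and the event's scope:
#' `"stump"` (on the order-1 axis within the stump length), `"taproot"`
#' (order-1 below the stump) or `"laterals"`. Events with zero CSA before
#' the branch are skipped and counted in `attr(, "qc_skipped")`.
#'
#' @param rs A [root_system()].
#' @param stump_length Stump length (m) separating stump from taproot events.
#' @param interp_dist Distance after the branch point at which the
#'   continuing axis' CSA is interpolated when the continuing segment is
#'   longer than this (default 0.02 m).
#' @return A tibble of branch events.
#' @export
branch_events <- function(rs, stump_length = 0.045, interp_dist = 0.02) {
  paths <- axis_paths(rs)
  children <- children_map(paths)
  skipped <- 0L
  rows <- list()
  for (aid in names(children)) {
    p <- paths[[aid]]
    kids <- children[[aid]]
    # group coincident daughters into single events
    ev_pos <- sort(unique(round(kids$s, 9)))
    for (s in ev_pos) {
      daughters <- kids$axis_id[abs(kids$s - s) < 1e-9]
      d_before <- interp_diameter(p, s)
      csa_before <- csa(d_before)
      if (csa_before <= 0) {
        skipped <- skipped + 1L
        next
      }
      # continuing CSA: absent when the axis terminates at the branch point
      at_tip <- s >= p$length - 1e-9
      csa_cont <- if (at_tip) NA_real_ else {
        k <- findInterval(s + 1e-12, p$s_bounds, rightmost.closed = TRUE)
        seg_end <- p$s_bounds[min(k + 1, length(p$s_bounds))]
        s_after <- if (seg_end - s > interp_dist) s + interp_dist else seg_end
        csa(interp_diameter(p, s_after))
      }
      csa_daughters <- purrr::map_dbl(daughters, function(d) {
        csa(paths[[d]]$d_bounds[1])
      })
      after <- c(if (!is.na(csa_cont)) csa_cont, csa_daughters)
      scope <- if (p$order == 1L) {
        if (s <= stump_length + 1e-12) "stump" else "taproot"
      } else "laterals"
      rows[[length(rows) + 1]] <- tibble::tibble(
        axis_id = aid, order = p$order, s = s, scope = scope,
        d_before = d_before, csa_before = csa_before,
        csa_cont = csa_cont,
        csa_daughters = sum(csa_daughters),
        n_daughters = length(daughters),
        csa_after = sum(after),
        p_branch = csa_before / sum(after),
        q = max(after) / sum(after)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out <- dplyr::mutate(out, plant_id = rs$plant_id, .before = 1)
  attr(out, "qc_skipped") <- skipped
  out
}

# per-axis inter-branch tapering (% CSA per cm) between consecutive events
p_within_events <- function(ev) {
  if (nrow(ev) == 0) return(tibble::tibble())
  per_axis <- purrr::map(split(ev, ev$axis_id), function(e) {
    e <- e[order(e$s), ]
    if (nrow(e) < 2) return(NULL)
    c1 <- e$csa_before[-nrow(e)]
    c2 <- e$csa_before[-1]
    gap_cm <- (e$s[-1] - e$s[-nrow(e)]) * 100
    ok <- gap_cm > 0 & c1 > 0
    tibble::tibble(
      axis_id = e$axis_id[1], order = e$order[1], scope = e$scope[-1],
      s_from = e$s[-nrow(e)], s_to = e$s[-1],
      p_within = ifelse(ok, 100 * (c1 - c2) / c1 / gap_cm, NA_real_)
    )
  })
  dplyr::bind_rows(per_axis)
}

#' Fractal branching parameters by scope
#'
#' Per-scope (stump / taproot / laterals) means of `p_branch`, `q` and
#' `p_within` over the branch events of a root system.
#'
#' @param rs A [root_system()].
#' @param ... Passed to [branch_events()].
#' @return A tibble: `scope`, `n_events`, `p_branch`, `q`, `n_intervals`,
#'   `p_within`.
#' @export
fractal_params <- function(rs, ...) {
  ev <- branch_events(rs, ...)
  scopes <- c("stump", "taproot", "laterals")
  if (nrow(ev) == 0) {
    return(tibble::tibble(
      scope = scopes, n_events = 0L, p_branch = NA_real_, q = NA_real_,
      n_intervals = 0L, p_within = NA_real_
    ))
  }
  pw <- p_within_events(ev)
  main <- dplyr::summarise(
    dplyr::group_by(ev, .data$scope),
    n_events = dplyr::n(),
    p_branch = mean(.data$p_branch),
    q = mean(.data$q),
    .groups = "drop"
  )
  within <- if (nrow(pw) > 0) {
    dplyr::summarise(
      dplyr::group_by(pw, .data$scope),
      n_intervals = sum(!is.na(.data$p_within)),
      p_within = mean(.data$p_within, na.rm = TRUE),
      .groups = "drop"
    )
  } else {
    tibble::tibble(scope = character(), n_intervals = integer(), p_within = numeric())
  }
  out <- dplyr::left_join(tibble::tibble(scope = scopes), main, by = "scope")
  out <- dplyr::left_join(out, within, by = "scope")
  dplyr::mutate(out,
    n_events = dplyr::coalesce(.data$n_events, 0L),
    n_intervals = dplyr::coalesce(.data$n_intervals, 0L),
    p_within = dplyr::if_else(is.nan(.data$p_within), NA_real_, .data$p_within)
  )
}

#' Mean inter-lateral length along an axis
#'
#' Mean curvilinear gap between successive branch points along each axis;
#' optionally merging unmeasured fine roots (attached at their bearing
#' segment's tip) into the position-sorted branch list. Axes with fewer than
#' two branch points get `NA`.
#'
#' @param rs A [root_system()].
#' @param include_fine_roots Merge fine-root positions into the branch list?
#' @return A tibble: `axis_id`, `order`, `n_branch_points`,
#'   `inter_lateral_length` (m).
#' @export
inter_lateral_length <- function(rs, include_fine_roots = TRUE) {
  paths <- axis_paths(rs)
  children <- children_map(paths)
  rows <- purrr::map(paths, function(p) {
    pos <- children[[p$axis_id]]$s
    if (include_fine_roots) {
      frc <- p$fine_root_count
      pos <- c(pos, rep(p$s_bounds[-1], frc))
    }
    pos <- sort(pos)
    tibble::tibble(
      axis_id = p$axis_id, order = p$order,
      n_branch_points = length(pos),
      inter_lateral_length = if (length(pos) >= 2) mean(diff(pos)) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}
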