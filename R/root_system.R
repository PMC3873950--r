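# Core container: a root system is a rooted tree of digitized segments plus
# plant-level metadata and the container geometry it grew in.

seg_cols <- c(
  "segment_id", "parent_id", "axis_id", "order",
  "base_x", "base_y", "base_z", "tip_x", "tip_y", "tip_z",
  "diameter", "fine_root_count", "fine_root_mean_length"
)

#' Construct a root system
#'
#' A `root_system` bundles a segment table (one row per digitized inter-node)
#' with plant metadata and container geometry. All coordinates are in metres
#' in the container frame: the origin is the collar, `x` points north/upslope
#' (azimuth 0), `y` runs parallel to the upper container border, and `z` is
#' perpendicular to the soil surface, positive upward (so depths are
#' negative).
#'
#' @param segments A data frame with columns `segment_id`, `parent_id`
#'   (`NA` for the collar segment), `axis_id`, `order` (1 for the
#'   stump + taproot axis), `base_x/y/z`, `tip_x/y/z` (metres), `diameter`
#'   (basal diameter, metres), `fine_root_count` and `fine_root_mean_length`
#'   (metres) for unmeasured fine roots (basal diameter < 0.7 mm) borne by
#'   the segment.
#' @param plant_id Plant identifier.
#' @param slope_deg Container tilt, 0 (flat) or 45 (slope).
#' @param flexed Logical; was the shoot flexed daily?
#' @param block Experimental block label.
#' @param container Numeric length-3: container width along x, width along y,
#'   and soil depth, in metres. Default `c(0.30, 0.30, 0.11)`, the standard
#'   square pot with 0.11 m of soil.
#' @param shoot_dry_weight_g,root_dry_weight_g Optional dry weights in grams.
#' @param volume_mode Solid model for segment volume: `"frustum"` (default)
#'   uses the basal diameter and the next segment's basal diameter;
#'   `"cylinder"` uses the basal diameter alone. The distal segment of an
#'   axis is always a cylinder of its basal diameter.
#'
#' @return An object of class `root_system`.
#' @export
#' @examples
#' rs <- root_system(tibble::tibble(
#'   segment_id = c("S1", "S2"), parent_id = c(NA, "S1"),
#'   axis_id = c("A1", "A1"), order = c(1L, 1L),
#'   base_x = c(0, 0), base_y = c(0, 0), base_z = c(0, -0.05),
#'   tip_x = c(0, 0), tip_y = c(0, 0), tip_z = c(-0.05, -0.10),
#'   diameter = c(0.008, 0.006),
#'   fine_root_count = c(0L, 0L), fine_root_mean_length = c(0, 0)
#' ), plant_id = "demo")
#' rs
root_system <- function(segments, plant_id = "plant",
                        slope_deg = 0, flexed = FALSE, block = "b1",
                        container = c(0.30, 0.30, 0.11),
                        shoot_dry_weight_g = NA_real_,
                        root_dry_weight_g = NA_real_,
                        volume_mode = c("frustum", "cylinder")) {
  volume_mode <- match.arg(volume_mode)
  segments <- tibble::as_tibble(segments)
  missing_cols <- setdiff(seg_cols, names(segments))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "segment table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  segments <- dplyr::mutate(
    segments[seg_cols],
    segment_id = as.character(.data$segment_id),
    parent_id = as.character(.data$parent_id),
    axis_id = as.character(.data$axis_id),
    order = as.integer(.data$order),
    fine_root_count = as.integer(.data$fine_root_count),
    dplyr::across(dplyr::all_of(c(
      "base_x", "base_y", "base_z", "tip_x", "tip_y", "tip_z",
      "diameter", "fine_root_mean_length"
    )), as.numeric)
  )
  if (anyDuplicated(segments$segment_id)) {
    rlang::abort("duplicate segment_id in segment table")
  }
  if (!slope_deg %in% c(0, 45)) {
    rlang::abort("slope_deg must be 0 or 45")
  }
  structure(
    list(
      segments = segments,
      plant_id = as.character(plant_id),
      slope_deg = as.numeric(slope_deg),
      flexed = isTRUE(flexed),
      block = as.character(block),
      container = as.numeric(container),
      shoot_dry_weight_g = as.numeric(shoot_dry_weight_g),
      root_dry_weight_g = as.numeric(root_dry_weight_g),
      volume_mode = volume_mode,
      ground_truth = NULL
    ),
    class = "root_system"
  )
}

#' @export
print.root_system <- function(x, ...) {
  cat(sprintf(
    "<root_system> plant %s: %d segments, %d axes, max order %d\n",
    x$plant_id, nrow(x$segments),
    dplyr::n_distinct(x$segments$axis_id), max(x$segments$order)
  ))
  cat(sprintf(
    "  slope %g deg, %s, block %s; container %.2f x %.2f x %.2f m\n",
    x$slope_deg, if (x$flexed) "flexed" else "not flexed", x$block,
    x$container[1], x$container[2], x$container[3]
  ))
  invisible(x)
}

#' Check the structural invariants of a root system
#'
#' Violations are returned as data, not raised as conditions, so a whole
#' cohort can be screened and reported in one pass.
#'
#' @param rs A [root_system()].
#' @param tol Positional tolerance in metres for the attachment rule that a
#'   segment's base must coincide with its parent's tip.
#' @return A tibble with columns `segment_id`, `rule`, `detail`; zero rows
#'   when every invariant holds.
#' @export
validate_root_system <- function(rs, tol = 1e-6) {
  seg <- rs$segments
  v <- list()
  bad <- function(ids, rule, detail) {
    tibble::tibble(segment_id = as.character(ids), rule = rule, detail = detail)
  }

  neg <- seg$segment_id[seg$diameter < 0]
  if (length(neg)) v <- c(v, list(bad(neg, "negative_diameter", "diameter < 0")))
  negf <- seg$segment_id[seg$fine_root_count < 0]
  if (length(negf)) v <- c(v, list(bad(negf, "negative_fine_root_count", "fine_root_count < 0")))

  collars <- seg$segment_id[is.na(seg$parent_id)]
  if (length(collars) != 1) {
    v <- c(v, list(bad(NA, "collar_count",
                       sprintf("expected exactly 1 parentless segment, found %d", length(collars)))))
  }
  orphan <- seg$segment_id[!is.na(seg$parent_id) & !(seg$parent_id %in% seg$segment_id)]
  if (length(orphan)) {
    v <- c(v, list(bad(orphan, "orphan", "parent_id not present in segment table")))
  }

  # order can only stay or increase by one from parent to child
  idx <- match(seg$parent_id, seg$segment_id)
  has_par <- !is.na(idx)
  jump <- has_par & !(seg$order == seg$order[idx] | seg$order == seg$order[idx] + 1L)
  if (any(jump)) {
    v <- c(v, list(bad(seg$segment_id[jump], "order_jump",
                       "order(child) must be order(parent) or order(parent) + 1")))
  }

  # same-axis children continue at the same order; new axes step up by one
  same_axis <- has_par & seg$axis_id == seg$axis_id[idx]
  ax_bad <- same_axis & seg$order != seg$order[idx]
  if (any(ax_bad)) {
    v <- c(v, list(bad(seg$segment_id[ax_bad], "axis_order",
                       "segment continues its parent's axis at a different order")))
  }

  # attachment: base must coincide with parent tip
  if (any(has_par)) {
    d <- sqrt((seg$base_x - seg$tip_x[idx])^2 +
                (seg$base_y - seg$tip_y[idx])^2 +
                (seg$base_z - seg$tip_z[idx])^2)
    det <- has_par & d > tol
    if (any(det, na.rm = TRUE)) {
      det[is.na(det)] <- FALSE
      v <- c(v, list(bad(seg$segment_id[det], "detached",
                         "segment base does not coincide with parent tip")))
    }
  }

  # acyclicity / reachability from the collar
  if (length(collars) == 1 && length(orphan) == 0) {
    reach <- collars
    frontier <- collars
    kid_of <- split(seg$segment_id, seg$parent_id)
    while (length(frontier)) {
      frontier <- unlist(kid_of[frontier], use.names = FALSE)
      frontier <- setdiff(frontier, reach)
      reach <- c(reach, frontier)
    }
    unreach <- setdiff(seg$segment_id, reach)
    if (length(unreach)) {
      v <- c(v, list(bad(unreach, "unreachable",
                         "segment not reachable from the collar (cycle or detached subtree)")))
    }
  }

  if (length(v) == 0) {
    return(tibble::tibble(segment_id = character(), rule = character(), detail = character()))
  }
  dplyr::bind_rows(v)
}

assert_valid <- function(rs) {
  viol <- validate_root_system(rs)
  if (nrow(viol) > 0) {
    rlang::abort(paste0(
      "invalid root system (", nrow(viol), " violation(s)); first: ",
      viol$rule[1], " at segment ", viol$segment_id[1]
    ))
  }
  invisible(rs)
}

#' Segment table of a root system
#'
#' @param rs A [root_system()].
#' @return The segment tibble (one row per digitized segment).
#' @export
root_segments <- function(rs) rs$segments

#' @export
summary.root_system <- function(object, ...) {
  ap <- axis_paths(object)
  cat(sprintf(
    "<root_system> plant %s: %d segments, %d axes, total length %.3f m, total volume %.2f cm3\n",
    object$plant_id, nrow(object$segments), length(ap),
    sum(purrr::map_dbl(ap, "length")),
    sum(purrr::map_dbl(ap, "volume")) * 1e6
  ))
  invisible(object)
}
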