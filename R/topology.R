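# Topological analysis: the exterior-path-length index qb and the mean
# branching order (MBO).
#
# The link tree of a root system follows the classical topological analysis
# of branching structures: an axis bearing m branches contributes m interior
# links (one between consecutive branch points) and one exterior link (last
# branch point to the tip); a lateral subtree hangs from its branch point.
# The path length of an exterior link is the number of links from the collar
# to that link, inclusive. qb normalises the sum of exterior path lengths
# between the minimum of the most balanced (dichotomous) binary topology
# (qb = 0) and the maximum of the herringbone topology (qb = 1) with the
# same number of exterior links. Multifurcations are resolved to binary
# trees by serial splitting (coincident branch points become consecutive
# binary nodes, in stable position order).

# --- explicit topologies -----------------------------------------------------
# A topology is a nested list: leaf = "tip"; internal node = list(left, right)
# meaning "one link, then split". The element itself is entered through one
# link, so a bare "tip" is a single exterior link.

#' Reference binary topologies
#'
#' `topo_herringbone(n_tips)` is a main axis bearing unbranched laterals
#' (the wholly herringbone pattern); `topo_balanced(depth)` is the complete
#' balanced binary tree with `2^depth` tips (the wholly dichotomous pattern).
#'
#' @param n_tips Number of exterior links (>= 1).
#' @param depth Bifurcation depth (>= 0).
#' @return A topology object usable with [qb_topology()].
#' @export
topo_herringbone <- function(n_tips) {
  stopifnot(n_tips >= 1)
  t <- "tip"
  for (i in seq_len(n_tips - 1)) t <- list(t, "tip")
  t
}

#' @rdname topo_herringbone
#' @export
topo_balanced <- function(depth) {
  stopifnot(depth >= 0)
  if (depth == 0) return("tip")
  list(topo_balanced(depth - 1), topo_balanced(depth - 1))
}

# number of exterior links
n_tips <- function(t) {
  if (identical(t, "tip")) return(1L)
  sum(vapply(t, n_tips, integer(1)))
}

# sum of exterior path lengths; the element is entered at link depth `d`
pe_sum <- function(t, d = 1L) {
  if (identical(t, "tip")) return(d)
  sum(vapply(t, pe_sum, numeric(1), d = d + 1L))
}

# extremes of Pe over binary topologies with n exterior links
pe_max_herringbone <- function(n) (n^2 + 3 * n - 2) / 2
pe_min_dichotomous <- function(n) {
  a <- floor(log2(n))
  (2^(a + 1) - n) * (a + 1) + 2 * (n - 2^a) * (a + 2)
}

qb_from_pe <- function(pe, n) {
  if (n < 3) return(NA_real_)
  lo <- pe_min_dichotomous(n)
  hi <- pe_max_herringbone(n)
  if (hi == lo) return(NA_real_)
  (pe - lo) / (hi - lo)
}

#' Topological index qb of an explicit topology
#'
#' qb positions an arbitrary binary tree between the wholly dichotomous
#' pattern (qb = 0) and the wholly herringbone pattern (qb = 1), based on
#' the sum of all path lengths from the collar to the exterior links.
#' Undefined (NA) for fewer than 3 exterior links, where the extremes
#' coincide.
#'
#' @param topo A topology from [topo_herringbone()], [topo_balanced()] or
#'   [link_tree()].
#' @return qb in `[0, 1]`, or `NA`.
#' @export
qb_topology <- function(topo) {
  qb_from_pe(pe_sum(topo), n_tips(topo))
}

# --- link tree of a root system ---------------------------------------------

# Build the topology of one axis and (recursively) everything it bears.
# `children` maps axis id -> tibble(axis_id, s); fine roots enter as extra
# exterior tips attached at the tip position of their bearing segment.
axis_topology <- function(aid, paths, children, include_fine_roots,
                          keep = NULL) {
  p <- paths[[aid]]
  kids <- children[[aid]]
  branches <- list()
  pos <- numeric(0)
  if (!is.null(kids)) {
    for (i in seq_len(nrow(kids))) {
      ka <- kids$axis_id[i]
      if (!is.null(keep) && !(ka %in% keep)) next
      branches <- c(branches, list(axis_topology(ka, paths, children,
                                                 include_fine_roots, keep)))
      pos <- c(pos, kids$s[i])
    }
  }
  if (include_fine_roots) {
    frc <- p$fine_root_count
    for (i in seq_along(frc)) {
      if (frc[i] > 0) {
        branches <- c(branches, replicate(frc[i], "tip", simplify = FALSE))
        pos <- c(pos, rep(p$s_bounds[i + 1], frc[i]))
      }
    }
  }
  if (length(branches) == 0) return("tip")
  ord <- order(pos)  # stable: coincident branches split serially
  t <- "tip"
  for (i in rev(ord)) t <- list(t, branches[[i]])
  t
}

# children map: axis id -> tibble of borne axes with attach positions
children_map <- function(paths) {
  rows <- purrr::map(paths, function(p) {
    if (is.na(p$parent_axis)) return(NULL)
    tibble::tibble(parent = p$parent_axis, axis_id = p$axis_id, s = p$attach_s)
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) return(list())
  purrr::map(split(tab, tab$parent), ~ .x[order(.x$s), ])
}

#' Link-tree topology of a root system
#'
#' @param rs A [root_system()].
#' @param scope `"total"` for the whole system, or a depth class
#'   (`"shallow"`, `"intermediate"`, `"deep"`) to keep only the lateral
#'   arborescences whose initial branching point on the order-1 root falls
#'   in that class (the order-1 chain and its tip remain the backbone).
#' @param include_fine_roots Count unmeasured fine roots as extra exterior
#'   links attached at their bearing segment's tip?
#' @return A topology object for [qb_topology()].
#' @export
link_tree <- function(rs, scope = "total", include_fine_roots = TRUE) {
  paths <- axis_paths(rs)
  o1 <- order1_axis(paths)
  children <- children_map(paths)
  keep <- NULL
  if (!identical(scope, "total")) {
    cls <- axis_classes(rs, paths)
    keep <- cls$axis_id[!is.na(cls$depth_class) & cls$depth_class == scope]
  }
  axis_topology(o1$axis_id, paths, children, include_fine_roots, keep)
}

#' Topological index qb of a root system
#'
#' @inheritParams link_tree
#' @return qb in `[0, 1]`; `NA` when the scoped tree has fewer than 3
#'   exterior links.
#' @export
qb <- function(rs, scope = "total", include_fine_roots = TRUE) {
  qb_topology(link_tree(rs, scope, include_fine_roots))
}

#' qb of a single lateral arborescence
#'
#' The subtree rooted at one second-order axis, scored on its own.
#'
#' @param rs A [root_system()].
#' @param axis_id Id of the arborescence's second-order axis.
#' @param include_fine_roots See [link_tree()].
#' @return qb in `[0, 1]`, or `NA` for arborescences with < 3 tips.
#' @export
arborescence_qb <- function(rs, axis_id, include_fine_roots = TRUE) {
  paths <- axis_paths(rs)
  children <- children_map(paths)
  qb_topology(axis_topology(axis_id, paths, children, include_fine_roots))
}

#' Mean branching order
#'
#' The mean, over lateral axes in scope, of the topological branching order
#' minus one, so a root system bearing only second-order laterals scores 1.
#' Fine roots count at the order of their bearing axis plus one, with
#' multiplicity equal to their count.
#'
#' @param rs A [root_system()].
#' @param scope `"total"` or a depth class, as in [link_tree()]; depth
#'   classes follow the arborescence's initial branching point.
#' @param include_fine_roots Include unmeasured fine roots?
#' @param sector Optionally restrict to lateral axes in one sector
#'   (`"us"`, `"pp"`, `"ds"`).
#' @return The mean branching order (`NA` for an empty scope).
#' @export
mbo <- function(rs, scope = "total", include_fine_roots = TRUE, sector = NULL) {
  paths <- axis_paths(rs)
  cls <- axis_classes(rs, paths)
  lat <- dplyr::filter(cls, .data$order > 1L)
  if (!identical(scope, "total")) {
    lat <- dplyr::filter(lat, .data$depth_class == scope)
  }
  if (!is.null(sector)) {
    lat <- dplyr::filter(lat, .data$sector == !!sector)
  }
  orders <- lat$order - 1L
  if (include_fine_roots) {
    for (aid in lat$axis_id) {
      p <- paths[[aid]]
      nfr <- sum(p$fine_root_count)
      if (nfr > 0) orders <- c(orders, rep(p$order, nfr))  # (order+1) - 1
    }
    # fine roots borne by the order-1 axis are order-2 laterals
    if (identical(scope, "total") || identical(scope, "shallow") ||
        identical(scope, "intermediate") || identical(scope, "deep")) {
      o1 <- order1_axis(paths)
      frc <- o1$fine_root_count
      if (is.null(sector) && any(frc > 0)) {
        z <- o1$verts[-1, 3]
        dc <- classify_depth(z)
        sel <- if (identical(scope, "total")) rep(TRUE, length(frc)) else dc == scope
        orders <- c(orders, rep(1L, sum(frc[sel])))
      }
    }
  }
  if (length(orders) == 0) return(NA_real_)
  mean(orders)
}
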