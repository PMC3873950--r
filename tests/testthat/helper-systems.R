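# Fixtures built in code: small hand-made root systems and independent
# oracles used across the test files.

seg_row <- function(id, parent, axis, order, base, tip, d,
                    frc = 0L, frl = 0) {
  tibble::tibble(
    segment_id = id, parent_id = parent, axis_id = axis, order = as.integer(order),
    base_x = base[1], base_y = base[2], base_z = base[3],
    tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
    diameter = d, fine_root_count = as.integer(frc), fine_root_mean_length = frl
  )
}

# taproot (2 segments) + one shallow lateral: the minimal two-axis system
toy_rs <- function(...) {
  root_system(dplyr::bind_rows(
    seg_row("S1", NA, "A1", 1, c(0, 0, 0), c(0, 0, -0.05), 0.008),
    seg_row("S2", "S1", "A1", 1, c(0, 0, -0.05), c(0, 0, -0.10), 0.005),
    seg_row("S3", "S1", "A2", 2, c(0, 0, -0.05), c(0.09, 0, -0.055), 0.003)
  ), plant_id = "toy", ...)
}

# one axis along `dirs` (list of unit vectors) with per-segment lengths and
# basal diameters; optionally borne by a short vertical mother
chain_rs <- function(lengths, diams, dirs = NULL, mother = FALSE,
                     mother_diam = 0.01, frc = NULL, ...) {
  n <- length(lengths)
  if (is.null(dirs)) dirs <- replicate(n, c(1, 0, 0), simplify = FALSE)
  if (is.null(frc)) frc <- rep(0L, n)
  rows <- list()
  if (mother) {
    rows[[1]] <- seg_row("M1", NA, "A0", 1, c(0, 0, 0.02), c(0, 0, 0), mother_diam)
    base <- c(0, 0, 0)
    parent <- "M1"
    axis <- "A1"; ord <- 2
  } else {
    base <- c(0, 0, 0)
    parent <- NA_character_
    axis <- "A1"; ord <- 1
  }
  for (i in seq_len(n)) {
    tip <- base + dirs[[i]] * lengths[i]
    rows[[length(rows) + 1]] <- seg_row(
      sprintf("C%d", i), parent, axis, ord, base, tip, diams[i], frc = frc[i],
      frl = if (frc[i] > 0) 0.02 else 0
    )
    parent <- sprintf("C%d", i)
    base <- tip
  }
  root_system(dplyr::bind_rows(rows), plant_id = "chain", ...)
}

# --- independent oracles -----------------------------------------------------

# all ordered rooted binary topologies with n exterior links
enum_topos <- function(n) {
  if (n == 1) return(list("tip"))
  out <- list()
  for (k in seq_len(n - 1)) {
    for (L in enum_topos(k)) for (R in enum_topos(n - k)) {
      out <- c(out, list(list(L, R)))
    }
  }
  out
}

# Pe by an igraph shortest-path computation, independent of the package's
# recursive accumulation: each element (node or tip) is one link; the path
# length of an exterior link is the vertex count from the root element to
# the tip element inclusive.
oracle_pe <- function(topo) {
  edges <- integer(0)
  leaves <- integer(0)
  counter <- 0L
  walk <- function(t, parent) {
    counter <<- counter + 1L
    me <- counter
    if (!is.na(parent)) edges <<- c(edges, parent, me)
    if (identical(t, "tip")) {
      leaves <<- c(leaves, me)
    } else {
      for (child in t) walk(child, me)
    }
    me
  }
  walk(topo, NA)
  if (length(edges) == 0) return(1)
  g <- igraph::make_graph(edges, directed = FALSE)
  d <- igraph::distances(g, v = 1, to = leaves)
  sum(d + 1)
}

# polyline length oracle
oracle_polyline_length <- function(verts) {
  sum(sqrt(rowSums(diff(verts)^2)))
}

# rotate a root system's coordinates about the z axis (degrees)
rotate_rs <- function(rs, theta_deg) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  seg <- rs$segments
  b <- as.matrix(seg[, c("base_x", "base_y", "base_z")]) %*% t(R)
  t_ <- as.matrix(seg[, c("tip_x", "tip_y", "tip_z")]) %*% t(R)
  seg[, c("base_x", "base_y", "base_z")] <- b
  seg[, c("tip_x", "tip_y", "tip_z")] <- t_
  rs$segments <- seg
  rs
}

total_volume_of <- function(rs) {
  sum(purrr::map_dbl(rootarch:::axis_paths(rs), "volume"))
}

total_length_of <- function(rs) {
  sum(purrr::map_dbl(rootarch:::axis_paths(rs), "length"))
}

# a bearing axis with one branch event; daughters attach at the tip of the
# first segment, the axis continues (or not) beyond it
event_rs <- function(d_before, d_cont = NULL, d_daughters, cont_length = 0.05,
                     cont_end = NULL) {
  rows <- list(
    seg_row("S1", NA, "A1", 1, c(0, 0, 0), c(0, 0, -0.05), d_before)
  )
  if (!is.null(d_cont)) {
    rows[[2]] <- seg_row("S2", "S1", "A1", 1, c(0, 0, -0.05),
                         c(0, 0, -0.05 - cont_length), d_cont)
    if (!is.null(cont_end)) {
      rows[[3]] <- seg_row("S3", "S2", "A1", 1, c(0, 0, -0.05 - cont_length),
                           c(0, 0, -0.07 - cont_length), cont_end)
    }
  }
  for (j in seq_along(d_daughters)) {
    rows[[length(rows) + 1]] <- seg_row(
      sprintf("L%d", j), "S1", sprintf("A%d", j + 1), 2,
      c(0, 0, -0.05), c(0.06 * cos(j), 0.06 * sin(j), -0.05), d_daughters[j]
    )
  }
  root_system(dplyr::bind_rows(rows), plant_id = "event")
}

csa_of <- function(d) pi / 4 * d^2

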