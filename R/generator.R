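# Synthetic container-grown seedling root systems.
#
# The generator is phenomenological: it samples a final architecture (one
# gravitropic taproot, shallow laterals tracking the soil surface, diameter
# taper within axes and across branch events, tunable herringbone vs
# dichotomous higher-order branching, tunable azimuthal anisotropy, wall
# deflection inside the container) rather than simulating growth. Hidden
# ground truth (true un-deflected tips, realized origin depths, configured
# distribution parameters) is stored alongside so that every downstream
# measurement can be checked against what was generated.

#' Generator configuration
#'
#' Defaults emulate a six-month container-grown seedling as digitized in
#' glasshouse studies of coarse-root architecture: collar diameter about
#' 9 mm, a 0.16 m near-vertical order-1 root tapering at ~6% diameter per
#' cm, a dozen measured laterals (mostly shallow and near-parallel to the
#' soil surface, with rare sinkers and oblique roots), CSA allocation at
#' branch points around p_branch 1.4 / q 0.75 on the taproot and p_branch
#' 1.05 / q 0.67 on laterals, and unmeasured fine roots (< 0.7 mm) recorded
#' only as counts and a mean length.
#'
#' @param seed Integer seed; the same configuration and seed always
#'   reproduce the same root system.
#' @param plant_id,slope_deg,flexed,block,container Plant metadata; see
#'   [root_system()].
#' @param taproot_length Total order-1 length (m), before wall deflection.
#' @param taproot_basal_diameter Basal (collar) diameter of the order-1
#'   root, m.
#' @param taproot_taper,lateral_taper Within-axis diameter decrease, % per
#'   cm, applied between branch points.
#' @param taproot_tilt_deg Deviation of the taproot from the vertical,
#'   degrees; `taproot_tilt_azimuth` its direction (NA = random).
#' @param segment_length Digitizing resolution: target segment length, m.
#' @param n_laterals Number of measured second-order laterals.
#' @param origin_weights Named weights for lateral origin depth classes
#'   (shallow / intermediate / deep initial branching point on the order-1
#'   root).
#' @param azimuth_distribution `"uniform"`, `"vonmises"` (mean
#'   `azimuth_mu`, concentration `azimuth_kappa`) or `"stratified"` (exact
#'   even spacing `180/n + k * 360/n`, which avoids all sector boundaries
#'   and makes sector shares exact).
#' @param azimuth_mu,azimuth_kappa Von Mises parameters, degrees / unitless.
#' @param lateral_angle_mean,lateral_angle_sd Angle toward the soil surface
#'   of horizontal laterals, degrees (negative = descending).
#' @param p_sinker,p_oblique Probability that a shallow-origin lateral is
#'   vertical (sinker) or oblique instead of horizontal.
#' @param lateral_length_mean,lateral_length_sd Second-order axis length, m.
#' @param stump_p_branch,stump_q,taproot_p_branch,taproot_q,lateral_p_branch,lateral_q
#'   Target CSA scaling at branch events, per bearing scope: `p_branch` =
#'   CSA before / CSA after, `q` = continuing share of post-branch CSA.
#'   The stump allocates more gently than the taproot below it.
#' @param lateral_diameter Fixed basal diameter (m) for all second-order
#'   laterals; overrides the CSA allocation rule (used by the stratified
#'   mode so that laterals are exactly identical).
#' @param tertiary_rate Expected third-order branches per cm of shallow
#'   lateral.
#' @param herringbone_weight h in `[0, 1]`: probability that a new
#'   higher-order branch attaches to the main chain of its arborescence
#'   (herringbone end) rather than to the shallowest exterior position
#'   (balanced end). h = 1 gives qb = 1 arborescences; h = 0 with a
#'   power-of-two tip count gives qb = 0.
#' @param child_length_ratio Length of a higher-order branch relative to
#'   its bearer.
#' @param fine_root_rate Expected unmeasured fine roots per cm of measured
#'   axis; `fine_root_mean_length` their recorded mean length, m.
#' @param wiggle_deg Per-segment direction jitter of laterals, degrees
#'   (the taproot is grown straight, as digitized taproots essentially are).
#' @param wall_behaviour `"deflect"` (root follows the container face,
#'   the straight-growth tip is kept as hidden ground truth) or `"clip"`
#'   (axis truncated at the face).
#' @param min_diameter Floor for measured diameters, m (the digitizing
#'   threshold below which roots are only counted as fine roots).
#' @param size_jitter Lognormal sd of plant-to-plant variability applied to
#'   taproot length, collar diameter and mean lateral length.
#' @param root_density Dry weight per root volume, g cm^-3, used to derive
#'   plant dry weights; `rpc_biomass` the root mass fraction used to derive
#'   the shoot weight.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             plant_id = "plant_1",
                             slope_deg = 0,
                             flexed = FALSE,
                             block = "b1",
                             container = c(0.30, 0.30, 0.11),
                             taproot_length = 0.16,
                             taproot_basal_diameter = 0.009,
                             taproot_taper = 6,
                             lateral_taper = 4.5,
                             taproot_tilt_deg = 15,
                             taproot_tilt_azimuth = NA_real_,
                             segment_length = 0.012,
                             n_laterals = 12L,
                             origin_weights = c(shallow = 0.6, intermediate = 0.3, deep = 0.1),
                             azimuth_distribution = c("uniform", "vonmises", "stratified"),
                             azimuth_mu = 0,
                             azimuth_kappa = 2,
                             lateral_angle_mean = -8,
                             lateral_angle_sd = 5,
                             p_sinker = 0.02,
                             p_oblique = 0.05,
                             lateral_length_mean = 0.13,
                             lateral_length_sd = 0.025,
                             stump_p_branch = 1.2,
                             stump_q = 0.78,
                             taproot_p_branch = 1.4,
                             taproot_q = 0.75,
                             lateral_p_branch = 1.05,
                             lateral_q = 0.67,
                             lateral_diameter = NULL,
                             tertiary_rate = 0.05,
                             herringbone_weight = 0.6,
                             child_length_ratio = 0.45,
                             fine_root_rate = 0.04,
                             fine_root_mean_length = 0.02,
                             wiggle_deg = 2,
                             wall_behaviour = c("deflect", "clip"),
                             min_diameter = 0.0008,
                             size_jitter = 0.10,
                             root_density = 0.528,
                             rpc_biomass = 0.20) {
  cfg <- as.list(environment())
  cfg$azimuth_distribution <- match.arg(azimuth_distribution)
  cfg$wall_behaviour <- match.arg(wall_behaviour)
  if (cfg$herringbone_weight < 0 || cfg$herringbone_weight > 1) {
    rlang::abort("herringbone_weight must be in [0, 1]")
  }
  if (cfg$taproot_basal_diameter <= 0 || cfg$min_diameter <= 0) {
    rlang::abort("diameters must be positive")
  }
  if (any(c(cfg$taproot_length, cfg$lateral_length_mean, cfg$fine_root_rate,
            cfg$tertiary_rate) < 0)) {
    rlang::abort("lengths and rates must be non-negative")
  }
  structure(cfg, class = "generator_config")
}

#' Stratified-azimuth configuration for exact sector tests
#'
#' `n` identical shallow horizontal laterals at azimuths `180/n + k * 360/n`
#' (22.5 + k*45 degrees for n = 8), none on a sector boundary: every noise
#' source is switched off and the taproot is vertical, so the upslope sector
#' holds exactly 25% of lateral volume, length and number.
#'
#' @param n_laterals Number of laterals (default 8).
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
config_stratified <- function(n_laterals = 8L, ...) {
  generator_config(
    n_laterals = n_laterals,
    azimuth_distribution = "stratified",
    origin_weights = c(shallow = 1, intermediate = 0, deep = 0),
    taproot_tilt_deg = 0,
    lateral_angle_sd = 0, lateral_length_sd = 0,
    lateral_length_mean = 0.10,
    lateral_diameter = 0.002,
    p_sinker = 0, p_oblique = 0,
    tertiary_rate = 0, fine_root_rate = 0, wiggle_deg = 0, size_jitter = 0,
    ...
  )
}

# von Mises sampler (Best & Fisher 1979); kappa = 0 falls back to uniform.
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa <= 0) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  (mu_deg + out * 180 / pi) %% 360
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) rlang::abort("zero direction vector")
  v / n
}

dir_from_angles <- function(azimuth_deg, surface_angle_deg) {
  az <- azimuth_deg * pi / 180
  an <- surface_angle_deg * pi / 180
  c(cos(an) * cos(az), cos(an) * sin(az), sin(an))
}

# Grow one axis polyline from `base` along `dir0` with boundaries at `breaks`
# (cumulative curvilinear positions, last = total length). Direction jitter
# applies while the axis grows freely and is frozen at the first container
# contact; the deflected part follows the face while the hidden true path
# continues straight, so the straight-growth tip is exact ground truth.
grow_axis_polyline <- function(base, dir0, breaks, wiggle_deg, container,
                               wall_behaviour) {
  steps <- diff(c(0, breaks))
  wx <- container[1] / 2; wy <- container[2] / 2; dz <- container[3]
  inside <- function(p, tol = 1e-12) {
    abs(p[1]) <= wx + tol && abs(p[2]) <= wy + tol && p[3] >= -dz - tol
  }
  # signed distance to each face (positive inside)
  face_norms <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, 1))
  face_offs <- c(wx, wx, wy, wy, dz)
  dist_to <- function(p) face_offs + face_norms %*% p
  verts <- matrix(NA_real_, length(steps) + 1, 3)
  verts[1, ] <- base
  pos <- base
  true_pos <- base
  dir <- unit3(dir0)
  contacted <- FALSE
  contact_vertex <- NA_integer_
  sdj <- sin(wiggle_deg * pi / 180)
  i <- 1L
  n_steps <- length(steps)
  while (i <= n_steps) {
    len <- steps[i]
    if (!contacted && wiggle_deg > 0) {
      dir <- unit3(dir + stats::rnorm(3, 0, sdj))
    }
    tip <- pos + dir * len
    if (!contacted && !inside(tip)) {
      # find the contact point and split the step there, so that the
      # contact becomes a vertex and the arriving segment keeps the true
      # pre-contact direction (as a digitizer would record it)
      dd <- dist_to(pos)
      step_d <- drop(face_norms %*% (dir * len))
      t_hit <- suppressWarnings(min(ifelse(step_d < 0, dd / (-step_d), Inf)))
      t_hit <- max(0, min(1, t_hit))
      contact <- pos + dir * len * t_hit
      contacted <- TRUE
      if (wall_behaviour == "clip") {
        verts[i + 1, ] <- contact
        verts <- verts[seq_len(i + 1), , drop = FALSE]
        true_pos <- contact
        contact_vertex <- i + 1L
        break
      }
      # insert the contact vertex: the current step is split in two
      verts <- rbind(
        verts[seq_len(i), , drop = FALSE], rep(NA_real_, 3),
        verts[seq(i + 1, n_steps + 1), , drop = FALSE]
      )
      steps <- c(steps[seq_len(i - 1)], len * t_hit, len * (1 - t_hit),
                 if (i < n_steps) steps[seq(i + 1, n_steps)])
      n_steps <- length(steps)
      verts[i + 1, ] <- contact
      contact_vertex <- i + 1L
      true_pos <- contact
      pos <- contact
      i <- i + 1L
      next
    }
    if (contacted) {
      true_pos <- true_pos + dir * len
      # actual path: project the frozen direction onto whichever faces are
      # violated (corners need up to two projections)
      adir <- dir
      for (rep_ in 1:3) {
        tip <- pos + adir * len
        dd <- drop(dist_to(tip))
        if (all(dd >= -1e-12)) break
        f <- which.min(dd)
        nrm <- face_norms[f, ]
        adir <- adir - sum(adir * nrm) * nrm
        if (sqrt(sum(adir^2)) < 1e-9) {
          adir <- c(-dir[2], dir[1], 0)  # degenerate head-on hit: slide
          if (sqrt(sum(adir^2)) < 1e-9) adir <- c(1, 0, 0)
        }
        adir <- unit3(adir)
      }
      tip <- pos + adir * len
    } else {
      true_pos <- tip
    }
    verts[i + 1, ] <- tip
    pos <- tip
    i <- i + 1L
  }
  list(verts = verts, contacted = contacted, contact_vertex = contact_vertex,
       true_tip = true_pos)
}

# Boundary diameters along an axis: exponential within-axis taper between
# branch events, CSA reallocation (p_branch, q) at branch events; returns
# per-segment basal diameters and the basal CSA granted to daughters at
# each branching boundary. The diameter recorded AT a branching boundary is
# the pre-branch measurement (digitized just before the branch); the
# post-branch allocation shows up from the next measurement point onward.
axis_diameters <- function(s_bounds, branch_bounds, d0, taper_pct_cm,
                           p_branch, q_alloc, min_d) {
  n_seg <- length(s_bounds) - 1
  d_basal <- numeric(n_seg)
  daughter_csa <- stats::setNames(
    rep(NA_real_, length(branch_bounds)), sprintf("%.9f", branch_bounds)
  )
  p_branch <- rep_len(p_branch, length(branch_bounds))
  q_alloc <- rep_len(q_alloc, length(branch_bounds))
  cc <- csa(d0)  # running CSA carried forward to the next boundary
  d_basal[1] <- d0
  if (n_seg >= 1) {
    for (i in seq_len(n_seg)[-1]) {
      gap_cm <- (s_bounds[i] - s_bounds[i - 1]) * 100
      cc <- cc * exp(-2 * taper_pct_cm / 100 * gap_cm)
      cc <- max(cc, csa(min_d))
      d_basal[i] <- sqrt(4 * cc / pi)  # recorded: still pre-branch here
      hit <- which(abs(branch_bounds - s_bounds[i]) < 1e-9)
      if (length(hit) == 1) {
        after <- cc / p_branch[hit]
        daughter_csa[hit] <- (1 - q_alloc[hit]) * after
        cc <- max(q_alloc[hit] * after, csa(min_d))
      }
    }
  }
  # events at the very tip (no continuing segment): daughters share it all
  tip_hit <- which(abs(branch_bounds - s_bounds[n_seg + 1]) < 1e-9)
  if (length(tip_hit) == 1) {
    daughter_csa[tip_hit] <- csa(d_basal[n_seg]) / p_branch
  }
  list(d_basal = d_basal, daughter_csa = daughter_csa)
}

# Abstract arborescence topology grown by m sequential attachments on the
# nested-node representation (node = list(rest-of-chain, branch)): with
# probability h the new tip becomes one more lateral on the main chain
# (herringbone move); otherwise the shallowest leaf of the whole tree is
# split (breadth-first move, which yields the complete balanced tree when
# the tip count reaches a power of two). The left spine of the result is
# realized as the main axis.
build_arbo_topology <- function(m_branches, h) {
  t <- "tip"
  for (b in seq_len(m_branches)) {
    t <- if (stats::runif(1) <= h) herringbone_insert(t) else split_shallowest(t)
  }
  t
}

# add a new unbranched lateral at the distal end of the main chain
herringbone_insert <- function(t) {
  if (identical(t, "tip")) return(list("tip", "tip"))
  t[[1]] <- herringbone_insert(t[[1]])
  t
}

min_leaf_depth <- function(t) {
  if (identical(t, "tip")) return(1)
  1 + min(vapply(t, min_leaf_depth, numeric(1)))
}

split_shallowest <- function(t) {
  if (identical(t, "tip")) return(list("tip", "tip"))
  depths <- vapply(t, min_leaf_depth, numeric(1))
  k <- which.min(depths)
  t[[k]] <- split_shallowest(t[[k]])
  t
}

#' Generate a synthetic root system
#'
#' @param config A [generator_config()].
#' @return A validated [root_system()]. Hidden ground truth is attached as
#'   the `ground_truth` element: per-axis true (straight-growth) tips,
#'   contact flags, realized origin depths and intended azimuths/angles,
#'   plus the generating configuration.
#' @export
generate_root_system <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  withr::local_seed(cfg$seed)

  # plant-to-plant size variability (lognormal on the main dimensions)
  if (cfg$size_jitter > 0) {
    jit <- function(x) x * exp(stats::rnorm(1, 0, cfg$size_jitter))
    cfg$taproot_length <- jit(cfg$taproot_length)
    cfg$taproot_basal_diameter <- jit(cfg$taproot_basal_diameter)
    cfg$lateral_length_mean <- jit(cfg$lateral_length_mean)
  }

  env <- new.env()
  env$rows <- list()
  env$truth <- list()
  env$seg_n <- 0L
  env$axis_n <- 0L
  env$extra_fine <- list()  # sub-threshold daughters recorded as fine roots

  add_axis <- function(verts, d_basal, parent_segment, order) {
    env$axis_n <- env$axis_n + 1L
    aid <- sprintf("A%03d", env$axis_n)
    n <- nrow(verts) - 1
    ids <- sprintf("S%04d", env$seg_n + seq_len(n))
    env$seg_n <- env$seg_n + n
    env$rows[[length(env$rows) + 1]] <- tibble::tibble(
      segment_id = ids,
      parent_id = c(parent_segment, ids[-n]),
      axis_id = aid, order = as.integer(order),
      base_x = verts[-(n + 1), 1], base_y = verts[-(n + 1), 2],
      base_z = verts[-(n + 1), 3],
      tip_x = verts[-1, 1], tip_y = verts[-1, 2], tip_z = verts[-1, 3],
      diameter = d_basal,
      fine_root_count = 0L, fine_root_mean_length = cfg$fine_root_mean_length
    )
    list(axis_id = aid, ids = ids)
  }

  regular_breaks <- function(L, extra = numeric(0)) {
    g <- seq(cfg$segment_length, L, by = cfg$segment_length)
    b <- sort(unique(c(g, extra, L)))
    b <- b[b > 1e-9 & b <= L + 1e-9]
    b[length(b)] <- L
    # drop boundaries closer than 1 mm to each other (keep branch points)
    keep <- c(TRUE, diff(b) > 1e-3)
    keep[b %in% extra] <- TRUE
    keep[length(b)] <- TRUE
    sort(unique(b[keep]))
  }

  # --- order-1 root ----------------------------------------------------------
  tilt_az <- if (is.na(cfg$taproot_tilt_azimuth)) stats::runif(1, 0, 360) else
    cfg$taproot_tilt_azimuth
  dir0 <- dir_from_angles(tilt_az, -(90 - cfg$taproot_tilt_deg))

  # lateral origin depth targets
  n_lat <- cfg$n_laterals
  w <- cfg$origin_weights[c("shallow", "intermediate", "deep")]
  w[is.na(w)] <- 0
  classes <- sample(names(w), n_lat, replace = TRUE, prob = w)
  depth_target <- vapply(classes, function(cl) {
    switch(cl,
      shallow = stats::runif(1, -0.030, -0.006),
      intermediate = stats::runif(1, -0.068, -0.036),
      deep = stats::runif(1, -0.105, -0.071)
    )
  }, numeric(1))

  # first pass: straight taproot on a regular grid to locate origin depths
  probe <- grow_axis_polyline(c(0, 0, 0), dir0,
                              regular_breaks(cfg$taproot_length),
                              wiggle_deg = 0, container = cfg$container,
                              wall_behaviour = cfg$wall_behaviour)
  zb <- probe$verts[, 3]
  sb <- c(0, cumsum(sqrt(rowSums(diff(probe$verts)^2))))
  s_of_depth <- function(zt) {
    k <- which(zb <= zt)
    if (length(k) == 0) return(max(sb) * stats::runif(1, 0.5, 1))
    k <- k[1]
    if (k == 1) return(0)
    sb[k - 1] + (zt - zb[k - 1]) / (zb[k] - zb[k - 1]) * (sb[k] - sb[k - 1])
  }
  attach_s <- vapply(depth_target, s_of_depth, numeric(1))
  attach_s <- pmin(pmax(attach_s, 0.004), max(sb) - 0.004)
  attach_s <- round(attach_s, 6)
  # grow again (deterministic: no jitter) with origins as exact boundaries
  tap_breaks <- regular_breaks(cfg$taproot_length, extra = attach_s)
  tap <- grow_axis_polyline(c(0, 0, 0), dir0, tap_breaks, 0,
                            cfg$container, cfg$wall_behaviour)
  tap_sb <- c(0, cumsum(sqrt(rowSums(diff(tap$verts)^2))))
  branch_bounds <- sort(unique(attach_s))
  on_stump <- branch_bounds <= 0.045 + 1e-12
  dd <- axis_diameters(tap_sb, branch_bounds, cfg$taproot_basal_diameter,
                       cfg$taproot_taper,
                       ifelse(on_stump, cfg$stump_p_branch, cfg$taproot_p_branch),
                       ifelse(on_stump, cfg$stump_q, cfg$taproot_q),
                       cfg$min_diameter)
  tap_ax <- add_axis(tap$verts, dd$d_basal, NA_character_, 1L)
  env$truth[[length(env$truth) + 1]] <- tibble::tibble(
    axis_id = tap_ax$axis_id, order = 1L, contacted = tap$contacted,
    true_tip_x = tap$true_tip[1], true_tip_y = tap$true_tip[2],
    true_tip_z = tap$true_tip[3],
    intended_azimuth = tilt_az, intended_angle = -(90 - cfg$taproot_tilt_deg),
    origin_class = NA_character_, origin_depth = NA_real_,
    contact_vertex = tap$contact_vertex, n_vertices = nrow(tap$verts)
  )

  # --- lateral azimuths ------------------------------------------------------
  azimuths <- switch(cfg$azimuth_distribution,
    uniform = stats::runif(n_lat, 0, 360),
    vonmises = rvonmises_deg(n_lat, cfg$azimuth_mu, cfg$azimuth_kappa),
    stratified = (cfg$azimuth_mu + 180 / n_lat + (seq_len(n_lat) - 1) * 360 / n_lat) %% 360
  )

  # number of coincident daughters per branching boundary (multifurcations)
  n_at <- table(sprintf("%.9f", attach_s))

  realize_lateral <- function(i) {
    s <- attach_s[i]
    key <- sprintf("%.9f", s)
    c_d <- dd$daughter_csa[[key]] / n_at[[key]]
    d0 <- if (!is.null(cfg$lateral_diameter)) cfg$lateral_diameter else
      max(sqrt(4 * c_d / pi), cfg$min_diameter)
    k <- which(abs(tap_sb - s) < 1e-9)
    base <- tap$verts[k, ]
    parent_seg <- tap_ax$ids[k - 1]
    cls <- classes[i]
    u <- stats::runif(1)
    angle <- if (cls == "shallow" && u < cfg$p_sinker) {
      stats::rnorm(1, -75, 4)
    } else if (cls == "shallow" && u < cfg$p_sinker + cfg$p_oblique) {
      stats::rnorm(1, -45, 4)
    } else {
      stats::rnorm(1, cfg$lateral_angle_mean, cfg$lateral_angle_sd)
    }
    angle <- max(min(angle, 85), -89)
    len <- max(stats::rnorm(1, cfg$lateral_length_mean, cfg$lateral_length_sd),
               0.02)
    m <- if (cfg$tertiary_rate > 0 && cls == "shallow") {
      stats::rpois(1, cfg$tertiary_rate * len * 100)
    } else 0L
    topo <- build_arbo_topology(m, cfg$herringbone_weight)
    topo_branches <- if (identical(topo, "tip")) list() else flatten_chain(topo)
    realize_axis(base, azimuths[i], angle, len, d0, parent_seg, 2L,
                 topo_branches, cls, s)
  }

  realize_axis <- function(base, az, angle, len, d0, parent_seg, order,
                           topo_branches, origin_class, origin_s) {
    m <- length(topo_branches)
    br_s <- if (m > 0) round(len * seq_len(m) / (m + 1), 9) else numeric(0)
    breaks <- regular_breaks(len, extra = br_s)
    g <- grow_axis_polyline(base, dir_from_angles(az, angle), breaks,
                            cfg$wiggle_deg, cfg$container, cfg$wall_behaviour)
    g_sb <- c(0, cumsum(sqrt(rowSums(diff(g$verts)^2))))
    dx <- axis_diameters(g_sb, br_s, d0, cfg$lateral_taper,
                         cfg$lateral_p_branch, cfg$lateral_q, cfg$min_diameter)
    ax <- add_axis(g$verts, dx$d_basal, parent_seg, order)
    env$truth[[length(env$truth) + 1]] <- tibble::tibble(
      axis_id = ax$axis_id, order = as.integer(order), contacted = g$contacted,
      true_tip_x = g$true_tip[1], true_tip_y = g$true_tip[2],
      true_tip_z = g$true_tip[3],
      intended_azimuth = az, intended_angle = angle,
      origin_class = origin_class, origin_depth = base[3],
      contact_vertex = g$contact_vertex, n_vertices = nrow(g$verts)
    )
    for (j in seq_along(topo_branches)) {
      kx <- which(abs(g_sb - br_s[j]) < 1e-9)
      if (length(kx) != 1) next  # clipped before this branch point
      sub <- topo_branches[[j]]
      sub_branches <- if (identical(sub, "tip")) list() else
        flatten_chain(sub)
      kkey <- sprintf("%.9f", br_s[j])
      c_d <- dx$daughter_csa[[kkey]]
      d_child <- sqrt(4 * c_d / pi)
      if (d_child < cfg$min_diameter) {
        # below the digitizing threshold: recorded as an additional fine
        # root on the bearing segment, not as a measured axis
        env$extra_fine[[ax$ids[kx - 1]]] <-
          (env$extra_fine[[ax$ids[kx - 1]]] %||% 0L) + 1L
        next
      }
      child_az <- (az + sample(c(-1, 1), 1) * stats::rnorm(1, 75, 15)) %% 360
      child_angle <- max(min(stats::rnorm(1, angle, 5), 85), -89)
      realize_axis(g$verts[kx, ], child_az, child_angle,
                   max(len * cfg$child_length_ratio * stats::runif(1, 0.7, 1.3), 0.015),
                   d_child,
                   ax$ids[kx - 1], order + 1L, sub_branches,
                   origin_class, origin_s)
    }
    ax
  }

  for (i in seq_len(n_lat)) realize_lateral(i)

  seg <- dplyr::bind_rows(env$rows)

  # unmeasured fine roots: Poisson per measured segment
  if (cfg$fine_root_rate > 0) {
    seg_len_cm <- 100 * sqrt((seg$tip_x - seg$base_x)^2 +
                               (seg$tip_y - seg$base_y)^2 +
                               (seg$tip_z - seg$base_z)^2)
    seg$fine_root_count <- stats::rpois(nrow(seg), cfg$fine_root_rate * seg_len_cm)
  }
  if (length(env$extra_fine) > 0) {
    k <- match(names(env$extra_fine), seg$segment_id)
    seg$fine_root_count[k] <- seg$fine_root_count[k] +
      unlist(env$extra_fine, use.names = FALSE)
  }
  seg$fine_root_mean_length <- ifelse(seg$fine_root_count > 0,
                                      cfg$fine_root_mean_length, 0)

  rs <- root_system(
    seg, plant_id = cfg$plant_id, slope_deg = cfg$slope_deg,
    flexed = cfg$flexed, block = cfg$block, container = cfg$container
  )
  # dry weights from volume and configured tissue density
  vol_cm3 <- sum(purrr::map_dbl(axis_paths(rs), "volume")) * 1e6
  rs$root_dry_weight_g <- vol_cm3 * cfg$root_density *
    exp(stats::rnorm(1, 0, 0.08))
  rs$shoot_dry_weight_g <- rs$root_dry_weight_g *
    (1 / cfg$rpc_biomass - 1) * exp(stats::rnorm(1, 0, 0.08))
  rs$ground_truth <- list(
    config = cfg,
    axes = dplyr::bind_rows(env$truth)
  )
  assert_valid(rs)
  rs
}

# the branches hanging off the main chain of a nested topology node, in
# proximal-to-distal order (the root node is the most proximal branch)
flatten_chain <- function(t) {
  out <- list()
  while (!identical(t, "tip")) {
    out <- c(out, list(t[[2]]))
    t <- t[[1]]
  }
  out
}

#' Generate a balanced cohort across the four treatment groups
#'
#' Builds `n_per_group` plants for each of the four groups of the 2 x 2
#' (slope x flexing) design, spread over two blocks, with group-specific
#' configuration tweaks that mirror the treatment responses the design is
#' meant to detect: slope groups get azimuthal anisotropy and bigger, more
#' branched systems; flexed groups get thicker, more vertical taproots with
#' more, thinner laterals.
#'
#' @param n_per_group Plants per treatment group (default 8).
#' @param seed Integer seed for the whole cohort.
#' @param base_config A [generator_config()] used for the control group.
#' @param group_tweaks Named list (`control`, `slope`, `flexed`,
#'   `slope_flexed`) of lists of [generator_config()] overrides; defaults
#'   described above. Pass empty lists for a null cohort with no group
#'   differences.
#' @return A list with `systems` (list of [root_system()]) and `meta`
#'   (tibble: plant_id, group, slope, flexed, block, seed).
#' @export
generate_cohort <- function(n_per_group = 8, seed = 1L,
                            base_config = generator_config(),
                            group_tweaks = default_group_tweaks()) {
  groups <- c("control", "slope", "flexed", "slope_flexed")
  meta <- tidyr::expand_grid(group = groups, rep = seq_len(n_per_group))
  meta <- dplyr::mutate(meta,
    plant_id = sprintf("%s_%02d", .data$group, .data$rep),
    slope_deg = ifelse(.data$group %in% c("slope", "slope_flexed"), 45, 0),
    flexed = .data$group %in% c("flexed", "slope_flexed"),
    block = ifelse(.data$rep %% 2 == 1, "b1", "b2"),
    seed = seed * 10000L + seq_len(dplyr::n())
  )
  systems <- purrr::pmap(meta, function(group, rep, plant_id, slope_deg,
                                        flexed, block, seed) {
    cfg <- base_config
    tw <- group_tweaks[[group]]
    for (nm in names(tw)) cfg[[nm]] <- tw[[nm]]
    cfg$seed <- seed
    cfg$plant_id <- plant_id
    cfg$slope_deg <- slope_deg
    cfg$flexed <- flexed
    cfg$block <- block
    generate_root_system(cfg)
  })
  list(systems = systems, meta = dplyr::select(meta, -"rep"))
}

#' @rdname generate_cohort
#' @export
default_group_tweaks <- function() {
  list(
    control = list(),
    slope = list(
      azimuth_distribution = "vonmises", azimuth_mu = 90, azimuth_kappa = 1.5,
      n_laterals = 20L, taproot_tilt_deg = 25,
      taproot_basal_diameter = 0.011, lateral_length_mean = 0.15
    ),
    flexed = list(
      n_laterals = 20L, taproot_tilt_deg = 6,
      taproot_basal_diameter = 0.012, taproot_p_branch = 1.8,
      lateral_q = 0.55, lateral_length_mean = 0.15
    ),
    slope_flexed = list(
      azimuth_distribution = "vonmises", azimuth_mu = 0, azimuth_kappa = 1.2,
      n_laterals = 24L, taproot_tilt_deg = 10,
      taproot_basal_diameter = 0.013, taproot_p_branch = 1.6,
      lateral_q = 0.58, lateral_length_mean = 0.15
    )
  )
}
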