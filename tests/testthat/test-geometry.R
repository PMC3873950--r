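test_that("axis length adds the mother-root radius for laterals only", {
  # two collinear 5 cm segments borne by a 1 cm diameter mother: 10.5 cm
  rs <- chain_rs(c(0.05, 0.05), c(0.004, 0.003), mother = TRUE, mother_diam = 0.01)
  ag <- axis_geometry(rs)
  expect_equal(ag$length[ag$order == 2], 0.105, tolerance = 1e-12)
  # order-1 root: no mother radius
  rs1 <- chain_rs(c(0.04, 0.03), c(0.004, 0.003),
                  dirs = list(c(0, 0, -1), c(0, 0, -1)))
  expect_equal(axis_geometry(rs1)$length, 0.07, tolerance = 1e-12)
})

test_that("axis length matches a brute-force polyline oracle on generated axes", {
  rs <- generate_root_system(generator_config(seed = 3))
  ag <- axis_geometry(rs)
  paths <- rootarch:::axis_paths(rs)
  for (p in paths) {
    expect_equal(ag$raw_length[ag$axis_id == p$axis_id],
                 oracle_polyline_length(p$verts), tolerance = 1e-9)
  }
})

test_that("mean diameter inverts the cylinder identity", {
  # volume pi cm^3, length 1 cm -> 2 cm
  expect_equal(mean_diameter(pi * 1e-6, 0.01), 0.02)
  expect_equal(mean_diameter(pi / 4 * 1e-6, 0.01), 0.01)
  expect_equal(mean_diameter(0, 0.01), 0)
  expect_error(mean_diameter(1e-6, 0), "undefined")
})

test_that("proximal taper interpolates the diameter profile over 3.5 cm", {
  # d0 = 0.20 cm falling to 0.13 cm at 3.5 cm -> 10 %/cm
  rs <- chain_rs(c(0.035, 0.04), c(0.0020, 0.0013))
  expect_equal(axis_geometry(rs)$proximal_taper[1], 10, tolerance = 1e-9)
  # constant diameter -> 0
  rs2 <- chain_rs(c(0.05, 0.05), c(0.002, 0.002))
  expect_equal(axis_geometry(rs2)$proximal_taper[1], 0)
  # knots at 2 and 5 cm: interpolated diameter at 3.5 cm by hand
  rs3 <- chain_rs(c(0.02, 0.03, 0.02), c(0.0030, 0.0020, 0.0012))
  d35 <- 0.0020 + (0.035 - 0.02) / 0.03 * (0.0012 - 0.0020)
  expect_equal(axis_geometry(rs3)$proximal_taper[1],
               100 * (0.0030 - d35) / 0.0030 / 3.5, tolerance = 1e-9)
  # shorter than 3.5 cm: flagged missing, not dropped
  rs4 <- chain_rs(c(0.02), c(0.002))
  ag4 <- axis_geometry(rs4)
  expect_true(is.na(ag4$proximal_taper[1]) && ag4$taper_flag[1])
})

test_that("virtual segmentation slices at 10 mm and conserves length and volume", {
  rs <- chain_rs(c(0.035), c(0.004))
  vs <- virtualize(rs)
  expect_equal(vs$length, c(0.010, 0.010, 0.010, 0.005))
  expect_equal(sum(vs$length), 0.035)
  rs2 <- chain_rs(c(0.010), c(0.004))
  expect_equal(nrow(virtualize(rs2)), 1)

  # frustum 4 -> 2 mm over 30 mm: slice volumes sum to the closed form
  rs3 <- chain_rs(c(0.030, 0.010), c(0.004, 0.002))
  vs3 <- virtualize(rs3)
  v_frustum <- pi * 0.030 / 12 * (0.004^2 + 0.004 * 0.002 + 0.002^2)
  expect_equal(sum(vs3$volume[vs3$slice <= 3 & vs3$segment_id == "C1"]),
               v_frustum, tolerance = 1e-12)
})

test_that("virtualization conserves totals on generated systems", {
  for (s in 1:5) {
    rs <- generate_root_system(generator_config(seed = 100 + s))
    vs <- virtualize(rs)
    expect_equal(sum(vs$length), total_length_of(rs), tolerance = 1e-9)
    expect_equal(sum(vs$volume), total_volume_of(rs), tolerance = 1e-9)
  }
})

test_that("taproot angle uses the collar-to-deep-limit line", {
  vert <- chain_rs(c(0.04, 0.04), c(0.005, 0.004),
                   dirs = list(c(0, 0, -1), c(0, 0, -1)))
  expect_equal(taproot_angle(vert)$angle_deg, -90)
  # 1:1 slope crossing -70 mm at x = 70 mm
  d <- c(1, 0, -1) / sqrt(2)
  slanted <- chain_rs(c(0.07, 0.07), c(0.005, 0.004), dirs = list(d, d))
  expect_equal(taproot_angle(slanted)$angle_deg, -45, tolerance = 1e-9)
  # crooked taproot: only the endpoints of the line matter
  crook <- chain_rs(
    c(0.03, 0.03, 0.03, 0.03, 0.03), c(0.006, 0.005, 0.004, 0.003, 0.002),
    dirs = list(c(0.4, 0, -0.9), c(-0.3, 0.2, -0.9), c(0.2, -0.1, -0.95),
                c(0, 0.3, -0.95), c(0.1, 0, -1)) |> lapply(\(v) v / sqrt(sum(v^2)))
  )
  p <- rootarch:::axis_paths(crook)[[1]]
  z <- p$verts[, 3]
  k <- which(z <= -0.07)[1]
  f <- (-0.07 - z[k - 1]) / (z[k] - z[k - 1])
  pt <- p$verts[k - 1, ] + f * (p$verts[k, ] - p$verts[k - 1, ])
  expect_equal(taproot_angle(crook)$angle_deg,
               atan2(pt[3], sqrt(pt[1]^2 + pt[2]^2)) * 180 / pi,
               tolerance = 1e-9)
  # too shallow: deepest point used and flagged
  shallow <- chain_rs(c(0.03), c(0.004), dirs = list(c(0.5, 0, -0.5) / sqrt(0.5)))
  expect_false(taproot_angle(shallow)$reached_limit)
})

test_that("axis azimuth is taken 1 cm from the base, compass convention", {
  rs <- chain_rs(c(0.05), c(0.002), mother = TRUE)
  expect_equal(axis_geometry(rs)$azimuth_1cm[2], 0)
  rs2 <- chain_rs(c(0.05), c(0.002), dirs = list(c(-1, 0, 0)), mother = TRUE)
  expect_equal(axis_geometry(rs2)$azimuth_1cm[2], 180)
  rs3 <- chain_rs(c(0.05), c(0.002), dirs = list(c(0, 1, 0)), mother = TRUE)
  expect_equal(axis_geometry(rs3)$azimuth_1cm[2], 90)
  # curved axis: equals the polyline interpolated at 1 cm
  dirs <- list(c(1, 0, 0), c(1, 1, 0) / sqrt(2), c(0, 1, 0))
  rs4 <- chain_rs(c(0.006, 0.006, 0.02), c(0.002, 0.002, 0.002),
                  dirs = dirs, mother = TRUE)
  p <- rootarch:::axis_paths(rs4)[["A1"]]
  pt <- drop(rootarch:::interp_point(p, 0.01))
  expect_equal(axis_geometry(rs4)$azimuth_1cm[2],
               (atan2(pt[2], pt[1]) * 180 / pi) %% 360, tolerance = 1e-9)
  # perfectly vertical first cm: undefined azimuth, flagged not dropped
  rs5 <- chain_rs(c(0.05), c(0.002), dirs = list(c(0, 0, -1)), mother = TRUE)
  expect_true(is.na(axis_geometry(rs5)$azimuth_1cm[2]))
})

test_that("RDD folds the wrap-around and winding has its closed forms", {
  # straight radial root: rdd 0, winding 1
  rs <- chain_rs(c(0.05, 0.05), c(0.002, 0.002), mother = TRUE)
  ag <- axis_geometry(rs)
  expect_equal(ag$rdd[2], 0, tolerance = 1e-12)
  expect_equal(ag$winding[2], 1, tolerance = 1e-12)

  # wrap-around fold: azimuth 10 at 10 mm, 350 at tip -> 20 degrees
  expect_equal(rootarch:::fold_angle(350 - 10), 20)
  expect_equal(rootarch:::fold_angle(10 - 350), 20)

  # quarter circle of radius r: winding = (pi r / 2) / (r sqrt(2))
  r <- 0.05
  th <- seq(0, pi / 2, length.out = 201)
  verts <- cbind(r * sin(th), r * (1 - cos(th)), 0)
  lens <- sqrt(rowSums(diff(verts)^2))
  dirs <- lapply(seq_len(nrow(verts) - 1),
                 \(i) (verts[i + 1, ] - verts[i, ]) / lens[i])
  arc <- chain_rs(lens, rep(0.002, length(lens)), dirs = dirs, mother = TRUE)
  expect_equal(axis_geometry(arc)$winding[2], (pi * r / 2) / (r * sqrt(2)),
               tolerance = 1e-3)
})

test_that("branching angle is the 3D angle between daughter and bearer vectors", {
  expect_equal(branching_angle(c(0, 1, 0), c(1, 0, 0)), 90)
  expect_equal(branching_angle(c(2, 0, 0), c(1, 0, 0)), 0)
  expect_equal(branching_angle(c(1, 1, 0), c(1, 0, 0)), 45)
  expect_error(branching_angle(c(0, 0, 0), c(1, 0, 0)), "zero-length")
})

test_that("angle measures co-rotate with a rigid rotation about z", {
  rs <- generate_root_system(generator_config(seed = 8, n_laterals = 6L))
  ag <- axis_geometry(rs)
  rot <- rotate_rs(rs, 90)
  agr <- axis_geometry(rot)
  lat <- ag$order > 1
  expect_equal(agr$azimuth_1cm[lat], (ag$azimuth_1cm[lat] + 90) %% 360,
               tolerance = 1e-6)
  expect_equal(agr$angle_to_soil, ag$angle_to_soil, tolerance = 1e-9)
  expect_equal(agr$winding, ag$winding, tolerance = 1e-9)
  expect_equal(agr$rdd, ag$rdd, tolerance = 1e-6)
  expect_equal(agr$branching_angle, ag$branching_angle, tolerance = 1e-9)
})
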