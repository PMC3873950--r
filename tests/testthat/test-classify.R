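test_that("the stump is the first 45 mm of the order-1 path", {
  # 30 + 30 mm: second segment split 15/15
  rs <- chain_rs(c(0.030, 0.030), c(0.006, 0.004),
                 dirs = list(c(0, 0, -1), c(0, 0, -1)))
  st <- split_stump(rs)
  expect_equal(st$length[st$part == "stump"], c(0.030, 0.015))
  expect_equal(st$length[st$part == "taproot"], 0.015)
  expect_false(attr(st, "short_order1"))
  # 40 mm total: all stump, flagged
  rs2 <- chain_rs(c(0.040), c(0.006), dirs = list(c(0, 0, -1)))
  st2 <- split_stump(rs2)
  expect_true(all(st2$part == "stump"))
  expect_true(attr(st2, "short_order1"))
  # volume is conserved across the split of a frustum taproot
  expect_equal(sum(st$volume), total_volume_of(rs), tolerance = 1e-12)
})

test_that("depth and direction classes use the stated limits and tie rules", {
  expect_equal(classify_depth(c(-0.020, -0.035, -0.050, -0.070, -0.080)),
               c("shallow", "intermediate", "intermediate", "deep", "deep"))
  expect_equal(classify_direction(c(-10, -29.9, -30, -45, -60, -75, 80)),
               c("horizontal", "horizontal", "oblique", "oblique",
                 "vertical", "vertical", "vertical"))
})

test_that("sector bins are half-open slope-oriented quadrants", {
  expect_equal(classify_sector(c(0, 44.9, 45, 90, 134, 135, 170, 224.9, 225, 315, 314.9)),
               c("us", "us", "pp", "pp", "pp", "ds", "ds", "ds", "pp", "us", "pp"))
})

# one lateral at a chosen origin depth and surface angle, plus a taproot
one_lateral_rs <- function(origin_z, angle_deg, length = 0.08, az = 0) {
  d <- rootarch:::dir_from_angles(az, angle_deg)
  taproot_z <- seq(0, -0.11, by = -0.01)
  rows <- list()
  for (i in seq_len(length(taproot_z) - 1)) {
    rows[[i]] <- seg_row(sprintf("S%d", i), if (i == 1) NA else sprintf("S%d", i - 1),
                         "A1", 1, c(0, 0, taproot_z[i]), c(0, 0, taproot_z[i + 1]),
                         0.008 - 0.0005 * i)
  }
  k <- which.min(abs(taproot_z - origin_z))
  base <- c(0, 0, taproot_z[k])
  rows[[length(rows) + 1]] <- seg_row("L1", sprintf("S%d", k - 1), "A2", 2,
                                      base, base + d * length, 0.002)
  root_system(dplyr::bind_rows(rows), plant_id = "one")
}

test_that("compartment assignment follows origin depth and direction classes", {
  # shallow origin, horizontal, near the taproot -> ZRT then beyond
  rs <- one_lateral_rs(-0.020, -5)
  vs <- classify_compartments(rs, zrt_limit = 0.05)
  lat <- vs[vs$order == 2, ]
  expect_true(all(lat$compartment[lat$rrd <= 0.05] == 3))
  expect_true(all(lat$compartment[lat$rrd > 0.05] == 4))
  expect_true(all(lat$pooled[lat$compartment == 3] == "zrt"))

  # deep origin -> deep roots (6)
  rs2 <- one_lateral_rs(-0.080, -5)
  expect_true(all(classify_compartments(rs2)$compartment[
    classify_compartments(rs2)$order == 2] == 6))

  # shallow origin, oblique -> oblique (8), pooled to intermediate
  rs3 <- one_lateral_rs(-0.020, -45)
  vs3 <- classify_compartments(rs3)
  expect_true(all(vs3$compartment[vs3$order == 2] == 8))
  expect_true(all(vs3$pooled[vs3$order == 2] == "intermediate"))

  # shallow origin, vertical -> sinker (5), pooled to taproot
  rs4 <- one_lateral_rs(-0.020, -75)
  vs4 <- classify_compartments(rs4)
  expect_true(all(vs4$compartment[vs4$order == 2] == 5))
  expect_true(all(vs4$pooled[vs4$order == 2] == "taproot"))

  # intermediate origin -> intermediate (7)
  rs5 <- one_lateral_rs(-0.050, -5)
  expect_true(all(classify_compartments(rs5)$compartment[
    classify_compartments(rs5)$order == 2] == 7))
})

test_that("relative radial distance and sector are taken about the bearing point", {
  rs <- one_lateral_rs(-0.020, 0, length = 0.03, az = 0)
  vs <- classify_compartments(rs)
  lat <- vs[vs$order == 2, ]
  # midpoints 5, 15, 25 mm along +x from the bearing point
  expect_equal(sort(lat$rrd), c(0.005, 0.015, 0.025), tolerance = 1e-9)
  expect_true(all(lat$sector == "us"))
  expect_true(all(is.na(vs$sector[vs$order == 1])))
  rs2 <- one_lateral_rs(-0.020, 0, az = 90)
  vs2 <- classify_compartments(rs2)
  expect_true(all(vs2$sector[vs2$order == 2] == "pp"))
  rs3 <- one_lateral_rs(-0.020, 0, az = 170)
  vs3 <- classify_compartments(rs3)
  expect_true(all(vs3$sector[vs3$order == 2] == "ds"))
})

test_that("compartments partition the total volume", {
  for (s in 1:4) {
    rs <- generate_root_system(generator_config(seed = 400 + s))
    vs <- classify_compartments(rs)
    expect_equal(sum(vs$volume), total_volume_of(rs), tolerance = 1e-9)
    # stump excluded, the five pooled non-stump compartments make the rest
    non_stump <- sum(vs$volume[vs$pooled != "stump"])
    stump <- sum(vs$volume[vs$pooled == "stump"])
    expect_equal(non_stump + stump, total_volume_of(rs), tolerance = 1e-9)
  }
})

test_that("sector shares sum to 100 and match a brute-force summation", {
  rs <- generate_root_system(generator_config(seed = 17))
  ss <- sector_shares(rs)
  sums <- dplyr::summarise(dplyr::group_by(ss, .data$compartment),
                           v = sum(.data$volume_share), .groups = "drop")
  expect_true(all(abs(sums$v - 100) < 1e-9 | is.na(sums$v)))
  # oracle: direct summation over labelled virtual segments
  vs <- classify_compartments(rs)
  lat <- vs[vs$order > 1 & !is.na(vs$sector), ]
  for (sec in c("us", "pp", "ds")) {
    expect_equal(
      ss$volume_share[ss$compartment == "all" & ss$sector == sec],
      100 * sum(lat$volume[lat$sector == sec]) / sum(lat$volume),
      tolerance = 1e-9
    )
  }
})

test_that("rotating the system 90 degrees permutes the sectors consistently", {
  rs <- generate_root_system(generator_config(seed = 23))
  ss <- sector_shares(rs)
  ssr <- sector_shares(rotate_rs(rs, 90))
  # us and ds both land in pp after a quarter turn
  expect_equal(
    ssr$volume_share[ssr$compartment == "all" & ssr$sector == "pp"],
    ss$volume_share[ss$compartment == "all" & ss$sector == "us"] +
      ss$volume_share[ss$compartment == "all" & ss$sector == "ds"],
    tolerance = 1e-6
  )
})

test_that("reinforcement is the excess over the uniform quadrant share", {
  expect_equal(reinforcement(25), 0)
  expect_equal(reinforcement(100), 300)
  expect_equal(reinforcement(0), -100)
  expect_equal(reinforcement(37.5), 50)
})

test_that("an all-in-one-lateral system reinforces upslope by +300%", {
  rs <- one_lateral_rs(-0.020, 0, az = 10)
  ss <- sector_shares(rs)
  expect_equal(ss$volume_share[ss$compartment == "all" & ss$sector == "us"], 100)
  expect_equal(ss$volume_reinforcement[ss$compartment == "all" & ss$sector == "us"], 300)
})
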