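test_that("qb scores the herringbone and dichotomous endpoints exactly", {
  expect_equal(qb_topology(topo_herringbone(8)), 1)
  expect_equal(qb_topology(topo_balanced(3)), 0)   # 8 tips
  expect_equal(qb_topology(topo_herringbone(5)), 1)
  expect_equal(qb_topology(topo_balanced(2)), 0)
  # fewer than 3 exterior links: undefined
  expect_true(is.na(qb_topology(topo_herringbone(2))))
  expect_true(is.na(qb_topology("tip")))
})

test_that("qb equals the exhaustive-enumeration oracle for all trees up to 7 tips", {
  for (n in 3:7) {
    topos <- enum_topos(n)
    pes <- vapply(topos, oracle_pe, numeric(1))
    lo <- min(pes); hi <- max(pes)
    # the package's closed-form extremes agree with enumeration
    expect_equal(rootarch:::pe_min_dichotomous(n), lo)
    expect_equal(rootarch:::pe_max_herringbone(n), hi)
    for (i in seq_along(topos)) {
      expect_equal(qb_topology(topos[[i]]), (pes[i] - lo) / (hi - lo))
    }
  }
})

test_that("qb is non-decreasing as subtrees move onto the main chain", {
  # n = 8 tips: j-link herringbone prefix ending in the most balanced
  # remainder; growing j herringbonizes the tree
  min_topo <- function(n) {
    topos <- enum_topos(n)
    topos[[which.min(vapply(topos, oracle_pe, numeric(1)))]]
  }
  qbs <- vapply(0:6, function(j) {
    t <- min_topo(8 - j)
    for (i in seq_len(j)) t <- list(t, "tip")
    qb_topology(t)
  }, numeric(1))
  expect_true(all(diff(qbs) >= 0))
  expect_equal(qbs[1], 0)
  expect_equal(qbs[7], 1)
})

test_that("the link tree of a root system resolves branches and fine roots", {
  # taproot bearing 3 unbranched laterals: herringbone with 4 exterior links
  rows <- list(seg_row("S1", NA, "A1", 1, c(0, 0, 0), c(0, 0, -0.02), 0.006))
  for (i in 2:4) {
    rows[[length(rows) + 1]] <- seg_row(
      sprintf("S%d", i), sprintf("S%d", i - 1), "A1", 1,
      c(0, 0, -0.02 * (i - 1)), c(0, 0, -0.02 * i), 0.006 - 0.001 * i
    )
    rows[[length(rows) + 1]] <- seg_row(
      sprintf("L%d", i), sprintf("S%d", i - 1), sprintf("A%d", i), 2,
      c(0, 0, -0.02 * (i - 1)), c(0.05, 0, -0.02 * (i - 1)), 0.002
    )
  }
  rs <- root_system(dplyr::bind_rows(rows), plant_id = "hb")
  expect_equal(qb(rs, include_fine_roots = FALSE), 1)
  expect_equal(rootarch:::n_tips(link_tree(rs, include_fine_roots = FALSE)), 4)

  # fine roots add serially split exterior links
  rs2 <- rs
  rs2$segments$fine_root_count[rs2$segments$segment_id == "L2"] <- 2L
  expect_equal(rootarch:::n_tips(link_tree(rs2, include_fine_roots = TRUE)), 6)
  expect_equal(rootarch:::n_tips(link_tree(rs2, include_fine_roots = FALSE)), 4)
})

test_that("multifurcations are resolved by serial splitting", {
  # two laterals at the same branch point
  rs <- root_system(dplyr::bind_rows(
    seg_row("S1", NA, "A1", 1, c(0, 0, 0), c(0, 0, -0.03), 0.006),
    seg_row("S2", "S1", "A1", 1, c(0, 0, -0.03), c(0, 0, -0.08), 0.004),
    seg_row("L1", "S1", "A2", 2, c(0, 0, -0.03), c(0.05, 0, -0.03), 0.002),
    seg_row("L2", "S1", "A3", 2, c(0, 0, -0.03), c(-0.05, 0, -0.03), 0.002)
  ), plant_id = "multi")
  t <- link_tree(rs, include_fine_roots = FALSE)
  expect_equal(rootarch:::n_tips(t), 3)
  # serial split: two consecutive binary nodes, Pe = 2 + 3 + 3
  expect_equal(rootarch:::pe_sum(t), 8)
})

test_that("mean branching order follows the order-minus-one convention", {
  # only 2nd-order laterals -> 1
  rs <- generate_root_system(generator_config(
    seed = 2, tertiary_rate = 0, fine_root_rate = 0
  ))
  expect_equal(mbo(rs), 1)

  # 7 order-2 + 3 order-3 axes -> 1.3 (weighted mean)
  expect_equal(stats::weighted.mean(c(1, 2), c(7, 3)), 1.3)
  co <- generate_root_system(generator_config(
    seed = 31, tertiary_rate = 0.2, fine_root_rate = 0
  ))
  ag <- axis_geometry(co)
  lat <- ag$order[ag$order > 1]
  expect_equal(mbo(co, include_fine_roots = FALSE), mean(lat - 1))

  # adding fine roots on a 2nd-order axis raises MBO by hand computation
  rs2 <- rs
  i <- which(rs2$segments$order == 2)[1]
  rs2$segments$fine_root_count[i] <- 5L
  rs2$segments$fine_root_mean_length[i] <- 0.02
  n2 <- sum(axis_geometry(rs)$order > 1)
  expect_equal(mbo(rs2, include_fine_roots = TRUE),
               (n2 * 1 + 5 * 2) / (n2 + 5))
  expect_equal(mbo(rs2, include_fine_roots = FALSE), 1)
})

test_that("qb and mbo scopes follow the arborescence origin depth class", {
  rs <- generate_root_system(generator_config(seed = 77))
  cls <- rootarch:::axis_classes(rs)
  for (sc in c("shallow", "intermediate", "deep")) {
    n_axes <- sum(cls$depth_class == sc, na.rm = TRUE)
    m <- mbo(rs, sc, include_fine_roots = FALSE)
    if (n_axes == 0) expect_true(is.na(m)) else expect_gte(m, 1)
  }
  # scoped trees never have more tips than the total tree
  nt <- function(sc) rootarch:::n_tips(link_tree(rs, sc))
  expect_gte(nt("total"), max(nt("shallow"), nt("intermediate"), nt("deep")))
})
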