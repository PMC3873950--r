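test_that("p_branch and q follow the CSA bookkeeping at a branch event", {
  # csa_before 2, csa_after {1, 0.5} (continuing + one daughter); the value
  # digitized at the branch boundary is the pre-branch diameter, so the
  # continuing segment's basal diameter carries CSA 2 and the post-branch
  # CSA 1 appears at the next measurement point
  d_b <- sqrt(4 * 2 / pi); d_c <- sqrt(4 * 1 / pi); d_d <- sqrt(4 * 0.5 / pi)
  rs <- event_rs(d_b, d_cont = d_b, d_daughters = d_d,
                 cont_length = 0.01, cont_end = d_c)  # short: uses its end
  ev <- branch_events(rs)
  ev <- ev[abs(ev$s - 0.05) < 1e-9, ]
  expect_equal(ev$csa_before, 2, tolerance = 1e-9)
  expect_equal(ev$csa_cont, 1, tolerance = 1e-9)
  expect_equal(ev$p_branch, 2 / 1.5, tolerance = 1e-9)
  expect_equal(ev$q, 1 / 1.5, tolerance = 1e-9)
})

test_that("q is 1/2 for an equal dichotomous split and tends to 1 with dominance", {
  # axis ends at the branch point; two daughters of identical CSA
  rs <- event_rs(0.006, d_cont = NULL, d_daughters = c(0.003, 0.003))
  ev <- branch_events(rs)
  expect_equal(ev$q, 0.5)
  expect_equal(ev$n_daughters, 2)
  # growing dominance of one daughter pushes q toward 1
  qs <- vapply(c(1, 2, 5, 20), function(r) {
    rs2 <- event_rs(0.006, d_cont = NULL,
                    d_daughters = c(0.001 * sqrt(r), 0.001))
    branch_events(rs2)$q
  }, numeric(1))
  expect_true(all(diff(qs) > 0))
  expect_gt(qs[4], 0.9)
  # a single daughter record means q = 1
  rs3 <- event_rs(0.006, d_cont = NULL, d_daughters = 0.002)
  expect_equal(branch_events(rs3)$q, 1)
})

test_that("p_branch exceeds 1 under tapering and equals 1 under CSA conservation", {
  # conservation: daughters exactly absorb the parent CSA
  c_b <- csa_of(0.006)
  d_each <- sqrt(4 * (c_b / 2) / pi)
  rs <- event_rs(0.006, d_cont = NULL, d_daughters = c(d_each, d_each))
  expect_equal(branch_events(rs)$p_branch, 1, tolerance = 1e-12)
  # tapering: parent CSA larger than the daughters' sum
  rs2 <- event_rs(0.006, d_cont = NULL, d_daughters = c(0.003, 0.002))
  expect_gt(branch_events(rs2)$p_branch, 1)
})

test_that("the continuing CSA is interpolated 2 cm after the branch", {
  # 3 cm continuing segment with linear diameter taper 4 -> 1 mm
  rs <- event_rs(0.006, d_cont = 0.004, d_daughters = 0.002,
                 cont_length = 0.03, cont_end = 0.001)
  ev <- branch_events(rs)
  ev <- ev[abs(ev$s - 0.05) < 1e-9, ]
  d_2cm <- 0.004 + 0.02 / 0.03 * (0.001 - 0.004)
  expect_equal(ev$csa_cont, csa_of(d_2cm), tolerance = 1e-12)
  # continuing segment shorter than 2 cm: its distal diameter is used
  rs2 <- event_rs(0.006, d_cont = 0.004, d_daughters = 0.002,
                  cont_length = 0.012, cont_end = 0.0015)
  ev2 <- branch_events(rs2)
  ev2 <- ev2[abs(ev2$s - 0.05) < 1e-9, ]
  expect_equal(ev2$csa_cont, csa_of(0.0015), tolerance = 1e-12)
})

test_that("scope means equal direct recomputation from the event table", {
  rs <- generate_root_system(generator_config(seed = 12))
  ev <- branch_events(rs)
  fp <- fractal_params(rs)
  for (sc in unique(ev$scope)) {
    expect_equal(fp$p_branch[fp$scope == sc], mean(ev$p_branch[ev$scope == sc]))
    expect_equal(fp$q[fp$scope == sc], mean(ev$q[ev$scope == sc]))
  }
  expect_true(all(ev$q > 0 & ev$q <= 1))
})

test_that("inter-lateral and apical unbranched lengths use curvilinear gaps", {
  # branches at 1, 2 and 4 cm along a 10 cm axis
  rows <- list(seg_row("S1", NA, "A1", 1, c(0, 0, 0), c(0, 0, -0.01), 0.006),
               seg_row("S2", "S1", "A1", 1, c(0, 0, -0.01), c(0, 0, -0.02), 0.005),
               seg_row("S3", "S2", "A1", 1, c(0, 0, -0.02), c(0, 0, -0.04), 0.004),
               seg_row("S4", "S3", "A1", 1, c(0, 0, -0.04), c(0, 0, -0.10), 0.003))
  for (j in 1:3) {
    src <- c("S1", "S2", "S3")[j]
    z <- c(-0.01, -0.02, -0.04)[j]
    rows[[length(rows) + 1]] <- seg_row(sprintf("L%d", j), src,
                                        sprintf("A%d", j + 1), 2,
                                        c(0, 0, z), c(0.03, 0, z), 0.002)
  }
  rs <- root_system(dplyr::bind_rows(rows), plant_id = "ill")
  ill <- inter_lateral_length(rs, include_fine_roots = FALSE)
  expect_equal(ill$inter_lateral_length[ill$axis_id == "A1"], 0.015)
  ag <- axis_geometry(rs)
  expect_equal(ag$apical_unbranched_length[ag$axis_id == "A1"], 0.06)
  # fine roots merge into the position-sorted branch list
  rs2 <- rs
  rs2$segments$fine_root_count[rs2$segments$segment_id == "S3"] <- 1L
  ill2 <- inter_lateral_length(rs2, include_fine_roots = TRUE)
  expect_equal(ill2$inter_lateral_length[ill2$axis_id == "A1"],
               mean(diff(c(0.01, 0.02, 0.04, 0.04))))
  # fewer than 2 branch points: missing value
  expect_true(is.na(ill$inter_lateral_length[ill$axis_id == "A2"]))
})

test_that("counts and specific traits follow their defining ratios", {
  # SRL: 10 cm / 2 cm^3 = 5 (single 10 cm lateral, constant diameter)
  d <- sqrt(4 * 2e-6 / (pi * 0.1))
  rs <- root_system(dplyr::bind_rows(
    seg_row("S1", NA, "A1", 1, c(0, 0, 0), c(0, 0, -0.05), 1e-9),
    seg_row("L1", "S1", "A2", 2, c(0, 0, -0.05), c(0.1, 0, -0.05), d)
  ), plant_id = "srl")
  cs <- counts_and_specifics(rs)
  lat_len <- cs$total_length_cm - 5  # order-1 contributes 5 cm of length
  expect_equal(lat_len / cs$total_volume_cm3, 5, tolerance = 1e-3)

  # density from inverted control-mean arithmetic: 3.49 g / 6.61 cm^3
  expect_equal(3.49 / 6.61, 0.528, tolerance = 1e-3)
  big <- generate_root_system(generator_config(seed = 5))
  csb <- counts_and_specifics(big)
  expect_equal(csb$root_density_g_cm3,
               big$root_dry_weight_g / csb$total_volume_incl_stump_cm3)

  # measured axes vs fine-root-inclusive count
  rs3 <- generate_root_system(generator_config(seed = 6, tertiary_rate = 0))
  cs3 <- counts_and_specifics(rs3)
  expect_equal(cs3$root_number, 12)
  expect_equal(cs3$root_number_iafr,
               12 + sum(rs3$segments$fine_root_count))
})
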