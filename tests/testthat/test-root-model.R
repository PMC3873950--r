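test_that("a minimal root system constructs, validates and summarises", {
  rs <- toy_rs()
  expect_s3_class(rs, "root_system")
  expect_equal(nrow(validate_root_system(rs)), 0)
  expect_equal(dplyr::n_distinct(rs$segments$axis_id), 2)
  expect_output(print(rs), "3 segments, 2 axes")
})

test_that("structural violations are reported as data, one row per rule", {
  rs <- toy_rs()
  # order jump 1 -> 3
  rs_jump <- rs
  rs_jump$segments$order[3] <- 3L
  v <- validate_root_system(rs_jump)
  expect_true("order_jump" %in% v$rule)
  expect_true("S3" %in% v$segment_id)

  # detached base
  rs_det <- rs
  rs_det$segments$base_x[3] <- 0.02
  expect_true("detached" %in% validate_root_system(rs_det)$rule)

  # cycle: S1 <- S2 <- S1 is unreachable from any collar
  seg <- rs$segments
  seg$parent_id[1] <- "S2"
  seg2 <- dplyr::bind_rows(
    seg_row("C0", NA, "A9", 1, c(0, 0, 0), c(0, 0, -0.01), 0.004), seg
  )
  v <- validate_root_system(root_system(seg2))
  expect_true("unreachable" %in% v$rule)

  # negative diameter
  rs_neg <- rs
  rs_neg$segments$diameter[2] <- -0.001
  expect_true("negative_diameter" %in% validate_root_system(rs_neg)$rule)
})

test_that("MTG round trip preserves ids, coordinates and diameters", {
  rs <- toy_rs(slope_deg = 45, flexed = TRUE, block = "b2",
               shoot_dry_weight_g = 14.2, root_dry_weight_g = 3.5)
  f <- withr::local_tempfile(fileext = ".mtg")
  write_mtg(rs, f)
  rs2 <- read_mtg(f)
  cols <- c("segment_id", "parent_id", "order", "base_x", "base_y", "base_z",
            "tip_x", "tip_y", "tip_z", "diameter", "fine_root_count",
            "fine_root_mean_length")
  a <- dplyr::arrange(rs$segments[cols], .data$segment_id)
  b <- dplyr::arrange(rs2$segments[cols], .data$segment_id)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-6)
  expect_equal(rs2$slope_deg, 45)
  expect_true(rs2$flexed)
  expect_equal(rs2$root_dry_weight_g, 3.5)
  # a second write/read is stable
  f2 <- withr::local_tempfile(fileext = ".mtg")
  write_mtg(rs2, f2)
  expect_equal(read_mtg(f2)$segments$tip_z, rs2$segments$tip_z, tolerance = 1e-9)
})

test_that("the MTG reader rejects malformed input with located errors", {
  rs <- toy_rs()
  f <- withr::local_tempfile(fileext = ".mtg")
  write_mtg(rs, f)
  lines <- readLines(f)

  # deleted parent id of the lateral -> structural error naming it
  bad <- sub("^S3\tS1", "S3\t-", sub("^S3\t\\+\tS1", "S3\t+\t-", lines))
  i <- grep("^S3\t", bad)
  parts <- strsplit(bad[i], "\t")[[1]]
  parts[3] <- "-"
  bad[i] <- paste(parts, collapse = "\t")
  f2 <- withr::local_tempfile(); writeLines(bad, f2)
  expect_error(read_mtg(f2), "missing parent.*S3")

  # unknown header key names the line
  f3 <- withr::local_tempfile()
  writeLines(c(lines[1], "# SCALE: 3", lines[-1]), f3)
  expect_error(read_mtg(f3), "unsupported MTG construct 'SCALE' at line 2")

  # wrong magic
  f4 <- withr::local_tempfile(); writeLines(lines[-1], f4)
  expect_error(read_mtg(f4), "line 1")

  # negative diameter
  neg <- lines
  i <- grep("^S2\t", neg)
  parts <- strsplit(neg[i], "\t")[[1]]
  parts[7] <- "-5"
  neg[i] <- paste(parts, collapse = "\t")
  f5 <- withr::local_tempfile(); writeLines(neg, f5)
  expect_error(read_mtg(f5), "negative diameter.*S2")
})

test_that("MTG parsing is independent of body row order", {
  rs <- toy_rs()
  f <- withr::local_tempfile(); write_mtg(rs, f)
  lines <- readLines(f)
  hdr_n <- max(grep("^#", lines)) + 1  # header + column row
  body <- lines[(hdr_n + 1):length(lines)]
  f2 <- withr::local_tempfile()
  writeLines(c(lines[1:hdr_n], rev(body)), f2)
  a <- read_mtg(f); b <- read_mtg(f2)
  cols <- c("segment_id", "parent_id", "order", "tip_x", "tip_y", "tip_z", "diameter")
  expect_equal(
    as.data.frame(dplyr::arrange(a$segments[cols], .data$segment_id)),
    as.data.frame(dplyr::arrange(b$segments[cols], .data$segment_id))
  )
})

test_that("unit declarations convert on load", {
  rs <- toy_rs()
  f_mm <- withr::local_tempfile(); write_mtg(rs, f_mm, unit = "mm")
  f_cm <- withr::local_tempfile(); write_mtg(rs, f_cm, unit = "cm")
  expect_equal(read_mtg(f_mm)$segments$diameter,
               read_mtg(f_cm)$segments$diameter, tolerance = 1e-9)
  expect_equal(read_mtg(f_cm)$segments$tip_z[2], -0.10, tolerance = 1e-9)
})

test_that("segment-table round trip is lossless, including on a generated system", {
  rs <- toy_rs()
  f <- withr::local_tempfile(fileext = ".csv")
  write_segment_table(rs, f)
  expect_equal(nrow(readr::read_csv(f, comment = "#", show_col_types = FALSE)), 3)
  rs2 <- read_segment_table(f)
  expect_equal(as.data.frame(rs$segments), as.data.frame(rs2$segments),
               tolerance = 1e-12)

  big <- generate_root_system(generator_config(seed = 11, n_laterals = 15L))
  expect_gt(nrow(big$segments), 100)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_segment_table(big, f2)
  big2 <- read_segment_table(f2)
  expect_equal(as.data.frame(big$segments), as.data.frame(big2$segments),
               tolerance = 1e-9)
  expect_equal(big2$slope_deg, big$slope_deg)
  expect_equal(big2$root_dry_weight_g, big$root_dry_weight_g, tolerance = 1e-6)

  # collar-only system still writes one row
  solo <- root_system(seg_row("S1", NA, "A1", 1, c(0, 0, 0), c(0, 0, -0.02), 0.005))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_segment_table(solo, f3)
  expect_equal(nrow(read_segment_table(f3)$segments), 1)
})
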