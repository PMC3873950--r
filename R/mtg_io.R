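# Reader/writer for a documented dialect of the MTG (multitree graph) text
# format. The full MTG grammar supports arbitrary scales and features; field
# digitizations of coarse roots only ever use two scales (axis, segment) and
# a fixed feature set, so this dialect supports exactly that and rejects
# anything else explicitly.
#
# Dialect (tab-separated):
#
#   # ROOT-MTG 1
#   # UNIT: mm            (mm, cm or m; applies to coordinates, diameters,
#   #                      fine-root lengths and the container line)
#   # PLANT_ID: p01
#   # SLOPE_DEG: 45
#   # FLEXED: yes
#   # BLOCK: b1
#   # CONTAINER: 300 300 110
#   # SHOOT_DW_G: 14.2    (optional)
#   # ROOT_DW_G: 3.5      (optional)
#   # FEATURES: XX YY ZZ Diameter FineRootCount FineRootMeanLength
#   ENTITY  TOPO  PARENT  XX  YY  ZZ  Diameter  FineRootCount  FineRootMeanLength
#   S1      /     -       0   0   -30  6.1      0  0
#   S2      <     S1      ...
#   S3      +     S1      ...
#
# Topology codes: `/` starts the plant (collar segment, exactly one row),
# `<` continues the parent's axis at the same branching order, `+` starts a
# new lateral axis at order(parent) + 1. XX/YY/ZZ are the coordinates of the
# segment TIP in the container frame; the base of every segment is its
# parent's tip (the collar's base is the collar position, origin by
# convention). Parent rows may appear after their children: the file is
# resolved in two passes, so row order does not matter.

mtg_units <- c(mm = 1e-3, cm = 1e-2, m = 1)
mtg_features <- c("XX", "YY", "ZZ", "Diameter", "FineRootCount", "FineRootMeanLength")

#' Read a root system from an MTG-dialect file
#'
#' @param path Path to a text file in the dialect documented at the top of
#'   the reader's source and in the package vignette. Coordinates and
#'   diameters are converted from the declared unit to metres on load.
#' @return A validated [root_system()].
#' @export
#' @examples
#' f <- system.file("extdata", "example_seedling.mtg", package = "rootarch")
#' rs <- read_mtg(f)
#' rs
read_mtg <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^#\\s*ROOT-MTG", lines[1])) {
    rlang::abort("malformed MTG header at line 1: expected '# ROOT-MTG 1'")
  }
  header_idx <- which(grepl("^#", lines))
  header_idx <- header_idx[header_idx == seq_along(header_idx)]  # leading block
  meta <- list(
    UNIT = "mm", PLANT_ID = "plant", SLOPE_DEG = "0", FLEXED = "no",
    BLOCK = "b1", CONTAINER = "300 300 110", SHOOT_DW_G = NA, ROOT_DW_G = NA,
    FEATURES = NULL, COLLAR = "0 0 0"
  )
  known <- names(meta)
  for (i in header_idx[-1]) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Z_]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3) {
      rlang::abort(sprintf("malformed MTG header at line %d: '%s'", i, lines[i]))
    }
    if (!m[2] %in% known) {
      rlang::abort(sprintf(
        "unsupported MTG construct '%s' at line %d (this dialect supports: %s)",
        m[2], i, paste(known, collapse = ", ")
      ))
    }
    meta[[m[2]]] <- trimws(m[3])
  }
  if (!meta$UNIT %in% names(mtg_units)) {
    rlang::abort(sprintf("unknown UNIT '%s' (use mm, cm or m)", meta$UNIT))
  }
  if (is.null(meta$FEATURES)) {
    rlang::abort("MTG header missing FEATURES line")
  }
  feats <- strsplit(meta$FEATURES, "\\s+")[[1]]
  if (!identical(feats, mtg_features)) {
    rlang::abort(paste0(
      "unsupported FEATURES declaration; this dialect requires exactly: ",
      paste(mtg_features, collapse = " ")
    ))
  }
  u <- mtg_units[[meta$UNIT]]

  body_lines <- lines[-header_idx]
  body_lines <- body_lines[nzchar(trimws(body_lines))]
  if (length(body_lines) < 2) rlang::abort("MTG body is empty")
  con <- textConnection(body_lines)
  on.exit(close(con))
  body <- utils::read.delim(con, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ENTITY", "TOPO", "PARENT", mtg_features)
  if (!identical(names(body), need)) {
    rlang::abort(paste0(
      "malformed MTG body header: expected columns ",
      paste(need, collapse = ", ")
    ))
  }
  if (any(!body$TOPO %in% c("/", "<", "+"))) {
    bad <- which(!body$TOPO %in% c("/", "<", "+"))[1]
    rlang::abort(sprintf("unknown topology code '%s' (row %d)", body$TOPO[bad], bad))
  }
  if (sum(body$TOPO == "/") != 1) {
    rlang::abort("MTG body must contain exactly one '/' (collar) row")
  }
  body$PARENT[body$PARENT %in% c("-", "")] <- NA_character_
  no_parent <- body$ENTITY[body$TOPO != "/" & is.na(body$PARENT)]
  if (length(no_parent)) {
    rlang::abort(paste0(
      "structural error: segment(s) with missing parent: ",
      paste(no_parent, collapse = ", ")
    ))
  }
  orphan <- body$ENTITY[!is.na(body$PARENT) & !(body$PARENT %in% body$ENTITY)]
  if (length(orphan)) {
    rlang::abort(paste0(
      "structural error: segment(s) with missing parent: ",
      paste(orphan, collapse = ", ")
    ))
  }
  if (any(body$Diameter < 0)) {
    bad <- body$ENTITY[body$Diameter < 0]
    rlang::abort(paste0("validation error: negative diameter at segment(s): ",
                        paste(bad, collapse = ", ")))
  }

  # second pass: resolve axis membership and order from topology codes,
  # independently of row order
  n <- nrow(body)
  ord <- rep(NA_integer_, n)
  axis <- rep(NA_character_, n)
  names(ord) <- names(axis) <- body$ENTITY
  pid <- stats::setNames(body$PARENT, body$ENTITY)
  topo <- stats::setNames(body$TOPO, body$ENTITY)
  axis_counter <- 0L
  resolve <- function(id) {
    if (!is.na(ord[[id]])) return()
    if (topo[[id]] == "/") {
      ord[[id]] <<- 1L
      axis_counter <<- axis_counter + 1L
      axis[[id]] <<- sprintf("A%03d", axis_counter)
      return()
    }
    p <- pid[[id]]
    resolve(p)
    if (topo[[id]] == "<") {
      ord[[id]] <<- ord[[p]]
      axis[[id]] <<- axis[[p]]
    } else {
      ord[[id]] <<- ord[[p]] + 1L
      axis_counter <<- axis_counter + 1L
      axis[[id]] <<- sprintf("A%03d", axis_counter)
    }
  }
  for (id in body$ENTITY) resolve(id)

  collar_xyz <- as.numeric(strsplit(meta$COLLAR, "\\s+")[[1]]) * u
  tip <- cbind(body$XX, body$YY, body$ZZ) * u
  idx <- match(body$PARENT, body$ENTITY)
  base <- tip[idx, , drop = FALSE]
  base[is.na(idx), ] <- rep(collar_xyz, each = sum(is.na(idx)))

  segs <- tibble::tibble(
    segment_id = body$ENTITY, parent_id = body$PARENT,
    axis_id = axis[body$ENTITY], order = ord[body$ENTITY],
    base_x = base[, 1], base_y = base[, 2], base_z = base[, 3],
    tip_x = tip[, 1], tip_y = tip[, 2], tip_z = tip[, 3],
    diameter = body$Diameter * u,
    fine_root_count = as.integer(body$FineRootCount),
    fine_root_mean_length = body$FineRootMeanLength * u
  )
  rs <- root_system(
    segs, plant_id = meta$PLANT_ID,
    slope_deg = as.numeric(meta$SLOPE_DEG),
    flexed = tolower(meta$FLEXED) %in% c("yes", "true", "1"),
    block = meta$BLOCK,
    container = as.numeric(strsplit(meta$CONTAINER, "\\s+")[[1]]) * u,
    shoot_dry_weight_g = suppressWarnings(as.numeric(meta$SHOOT_DW_G)),
    root_dry_weight_g = suppressWarnings(as.numeric(meta$ROOT_DW_G))
  )
  viol <- validate_root_system(rs)
  structural <- viol[viol$rule %in% c("orphan", "unreachable", "collar_count"), ]
  if (nrow(structural) > 0) {
    rlang::abort(paste0(
      "structural error in MTG file: ",
      paste(unique(structural$segment_id), collapse = ", ")
    ))
  }
  rs
}

#' Write a root system to an MTG-dialect file
#'
#' @param rs A [root_system()].
#' @param path Output file path.
#' @param unit Unit for coordinates/diameters in the file: "mm", "cm" or "m".
#' @return `path`, invisibly.
#' @export
write_mtg <- function(rs, path, unit = "mm") {
  if (!unit %in% names(mtg_units)) rlang::abort("unit must be mm, cm or m")
  u <- mtg_units[[unit]]
  seg <- rs$segments
  # depth-first order so parents precede children (readers do not rely on it)
  kid_of <- split(seg$segment_id, seg$parent_id)
  collar <- seg$segment_id[is.na(seg$parent_id)]
  ordered <- character(0)
  stack <- collar
  while (length(stack)) {
    id <- stack[1]; stack <- stack[-1]
    ordered <- c(ordered, id)
    kids <- kid_of[[id]]
    if (!is.null(kids)) stack <- c(kids, stack)
  }
  seg <- seg[match(ordered, seg$segment_id), ]
  idx <- match(seg$parent_id, seg$segment_id)
  topo <- ifelse(is.na(idx), "/",
                 ifelse(seg$axis_id == seg$axis_id[idx], "<", "+"))
  num <- function(x) formatC(x / u, format = "fg", digits = 12)
  collar_row <- which(is.na(idx))
  hdr <- c(
    "# ROOT-MTG 1",
    sprintf("# UNIT: %s", unit),
    sprintf("# PLANT_ID: %s", rs$plant_id),
    sprintf("# SLOPE_DEG: %g", rs$slope_deg),
    sprintf("# FLEXED: %s", if (rs$flexed) "yes" else "no"),
    sprintf("# BLOCK: %s", rs$block),
    sprintf("# CONTAINER: %s %s %s",
            num(rs$container[1]), num(rs$container[2]), num(rs$container[3])),
    sprintf("# SHOOT_DW_G: %s", format(rs$shoot_dry_weight_g)),
    sprintf("# ROOT_DW_G: %s", format(rs$root_dry_weight_g)),
    sprintf("# COLLAR: %s %s %s",
            num(seg$base_x[collar_row]), num(seg$base_y[collar_row]),
            num(seg$base_z[collar_row])),
    sprintf("# FEATURES: %s", paste(mtg_features, collapse = " "))
  )
  body <- data.frame(
    ENTITY = seg$segment_id, TOPO = topo,
    PARENT = ifelse(is.na(seg$parent_id), "-", seg$parent_id),
    XX = num(seg$tip_x), YY = num(seg$tip_y), ZZ = num(seg$tip_z),
    Diameter = num(seg$diameter),
    FineRootCount = seg$fine_root_count,
    FineRootMeanLength = num(seg$fine_root_mean_length),
    check.names = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the portable segment-table format
#'
#' A flat CSV with one row per segment and all `root_system` fields; plant
#' metadata travels in `#`-prefixed header comments. Units are metres and the
#' frame is the container frame (x = north/upslope, z up through the collar).
#' `read_segment_table(write_segment_table(rs, p))` reproduces `rs`.
#'
#' @param rs A [root_system()].
#' @param path File path.
#' @return `path` invisibly (writer); a [root_system()] (reader).
#' @export
write_segment_table <- function(rs, path) {
  hdr <- c(
    "# rootarch segment table; units: metres; frame: container frame,",
    "#   x = north/upslope (azimuth 0), y = parallel to upper container",
    "#   border, z = perpendicular to soil surface through the collar (up).",
    sprintf("# PLANT_ID: %s", rs$plant_id),
    sprintf("# SLOPE_DEG: %g", rs$slope_deg),
    sprintf("# FLEXED: %s", if (rs$flexed) "yes" else "no"),
    sprintf("# BLOCK: %s", rs$block),
    sprintf("# CONTAINER: %.9g %.9g %.9g",
            rs$container[1], rs$container[2], rs$container[3]),
    sprintf("# SHOOT_DW_G: %s", format(rs$shoot_dry_weight_g)),
    sprintf("# ROOT_DW_G: %s", format(rs$root_dry_weight_g)),
    sprintf("# VOLUME_MODE: %s", rs$volume_mode)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(rs$segments), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_segment_table
#' @export
read_segment_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  get <- function(key, default = NA) {
    m <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    trimws(sub(sprintf("^#\\s*%s:", key), "", m[1]))
  }
  body <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                          stringsAsFactors = FALSE)
  body$parent_id <- as.character(body$parent_id)
  body$parent_id[body$parent_id %in% c("NA", "")] <- NA_character_
  root_system(
    body,
    plant_id = get("PLANT_ID", "plant"),
    slope_deg = as.numeric(get("SLOPE_DEG", "0")),
    flexed = tolower(get("FLEXED", "no")) %in% c("yes", "true", "1"),
    block = get("BLOCK", "b1"),
    container = as.numeric(strsplit(get("CONTAINER", "0.3 0.3 0.11"), "\\s+")[[1]]),
    shoot_dry_weight_g = suppressWarnings(as.numeric(get("SHOOT_DW_G"))),
    root_dry_weight_g = suppressWarnings(as.numeric(get("ROOT_DW_G"))),
    volume_mode = get("VOLUME_MODE", "frustum")
  )
}
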