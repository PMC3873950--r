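# End-to-end orchestration: from MTG files or generator settings to the
# full set of output tables.

#' Run the whole analysis pipeline
#'
#' Reads (or generates) a cohort of root systems, applies wall correction,
#' computes every per-plant table and the statistical layer, and writes CSV
#' outputs to a directory: `segments.csv`, `axes.csv`, `branch_events.csv`,
#' `traits.csv`, `sector_table.csv`, `anova.csv`, `sector_model.csv`,
#' `pca_scores.csv`, `pca_loadings.csv` and `qc_log.csv`.
#'
#' @param config A list (or path to a JSON file) with either
#'   `input_dir` (directory of `.mtg` files) or `generator` (a list:
#'   `n_per_group`, `seed`, plus [generator_config()] overrides for the
#'   base configuration), and optionally `zrt_limit`, `stump_length`,
#'   `include_fine_roots`, `output_dir`.
#' @return The output directory, invisibly. Errors name the failing stage
#'   and plant.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      rlang::abort(sprintf("config file not found: %s", config))
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out_dir <- config$output_dir %||% tempfile("rootarch_out_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  zrt <- config$zrt_limit %||% 0.050
  stump <- config$stump_length %||% 0.045
  iafr <- config$include_fine_roots %||% TRUE

  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir)) {
      rlang::abort(sprintf("input_dir not found: %s", config$input_dir))
    }
    files <- list.files(config$input_dir, pattern = "\\.mtg$", full.names = TRUE)
    if (length(files) == 0) {
      rlang::abort(sprintf("no .mtg files in %s", config$input_dir))
    }
    systems <- purrr::map(files, function(f) {
      tryCatch(read_mtg(f), error = function(e) {
        rlang::abort(sprintf("stage read_mtg failed for %s: %s", f, conditionMessage(e)))
      })
    })
    cohort <- list(systems = systems)
  } else if (!is.null(config$generator)) {
    g <- config$generator
    base <- generator_config()
    for (nm in setdiff(names(g), c("n_per_group", "seed", "group_tweaks"))) {
      base[[nm]] <- g[[nm]]
    }
    cohort <- generate_cohort(
      n_per_group = g$n_per_group %||% 8,
      seed = g$seed %||% 1L,
      base_config = base,
      group_tweaks = g$group_tweaks %||% default_group_tweaks()
    )
  } else {
    rlang::abort("config must provide input_dir or generator settings")
  }
  systems <- purrr::map(cohort$systems, function(rs) {
    suppressWarnings(extend_wall_roots(rs))
  })
  cohort$systems <- systems

  qc <- list()
  per_plant <- function(fn, stage) {
    purrr::map(systems, function(rs) {
      tryCatch(fn(rs), error = function(e) {
        rlang::abort(sprintf("stage %s failed for plant %s: %s",
                             stage, rs$plant_id, conditionMessage(e)))
      })
    })
  }
  segs <- dplyr::bind_rows(purrr::map(systems, function(rs) {
    dplyr::mutate(rs$segments, plant_id = rs$plant_id, .before = 1)
  }))
  axes <- dplyr::bind_rows(per_plant(axis_geometry, "axis_geometry"))
  evs <- dplyr::bind_rows(per_plant(
    function(rs) branch_events(rs, stump_length = stump), "branch_events"
  ))
  for (rs in systems) {
    v <- validate_root_system(rs)
    if (nrow(v) > 0) qc[[rs$plant_id]] <- dplyr::mutate(v, plant_id = rs$plant_id)
  }
  tt <- build_trait_table(cohort, zrt_limit = zrt, stump_length = stump,
                          correct_walls = FALSE,
                          include_fine_roots = iafr)
  st <- sector_table(cohort, zrt_limit = zrt, stump_length = stump)
  an <- anova_by_trait(tt)
  sm <- sector_mixed_model(st)
  pc <- pca_traits(tt)

  wr <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, name))
  }
  wr(segs, "segments.csv")
  wr(axes, "axes.csv")
  wr(evs, "branch_events.csv")
  wr(tt, "traits.csv")
  wr(st, "sector_table.csv")
  wr(an, "anova.csv")
  wr(sm, "sector_model.csv")
  wr(tidy(pc, "scores"), "pca_scores.csv")
  wr(tidy(pc, "loadings"), "pca_loadings.csv")
  qc_tbl <- if (length(qc)) dplyr::bind_rows(qc) else
    tibble::tibble(plant_id = character(), segment_id = character(),
                   rule = character(), detail = character())
  wr(qc_tbl, "qc_log.csv")
  if (nrow(qc_tbl) > 0) {
    rlang::warn(sprintf("%d validation issue(s); see qc_log.csv", nrow(qc_tbl)))
  }
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
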