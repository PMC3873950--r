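# PCA of the plant-by-trait table, on centred and scaled values.

#' Default trait selection for the multivariate analysis
#'
#' Seventeen variables representing the main features of the seedlings:
#' overall size and allocation, branching, compartment volume shares and
#' circular distribution.
#'
#' @return Character vector of 17 trait names.
#' @export
default_pca_traits <- function() {
  c(
    "rpc_biomass_pct", "dw1d", "srn_n_g", "muaxe_vol_zrt_cm3",
    "srl_laterals_iafr_cm_cm3", "qb_shallow_iafr", "ill_taproot_iafr_cm",
    "srl_order1_cm_cm3", "stump_rv_incl_pct", "rv_taproot_pct",
    "rv_zrt_pct", "rv_shallow_beyond_pct", "rv_intermediate_pct",
    "rv_deep_pct", "vol_share_us_zrt_pct", "vol_share_pp_shallow_pct",
    "taproot_angle_deg"
  )
}

#' Principal component analysis of the trait table
#'
#' Centred, unit-variance PCA of selected traits. The sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#'
#' @param tt A trait table from [build_trait_table()].
#' @param traits Trait columns to use (default [default_pca_traits()],
#'   intersected with available non-constant columns).
#' @param na_action `"impute_mean"` (default: missing values replaced by
#'   the column mean), `"drop_plants"` or `"error"`.
#' @return A `root_pca` object with `tidy()`, `glance()` and `autoplot()`
#'   methods.
#' @export
pca_traits <- function(tt, traits = default_pca_traits(),
                       na_action = c("impute_mean", "drop_plants", "error")) {
  na_action <- match.arg(na_action)
  traits <- intersect(traits, names(tt))
  if (length(traits) < 2) rlang::abort("need at least 2 trait columns")
  x <- as.data.frame(tt[, traits])
  meta <- tt[, intersect(c("plant_id", "slope", "flexing", "block"), names(tt))]
  if (anyNA(x)) {
    if (na_action == "error") {
      rlang::abort("missing values among selected traits")
    } else if (na_action == "drop_plants") {
      keep <- stats::complete.cases(x)
      x <- x[keep, , drop = FALSE]
      meta <- meta[keep, , drop = FALSE]
    } else {
      x <- purrr::map_dfc(x, ~ tidyr::replace_na(.x, mean(.x, na.rm = TRUE)))
    }
  }
  const <- vapply(x, function(v) stats::sd(v) < 1e-12, logical(1))
  if (any(const)) x <- x[, !const, drop = FALSE]
  if (nrow(x) < 3) rlang::abort("PCA needs at least 3 plants")
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # orient: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(fit$rotation))) {
    k <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[k, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  structure(
    list(prcomp = fit, meta = tibble::as_tibble(meta),
         traits = colnames(x),
         var_explained = fit$sdev^2 / sum(fit$sdev^2)),
    class = "root_pca"
  )
}

#' @export
print.root_pca <- function(x, ...) {
  cat(sprintf(
    "<root_pca> %d plants x %d traits; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    nrow(x$prcomp$x), length(x$traits),
    100 * x$var_explained[1], 100 * x$var_explained[2]
  ))
  invisible(x)
}

#' Tidy a root PCA
#'
#' @param x A `root_pca`.
#' @param matrix `"scores"` (plants), `"loadings"` (traits) or
#'   `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.root_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                          ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    dplyr::bind_cols(x$meta, tibble::as_tibble(x$prcomp$x))
  } else if (matrix == "loadings") {
    dplyr::bind_cols(tibble::tibble(trait = rownames(x$prcomp$rotation)),
                     tibble::as_tibble(x$prcomp$rotation))
  } else {
    tibble::tibble(
      component = seq_along(x$var_explained),
      eigenvalue = x$prcomp$sdev^2,
      var_explained_pct = 100 * x$var_explained,
      cumulative_pct = 100 * cumsum(x$var_explained)
    )
  }
}

#' @export
glance.root_pca <- function(x, ...) {
  tibble::tibble(
    n_plants = nrow(x$prcomp$x),
    n_traits = length(x$traits),
    pc1_var_pct = 100 * x$var_explained[1],
    pc2_var_pct = 100 * x$var_explained[2]
  )
}

#' Score plot of a root PCA
#'
#' @param object A `root_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.root_pca <- function(object, ...) {
  sc <- tidy(object, "scores")
  grp <- if (all(c("slope", "flexing") %in% names(sc))) {
    interaction(sc$slope, sc$flexing, sep = "/")
  } else factor("all")
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2, colour = grp)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = "slope/flexing"
    ) +
    ggplot2::theme_minimal()
}
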