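#' Percent change in admissions per temperature increment
#'
#' Transforms log-linear slope draws to the reporting scale: for each
#' draw, `100 * (exp(gamma * delta_t) - 1)`, summarised by the
#' posterior median and central 95 percent credible interval.
#'
#' @param gamma_draws Numeric vector of slope draws (per degree C).
#' @param delta_t Temperature increment in degrees C (default 10).
#' @param point Point summary, `"median"` (default, robust on the
#'   exponentiated scale) or `"mean"`.
#' @return A list with `estimate`, `lower`, `upper` (percent) and the
#'   transformed `draws`.
#' @export
#' @examples
#' percent_change(log(1.072) / 10)$estimate  # 7.2
percent_change <- function(gamma_draws, delta_t = 10,
                           point = c("median", "mean")) {
  point <- match.arg(point)
  if (length(gamma_draws) == 0 || any(!is.finite(gamma_draws)))
    stop_invalid("slope draws must be non-empty and finite")
  pct <- 100 * (exp(gamma_draws * delta_t) - 1)
  est <- if (point == "median") median(pct) else mean(pct)
  list(estimate = est,
       lower = unname(quantile(pct, 0.025)),
       upper = unname(quantile(pct, 0.975)),
       draws = pct)
}

#' Additional admissions per day implied by a percent effect
#'
#' The daily admission burden implied by an estimated percent change:
#' `mean_rate * pct / 100`, reported to one decimal place.
#'
#' @param mean_rate Mean admissions per day.
#' @param pct Percent change in admissions.
#' @return Additional admissions per day (1 decimal).
#' @export
#' @examples
#' extra_admissions(193, 7.2)  # 13.9
extra_admissions <- function(mean_rate, pct) {
  if (mean_rate < 0) stop_invalid("mean_rate must be >= 0")
  round(mean_rate * pct / 100, 1)
}

#' Area slope table with significance classes
#'
#' Summarises every area's temperature slope as percent change per
#' 10 degrees C with its 95 percent credible interval, and classifies
#' each area: `positive` when the interval lies above zero, `negative`
#' when below, `null` otherwise.  Rows are arranged as in a published
#' risk table: significant positive areas by descending effect, then
#' significant negative areas by ascending effect, then the rest.
#'
#' @param fit A model-2 or model-3 `heat_fit`.
#' @param areas Optional `area_frame`; its covariates are joined onto
#'   the table.
#' @param point Passed to [percent_change()].
#' @return A `data.frame` with `area_id`, `pct_per_10C`, `cri_low`,
#'   `cri_high`, `signif`, plus any area covariates; attribute
#'   `signif_counts` holds the number of positive / negative areas.
#' @export
slope_table <- function(fit, areas = NULL, point = "median") {
  stopifnot(inherits(fit, "heat_fit"))
  if (fit$model == "model1")
    stop_invalid("slope_table needs per-area draws (models 2-3)")
  missing_areas <- setdiff(paste0("gamma_", fit$meta$area_id),
                           colnames(fit$draws))
  if (length(missing_areas))
    stop_invalid("internal inconsistency: no draws for %s",
                 paste(missing_areas, collapse = ", "))
  G <- gamma_draws(fit)
  rows <- lapply(seq_along(fit$meta$area_id), function(k) {
    pc <- percent_change(G[, k], point = point)
    data.frame(area_id = fit$meta$area_id[k],
               pct_per_10C = pc$estimate, cri_low = pc$lower,
               cri_high = pc$upper, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$signif <- ifelse(tab$cri_low > 0, "positive",
                       ifelse(tab$cri_high < 0, "negative", "null"))
  ord <- c(which(tab$signif == "positive")[
             order(-tab$pct_per_10C[tab$signif == "positive"])],
           which(tab$signif == "negative")[
             order(tab$pct_per_10C[tab$signif == "negative"])],
           which(tab$signif == "null")[
             order(-tab$pct_per_10C[tab$signif == "null"])])
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(areas))
    tab <- merge(tab, as.data.frame(areas)[, setdiff(names(areas),
                   c("population", "centroid_ew", "centroid_ns"))],
                 by = "area_id", sort = FALSE)
  attr(tab, "signif_counts") <- c(positive = sum(tab$signif == "positive"),
                                  negative = sum(tab$signif == "negative"))
  tab
}

#' Cross-level modifier effect table
#'
#' Converts `lambda` draws from model-3 fits into the reported scale:
#' the percent change in the temperature-admissions slope per stated
#' unit of each area-level predictor, computed per draw as
#' `100 * lambda * unit / gamma_star` and summarised by the posterior
#' median and 95 percent credible interval.
#'
#' @param fits A named list of model-3 `heat_fit` objects (one entry
#'   may contain several modifiers, e.g. the joint density + income
#'   model).
#' @param unit_changes Named numeric vector mapping each modifier
#'   covariate to its reporting unit (e.g. `c(density = 1000)` for
#'   "per 1,000 persons/km^2").
#' @return A `data.frame` with one row per (fit, modifier): `model`,
#'   `predictor`, `unit`, `pct_change`, `cri_low`, `cri_high`,
#'   `signif`.
#' @export
modifier_table <- function(fits, unit_changes) {
  if (inherits(fits, "heat_fit")) fits <- list(fits)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f)
      paste(f$meta$modifiers, collapse = "+"), "")
  rows <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    mods <- fit$meta$modifiers
    if (is.null(mods))
      stop_invalid("fit '%s' has no modifiers (not a model-3 fit)", nm)
    gs <- fit$draws[, "gamma_star"]
    for (mv in mods) {
      if (!mv %in% names(unit_changes))
        stop_invalid("no reporting unit given for modifier '%s'", mv)
      u <- unit_changes[[mv]]
      lam <- fit$draws[, paste0("lambda_", mv)]
      ratio <- 100 * lam * u / gs
      lo <- unname(quantile(ratio, 0.025))
      hi <- unname(quantile(ratio, 0.975))
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, predictor = mv, unit = u,
        pct_change = median(ratio), cri_low = lo, cri_high = hi,
        signif = if (lo > 0) "positive" else if (hi < 0) "negative" else "null",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Row-standardised k-nearest-neighbour spatial weights
#'
#' Builds a spatial weights matrix from area centroids: each area's k
#' nearest neighbours (Euclidean distance) receive equal weight summing
#' to one.  Used for Moran's I on synthetic layouts, where no polygon
#' contiguity exists.
#'
#' @param coords Two-column matrix (or `area_frame`) of planar
#'   centroid coordinates.
#' @param k Number of neighbours (default 5).
#' @return An n x n row-standardised weight matrix with zero diagonal
#'   and a `weights_spec` attribute.
#' @export
knn_weights <- function(coords, k = 5L) {
  if (inherits(coords, "data.frame"))
    coords <- as.matrix(coords[, c("centroid_ew", "centroid_ns")])
  n <- nrow(coords)
  if (n < k + 1L)
    stop_invalid("need at least k+1 = %d areas for k-nearest neighbours", k + 1L)
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    W[i, nb] <- 1 / k
  }
  attr(W, "weights_spec") <- sprintf("k-nearest-neighbour (k=%d), row-standardised", k)
  W
}

#' Moran's I with a permutation test
#'
#' Spatial autocorrelation of a per-area statistic (here, the posterior
#' area slopes): `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' centred values `z` and `S0 = sum_ij w_ij`.  The p-value is a
#' two-sided permutation test: values are randomly reassigned to areas
#' `n_perm` times and `p = (r + 1) / (n_perm + 1)`, where `r` counts
#' permutations at least as extreme (relative to the permutation null
#' mean `-1/(n-1)`) as the observed statistic.
#'
#' @param values Numeric per-area statistic (length >= 3, not
#'   constant).
#' @param weights Non-negative spatial weight matrix with zero
#'   diagonal, e.g. from [knn_weights()].
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer RNG seed for the permutations.
#' @return A list of class `moran_result`: `I`, `p_value`, `n_perm`,
#'   `weights_spec`.
#' @export
morans_i <- function(values, weights, n_perm = 999L, seed = 1L) {
  n <- length(values)
  if (n < 3L) stop_invalid("Moran's I needs at least 3 areas")
  if (nrow(weights) != n || ncol(weights) != n)
    stop_invalid("weights must be an n x n matrix matching values")
  if (any(weights < 0) || any(diag(weights) != 0))
    stop_invalid("weights must be non-negative with a zero diagonal")
  if (sd(values) == 0)
    stop_invalid("Moran's I is undefined for constant values")
  S0 <- sum(weights)
  moran_stat <- function(v) {
    z <- v - mean(v)
    (n / S0) * as.numeric(t(z) %*% weights %*% z) / sum(z^2)
  }
  I <- moran_stat(values)
  e0 <- -1 / (n - 1)  # permutation-null mean
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(i) moran_stat(sample(values)), 0)
  r <- sum(abs(perm - e0) >= abs(I - e0))
  structure(list(I = I, p_value = (r + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm),
                 weights_spec = attr(weights, "weights_spec") %||%
                   "user-supplied matrix, as given"),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.3f (permutation p = %.3g, %d permutations)\n  weights: %s\n",
              x$I, x$p_value, x$n_perm, x$weights_spec))
  invisible(x)
}
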