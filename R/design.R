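#' Combine two station temperature series
#'
#' Two nearby stations are merged into a single exposure series: the
#' mean of both measurements on days where both are present, the single
#' available measurement where one is missing, and missing where both
#' are.
#'
#' @param a,b `weather_series` objects on the same date grid.
#' @return A `weather_series` on the shared grid.
#' @export
#' @examples
#' d <- as.Date("2007-01-01") + 0:1
#' a <- data.frame(date = d, tmax = c(30, NA))
#' b <- data.frame(date = d, tmax = c(32, 28))
#' combine_stations(a, b)$tmax  # 31, 28
combine_stations <- function(a, b) {
  if (!identical(as.Date(a$date), as.Date(b$date)))
    stop_invalid("station series are on different date grids")
  tmax <- rowMeans(cbind(a$tmax, b$tmax), na.rm = TRUE)
  tmax[is.na(a$tmax) & is.na(b$tmax)] <- NA_real_
  structure(data.frame(date = as.Date(a$date), tmax = tmax),
            class = c("weather_series", "data.frame"))
}

#' Restrict dates to the warm season and label seasons
#'
#' The models use the warm season only, defined as October through
#' March.  A season spanning the year boundary (October of year Y to
#' March of year Y+1) receives the single label `"Y-Y+1"`.
#'
#' @param dates A vector of calendar dates.
#' @param months Integer months defining the warm season.
#' @return A `data.frame` with columns `date` (the retained dates, in
#'   order) and `season_id`.
#' @export
#' @examples
#' warm_season_subset(as.Date(c("2007-10-01", "2008-04-01")))
warm_season_subset <- function(dates, months = c(10:12, 1:3)) {
  dates <- sort(unique(as_date_strict(dates)))
  m <- as.integer(format(dates, "%m"))
  keep <- m %in% months
  dates <- dates[keep]
  m <- m[keep]
  y <- as.integer(format(dates, "%Y"))
  start_year <- ifelse(m >= 10L, y, y - 1L)
  data.frame(date = dates,
             season_id = sprintf("%d-%d", start_year, start_year + 1L),
             stringsAsFactors = FALSE)
}

#' Lagged temperature exposure
#'
#' Shifts the daily maximum temperature forward by `lag` days, giving
#' the exposure series `tmax1` (previous day's maximum for the default
#' lag of 1).  Dates whose lagged value is absent from the input are
#' flagged missing; model fits drop them from the likelihood.
#'
#' @param weather A `weather_series`.
#' @param lag Non-negative integer lag in days.
#' @return A `data.frame` of class `exposure_series` with columns
#'   `date`, `tmax1`.
#' @export
lagged_exposure <- function(weather, lag = 1L) {
  if (lag < 0) stop_invalid("lag must be >= 0")
  date <- as_date_strict(weather$date)
  idx <- match(date - lag, date)
  structure(data.frame(date = date, tmax1 = weather$tmax[idx]),
            class = c("exposure_series", "data.frame"))
}

# natural cubic spline block for one season's dates; interior knots at
# equally spaced quantiles of the within-season day index
ns_season_block <- function(dates, n_knots) {
  x <- as.numeric(dates - min(dates))
  if (length(unique(x)) < n_knots + 2L)
    stop_invalid("season of %d days is too short for %d interior knots",
                 length(x), n_knots)
  kn <- quantile(x, probs = seq_len(n_knots) / (n_knots + 1), names = FALSE)
  splines::ns(x, knots = kn, Boundary.knots = range(x))
}

#' Piecewise per-season day-of-year spline basis
#'
#' Builds the seasonal / long-term-trend adjustment: for every warm
#' season a separate natural cubic spline in the within-season day
#' index, with interior knots at equally spaced quantiles — 5 knots for
#' interior seasons and 4 for the (possibly truncated) first and last
#' seasons of the study period.  Season-level indicator columns carry
#' between-season level shifts, so interannual trends are absorbed by
#' the basis rather than by the temperature slope.  Blocks for
#' different seasons have disjoint support.
#'
#' @param seasons A `data.frame` with columns `date`, `season_id`, as
#'   returned by [warm_season_subset()].
#' @param interior_knots Interior knots per interior season (default 5).
#' @param edge_knots Interior knots for the first and last season
#'   (default 4).
#' @return A numeric matrix with one row per input date; columns are the
#'   season indicators (all seasons but the first) followed by the
#'   per-season spline blocks.
#' @export
doy_spline_basis <- function(seasons, interior_knots = 5L, edge_knots = 4L) {
  sid <- unique(seasons$season_id[order(seasons$date)])
  S <- length(sid)
  n <- nrow(seasons)
  blocks <- list()
  if (S > 1L) {
    ind <- matrix(0, n, S - 1L,
                  dimnames = list(NULL, paste0("season_", sid[-1L])))
    for (s in 2:S) ind[seasons$season_id == sid[s], s - 1L] <- 1
    blocks[[length(blocks) + 1L]] <- ind
  }
  for (s in seq_len(S)) {
    rows <- which(seasons$season_id == sid[s])
    k <- if (s == 1L || s == S) edge_knots else interior_knots
    B <- ns_season_block(seasons$date[rows], k)
    M <- matrix(0, n, ncol(B),
                dimnames = list(NULL, sprintf("doy_%s_%d", sid[s],
                                              seq_len(ncol(B)))))
    M[rows, ] <- B
    blocks[[length(blocks) + 1L]] <- M
  }
  do.call(cbind, blocks)
}

#' Temporal design matrix: day of week, holidays, seasonal spline
#'
#' Assembles the shared `time_j` component of all three models for the
#' warm-season subset of the supplied dates: six day-of-week indicators
#' (reference Monday), four holiday-category indicators (reference
#' `none`), and the piecewise per-season day-of-year spline of
#' [doy_spline_basis()].
#'
#' @param dates Calendar dates (any order; restricted to the warm season
#'   internally).
#' @param calendar A `holiday_calendar` covering all retained dates.
#' @param interior_knots,edge_knots Passed to [doy_spline_basis()].
#' @param months Warm-season months, passed to [warm_season_subset()].
#' @return An object of class `temporal_design`: a list with `date`,
#'   `season_id`, the model matrix `X`, and `groups` giving the column
#'   indices of the `dow`, `hols` and `doy` blocks.
#' @export
temporal_design <- function(dates, calendar, interior_knots = 5L,
                            edge_knots = 4L, months = c(10:12, 1:3)) {
  ws <- warm_season_subset(dates, months = months)
  if (!all(ws$date %in% as.Date(calendar$date)))
    stop_invalid("holiday calendar does not cover all design dates")
  # day of week, reference Monday
  dow_lab <- c("Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  u <- as.integer(format(ws$date, "%u"))  # 1 = Monday
  dow <- matrix(0, nrow(ws), 6L, dimnames = list(NULL, paste0("dow_", dow_lab)))
  for (i in 2:7) dow[u == i, i - 1L] <- 1
  # holidays, reference none
  cat_lab <- c("standard", "christmas", "jan2", "other")
  cats <- calendar$category[match(ws$date, as.Date(calendar$date))]
  hols <- matrix(0, nrow(ws), 4L,
                 dimnames = list(NULL, paste0("hols_", cat_lab)))
  for (i in seq_along(cat_lab)) hols[cats == cat_lab[i], i] <- 1
  doy <- doy_spline_basis(ws, interior_knots = interior_knots,
                          edge_knots = edge_knots)
  X <- cbind(dow, hols, doy)
  structure(list(date = ws$date, season_id = ws$season_id, X = X,
                 groups = list(dow = 1:6, hols = 7:10,
                               doy = 10L + seq_len(ncol(doy)))),
            class = "temporal_design")
}

#' @export
print.temporal_design <- function(x, ...) {
  cat(sprintf("Temporal design: %d days, %d seasons, %d columns (6 dow + 4 hols + %d doy)\n",
              length(x$date), length(unique(x$season_id)), ncol(x$X),
              length(x$groups$doy)))
  invisible(x)
}

#' Directional spatial spline basis over area centroids
#'
#' A smooth large-scale spatial trend in admissions is modelled as the
#' sum of a natural cubic spline in the east-west centroid coordinate
#' and one in the north-south coordinate, each with 2 degrees of
#' freedom by default.  Columns are centred so the trend is identified
#' next to the global intercept and the area random intercepts.
#'
#' @param areas An `area_frame` with `centroid_ew`, `centroid_ns`.
#' @param df_per_direction Spline degrees of freedom per direction.
#' @return An object of class `spatial_basis`: list with `area_id` and
#'   the centred basis matrix `S` (columns `ew_*` then `ns_*`).
#' @export
spatial_basis <- function(areas, df_per_direction = 2L) {
  for (cc in c("centroid_ew", "centroid_ns")) {
    if (length(unique(areas[[cc]])) < df_per_direction + 1L)
      stop_invalid("degenerate %s coordinates: need at least %d distinct values",
                   cc, df_per_direction + 1L)
  }
  Bew <- splines::ns(areas$centroid_ew, df = df_per_direction)
  Bns <- splines::ns(areas$centroid_ns, df = df_per_direction)
  S <- cbind(Bew, Bns)
  colnames(S) <- c(paste0("ew_", seq_len(df_per_direction)),
                   paste0("ns_", seq_len(df_per_direction)))
  S <- scale(S, center = TRUE, scale = FALSE)
  attr(S, "scaled:center") <- NULL
  structure(list(area_id = areas$area_id, S = S), class = "spatial_basis")
}
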