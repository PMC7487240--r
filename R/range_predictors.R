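# Life-history / environmental predictors computed from seasonal range
# polygons and raster layers.  Polygons are plain data.frames of vertices in
# geographic coordinates (columns `lon`, `lat`, degrees); rasters are small
# in-memory grids (see `simple_raster`).  No GIS stack is required: the
# package targets the generic geometry these predictors need, and ships an
# analytic day-length model so the pipeline runs with no downloads.

as_polygon <- function(p) {
  p <- as.data.frame(p)
  if (!all(c("lon", "lat") %in% names(p)))
    stop("polygon needs `lon` and `lat` columns")
  if (nrow(p) < 3) stop("validation error: polygon with fewer than 3 vertices")
  if (any(abs(p$lat) > 90)) stop("latitude outside [-90, 90]")
  p
}

polygon_centroid <- function(p) {
  p <- as_polygon(p)
  x <- p$lon; y <- p$lat
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  a <- x * y2 - x2 * y
  A <- sum(a) / 2
  if (abs(A) < 1e-12) return(c(lon = mean(x), lat = mean(y)))
  c(lon = sum((x + x2) * a) / (6 * A), lat = sum((y + y2) * a) / (6 * A))
}

#' Six migration-distance measures from seasonal ranges
#'
#' Given breeding and nonbreeding range polygons, computes, in order:
#' \enumerate{
#'   \item distance between the midlatitudes of the two distributions, where
#'     midlatitude = (min lat + max lat) / 2;
#'   \item distance between the maximum latitudes;
#'   \item distance between the minimum latitudes;
#'   \item distance between the maximum breeding latitude and minimum
#'     nonbreeding latitude;
#'   \item distance between the minimum breeding latitude and maximum
#'     nonbreeding latitude;
#'   \item great-circle (haversine, 6371-km sphere) distance between the
#'     polygon centroids, in km.
#' }
#' Measures 1-5 are in degrees latitude.  Strict nonmigrants (complete
#' breeding/nonbreeding overlap) are always set to zero on all six measures;
#' partial migrants are computed from their overlapping polygons as-is.
#'
#' @param breeding,nonbreeding Polygons (data.frames with `lon`, `lat`).
#' @param migrant_class `"migrant"`, `"partial"` or `"nonmigrant"`; if `NULL`
#'   it is derived with [classify_migrant()].
#' @return Named numeric vector of the six measures.
#' @export
migration_distance_measures <- function(breeding, nonbreeding,
                                        migrant_class = NULL) {
  b <- as_polygon(breeding); w <- as_polygon(nonbreeding)
  if (is.null(migrant_class)) migrant_class <- classify_migrant(b, w)
  migrant_class <- match.arg(migrant_class,
                             c("migrant", "partial", "nonmigrant"))
  out <- c(midlat = 0, maxlat = 0, minlat = 0, maxb_minw = 0,
           minb_maxw = 0, centroid_km = 0)
  if (migrant_class == "nonmigrant") return(out)
  mid <- function(p) (min(p$lat) + max(p$lat)) / 2
  out["midlat"] <- abs(mid(b) - mid(w))
  out["maxlat"] <- abs(max(b$lat) - max(w$lat))
  out["minlat"] <- abs(min(b$lat) - min(w$lat))
  out["maxb_minw"] <- abs(max(b$lat) - min(w$lat))
  out["minb_maxw"] <- abs(min(b$lat) - max(w$lat))
  cb <- polygon_centroid(b); cw <- polygon_centroid(w)
  out["centroid_km"] <- geosphere::distHaversine(
    c(cb["lon"], cb["lat"]), c(cw["lon"], cw["lat"]), r = 6371000) / 1000
  out
}

#' Classify migratory behavior from range overlap
#'
#' Migrants have no spatial overlap between breeding and nonbreeding
#' distributions, nonmigrants complete overlap, partial migrants some
#' overlap.  Overlap is assessed by testing a deterministic grid of points
#' from each polygon's bounding box for joint membership.
#'
#' @param breeding,nonbreeding Polygons.
#' @param grid_n Grid resolution per axis.
#' @return `"migrant"`, `"partial"` or `"nonmigrant"`.
#' @export
classify_migrant <- function(breeding, nonbreeding, grid_n = 40) {
  b <- as_polygon(breeding); w <- as_polygon(nonbreeding)
  frac_inside <- function(p, q) {
    gx <- seq(min(p$lon), max(p$lon), length.out = grid_n)
    gy <- seq(min(p$lat), max(p$lat), length.out = grid_n)
    g <- expand.grid(lon = gx, lat = gy)
    inp <- pracma::inpolygon(g$lon, g$lat, p$lon, p$lat, boundary = TRUE)
    if (!any(inp)) stop("validation error: empty polygon")
    inq <- pracma::inpolygon(g$lon[inp], g$lat[inp], q$lon, q$lat,
                             boundary = TRUE)
    mean(inq)
  }
  f_bw <- frac_inside(b, w)
  f_wb <- frac_inside(w, b)
  if (f_bw == 0 && f_wb == 0) "migrant"
  else if (f_bw > 0.999 && f_wb > 0.999) "nonmigrant"
  else "partial"
}

#' Choose the representative migration-distance measure
#'
#' For each of the candidate measures, fits simple linear regressions
#' predicting every other measure and averages the R^2 values; the measure
#' with the highest mean R^2 — the one that best predicts the others — is
#' selected.  Ties break toward the lowest index.  Constant columns are
#' excluded with a warning.
#'
#' @param measures Numeric matrix, species x measures.
#' @return List with `index` (selected column), `mean_r2` (per measure; NA
#'   for excluded columns), and `r2` (full measure-by-measure R^2 matrix).
#' @export
select_representative_measure <- function(measures) {
  M <- as.matrix(measures)
  if (nrow(M) < 3) stop("need at least 3 species")
  p <- ncol(M)
  sds <- apply(M, 2, sd)
  ok <- sds > 0
  if (!all(ok))
    warning("constant measure column(s) excluded: ",
            paste(which(!ok), collapse = ", "))
  if (sum(ok) < 2) stop("need at least 2 varying measures")
  R2 <- matrix(NA_real_, p, p)
  for (i in which(ok)) for (j in which(ok)) {
    if (i == j) next
    R2[i, j] <- suppressWarnings(cor(M[, i], M[, j]))^2
  }
  mean_r2 <- rowMeans(R2, na.rm = TRUE)
  mean_r2[!ok] <- NA_real_
  idx <- which.max(mean_r2) # which.max breaks ties toward lowest index
  list(index = idx, mean_r2 = mean_r2, r2 = R2)
}

#' Analytic day length
#'
#' Daylight hours from standard solar-declination geometry (the Forsythe et
#' al. CBM model), clamped to `[0, 24]`; used in place of a day-length
#' raster so the pipeline needs no external data.
#'
#' @param latitude Degrees, in `[-90, 90]`.
#' @param day_of_year Integer day 1-365 (vectorized).
#' @return Daylight hours per day.
#' @export
day_length_analytic <- function(latitude, day_of_year) {
  if (any(abs(latitude) > 90)) stop("latitude outside [-90, 90]")
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (day_of_year - 186)))
  decl <- asin(0.39795 * cos(theta))
  latr <- latitude * pi / 180
  x <- sin(latr) * sin(decl) / (cos(latr) * cos(decl))
  x <- pmin(1, pmax(-1, x))
  24 - (24 / pi) * acos(x)
}

#' Mean daylight hours over a window of the year
#'
#' @param latitude Degrees.
#' @param days Days of year to average over (default the whole year).
#' @return Mean hours of daylight per day.
#' @export
day_length_mean <- function(latitude, days = 1:365) {
  mean(day_length_analytic(latitude, days))
}

#' A minimal in-memory raster
#'
#' @param values Numeric matrix; rows run north (first row) to south.
#' @param xmin,xmax,ymin,ymax Geographic extent in degrees.
#' @return A `simple_raster` list.
#' @export
simple_raster <- function(values, xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  structure(list(values = as.matrix(values), xmin = xmin, xmax = xmax,
                 ymin = ymin, ymax = ymax),
            class = "simple_raster")
}

raster_lookup <- function(r, lon, lat) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- pmin(nc, pmax(1, floor((lon - r$xmin) / (r$xmax - r$xmin) * nc) + 1))
  row <- pmin(nr, pmax(1, floor((r$ymax - lat) / (r$ymax - r$ymin) * nr) + 1))
  out <- r$values[cbind(row, col)]
  out[lon < r$xmin | lon > r$xmax | lat < r$ymin | lat > r$ymax] <- NA
  out
}

#' Mean raster value over a range polygon
#'
#' Draws `n_points` uniform points within the polygon (rejection sampling
#' from the bounding box), looks up the raster value at each, skips no-data
#' cells, and returns their mean.  Reproducible bit-for-bit given
#' `(seed, n_points)`.
#'
#' @param polygon Polygon data.frame (`lon`, `lat`).
#' @param raster A [simple_raster()].
#' @param n_points Number of in-polygon sample points (default 10000).
#' @param seed Integer seed, recorded in the result.
#' @return List: `mean`, `n_valid` (non-NA samples), `n_points`, `seed`.
#' @export
sample_raster_mean <- function(polygon, raster, n_points = 10000, seed = 1) {
  p <- as_polygon(polygon)
  set.seed(seed)
  lon <- numeric(0); lat <- numeric(0)
  guard <- 0L
  while (length(lon) < n_points) {
    m <- max(2L * (n_points - length(lon)), 100L)
    cx <- runif(m, min(p$lon), max(p$lon))
    cy <- runif(m, min(p$lat), max(p$lat))
    keep <- pracma::inpolygon(cx, cy, p$lon, p$lat, boundary = TRUE)
    lon <- c(lon, cx[keep]); lat <- c(lat, cy[keep])
    guard <- guard + 1L
    if (guard > 200L) stop("polygon rejection sampling failed (degenerate ",
                           "polygon?)")
  }
  lon <- lon[seq_len(n_points)]; lat <- lat[seq_len(n_points)]
  vals <- raster_lookup(raster, lon, lat)
  ok <- !is.na(vals)
  if (!any(ok))
    stop("zero valid raster samples in polygon (all no-data)")
  list(mean = mean(vals[ok]), n_valid = sum(ok), n_points = n_points,
       seed = seed)
}

#' Solar exposure composite
#'
#' Solar radiation (kWh m^-2 month^-1) multiplied by day length — a crude
#' index of cumulative feather-bleaching exposure.
#'
#' @param radiation,day_length Non-negative numerics (vectorized).
#' @return Elementwise product.
#' @export
solar_exposure <- function(radiation, day_length) {
  if (any(radiation < 0) || any(day_length < 0))
    stop("radiation and day length must be non-negative")
  radiation * day_length
}

#' Seasonal extraction windows
#'
#' Breeding values are extracted over May-July and nonbreeding over
#' November-February, for all species regardless of migrant class.
#'
#' @param season `"breeding"` or `"nonbreeding"`.
#' @return Integer days of year in the window.
#' @export
season_days <- function(season = c("breeding", "nonbreeding")) {
  season <- match.arg(season)
  # month boundaries for a 365-day year
  mstart <- cumsum(c(1, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))
  mend <- c(mstart[-1] - 1, 365)
  months <- if (season == "breeding") 5:7 else c(11, 12, 1, 2)
  unlist(lapply(months, function(m) mstart[m]:mend[m]), use.names = FALSE)
}
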