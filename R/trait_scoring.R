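# Region-wise molt / dichromatism scores.  A score matrix is species x
# feather-region with values in {0, 0.5, 1}: 1 = complete replacement of the
# feathers in the region (or a completely dichromatic region), 0.5 = partial
# replacement / partial dichromatism or intraspecific variation, 0 = absent.

#' Canonical feather-region order
#'
#' Default head-to-alula ordering used for succession analyses.  The region
#' list is data, not code: any ordered character vector can be supplied to
#' the scoring functions instead.
#'
#' @return Character vector of 11 region names.
#' @export
canonical_regions <- function() {
  c("head", "breast", "belly", "back", "tertials", "median_coverts",
    "greater_coverts", "rump", "tail", "remiges", "alula")
}

#' Construct a region score matrix
#'
#' @param scores Matrix or data.frame, species in rows (rownames = species
#'   labels), regions in columns; every value in `{0, 0.5, 1}`.
#' @param channel `"molt"` or `"dichromatism"`.
#' @param regions Optional region order; defaults to the column names.
#' @return A numeric matrix of class `region_scores` with a `channel`
#'   attribute.
#' @export
region_scores <- function(scores, channel = c("molt", "dichromatism"),
                          regions = NULL) {
  channel <- match.arg(channel)
  m <- as.matrix(scores)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) stop("scores must have species rownames")
  if (!is.null(regions)) {
    if (!all(regions %in% colnames(m)))
      stop("regions absent from scores: ",
           paste(setdiff(regions, colnames(m)), collapse = ", "))
    m <- m[, regions, drop = FALSE]
  }
  bad <- !(m %in% c(0, 0.5, 1))
  if (any(bad))
    stop("scores must be in {0, 0.5, 1}; offending cells: ",
         paste(head(which(bad)), collapse = ", "))
  class(m) <- c("region_scores", class(m))
  attr(m, "channel") <- channel
  m
}

#' Extent of molt or dichromatism
#'
#' Row sum of region scores (half-scores contribute 0.5), i.e. the number of
#' feather regions involved.  With `round_half = TRUE` half-scores are
#' rounded up to 1 before summing (an alternative integer reading of
#' "number of regions involved").
#'
#' @param scores A `region_scores` matrix (or plain matrix of valid scores).
#' @param round_half Round 0.5 cells up to 1 before summing.
#' @return Named numeric vector, one value per species, in
#'   `[0, ncol(scores)]`.
#' @export
extent <- function(scores, round_half = FALSE) {
  m <- unclass(scores)
  if (round_half) m <- ceiling(m)
  rowSums(m)
}

#' Presence of molt or dichromatism
#'
#' A species scores 1 if any region score exceeds zero (partial scores count
#' as presence).  With `by_region = TRUE` the per-region binary matrix is
#' returned instead.
#'
#' @param scores A `region_scores` matrix.
#' @param by_region Return the per-region 0/1 matrix.
#' @return Named 0/1 vector per species, or a 0/1 matrix.
#' @export
presence <- function(scores, by_region = FALSE) {
  m <- unclass(scores)
  if (by_region) return((m > 0) + 0)
  as.integer(rowSums(m > 0) > 0) |> setNames(rownames(m))
}

#' Stereotyped succession of feather-region inclusion
#'
#' Tests, per species, whether the set of regions with any replacement
#' (score > 0) forms a prefix of the supplied head-to-alula order, and
#' tabulates per-region inclusion frequency across species.  On data obeying
#' the stereotyped succession the frequency table is monotone non-increasing
#' along the order.
#'
#' @param scores A `region_scores` matrix.
#' @param order Region order; defaults to [canonical_regions()] intersected
#'   with the matrix columns.
#' @return List with `is_prefix` (logical per species) and `frequency`
#'   (named numeric per region, in `order`).
#' @export
succession_index <- function(scores, order = NULL) {
  m <- unclass(scores)
  if (is.null(order)) order <- intersect(canonical_regions(), colnames(m))
  if (!all(order %in% colnames(m)))
    stop("validation error: regions not in score matrix: ",
         paste(setdiff(order, colnames(m)), collapse = ", "))
  inc <- m[, order, drop = FALSE] > 0
  is_prefix <- apply(inc, 1, function(z) {
    k <- sum(z)
    k == 0 || all(z[seq_len(k)])
  })
  freq <- colMeans(inc)
  list(is_prefix = is_prefix, frequency = freq)
}

#' Consistency of dichromatism with molt
#'
#' Seasonal color change in a region requires that region to be replaced, so
#' region-wise dichromatism presence should imply molt presence.  Real
#' scores may disagree; this diagnostic reports violations without
#' enforcing anything.
#'
#' @param molt,dichromatism `region_scores` matrices over the same species
#'   and regions.
#' @return List with `n_violations` and a logical matrix `violation`
#'   (dichromatism present where molt absent).
#' @export
region_consistency <- function(molt, dichromatism) {
  m <- unclass(molt); d <- unclass(dichromatism)
  if (!identical(dim(m), dim(d)))
    stop("molt and dichromatism matrices differ in shape")
  d <- d[rownames(m), colnames(m), drop = FALSE]
  v <- (d > 0) & (m == 0)
  list(n_violations = sum(v), violation = v)
}

#' Read / write region score tables
#'
#' CSV layout: one row per species (column `species`), score columns named
#' `<channel>_<region>` (e.g. `pa_head`, `sd_breast`).  `pa` = prealternate
#' molt, `sd` = seasonal dichromatism.
#'
#' @param path CSV path.
#' @param prefix Column prefix for the channel (`"pa"` or `"sd"`).
#' @param channel Channel tag for the resulting matrix.
#' @return A `region_scores` matrix.
#' @export
read_region_scores <- function(path, prefix = "pa",
                               channel = c("molt", "dichromatism")) {
  channel <- match.arg(channel)
  df <- read.csv(path, check.names = FALSE)
  if (!"species" %in% names(df)) stop("score CSV needs a `species` column")
  cols <- grep(paste0("^", prefix, "_"), names(df), value = TRUE)
  cols <- setdiff(cols, paste0(prefix, c("_extent", "_presence")))
  if (!length(cols)) stop("no columns with prefix `", prefix, "_` found")
  m <- as.matrix(df[, cols, drop = FALSE])
  rownames(m) <- df$species
  colnames(m) <- sub(paste0("^", prefix, "_"), "", cols)
  region_scores(m, channel = channel)
}

#' @rdname read_region_scores
#' @param molt,dichromatism `region_scores` matrices to write side by side.
#' @export
write_region_scores <- function(molt, dichromatism, path) {
  m <- unclass(molt); d <- unclass(dichromatism)
  d <- d[rownames(m), colnames(m), drop = FALSE]
  out <- data.frame(species = rownames(m), check.names = FALSE)
  for (r in colnames(m)) out[[paste0("pa_", r)]] <- m[, r]
  for (r in colnames(d)) out[[paste0("sd_", r)]] <- d[, r]
  out$pa_extent <- extent(molt)
  out$pa_presence <- presence(molt)
  out$sd_extent <- extent(dichromatism)
  out$sd_presence <- presence(dichromatism)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Validate ordinal life-history codes
#'
#' Habitat codes run 0 (tall deciduous forest) to 6 (open habitat); foraging
#' stratum 0 (ground or near ground) to 4 (canopy/edge/open); nest type
#' 0 = cavity, 1 = dome/closed, 2 = open cup.  Breeding and wintering
#' habitat/stratum are scored separately.
#'
#' @param x Integer vector of codes.
#' @param kind One of `"habitat"`, `"stratum"`, `"nest_type"`.
#' @return `x`, invisibly, after validation.
#' @export
ordinal_codes <- function(x, kind = c("habitat", "stratum", "nest_type")) {
  kind <- match.arg(kind)
  rng <- switch(kind, habitat = 0:6, stratum = 0:4, nest_type = 0:2)
  if (any(is.na(x)) || any(x != round(x)) || any(x < min(rng) | x > max(rng)))
    stop(kind, " codes must be integers in [", min(rng), ", ", max(rng), "]")
  invisible(as.integer(x))
}
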