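#' Inclusive RGB colour box
#'
#' Per-channel inclusive `[lo, hi]` bounds defining a colour class in RGB
#' space. A pixel is in the box iff `lo[c] <= value[c] <= hi[c]` for all
#' three channels.
#'
#' @param lo,hi integer RGB triples, `0 <= lo[c] <= hi[c] <= 255`.
#' @return object of class `color_range`.
#' @export
color_range <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L)
    stop("`lo` and `hi` must be RGB triples")
  if (anyNA(lo) || anyNA(hi) || any(lo < 0L) || any(hi > 255L) ||
      any(lo > hi))
    stop("bounds must satisfy 0 <= lo <= hi <= 255 per channel")
  structure(list(lo = setNames(lo, c("R", "G", "B")),
                 hi = setNames(hi, c("R", "G", "B"))),
            class = "color_range")
}

#' @export
print.color_range <- function(x, ...) {
  cat(sprintf("<color_range> R %d-%d, G %d-%d, B %d-%d\n",
              x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$lo[3], x$hi[3]))
  invisible(x)
}

#' The published yellow range for gilthead seabream skin
#'
#' The RGB box obtained in the source study by sampling yellow pixels on
#' calibrated photographs: R 205-255, G 130-255, B 0-15 (inclusive).
#'
#' @return a [color_range()].
#' @export
yellow_reference_range <- function() {
  color_range(c(205L, 130L, 0L), c(255L, 255L, 15L))
}

#' Derive a colour range from sampled pixels
#'
#' Channel-wise minimum/maximum over a set of sampled pixels — the
#' protocol used to define the yellow box (five yellow pixels sampled in
#' three images per tank, nine images per treatment).
#'
#' @param samples an `n x 3` matrix of RGB values (or a list of RGB
#'   triples), `n >= 2`.
#' @return a [color_range()] with `lo` = per-channel minima and `hi` =
#'   per-channel maxima.
#' @export
derive_color_range <- function(samples) {
  if (is.list(samples) && !is.data.frame(samples))
    samples <- do.call(rbind, samples)
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L)
    stop("at least 2 sampled pixels are required")
  color_range(apply(samples, 2L, min), apply(samples, 2L, max))
}

#' Sample foreground pixel colours from an image
#'
#' Helper for the range-derivation protocol: draws `n` pixels uniformly
#' without replacement from the fish foreground (optionally restricted to
#' a supplied mask, e.g. an annotated yellow region) and records their
#' coordinates.
#'
#' @param image a [masked_image()].
#' @param n number of pixels to sample.
#' @param within optional logical matrix further restricting the sampling
#'   region (intersected with the fish mask).
#' @return `n x 3` integer matrix of RGB values with a `coords` attribute
#'   (`n x 2` matrix of 0-based (row, col) positions).
#' @export
sample_pixels <- function(image, n = 5, within = NULL) {
  stopifnot(inherits(image, "masked_image"))
  m <- image$mask
  if (!is.null(within)) m <- m & within
  idx <- which(m)
  if (length(idx) < n)
    stop("sampling region has fewer than ", n, " pixels [",
         image$image_id, "]")
  take <- sample(idx, n)
  H <- nrow(m)
  rows <- (take - 1L) %% H + 1L
  cols <- (take - 1L) %/% H + 1L
  rgb <- cbind(R = image$pixels[cbind(rows, cols, 1L)],
               G = image$pixels[cbind(rows, cols, 2L)],
               B = image$pixels[cbind(rows, cols, 3L)])
  attr(rgb, "coords") <- cbind(row = rows - 1L, col = cols - 1L)
  rgb
}

#' Perturb a colour range by a percentage of each bound
#'
#' Each bound moves by `pct` percent of its own value: expanding widens
#' the box (lower bounds scaled down and rounded down, upper bounds scaled
#' up and rounded up); shrinking narrows it (reversed, rounding inward).
#' Results are clamped to `[0, 255]` and re-ordered per channel so that
#' `lo <= hi`. A bound of 0 is a fixed point.
#'
#' @param range a [color_range()].
#' @param pct percentage, `|pct| <= 50`.
#' @param mode `"expand"` or `"shrink"`.
#' @return the perturbed [color_range()].
#' @export
perturb_range <- function(range, pct, mode = c("expand", "shrink")) {
  stopifnot(inherits(range, "color_range"))
  mode <- match.arg(mode)
  if (abs(pct) > 50) stop("|pct| must be <= 50")
  f <- pct / 100
  if (mode == "expand") {
    lo <- floor(range$lo * (1 - f))
    hi <- ceiling(range$hi * (1 + f))
  } else {
    lo <- ceiling(range$lo * (1 + f))
    hi <- floor(range$hi * (1 - f))
  }
  lo <- clamp8(lo); hi <- clamp8(hi)
  color_range(pmin(lo, hi), pmax(lo, hi))
}

#' Binary mask of in-range (yellow) foreground pixels
#'
#' `TRUE` exactly at foreground pixels whose RGB value lies inside the
#' inclusive colour box. Background pixels are never marked, whatever
#' their colour.
#'
#' @param image a [masked_image()].
#' @param range a [color_range()].
#' @return logical `H x W` matrix.
#' @export
yellow_mask <- function(image, range) {
  stopifnot(inherits(image, "masked_image"), inherits(range, "color_range"))
  p <- image$pixels
  inr <- p[, , 1] >= range$lo[1] & p[, , 1] <= range$hi[1] &
         p[, , 2] >= range$lo[2] & p[, , 2] <= range$hi[2] &
         p[, , 3] >= range$lo[3] & p[, , 3] <= range$hi[3]
  inr & image$mask
}

#' Standard distance deviation of a set of pixel coordinates
#'
#' The spatial dispersion statistic used to describe how scattered the
#' yellow pixels are. Two definitions are available:
#' \describe{
#'   \item{`centroid` (default)}{the classical standard distance about the
#'     mean centre: `sqrt( sum_i d_i^2 / n )` where `d_i` is the distance
#'     of point `i` from the centroid.}
#'   \item{`pairwise`}{the population standard deviation of all
#'     `n(n-1)/2` inter-point distances.}
#' }
#' Units are pixels. With fewer than 2 points the statistic is undefined
#' and `NA` is returned (never 0, which would fake maximal concentration).
#'
#' @param coords numeric `n x 2` matrix of (row, col) pixel coordinates.
#' @param method `"centroid"` or `"pairwise"`.
#' @param distance distance metric between points (or from the centroid),
#'   `"euclidean"` (default) or `"manhattan"`.
#' @return nonnegative scalar, or `NA_real_` when `n < 2`.
#' @export
compute_sdd <- function(coords, method = c("centroid", "pairwise"),
                        distance = c("euclidean", "manhattan")) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(n) || n < 2L) return(NA_real_)
  if (method == "centroid") {
    dr <- coords[, 1] - mean(coords[, 1])
    dc <- coords[, 2] - mean(coords[, 2])
    d2 <- if (distance == "euclidean") dr^2 + dc^2 else (abs(dr) + abs(dc))^2
    sqrt(sum(d2) / n)
  } else {
    d <- as.numeric(dist(coords, method = distance))
    sqrt(mean((d - mean(d))^2))          # population SD over the multiset
  }
}

# 1-based (row, col) coordinates of TRUE cells of a mask
mask_coords <- function(m) {
  idx <- which(m)
  H <- nrow(m)
  cbind(row = (idx - 1L) %% H + 1L, col = (idx - 1L) %/% H + 1L)
}

#' Quantify yellow pigmentation on one image
#'
#' Counts foreground pixels inside the colour box, standardizes the count
#' by the total foreground pixel number of the individual, and computes
#' the SDD of the yellow pixel coordinates.
#'
#' @param image a [masked_image()].
#' @param range a [color_range()].
#' @param fish_id,treatment,tank metadata carried into the record.
#' @param sdd_method,sdd_distance passed to [compute_sdd()].
#' @return one-row data.frame with columns `image_id`, `fish_id`,
#'   `treatment`, `tank`, `view`, `yellow_count`, `total_foreground`,
#'   `yellow_fraction`, `sdd` (`NA` when fewer than 2 yellow pixels).
#' @export
quantify <- function(image, range, fish_id = image$image_id,
                     treatment = NA_character_, tank = NA_character_,
                     sdd_method = c("centroid", "pairwise"),
                     sdd_distance = c("euclidean", "manhattan")) {
  ym <- yellow_mask(image, range)
  total <- sum(image$mask)
  count <- sum(ym)
  sdd <- if (count >= 2L)
    compute_sdd(mask_coords(ym), method = match.arg(sdd_method),
                distance = match.arg(sdd_distance))
  else NA_real_
  data.frame(image_id = image$image_id, fish_id = fish_id,
             treatment = as.character(treatment), tank = as.character(tank),
             view = image$view, yellow_count = count,
             total_foreground = total, yellow_fraction = count / total,
             sdd = sdd, stringsAsFactors = FALSE)
}
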