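#' Construct a masked image
#'
#' The basic unit of quantification: an 8-bit RGB pixel array together with
#' a logical fish-foreground mask. All downstream operations (yellow-pixel
#' counting, SDD, overlays, mean images) run on this structure. Coordinates
#' are row-major with the origin at the top-left pixel.
#'
#' @param pixels integer array `H x W x 3` with channel values in `[0, 255]`
#'   (order R, G, B).
#' @param mask logical matrix `H x W`; `TRUE` marks fish foreground. Must
#'   contain at least one `TRUE` entry.
#' @param view `"lateral"` or `"frontal"`.
#' @param image_id identifier string used in records and diagnostics.
#' @return An object of class `masked_image`.
#' @export
masked_image <- function(pixels, mask, view = c("lateral", "frontal"),
                         image_id = "img") {
  view <- match.arg(view)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (!is.matrix(mask) || !identical(dim(mask), dim(pixels)[1:2]))
    stop("`mask` dimensions must match `pixels` [", image_id, "]")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("channel values must be integers in [0, 255]")
  mask <- mask & !is.na(mask)
  if (!any(mask))
    stop("empty foreground: image rejected [", image_id, "]")
  structure(list(pixels = pixels, mask = mask, view = view,
                 image_id = image_id),
            class = "masked_image")
}

#' @export
print.masked_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<masked_image '%s' (%s): %d x %d px, %d foreground>\n",
              x$image_id, x$view, d[1], d[2], sum(x$mask)))
  invisible(x)
}

# read an image file into an 8-bit integer array (H x W x C)
read_image_array <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("JPEG support requires the 'jpeg' package; convert to PNG/TIFF")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, " (", path, ")")
  )
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  arr <- round_half_up(a * 255)
  storage.mode(arr) <- "integer"
  arr
}

#' Load an image and establish the fish-foreground mask
#'
#' Replaces manual background elimination with a deterministic machine
#' policy. Three policies are supported: `"alpha"` (foreground where the
#' alpha channel is positive), `"chroma_key"` (foreground where the
#' Chebyshev distance of a pixel from the key colour exceeds `tolerance`)
#' and `"mask"` (an external single-channel PNG, nonzero = foreground).
#'
#' @param path path to an 8-bit PNG, TIFF or JPEG image.
#' @param background background-removal policy; one of `"alpha"`,
#'   `"chroma_key"`, `"mask"`.
#' @param key_color RGB triple of the chroma-key colour (0-255 integers);
#'   required for `background = "chroma_key"`.
#' @param tolerance Chebyshev (max per-channel absolute difference)
#'   tolerance for the chroma key; pixels within `tolerance` of
#'   `key_color` on every channel are background. Default 10.
#' @param mask_path path to the external mask image for
#'   `background = "mask"`; dimensions must match the image.
#' @inheritParams masked_image
#' @return A [masked_image()]. An image whose policy yields an empty
#'   foreground is rejected with an error naming the file.
#' @export
load_image <- function(path, background = c("alpha", "chroma_key", "mask"),
                       key_color = NULL, tolerance = 10, mask_path = NULL,
                       view = c("lateral", "frontal"),
                       image_id = basename(path)) {
  background <- match.arg(background)
  arr <- read_image_array(path)
  nc <- dim(arr)[3]
  if (nc < 3L) stop("image must have at least 3 channels: ", path)
  px <- arr[, , 1:3, drop = FALSE]
  mask <- switch(background,
    alpha = {
      if (nc < 4L) stop("policy 'alpha' needs an alpha channel: ", path)
      arr[, , 4] > 0L
    },
    chroma_key = {
      if (is.null(key_color) || length(key_color) != 3L)
        stop("policy 'chroma_key' needs `key_color` (RGB triple)")
      cheb <- pmax(abs(px[, , 1] - key_color[1]),
                   abs(px[, , 2] - key_color[2]),
                   abs(px[, , 3] - key_color[3]))
      cheb > tolerance
    },
    mask = {
      if (is.null(mask_path)) stop("policy 'mask' needs `mask_path`")
      m <- read_image_array(mask_path)
      if (!identical(dim(m)[1:2], dim(px)[1:2]))
        stop("mask dimensions do not match image: ", mask_path)
      m[, , 1] > 0L
    }
  )
  masked_image(px, mask, view = match.arg(view), image_id = image_id)
}

#' Write an RGB array or masked image to PNG
#'
#' @param x a `masked_image` or an `H x W x 3` array of 0-255 values.
#' @param path output PNG path.
#' @export
write_image <- function(x, path) {
  if (inherits(x, "masked_image")) x <- x$pixels
  png::writePNG(x / 255, path)
  invisible(path)
}

#' Reference sRGB values for the 24-patch ColorChecker chart
#'
#' The standard published sRGB coordinates of the classic 24-patch colour
#' calibration chart, shipped as a plain-text fixture. Used as the target
#' of [fit_calibration()].
#'
#' @return data.frame with columns `patch_index`, `name`, `R`, `G`, `B`.
#' @export
colorchecker_reference <- function() {
  read.csv(system.file("extdata", "colorchecker24_srgb.csv",
                       package = "yellowpix"))
}

#' Fit an affine colour calibration from a photographed chart
#'
#' Ordinary least squares fit of an affine RGB transform (3x3 matrix plus
#' offset) mapping the 24 measured chart patches onto their reference
#' values, i.e. minimizing the summed squared RGB error over the 24
#' patch pairs.
#'
#' @param measured 24 x 3 matrix (or data.frame with columns R, G, B) of
#'   mean RGB values sampled from the photographed chart, index-aligned
#'   with `reference`.
#' @param reference 24 x 3 matrix of reference RGB values; defaults to
#'   [colorchecker_reference()].
#' @return An object of class `color_calibration`: list with `matrix`
#'   (3x3), `offset` (length 3) and `rmse` (root mean squared residual
#'   over all 72 channel values).
#' @export
fit_calibration <- function(measured, reference = colorchecker_reference()) {
  as_rgb_mat <- function(x) {
    if (is.data.frame(x)) x <- as.matrix(x[, c("R", "G", "B")])
    storage.mode(x) <- "double"
    x
  }
  X <- as_rgb_mat(measured)
  Y <- as_rgb_mat(reference)
  if (nrow(X) != nrow(Y) || ncol(X) != 3L)
    stop("measured and reference must be index-aligned n x 3 tables")
  if (nrow(X) < 4L) stop("at least 4 patch pairs required")
  D <- cbind(1, X)
  qrD <- qr(D)
  if (qrD$rank < 4L)
    stop("rank-deficient calibration design (degenerate measured patches)")
  B <- qr.coef(qrD, Y)                       # 4 x 3: offset row + matrix
  fitted <- D %*% B
  rmse <- sqrt(mean((Y - fitted)^2))
  M <- t(B[-1, , drop = FALSE])
  dimnames(M) <- NULL
  structure(list(matrix = M, offset = as.numeric(B[1, ]),
                 rmse = rmse),
            class = "color_calibration")
}

#' @export
print.color_calibration <- function(x, ...) {
  cat("<color_calibration> affine RGB transform, RMSE =",
      format(x$rmse, digits = 4), "\n")
  invisible(x)
}

#' Apply a colour calibration to a masked image
#'
#' Maps every pixel through the affine transform, rounds half-up and
#' clamps to `[0, 255]`. The mask is untouched.
#'
#' @param image a [masked_image()].
#' @param calibration a `color_calibration` from [fit_calibration()].
#' @return the calibrated `masked_image`.
#' @export
apply_calibration <- function(image, calibration) {
  stopifnot(inherits(image, "masked_image"),
            inherits(calibration, "color_calibration"))
  d <- dim(image$pixels)
  v <- matrix(as.numeric(image$pixels), ncol = 3L)   # (H*W) x 3
  out <- v %*% t(calibration$matrix)
  out <- sweep(out, 2L, calibration$offset, "+")
  out <- clamp8(round_half_up(out))
  px <- array(as.integer(out), d)
  masked_image(px, image$mask, view = image$view, image_id = image$image_id)
}
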