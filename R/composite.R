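#' Re-plot yellow pixels in a contrasting colour
#'
#' Returns a copy of the image in which every yellow-mask pixel is set to
#' the overlay colour (magenta by default) to increase contrast. Only
#' fish-foreground pixels are ever altered.
#'
#' @param image a [masked_image()].
#' @param yellow logical `H x W` mask (e.g. from [yellow_mask()]).
#' @param color RGB triple of the overlay colour; default magenta
#'   `(255, 0, 255)`.
#' @return a `masked_image` with the overlay applied.
#' @export
overlay_yellow <- function(image, yellow, color = c(255L, 0L, 255L)) {
  stopifnot(inherits(image, "masked_image"))
  if (!identical(dim(yellow), dim(image$mask)))
    stop("yellow mask dimensions do not match image")
  sel <- yellow & image$mask
  px <- image$pixels
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[sel] <- as.integer(color[ch])
    px[, , ch] <- plane
  }
  masked_image(px, image$mask, view = image$view, image_id = image$image_id)
}

# fill background with a flat colour, return double H x W x 3 array
flatten_background <- function(image, fill = c(255, 255, 255)) {
  px <- array(as.numeric(image$pixels), dim(image$pixels))
  bg <- !image$mask
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[bg] <- fill[ch]
    px[, , ch] <- plane
  }
  px
}

# bilinear resize of an H x W x 3 double array (0-255) to (H2, W2)
resize_bilinear <- function(arr, H2, W2) {
  if (identical(dim(arr)[1:2], c(H2, W2))) return(arr)
  img <- EBImage::Image(aperm(arr / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = W2, h = H2, filter = "bilinear")
  aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
}

#' Per-treatment mean image
#'
#' Averages a set of images of the same view: each image has its
#' background filled with a flat colour, is resized (bilinear) to a common
#' canvas, and the per-pixel per-channel arithmetic mean is taken and
#' rounded to 8 bits. The default canvas is the per-view median height and
#' width of the inputs; there is no landmark registration (acquisition is
#' assumed geometrically standardized).
#'
#' @param images list of [masked_image()] objects, all the same view.
#'   Typically magenta overlays from [overlay_yellow()].
#' @param canvas `(H, W)` integer pair; default median dimensions.
#' @param fill background fill colour before averaging; default white.
#' @return integer `H x W x 3` array (0-255).
#' @export
mean_image <- function(images, canvas = NULL, fill = c(255, 255, 255)) {
  if (length(images) < 1L) stop("at least one image required")
  views <- vapply(images, function(x) x$view, "")
  if (length(unique(views)) != 1L)
    stop("all images must share the same view")
  dims <- vapply(images, function(x) dim(x$pixels)[1:2], integer(2))
  if (is.null(canvas))
    canvas <- c(round_half_up(stats::median(dims[1, ])),
                round_half_up(stats::median(dims[2, ])))
  acc <- array(0, c(canvas[1], canvas[2], 3))
  for (im in images)
    acc <- acc + resize_bilinear(flatten_background(im, fill),
                                 canvas[1], canvas[2])
  out <- clamp8(round_half_up(acc / length(images)))
  storage.mode(out) <- "integer"
  out
}
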