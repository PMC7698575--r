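# Independent naive/brute-force oracles used to validate the vectorized
# implementations, plus small fixture builders. Everything here is written
# deliberately as plain loops, separate from the code paths under test.

# count pixels inside an inclusive RGB box, foreground only, by triple loop
naive_count_yellow <- function(pixels, mask, lo, hi) {
  cnt <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j]) next
    ok <- TRUE
    for (ch in 1:3)
      if (pixels[i, j, ch] < lo[ch] || pixels[i, j, ch] > hi[ch]) ok <- FALSE
    if (ok) cnt <- cnt + 1L
  }
  cnt
}

# pairwise distance matrix by double loop
naive_dist <- function(X, metric) {
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- if (metric == "manhattan") sum(abs(X[i, ] - X[j, ]))
    else sqrt(sum((X[i, ] - X[j, ])^2))
  }
  d
}

# standard distance about the centroid, naive accumulation
naive_sdd_centroid <- function(coords) {
  rbar <- mean(coords[, 1]); cbar <- mean(coords[, 2])
  acc <- 0
  for (i in seq_len(nrow(coords)))
    acc <- acc + (coords[i, 1] - rbar)^2 + (coords[i, 2] - cbar)^2
  sqrt(acc / nrow(coords))
}

# population SD of all pairwise Euclidean distances, naive double loop
naive_sdd_pairwise <- function(coords) {
  n <- nrow(coords)
  ds <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ds <- c(ds, sqrt(sum((coords[i, ] - coords[j, ])^2)))
  sqrt(mean((ds - mean(ds))^2))
}

# affine least squares through the normal equations / pseudo-inverse
naive_affine_fit <- function(measured, reference) {
  D <- cbind(1, measured)
  B <- solve(t(D) %*% D) %*% t(D) %*% reference
  M <- t(B[-1, , drop = FALSE])
  dimnames(M) <- NULL
  list(matrix = M, offset = as.numeric(B[1, ]),
       rmse = sqrt(mean((reference - D %*% B)^2)))
}

# textbook one-way ANOVA F ratio
naive_anova_F <- function(values, groups) {
  g <- factor(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (lv in levels(g)) {
    v <- values[g == lv]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  dfb <- nlevels(g) - 1
  dfw <- length(values) - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

# build a masked_image from a matrix of hex-like RGB triples
tiny_image <- function(rgb_list, mask = NULL, view = "lateral",
                       image_id = "tiny") {
  H <- length(rgb_list); W <- length(rgb_list[[1]])
  px <- array(0L, c(H, W, 3))
  for (i in seq_len(H)) for (j in seq_len(W))
    px[i, j, ] <- as.integer(rgb_list[[i]][[j]])
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  masked_image(px, mask, view = view, image_id = image_id)
}

# uniform-colour masked image
flat_image <- function(H, W, rgb, mask = NULL, view = "lateral",
                       image_id = "flat") {
  px <- array(rep(as.integer(rgb), each = H * W), c(H, W, 3))
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  masked_image(px, mask, view = view, image_id = image_id)
}

# write a small RGBA png; alpha is a logical matrix (TRUE = opaque)
write_rgba_png <- function(path, rgb, alpha) {
  H <- nrow(alpha); W <- ncol(alpha)
  a <- array(0, c(H, W, 4))
  for (ch in 1:3) a[, , ch] <- rgb[ch] / 255
  a[, , 4] <- ifelse(alpha, 1, 0)
  png::writePNG(a, path)
  path
}

# (row, col) coordinates of TRUE cells, for feeding compute_sdd in tests
mask_coords_for_test <- function(m) {
  idx <- which(m); H <- nrow(m)
  cbind(row = (idx - 1L) %% H + 1L, col = (idx - 1L) %/% H + 1L)
}
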