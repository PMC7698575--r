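test_that("derive_color_range takes channel-wise extremes", {
  r <- derive_color_range(rbind(c(210, 140, 5), c(250, 255, 0),
                                c(205, 130, 15)))
  expect_equal(unname(r$lo), c(205, 130, 0))
  expect_equal(unname(r$hi), c(250, 255, 15))

  r2 <- derive_color_range(rbind(c(220, 200, 10), c(220, 200, 10)))
  expect_equal(unname(r2$lo), unname(r2$hi))

  expect_error(derive_color_range(rbind(c(1, 2, 3))), "at least 2")

  set.seed(5)
  box <- cbind(sample(205:255, 45, TRUE), sample(130:255, 45, TRUE),
               sample(0:15, 45, TRUE))
  r3 <- derive_color_range(box)
  # brute-force extremes over the drawn set, contained in the drawing box
  expect_equal(unname(r3$lo),
               c(min(box[, 1]), min(box[, 2]), min(box[, 3])))
  expect_equal(unname(r3$hi),
               c(max(box[, 1]), max(box[, 2]), max(box[, 3])))
  expect_true(all(r3$lo >= c(205, 130, 0)) && all(r3$hi <= c(255, 255, 15)))
})

test_that("perturb_range moves each bound by a share of its own value", {
  r <- color_range(c(205, 130, 0), c(255, 255, 15))
  ex <- perturb_range(r, 5, "expand")
  # 205*0.95 = 194.75 -> 194; 130*0.95 = 123.5 -> 123; 15*1.05 = 15.75 -> 16
  expect_equal(unname(ex$lo), c(194, 123, 0))
  expect_equal(unname(ex$hi), c(255, 255, 16))

  expect_equal(perturb_range(r, 0, "expand"), r)
  expect_equal(perturb_range(r, 0, "shrink"), r)

  sh <- perturb_range(color_range(c(0, 0, 0), c(255, 255, 255)), 5, "shrink")
  expect_equal(unname(sh$lo), c(0, 0, 0))      # zero is a fixed point

  expect_error(perturb_range(r, 60, "expand"), "50")
})

test_that("yellow_mask applies inclusive bounds gated by the fish mask", {
  paper <- yellow_reference_range()
  img <- tiny_image(list(list(c(210, 140, 5), c(210, 140, 20)),
                         list(c(0, 0, 0), c(255, 255, 255))))
  ym <- yellow_mask(img, paper)
  expect_equal(sum(ym), 1L)
  expect_true(ym[1, 1])                         # B = 20 fails B <= 15

  # an in-range colour on a background pixel is never marked
  m <- matrix(TRUE, 2, 2); m[1, 1] <- FALSE
  img2 <- masked_image(img$pixels, m, view = "lateral")
  expect_equal(sum(yellow_mask(img2, paper)), 0L)

  # the universal range reproduces the fish mask
  full <- color_range(c(0, 0, 0), c(255, 255, 255))
  expect_identical(yellow_mask(img2, full), img2$mask)
})

test_that("quantify standardizes by foreground size", {
  # 100 foreground pixels, 25 in range
  px <- array(0L, c(10, 10, 3))
  px[1:5, 1:5, 1] <- 210L; px[1:5, 1:5, 2] <- 140L; px[1:5, 1:5, 3] <- 5L
  img <- masked_image(px, matrix(TRUE, 10, 10), view = "frontal")
  q <- quantify(img, yellow_reference_range())
  expect_equal(q$yellow_count, 25L)
  expect_equal(q$total_foreground, 100L)
  expect_equal(q$yellow_fraction, 0.25)

  # zero yellow pixels: count 0, fraction 0, SDD undefined (NA, never 0)
  q0 <- quantify(flat_image(4, 4, c(10, 10, 10)), yellow_reference_range())
  expect_equal(q0$yellow_count, 0L)
  expect_equal(q0$yellow_fraction, 0)
  expect_true(is.na(q0$sdd))

  # constructed 7x7 in-range patch on an out-of-range body
  px2 <- array(80L, c(50, 50, 3))
  px2[20:26, 30:36, 1] <- 230L
  px2[20:26, 30:36, 2] <- 200L
  px2[20:26, 30:36, 3] <- 10L
  img2 <- masked_image(px2, matrix(TRUE, 50, 50), view = "lateral")
  expect_equal(quantify(img2, yellow_reference_range())$yellow_count, 49L)
})

test_that("SDD matches hand values and the naive oracles", {
  expect_equal(compute_sdd(rbind(c(0, 0), c(0, 2)), "centroid"), 1.0)
  expect_equal(compute_sdd(matrix(5, 10, 2), "centroid"), 0)
  expect_equal(compute_sdd(matrix(5, 10, 2), "pairwise"), 0)
  # a single pair has one distance: population SD over the multiset is 0
  expect_equal(compute_sdd(rbind(c(0, 0), c(0, 2)), "pairwise"), 0)
  expect_true(is.na(compute_sdd(rbind(c(1, 1)))))
  expect_true(is.na(compute_sdd(matrix(0, 0, 2))))

  set.seed(9)
  pts <- cbind(sample(0:99, 200, TRUE), sample(0:99, 200, TRUE))
  expect_equal(compute_sdd(pts, "centroid"), naive_sdd_centroid(pts),
               tolerance = 1e-12)
  small <- pts[1:40, ]
  expect_equal(compute_sdd(small, "pairwise"), naive_sdd_pairwise(small),
               tolerance = 1e-12)
})

test_that("SDD is translation invariant and scales with the coordinates", {
  set.seed(13)
  for (k in 1:5) {
    pts <- matrix(rnorm(60, 50, 12), ncol = 2)
    base <- compute_sdd(pts, "centroid")
    expect_equal(compute_sdd(pts + 17.3, "centroid"), base,
                 tolerance = 1e-10)
    expect_equal(compute_sdd(pts * 3, "centroid"), 3 * base,
                 tolerance = 1e-10)
    pw <- compute_sdd(pts, "pairwise")
    expect_equal(compute_sdd(pts + 5, "pairwise"), pw, tolerance = 1e-10)
  }
})

test_that("yellow counts grow monotonically under range expansion", {
  set.seed(21)
  for (k in 1:10) {
    px <- array(sample(0:255, 12 * 12 * 3, TRUE), c(12, 12, 3))
    img <- masked_image(px, matrix(sample(c(TRUE, FALSE), 144, TRUE,
                                          c(0.8, 0.2)), 12, 12),
                        view = "frontal")
    lo <- sample(0:200, 3); hi <- lo + sample(20:55, 3)
    inner <- color_range(lo, hi)
    outer <- color_range(pmax(lo - 10, 0), pmin(hi + 10, 255))
    expect_lte(sum(yellow_mask(img, inner)), sum(yellow_mask(img, outer)))
  }
})

test_that("quantify is deterministic for identical inputs", {
  set.seed(31)
  px <- array(sample(0:255, 300, TRUE), c(10, 10, 3))
  img <- masked_image(px, matrix(TRUE, 10, 10), view = "lateral")
  expect_identical(quantify(img, yellow_reference_range()),
                   quantify(img, yellow_reference_range()))
})
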