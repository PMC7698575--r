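# small canvases keep the generator tests fast; geometry scales with size

test_that("fish canvases are deterministic, plausible and out of range", {
  a <- make_fish_canvas("lateral", c(96, 96), seed = 5)
  b <- make_fish_canvas("lateral", c(96, 96), seed = 5)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$mask, b$mask)

  n_fg <- sum(a$mask)
  expect_gt(n_fg, 0)
  expect_lt(n_fg, 96 * 96)

  # with zero noise every body pixel sits outside the yellow box
  flat <- make_fish_canvas("frontal", c(96, 96), noise_sd = 0, seed = 6)
  expect_equal(sum(yellow_mask(flat, yellow_reference_range())), 0L)

  expect_error(make_fish_canvas("lateral", c(32, 32)), "64")
})

test_that("painted patches hit the requested area exactly", {
  cv <- make_fish_canvas("lateral", c(128, 128), noise_sd = 0, seed = 7)
  n_fg <- sum(cv$mask)

  z <- paint_yellow_patches(cv, 0, seed = 8)
  expect_equal(z$truth$count, 0L)
  expect_equal(quantify(z$image, yellow_reference_range())$yellow_count, 0L)

  p <- paint_yellow_patches(cv, 0.10, n_patches = 3, dispersion = 10,
                            seed = 9)
  expect_equal(p$truth$count, round(0.10 * n_fg))
  # pipeline count equals ground truth exactly at zero noise
  q <- quantify(p$image, yellow_reference_range())
  expect_equal(q$yellow_count, p$truth$count)
  # and within 2% of the requested fraction
  expect_lt(abs(q$yellow_fraction - 0.10), 0.002)

  expect_error(paint_yellow_patches(cv, 1e-6, n_patches = 5),
               "infeasible")
})

test_that("doubling the dispersion spreads the yellow pixels out", {
  # the frontal anchors sit well inside the silhouette, so the centre
  # jitter has room to act; lateral anchors hug the boundary and the
  # mask truncates large jitters there
  cv <- make_fish_canvas("frontal", c(128, 128), noise_sd = 0, seed = 10)
  sdd_at <- function(disp, seed) {
    p <- paint_yellow_patches(cv, 0.06, n_patches = 3, dispersion = disp,
                              seed = seed)
    compute_sdd(mask_coords_for_test(yellow_mask(p$image,
                                                 yellow_reference_range())))
  }
  lo <- vapply(1:20, function(s) sdd_at(4, 100 + s), 0)
  hi <- vapply(1:20, function(s) sdd_at(8, 100 + s), 0)
  expect_gt(median(hi), median(lo))
})

test_that("a small study is reproducible and structured as designed", {
  des <- study_design(treatments = diet_carotenoids()[c(1, 5, 9), ],
                      tanks_per_treatment = 2, fish_per_tank = 3,
                      image_size = list(lateral = c(96, 96),
                                        frontal = c(96, 96)))
  s1 <- simulate_study(des, seed = 11)
  s2 <- simulate_study(des, seed = 11)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$fish, s2$fish)

  expect_equal(nrow(s1$fish), 3 * 2 * 3)
  expect_equal(nrow(s1$records), 3 * 2 * 3 * 2)   # two views per fish
  expect_setequal(unique(s1$records$view), c("frontal", "lateral"))
})

test_that("zero noise terms give identical fractions within a treatment", {
  des <- study_design(treatments = data.frame(treatment = "T1",
                                              carotenoid = 100),
                      tanks_per_treatment = 2, fish_per_tank = 3,
                      image_size = list(lateral = c(96, 96),
                                        frontal = c(96, 96)))
  s <- simulate_study(des, dose = dose_response(sd_individual = 0,
                                                sd_tank = 0), seed = 12)
  fr <- s$truth$target_fraction[s$truth$view == "frontal"]
  expect_true(all(abs(fr - fr[1]) < 1e-12))
})

test_that("measured fractions track the generating fractions", {
  des <- study_design(treatments = diet_carotenoids()[c(2, 5, 9), ],
                      tanks_per_treatment = 2, fish_per_tank = 4,
                      image_size = list(lateral = c(96, 96),
                                        frontal = c(96, 96)))
  s <- simulate_study(des, seed = 13)
  m <- merge(s$records, s$truth[, c("image_id", "target_fraction")],
             by = "image_id")
  m <- m[m$target_fraction > 0.005, ]
  slope <- coef(lm(yellow_fraction ~ target_fraction, data = m))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("treatment ranks of measured yellow recover the carotenoid ranks", {
  # distinguishable doses: several default diets share (or nearly share) a
  # concentration, so exact rank recovery is only a meaningful property
  # when the dose gaps exceed the per-treatment sampling error
  des <- study_design(treatments = data.frame(
                        treatment = c("lo", "mid", "hi", "vhi", "alga"),
                        carotenoid = c(2, 10, 30, 80, 234.2)),
                      tanks_per_treatment = 2, fish_per_tank = 10,
                      image_size = list(lateral = c(96, 96),
                                        frontal = c(96, 96)))
  s <- simulate_study(des, seed = 14)
  fe <- fish_feature_table(s$records)
  mf <- tapply(fe$frontal_fraction, fe$treatment, mean)
  caro <- setNames(des$treatments$carotenoid,
                   des$treatments$treatment)[names(mf)]
  expect_equal(cor(mf, caro, method = "spearman"), 1)

  # on the default diet table the microalgae treatment always tops the list
  des2 <- study_design(tanks_per_treatment = 2, fish_per_tank = 10,
                       image_size = list(lateral = c(96, 96),
                                         frontal = c(96, 96)))
  fe2 <- fish_feature_table(simulate_study(des2, seed = 15)$records)
  mf2 <- tapply(fe2$frontal_fraction, fe2$treatment, mean)
  expect_equal(names(which.max(mf2)), "MA10")
})

test_that("generate_study writes images, tables and a manifest", {
  out <- file.path(tempdir(), "yp_study")
  unlink(out, recursive = TRUE)
  des <- study_design(treatments = diet_carotenoids()[c(1, 9), ],
                      tanks_per_treatment = 1, fish_per_tank = 2,
                      image_size = list(lateral = c(96, 96),
                                        frontal = c(96, 96)))
  res <- generate_study(des, seed = 15, out_dir = out)
  expect_equal(length(list.files(file.path(out, "images"))), 2 * 2 * 2)
  design <- read.csv(file.path(out, "design.csv"))
  expect_equal(nrow(design), 8)
  expect_true(file.exists(file.path(out, "ground_truth.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))

  # written images reload to the same quantification
  row <- design[design$view == "frontal", ][1, ]
  img <- load_image(file.path(out, row$path), background = "chroma_key",
                    key_color = c(255, 255, 255), tolerance = 0,
                    view = "frontal")
  q <- quantify(img, yellow_reference_range())
  rec <- res$records[res$records$image_id == row$image_id &
                     res$records$view == "frontal", ]
  expect_equal(q$yellow_count, rec$yellow_count)
})
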