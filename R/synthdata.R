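#' Dietary treatments and total carotenoid concentrations
#'
#' The nine fishmeal-free test diets and their measured total carotenoid
#' concentrations (mg per kg dry weight): a vegetable control (CV),
#' graded insect-meal substitutions (H10, H20, H40), poultry by-product
#' meal (P20, P40), a combination (H10P30), red swamp crayfish meal
#' (RC10) and a marine microalgae blend (MA10).
#'
#' @return data.frame with columns `treatment`, `carotenoid`.
#' @export
diet_carotenoids <- function() {
  data.frame(
    treatment = c("CV", "H10", "H20", "H40", "P20", "P40",
                  "H10P30", "RC10", "MA10"),
    carotenoid = c(4.6, 3.5, 3.5, 3.5, 3.3, 2.4, 2.7, 5.4, 234.2),
    stringsAsFactors = FALSE)
}

#' Growth-trait presets per treatment
#'
#' Treatment-level means and standard deviations of total length (cm) and
#' final weight (g) used as the default generating model for synthetic
#' fish.
#'
#' @return data.frame with columns `treatment`, `tl_mean`, `tl_sd`,
#'   `w_mean`, `w_sd`.
#' @export
growth_presets <- function() {
  data.frame(
    treatment = c("CV", "H10", "H20", "H40", "P20", "P40",
                  "H10P30", "RC10", "MA10"),
    tl_mean = c(21.7, 22.5, 23.0, 23.3, 22.9, 23.0, 22.0, 22.3, 22.2),
    tl_sd   = c(1.0, 1.0, 0.8, 1.0, 0.9, 0.8, 0.8, 0.8, 0.8),
    w_mean  = c(177.7, 186.8, 187.5, 192.2, 191.6, 192.3, 190.7, 180.5, 166.9),
    w_sd    = c(22.4, 26.9, 22.0, 22.2, 24.3, 23.2, 21.6, 23.9, 19.8),
    stringsAsFactors = FALSE)
}

#' Study design for a synthetic pigmentation trial
#'
#' Describes the factorial layout the generator emulates: dietary
#' treatments with their carotenoid concentrations, replicate tanks per
#' treatment, fish per tank, and the image size of the two photographic
#' views. The default reproduces the source trial's geometry: 9
#' treatments x 3 tanks x 18 fish, two views per fish (486 fish, 972
#' images).
#'
#' @param treatments data.frame with columns `treatment`, `carotenoid`
#'   (mg per kg dry weight); default [diet_carotenoids()].
#' @param tanks_per_treatment replicate tanks per treatment (default 3).
#' @param fish_per_tank fish per tank (default 18).
#' @param image_size named list of `(H, W)` per view (default 256 x 256
#'   for both views).
#' @return object of class `study_design`.
#' @export
study_design <- function(treatments = diet_carotenoids(),
                         tanks_per_treatment = 3L, fish_per_tank = 18L,
                         image_size = list(lateral = c(256L, 256L),
                                           frontal = c(256L, 256L))) {
  stopifnot(all(c("treatment", "carotenoid") %in% names(treatments)),
            all(treatments$carotenoid >= 0),
            tanks_per_treatment >= 1L, fish_per_tank >= 1L)
  structure(list(treatments = treatments,
                 tanks_per_treatment = as.integer(tanks_per_treatment),
                 fish_per_tank = as.integer(fish_per_tank),
                 image_size = image_size),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d treatments x %d tanks x %d fish (2 views)\n",
              nrow(x$treatments), x$tanks_per_treatment, x$fish_per_tank))
  invisible(x)
}

#' Dose-response and noise model for synthetic pigmentation
#'
#' Maps dietary carotenoid concentration `C` to the expected yellow area
#' fraction of the fish foreground through a saturating curve
#' `f(C) = fmax * C / (C + K)`: low-carotenoid vegetable-type diets give
#' small fractions and the microalgae-type diet approaches `fmax`. The
#' lateral view carries `lateral_scale` times the frontal fraction
#' (lateral yellow areas are small relative to the forefront patch).
#' Per-tank shared intercepts and per-fish noise are added on the
#' fraction scale.
#'
#' @param fmax asymptotic frontal area fraction (default 0.17).
#' @param K half-saturation carotenoid concentration, mg/kg (default 50).
#' @param lateral_scale lateral-to-frontal fraction ratio (default 0.10).
#' @param sd_individual per-fish SD of the frontal area fraction
#'   (default 0.010); the lateral SD is scaled by `lateral_scale`.
#' @param sd_tank SD of the shared per-tank intercept (default 0: the
#'   emulated trial found no replicate effect on yellow-pixel counts, and
#'   any detectable tank variance would contradict that structure; set a
#'   positive value to study tank confounding).
#' @return object of class `dose_response`.
#' @export
dose_response <- function(fmax = 0.17, K = 50, lateral_scale = 0.10,
                          sd_individual = 0.010, sd_tank = 0) {
  structure(list(fmax = fmax, K = K, lateral_scale = lateral_scale,
                 sd_individual = sd_individual, sd_tank = sd_tank),
            class = "dose_response")
}

expected_fraction <- function(dose, carotenoid, view) {
  f <- dose$fmax * carotenoid / (carotenoid + dose$K)
  if (view == "lateral") f * dose$lateral_scale else f
}

#' Patch layout per view
#'
#' Number of yellow patches and the dispersion (SD, in pixels) of patch
#' centres about their anchor sites. Defaults emulate the observed
#' pattern: a concentrated between-the-eyes patch pair on the frontal
#' view, and two-to-three scattered patches (operculum, pectoral fin,
#' belly) on the lateral view.
#'
#' @param frontal,lateral lists with elements `n` (patch count) and
#'   `dispersion` (pixels).
#' @return list of per-view patch settings.
#' @export
patch_layout <- function(frontal = list(n = 2L, dispersion = 8),
                         lateral = list(n = 3L, dispersion = 20)) {
  list(frontal = frontal, lateral = lateral)
}

# silhouette geometry (mask, body tone base, anchor sites), cached per
# (view, H, W) — identical for every image of a view
fish_geometry <- function(view, size) {
  key <- paste(view, size[1], size[2], sep = "x")
  if (!is.null(.yp_cache[[key]])) return(.yp_cache[[key]])
  H <- size[1]; W <- size[2]
  if (H < 64L || W < 64L) stop("degenerate canvas: minimum size is 64 x 64")
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  if (view == "lateral") {
    cy <- 0.50 * H; cx <- 0.58 * W
    body <- ((cc - cx) / (0.30 * W))^2 + ((rr - cy) / (0.20 * H))^2 <= 1
    tail <- cc >= 0.08 * W & cc <= 0.30 * W &
      abs(rr - cy) <= 0.14 * H * (0.30 * W - cc) / (0.22 * W)
    mask <- body | tail
    anchors <- rbind(c(0.50 * H, 0.80 * W),   # operculum
                     c(0.62 * H, 0.66 * W),   # pectoral fin
                     c(0.68 * H, 0.50 * W))   # belly
  } else {
    cy <- 0.50 * H; cx <- 0.50 * W
    mask <- ((cc - cx) / (0.22 * W))^2 + ((rr - cy) / (0.38 * H))^2 <= 1
    anchors <- rbind(c(0.34 * H, 0.50 * W),   # forefront, between the eyes
                     c(0.46 * H, 0.50 * W),
                     c(0.40 * H, 0.50 * W))
  }
  fg <- mask_coords(mask)
  geo <- list(mask = mask, coords = fg, n_fg = nrow(fg), anchors = anchors)
  .yp_cache[[key]] <- geo
  geo
}

#' Blank fish canvas for one view
#'
#' An elliptical fish silhouette (horizontal body ellipse plus a
#' triangular tail for the lateral view; a vertical ellipse for the
#' frontal view) filled with a gray-brown body tone — outside the yellow
#' colour box — plus clamped Gaussian channel noise. The mask is the
#' silhouette.
#'
#' @param view `"lateral"` or `"frontal"`.
#' @param size `(H, W)` integer pair, at least 64 x 64.
#' @param noise_sd per-channel Gaussian noise SD (default 5; 0 gives the
#'   flat body tone).
#' @param image_id identifier for the resulting image.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return a [masked_image()].
#' @export
make_fish_canvas <- function(view = c("lateral", "frontal"),
                             size = c(256L, 256L), noise_sd = 5,
                             image_id = "canvas", seed = NULL) {
  view <- match.arg(view)
  if (!is.null(seed)) set.seed(seed)
  geo <- fish_geometry(view, size)
  H <- size[1]; W <- size[2]
  base <- c(150, 140, 120)                       # gray-brown, outside the box
  px <- array(255L, c(H, W, 3))                  # white background
  n <- geo$n_fg
  for (ch in 1:3) {
    vals <- base[ch] + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    plane <- px[, , ch]
    plane[geo$coords] <- clamp8(round_half_up(vals))
    px[, , ch] <- plane
  }
  storage.mode(px) <- "integer"
  masked_image(px, geo$mask, view = view, image_id = image_id)
}

#' Paint yellow patches onto a fish canvas
#'
#' Places disk-shaped yellow patches around view-specific anchor sites
#' (operculum, pectoral fin and belly for the lateral view; the
#' between-the-eyes forefront for the frontal view). Patch centres are
#' jittered about the anchors with the stated dispersion; exactly
#' `round(area_fraction * foreground)` pixels are painted (the nearest
#' foreground pixels to the jittered centres), each with a colour drawn
#' uniformly from the yellow reference box — so the ground-truth
#' in-range count is exact by construction.
#'
#' @param canvas a [masked_image()] from [make_fish_canvas()].
#' @param area_fraction target yellow fraction of the foreground, in
#'   `[0, 1]`.
#' @param n_patches number of patches.
#' @param dispersion SD (pixels) of the patch-centre jitter.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with `image` (the painted [masked_image()]) and `truth`
#'   (list: `count`, `centers`, `dispersion`).
#' @export
paint_yellow_patches <- function(canvas, area_fraction, n_patches = 3L,
                                 dispersion = 15, seed = NULL) {
  stopifnot(inherits(canvas, "masked_image"),
            area_fraction >= 0, area_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  geo <- fish_geometry(canvas$view, dim(canvas$mask))
  n_fg <- geo$n_fg
  target <- round_half_up(area_fraction * n_fg)
  if (area_fraction > 0 && target < n_patches)
    stop("infeasible geometry: fewer target pixels than patches")
  if (target == 0)
    return(list(image = canvas,
                truth = list(count = 0L, centers = NULL,
                             dispersion = dispersion)))
  anchors <- geo$anchors[((seq_len(n_patches) - 1L) %% nrow(geo$anchors)) + 1L,
                         , drop = FALSE]
  centers <- anchors + matrix(rnorm(2L * n_patches, 0, dispersion),
                              ncol = 2L)
  # per-patch quotas filled from each patch's own Voronoi cell, so the
  # painted area stays split into n_patches disks whatever the jitter
  d2 <- matrix(0, n_fg, n_patches)
  for (k in seq_len(n_patches))
    d2[, k] <- (geo$coords[, 1] - centers[k, 1])^2 +
               (geo$coords[, 2] - centers[k, 2])^2
  nearest <- max.col(-d2, ties.method = "first")
  quota <- rep(target %/% n_patches, n_patches)
  if (target %% n_patches > 0)
    quota[seq_len(target %% n_patches)] <- quota[seq_len(target %% n_patches)] + 1L
  cells <- lapply(seq_len(n_patches), function(k) {
    members <- which(nearest == k)
    members[order(d2[members, k])]
  })
  take <- pmin(quota, lengths(cells))
  deficit <- target - sum(take)
  while (deficit > 0) {               # a tiny cell spills into the others
    spare <- which(lengths(cells) > take)
    add <- pmin(lengths(cells)[spare] - take[spare],
                ceiling(deficit / length(spare)))
    add <- pmin(add, deficit - c(0, cumsum(add))[seq_along(add)])
    take[spare] <- take[spare] + pmax(add, 0)
    deficit <- target - sum(take)
  }
  sel <- unlist(lapply(seq_len(n_patches),
                       function(k) cells[[k]][seq_len(take[k])]),
                use.names = FALSE)
  px <- canvas$pixels
  cols <- cbind(sample(205:255, target, replace = TRUE),
                sample(130:255, target, replace = TRUE),
                sample(0:15, target, replace = TRUE))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[geo$coords[sel, , drop = FALSE]] <- cols[, ch]
    px[, , ch] <- plane
  }
  img <- masked_image(px, canvas$mask, view = canvas$view,
                      image_id = canvas$image_id)
  list(image = img,
       truth = list(count = as.integer(target), centers = centers,
                    dispersion = dispersion))
}

#' Simulate a complete pigmentation study and quantify it
#'
#' The streaming workhorse behind the synthetic pipeline: generates every
#' fish of the design (tank intercepts, per-fish noise, growth traits,
#' two images per fish), quantifies each image with one or more colour
#' ranges as it is generated, records the ground truth, and discards the
#' pixels unless asked to keep or write them. Fully reproducible from
#' `seed`.
#'
#' @param design a [study_design()].
#' @param dose a [dose_response()].
#' @param growth growth presets data.frame (see [growth_presets()]);
#'   rows matched to `design$treatments$treatment`. Treatments without a
#'   preset fall back to TL 22 +/- 1 cm, W 185 +/- 23 g.
#' @param layout a [patch_layout()].
#' @param ranges named list of [color_range()] objects to quantify with;
#'   default `list(base = yellow_reference_range())`.
#' @param noise_sd body-tone channel noise SD (default 5).
#' @param sdd_method,sdd_distance passed to [quantify()].
#' @param seed integer seed for the whole study.
#' @param image_fun optional callback `function(image, truth, meta)`
#'   invoked on every generated image (e.g. to accumulate mean images or
#'   write overlays); must not consume random numbers if byte-identical
#'   reruns are required.
#' @param out_dir optional directory; when given, images are written as
#'   PNG under `out_dir/images/`.
#' @return list with `records` (one row per image x range; columns of
#'   [quantify()] plus `range_id`), `fish` (fish_id, treatment, tank,
#'   replicate, TL, W), `truth` (per image: true count/fraction,
#'   dispersion), and the echoed `seed`.
#' @export
simulate_study <- function(design = study_design(), dose = dose_response(),
                           growth = growth_presets(), layout = patch_layout(),
                           ranges = list(base = yellow_reference_range()),
                           noise_sd = 5,
                           sdd_method = "centroid",
                           sdd_distance = "euclidean",
                           seed = 1L, image_fun = NULL, out_dir = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(dose, "dose_response"))
  set.seed(seed)
  if (!is.null(out_dir))
    dir.create(file.path(out_dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
  views <- c("frontal", "lateral")
  rec <- list(); fi <- list(); tr <- list()
  for (ti in seq_len(nrow(design$treatments))) {
    treat <- design$treatments$treatment[ti]
    caro <- design$treatments$carotenoid[ti]
    gp <- growth[match(treat, growth$treatment), ]
    if (nrow(gp) == 0L || anyNA(gp))
      gp <- data.frame(tl_mean = 22, tl_sd = 1, w_mean = 185, w_sd = 23)
    for (tk in seq_len(design$tanks_per_treatment)) {
      tank <- sprintf("%s_t%d", treat, tk)
      u_tank <- rnorm(1, 0, dose$sd_tank)
      for (fs in seq_len(design$fish_per_tank)) {
        fish_id <- sprintf("%s_f%02d", tank, fs)
        TL <- max(1, rnorm(1, gp$tl_mean, gp$tl_sd))
        W <- max(1, rnorm(1, gp$w_mean, gp$w_sd))
        fi[[length(fi) + 1L]] <- data.frame(
          fish_id = fish_id, treatment = treat, tank = tank,
          replicate = tk, carotenoid = caro, TL = TL, W = W,
          stringsAsFactors = FALSE)
        for (vw in views) {
          scl <- if (vw == "lateral") dose$lateral_scale else 1
          frac <- expected_fraction(dose, caro, vw) + scl * u_tank +
            rnorm(1, 0, dose$sd_individual * scl)
          frac <- min(max(frac, 0), 0.5)
          image_id <- paste0(fish_id, "_", vw)
          canvas <- make_fish_canvas(vw, design$image_size[[vw]],
                                     noise_sd = noise_sd,
                                     image_id = image_id)
          lay <- layout[[vw]]
          # a fish with almost no yellow gets fewer (or no) patches
          tgt <- round_half_up(frac * fish_geometry(vw, dim(canvas$mask))$n_fg)
          n_p <- max(1L, min(lay$n, tgt))
          painted <- paint_yellow_patches(canvas, if (tgt == 0) 0 else frac,
                                          n_p, lay$dispersion)
          img <- painted$image
          for (rg in names(ranges)) {
            q <- quantify(img, ranges[[rg]], fish_id = fish_id,
                          treatment = treat, tank = tank,
                          sdd_method = sdd_method,
                          sdd_distance = sdd_distance)
            q$range_id <- rg
            rec[[length(rec) + 1L]] <- q
          }
          tr[[length(tr) + 1L]] <- data.frame(
            image_id = image_id, fish_id = fish_id, view = vw,
            true_count = painted$truth$count,
            true_fraction = painted$truth$count / sum(img$mask),
            target_fraction = frac,
            dispersion = painted$truth$dispersion,
            stringsAsFactors = FALSE)
          if (!is.null(out_dir))
            write_image(img, file.path(out_dir, "images",
                                       paste0(image_id, ".png")))
          if (!is.null(image_fun))
            image_fun(img, painted$truth,
                      list(fish_id = fish_id, treatment = treat,
                           tank = tank, view = vw))
        }
      }
    }
  }
  list(records = do.call(rbind, rec), fish = do.call(rbind, fi),
       truth = do.call(rbind, tr), seed = seed)
}

#' Generate a synthetic study to disk
#'
#' Convenience wrapper over [simulate_study()] that writes the study as
#' files: PNG images under `out_dir/images/`, `design.csv` (one row per
#' image with fish metadata and image path), `ground_truth.csv`, the
#' per-image quantification `records.csv`, and `manifest.json` echoing
#' the full parameterization and seed.
#'
#' @inheritParams simulate_study
#' @param out_dir output directory (created if needed).
#' @return invisibly, the [simulate_study()] result.
#' @export
generate_study <- function(design = study_design(), dose = dose_response(),
                           growth = growth_presets(),
                           layout = patch_layout(), noise_sd = 5,
                           seed = 1L, out_dir) {
  res <- simulate_study(design, dose, growth, layout,
                        noise_sd = noise_sd, seed = seed, out_dir = out_dir)
  per_image <- merge(res$truth[, c("image_id", "fish_id", "view")],
                     res$fish, by = "fish_id", sort = FALSE)
  per_image$path <- file.path("images", paste0(per_image$image_id, ".png"))
  write.csv(per_image, file.path(out_dir, "design.csv"), row.names = FALSE)
  write.csv(res$truth, file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
  write.csv(res$records, file.path(out_dir, "records.csv"), row.names = FALSE)
  manifest <- list(
    package = "yellowpix",
    version = as.character(utils::packageVersion("yellowpix")),
    seed = seed, noise_sd = noise_sd,
    design = list(treatments = design$treatments,
                  tanks_per_treatment = design$tanks_per_treatment,
                  fish_per_tank = design$fish_per_tank,
                  image_size = design$image_size),
    dose = unclass(dose), layout = layout)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
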