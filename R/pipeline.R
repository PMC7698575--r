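#' Per-fish feature table from image records
#'
#' Reshapes per-image pigmentation records into one row per fish with the
#' frontal and lateral measurements side by side — the feature table the
#' permutation tests run on (the standardized yellow fractions of the two
#' views). Fish missing a view are dropped with a warning.
#'
#' @param records data.frame of [quantify()] rows (a single `range_id`).
#' @return data.frame: `fish_id`, `treatment`, `tank`, `frontal_count`,
#'   `lateral_count`, `frontal_fraction`, `lateral_fraction`,
#'   `frontal_sdd`, `lateral_sdd`.
#' @export
fish_feature_table <- function(records) {
  if (!is.null(records$range_id) && length(unique(records$range_id)) > 1L)
    stop("records contain multiple range_ids; subset to one")
  agg <- function(v, f) tapply(v, f, mean)
  out <- NULL
  for (vw in c("frontal", "lateral")) {
    sub <- records[records$view == vw, ]
    t1 <- data.frame(fish_id = names(agg(sub$yellow_count, sub$fish_id)),
                     count = as.numeric(agg(sub$yellow_count, sub$fish_id)),
                     fraction = as.numeric(agg(sub$yellow_fraction,
                                               sub$fish_id)),
                     sdd = as.numeric(agg(sub$sdd, sub$fish_id)),
                     stringsAsFactors = FALSE)
    names(t1)[-1] <- paste0(vw, "_", names(t1)[-1])
    out <- if (is.null(out)) t1 else merge(out, t1, by = "fish_id")
  }
  meta <- unique(records[, c("fish_id", "treatment", "tank")])
  n_all <- length(unique(records$fish_id))
  if (nrow(out) < n_all)
    warning(n_all - nrow(out), " fish missing a view were dropped")
  merge(meta, out, by = "fish_id")
}

#' Treatment-level summary table
#'
#' Per-treatment means and standard deviations of growth traits and of
#' the lateral/frontal pigmentation measures (pixel counts, SDD and the
#' percentage of yellow pixels on the total foreground). Fish with
#' undefined SDD are excluded from the SDD columns only.
#'
#' @param features output of [fish_feature_table()].
#' @param fish data.frame with `fish_id`, `TL`, `W` (optional; growth
#'   columns are omitted when absent).
#' @return data.frame, one row per treatment.
#' @export
treatment_summary <- function(features, fish = NULL) {
  if (!is.null(fish))
    features <- merge(features, fish[, c("fish_id", "TL", "W")],
                      by = "fish_id")
  sp <- split(features, features$treatment)
  rows <- lapply(sp, function(d) {
    ms <- function(v) c(mean(v, na.rm = TRUE), sd(v, na.rm = TRUE))
    r <- data.frame(treatment = d$treatment[1], N = nrow(d))
    if (!is.null(d$TL)) {
      r$TL_mean <- ms(d$TL)[1]; r$TL_sd <- ms(d$TL)[2]
      r$W_mean <- ms(d$W)[1];  r$W_sd <- ms(d$W)[2]
    }
    for (vw in c("lateral", "frontal")) {
      cnt <- ms(d[[paste0(vw, "_count")]])
      sdd <- ms(d[[paste0(vw, "_sdd")]])
      pct <- ms(100 * d[[paste0(vw, "_fraction")]])
      r[[paste0(vw, "_pixels_mean")]] <- cnt[1]
      r[[paste0(vw, "_pixels_sd")]] <- cnt[2]
      r[[paste0(vw, "_sdd_mean")]] <- sdd[1]
      r[[paste0(vw, "_sdd_sd")]] <- sdd[2]
      r[[paste0(vw, "_pct_mean")]] <- pct[1]
      r[[paste0(vw, "_pct_sd")]] <- pct[2]
    }
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pigmentation statistics on a feature table
#'
#' The inferential block of the pipeline: two-way crossed ANOSIM
#' (treatment x replicate) on Manhattan distances over the per-fish
#' (frontal, lateral) yellow-fraction 2-vector; Bonferroni-corrected
#' pairwise ANOSIM among treatments; and a Mantel test (Spearman)
#' between the pigmentation distance matrix and Euclidean distances on
#' the per-fish dietary carotenoid concentration.
#'
#' @param features output of [fish_feature_table()] with a `replicate`
#'   column or tank labels of the form `<treatment>_t<k>`.
#' @param carotenoids data.frame `treatment`, `carotenoid`; default
#'   [diet_carotenoids()].
#' @param n_perm_anosim,n_perm_mantel permutation counts (999 / 9999).
#' @param seed integer seed for the permutation streams.
#' @param pairwise compute the pairwise ANOSIM table (default TRUE).
#' @return list with `anosim` (two-way result), `pairwise` (data.frame
#'   or NULL), `mantel` (mantel_result), and the echoed settings.
#' @export
pigmentation_stats <- function(features, carotenoids = diet_carotenoids(),
                               n_perm_anosim = 999, n_perm_mantel = 9999,
                               seed = 1L, pairwise = TRUE) {
  if (is.null(features$replicate))
    features$replicate <- sub(".*_t", "", features$tank)
  X <- as.matrix(features[, c("frontal_fraction", "lateral_fraction")])
  rownames(X) <- features$fish_id
  dm <- distance_matrix(X, metric = "manhattan")
  set.seed(seed)
  two <- anosim_twoway(dm, features$treatment, features$replicate,
                       n_perm = n_perm_anosim)
  pw <- if (pairwise)
    anosim_pairwise(dm, features$treatment, n_perm = n_perm_anosim)
  else NULL
  caro <- carotenoids$carotenoid[match(features$treatment,
                                       carotenoids$treatment)]
  if (anyNA(caro)) stop("missing carotenoid concentration for a treatment")
  dm_caro <- distance_matrix(matrix(caro, ncol = 1,
                                    dimnames = list(features$fish_id, NULL)),
                             metric = "euclidean")
  mt <- mantel_test(dm, dm_caro, method = "spearman",
                    n_perm = n_perm_mantel)
  list(anosim = two, pairwise = pw, mantel = mt,
       settings = list(seed = seed, n_perm_anosim = n_perm_anosim,
                       n_perm_mantel = n_perm_mantel,
                       anosim_metric = "manhattan",
                       mantel_metrics = c("manhattan", "euclidean")))
}

#' Compare treatment rankings across colour-range perturbations
#'
#' Ranks treatments by mean yellow fraction (per view) under each
#' `range_id` present in the records and reports whether every
#' perturbed ranking matches the base ranking — the sensitivity check
#' behind "the bounds were perturbed by +/-5% and the results did not
#' change".
#'
#' @param records multi-range records from [simulate_study()] (or rbind
#'   of per-range [quantify()] outputs with a `range_id` column).
#' @param base_id the reference `range_id` (default `"base"`).
#' @return list with `rankings` (data.frame: view, range_id, ranking
#'   string) and `unchanged` (logical).
#' @export
sensitivity_report <- function(records, base_id = "base") {
  stopifnot(!is.null(records$range_id))
  ids <- unique(records$range_id)
  rows <- list()
  for (vw in unique(records$view)) for (rg in ids) {
    sub <- records[records$view == vw & records$range_id == rg, ]
    mfrac <- sort(tapply(sub$yellow_fraction, sub$treatment, mean),
                  decreasing = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      view = vw, range_id = rg,
      ranking = paste(names(mfrac), collapse = " > "),
      stringsAsFactors = FALSE)
  }
  rk <- do.call(rbind, rows)
  base <- rk[rk$range_id == base_id, c("view", "ranking")]
  unchanged <- all(vapply(seq_len(nrow(rk)), function(k) {
    rk$ranking[k] == base$ranking[base$view == rk$view[k]]
  }, TRUE))
  list(rankings = rk, unchanged = unchanged)
}

pipeline_defaults <- function() {
  list(mode = "synthetic", seed = 1L,
       range = "reference",            # "reference", "derive", or 6 integers
       perturb_pct = 5, sensitivity = FALSE,
       sdd_method = "centroid", sdd_distance = "euclidean",
       n_perm_anosim = 999, n_perm_mantel = 9999, pairwise = TRUE,
       noise_sd = 5, write_images = FALSE, mean_images = TRUE,
       mean_on = "overlay",            # or "raw"
       # synthetic-mode design knobs
       tanks_per_treatment = 3L, fish_per_tank = 18L, image_height = 256L,
       image_width = 256L,
       # images-mode inputs
       image_dir = NULL, design_csv = NULL,
       background = "chroma_key", key_color = c(0L, 255L, 0L),
       tolerance = 10, calibration_csv = NULL)
}

resolve_range <- function(config, sim = NULL) {
  r <- config$range
  if (is.character(r) && r[1] == "reference") return(yellow_reference_range())
  if (is.numeric(r) && length(r) == 6L)
    return(color_range(r[c(1, 3, 5)], r[c(2, 4, 6)]))
  if (is.character(r) && r[1] == "derive") {
    if (is.null(sim)) stop("range 'derive' is only supported in synthetic mode")
    # sampling protocol: five pixels from the true yellow region of the
    # first three images per tank (the ground-truth region stands in for
    # the human annotator clicking yellow pixels)
    stop("derive mode requires derive_range_from_study(); see run_pipeline")
  }
  stop("unsupported range specification")
}

#' Derive the yellow range from a synthetic study
#'
#' Applies the range-derivation protocol to generated images: for each
#' tank, five pixels are sampled from the true yellow region of each of
#' the first three images (nine images per treatment), and the
#' channel-wise min/max over all samples defines the box. The
#' ground-truth yellow region stands in for the human annotator.
#'
#' @param design a [study_design()]; regenerated deterministically from
#'   `seed`, so must match the study being analysed.
#' @param dose,growth,layout,noise_sd,seed as in [simulate_study()].
#' @param n_images images per tank to sample from (default 3).
#' @param n_pixels pixels sampled per image (default 5).
#' @return a [color_range()].
#' @export
derive_range_from_study <- function(design = study_design(),
                                    dose = dose_response(),
                                    growth = growth_presets(),
                                    layout = patch_layout(), noise_sd = 5,
                                    seed = 1L, n_images = 3L, n_pixels = 5L) {
  samples <- list()
  counter <- new.env(parent = emptyenv())
  cb <- function(img, truth, meta) {
    key <- paste(meta$tank, meta$view)
    k <- if (is.null(counter[[key]])) 0L else counter[[key]]
    if (k < n_images && truth$count >= n_pixels) {
      ym <- yellow_mask(img, yellow_reference_range())
      co <- mask_coords(ym)
      take <- co[seq(1L, nrow(co), length.out = n_pixels), , drop = FALSE]
      rgb <- cbind(img$pixels[cbind(take, 1L)], img$pixels[cbind(take, 2L)],
                   img$pixels[cbind(take, 3L)])
      samples[[length(samples) + 1L]] <<- rgb
      counter[[key]] <- k + 1L
    }
  }
  simulate_study(design, dose, growth, layout, noise_sd = noise_sd,
                 seed = seed, image_fun = cb)
  derive_color_range(do.call(rbind, samples))
}

#' Run the end-to-end pigmentation pipeline
#'
#' Orchestrates a complete run from a single configuration: simulate (or
#' load) the images, fix or derive the yellow colour box, quantify every
#' image, build the treatment summary, run the permutation statistics
#' and the growth-trait ANOVAs, optionally produce overlays, mean images
#' and a +/- perturbation sensitivity report, and write every table plus
#' a manifest into the run directory. A run is a pure function of
#' (config, seed): rerunning with the same configuration produces
#' byte-identical CSV and JSON outputs.
#'
#' @param config a named list overriding the defaults, or a path to a
#'   YAML file with the same keys. Keys include `mode`
#'   (`"synthetic"` or `"images"`), `seed`, `range` (`"reference"`,
#'   `"derive"`, or six integers `R_lo,R_hi,G_lo,G_hi,B_lo,B_hi`),
#'   `sensitivity`, `perturb_pct`, `sdd_method`, `n_perm_anosim`,
#'   `n_perm_mantel`, `noise_sd`, `write_images`, `mean_images`,
#'   design sizes for synthetic mode, and `image_dir`/`design_csv`/
#'   `background`/`key_color`/`calibration_csv` for images mode.
#' @param output_dir run directory (created; overwritten files replaced).
#' @return invisibly, a list with `records`, `features`, `summary`,
#'   `stats`, `anova`, `sensitivity` (or NULL) and `output_dir`.
#' @export
run_pipeline <- function(config = list(), output_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(output_dir, "run.log")
  cat("yellowpix run, seed ", cfg$seed, "\n", file = logf)
  log_msg <- function(...) cat(..., "\n", file = logf, append = TRUE)

  design <- study_design(
    tanks_per_treatment = cfg$tanks_per_treatment,
    fish_per_tank = cfg$fish_per_tank,
    image_size = list(lateral = c(cfg$image_height, cfg$image_width),
                      frontal = c(cfg$image_height, cfg$image_width)))

  base_range <- if (identical(cfg$range, "derive")) {
    if (cfg$mode != "synthetic")
      stop("range 'derive' is implemented for synthetic mode")
    derive_range_from_study(design, noise_sd = cfg$noise_sd, seed = cfg$seed)
  } else resolve_range(cfg)
  ranges <- list(base = base_range)
  if (isTRUE(cfg$sensitivity)) {
    ranges$expand <- perturb_range(base_range, cfg$perturb_pct, "expand")
    ranges$shrink <- perturb_range(base_range, cfg$perturb_pct, "shrink")
  }

  # mean-image accumulators (per treatment x view), fed streaming
  acc <- new.env(parent = emptyenv())
  accumulate <- function(img, truth, meta) {
    if (!isTRUE(cfg$mean_images)) return(invisible())
    use <- if (identical(cfg$mean_on, "overlay"))
      overlay_yellow(img, yellow_mask(img, base_range))
    else img
    key <- paste0(meta$treatment, "_", meta$view)
    arr <- flatten_background(use)
    if (is.null(acc[[key]])) acc[[key]] <- list(sum = arr, n = 1L)
    else acc[[key]] <- list(sum = acc[[key]]$sum + arr,
                            n = acc[[key]]$n + 1L)
  }

  if (cfg$mode == "synthetic") {
    sim <- simulate_study(design, ranges = ranges,
                          noise_sd = cfg$noise_sd,
                          sdd_method = cfg$sdd_method,
                          sdd_distance = cfg$sdd_distance,
                          seed = cfg$seed, image_fun = accumulate,
                          out_dir = if (isTRUE(cfg$write_images)) output_dir
                                    else NULL)
    records <- sim$records
    fish <- sim$fish
    write.csv(sim$truth, file.path(output_dir, "ground_truth.csv"),
              row.names = FALSE)
  } else {
    inp <- read.csv(cfg$design_csv, stringsAsFactors = FALSE)
    cal <- if (!is.null(cfg$calibration_csv)) {
      meas <- read.csv(cfg$calibration_csv)
      fit_calibration(meas)
    } else NULL
    rec <- list()
    for (k in seq_len(nrow(inp))) {
      row <- inp[k, ]
      img <- tryCatch(
        load_image(file.path(cfg$image_dir, row$path),
                   background = cfg$background,
                   key_color = cfg$key_color, tolerance = cfg$tolerance,
                   view = row$view, image_id = row$image_id),
        error = function(e) {
          log_msg("DROPPED ", row$image_id, ": ", conditionMessage(e))
          NULL
        })
      if (is.null(img)) next
      if (!is.null(cal)) img <- apply_calibration(img, cal)
      accumulate(img, NULL, list(treatment = row$treatment, view = row$view))
      for (rg in names(ranges)) {
        q <- quantify(img, ranges[[rg]], fish_id = row$fish_id,
                      treatment = row$treatment, tank = row$tank,
                      sdd_method = cfg$sdd_method,
                      sdd_distance = cfg$sdd_distance)
        q$range_id <- rg
        rec[[length(rec) + 1L]] <- q
      }
    }
    records <- do.call(rbind, rec)
    fish <- unique(inp[, intersect(c("fish_id", "treatment", "tank",
                                     "replicate", "TL", "W"), names(inp))])
    cells <- table(records$treatment[records$range_id == names(ranges)[1]],
                   records$tank[records$range_id == names(ranges)[1]])
    if (any(cells[cells > 0] < 1)) stop("a design cell lost all images")
  }

  base_rec <- records[records$range_id == "base", ]
  n_nosdd <- sum(is.na(base_rec$sdd))
  if (n_nosdd > 0)
    log_msg(n_nosdd, " image(s) with undefined SDD (fewer than 2 yellow ",
            "pixels); retained for counts, dropped from SDD summaries")
  features <- fish_feature_table(base_rec)
  summary_tab <- treatment_summary(features, fish)

  stats <- pigmentation_stats(features, n_perm_anosim = cfg$n_perm_anosim,
                              n_perm_mantel = cfg$n_perm_mantel,
                              seed = cfg$seed, pairwise = isTRUE(cfg$pairwise))

  anova_res <- NULL
  if (!is.null(fish$TL)) {
    anova_res <- list(TL = anova_tukey(fish$TL, fish$treatment),
                      W = anova_tukey(fish$W, fish$treatment))
    atab <- rbind(cbind(trait = "TL", anova_res$TL$table),
                  cbind(trait = "W", anova_res$W$table))
    write.csv(atab, file.path(output_dir, "anova_letters.csv"),
              row.names = FALSE)
  }

  sens <- NULL
  if (isTRUE(cfg$sensitivity)) {
    sens <- sensitivity_report(records)
    write.csv(sens$rankings, file.path(output_dir, "sensitivity.csv"),
              row.names = FALSE)
  }

  write.csv(records, file.path(output_dir, "records.csv"), row.names = FALSE)
  write.csv(summary_tab, file.path(output_dir, "summary.csv"),
            row.names = FALSE)
  if (!is.null(stats$pairwise))
    write.csv(stats$pairwise, file.path(output_dir, "anosim_pairwise.csv"),
              row.names = FALSE)

  stats_json <- list(
    anosim_treatment = list(R = stats$anosim$a$R, p = stats$anosim$a$p,
                            n_perm = cfg$n_perm_anosim),
    anosim_replicate = list(R = stats$anosim$b$R, p = stats$anosim$b$p,
                            n_perm = cfg$n_perm_anosim),
    mantel = list(r = stats$mantel$r, p = stats$mantel$p,
                  n_perm = cfg$n_perm_mantel, method = stats$mantel$method),
    anova = if (!is.null(anova_res))
      list(TL = list(F = anova_res$TL$F, p = anova_res$TL$p),
           W = list(F = anova_res$W$F, p = anova_res$W$p)) else NULL,
    sensitivity_unchanged = if (!is.null(sens)) sens$unchanged else NULL,
    seed = cfg$seed)
  jsonlite::write_json(stats_json, file.path(output_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (isTRUE(cfg$mean_images)) {
    for (key in ls(acc)) {
      m <- clamp8(round_half_up(acc[[key]]$sum / acc[[key]]$n))
      storage.mode(m) <- "integer"
      write_image(m, file.path(output_dir, paste0(key, "_mean.png")))
    }
  }

  cfg_path <- file.path(output_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(package = "yellowpix",
                   version = as.character(utils::packageVersion("yellowpix")),
                   seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   range = list(lo = unname(base_range$lo),
                                hi = unname(base_range$hi)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(records = records, features = features,
                 summary = summary_tab, stats = stats, anova = anova_res,
                 sensitivity = sens, range = base_range,
                 output_dir = output_dir))
}
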