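#!/usr/bin/env Rscript
# Step 4 — diagnostic composites: magenta overlays and per-treatment mean
# images, on a reduced copy of the study (figures only; tables come from
# steps 2-3).

library(yellowpix)

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
rng <- yellow_reference_range()

design <- study_design(tanks_per_treatment = 1, fish_per_tank = 6,
                       image_size = list(lateral = c(128L, 128L),
                                         frontal = c(128L, 128L)))

acc <- new.env(parent = emptyenv())
first_overlay_done <- new.env(parent = emptyenv())
cb <- function(img, truth, meta) {
  ov <- overlay_yellow(img, yellow_mask(img, rng))
  key <- paste0(meta$treatment, "_", meta$view)
  arr <- yellowpix:::flatten_background(ov)
  if (is.null(acc[[key]])) acc[[key]] <- list(sum = arr, n = 1L)
  else acc[[key]] <- list(sum = acc[[key]]$sum + arr, n = acc[[key]]$n + 1L)
  if (is.null(first_overlay_done[[key]])) {
    write_image(ov, file.path("results/figures",
                              paste0(key, "_overlay_example.png")))
    first_overlay_done[[key]] <- TRUE
  }
}
invisible(simulate_study(design, seed = 1, image_fun = cb))

for (key in ls(acc)) {
  m <- acc[[key]]$sum / acc[[key]]$n
  m <- floor(m + 0.5); m[m > 255] <- 255
  storage.mode(m) <- "integer"
  write_image(m, file.path("results/figures", paste0(key, "_mean.png")))
}
cat("Wrote", length(list.files("results/figures")),
    "overlay and mean-image PNGs to results/figures\n")
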