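#' Simulation configuration
#'
#' Parameters of the synthetic pre/post thermal-imaging study. Defaults
#' emulate the real design: 12 horses, 6 riders (2 per L/M/H group), every
#' rider x horse combination imaged pre- and post-exercise (144 images), four
#' ROIs on the thoracolumbar region. Temperature effects are injected in
#' temperature space and only then rendered to pseudo-color, so conventional
#' and texture pipelines see one physically coherent signal.
#'
#' @param n_horses number of horses (default 12).
#' @param riders_per_group riders in each of L/M/H (default 2).
#' @param seed master seed; every downstream seed is derived from it by
#'   stable hashing, so subsets regenerate identically.
#' @param image_size c(rows, cols) of the images (default 120 x 160 px).
#' @param baseline_temp mean coat temperature, degC (default 30).
#' @param smooth_sd sd of the smooth anatomical component, degC (default 1.5).
#' @param corr_length correlation length (Gaussian kernel sd) of the smooth
#'   component, pixels (default 12).
#' @param noise_sd per-pixel measurement noise sd, degC (default 0.25).
#' @param exercise_warming uniform post-exercise warming, degC (default 1.5).
#' @param heterogeneity_sd named vector (L, M, H): sd (degC) of the extra
#'   post-exercise high-frequency noise added inside the muscle-rich ROIs
#'   (1, 3, 4); the group-dependent texture effect.
#' @param palette a [iron_palette()]-style palette spec.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_horses = 12, riders_per_group = 2, seed = 1,
                       image_size = c(120, 160),
                       baseline_temp = 30, smooth_sd = 1.5, corr_length = 12,
                       noise_sd = 0.25, exercise_warming = 1.5,
                       heterogeneity_sd = c(L = 0.5, M = 1.0, H = 1.5),
                       palette = iron_palette()) {
  stopifnot(all(heterogeneity_sd >= 0), length(image_size) == 2)
  structure(
    list(
      n_horses = n_horses, riders_per_group = riders_per_group, seed = seed,
      image_size = image_size, baseline_temp = baseline_temp,
      smooth_sd = smooth_sd, corr_length = corr_length, noise_sd = noise_sd,
      exercise_warming = exercise_warming,
      heterogeneity_sd = heterogeneity_sd, palette = palette
    ),
    class = "sim_config"
  )
}

# Stable 31-bit hash of a master seed plus a character key; keeps derived
# seeds reproducible across platforms and below 2^31.
derive_seed <- function(master, key) {
  h <- master %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Iron-like temperature palette
#'
#' A monotone 6-control-point palette over the camera working range
#' 10-50 degC, from black through blue/purple and orange to white. The red
#' channel is non-decreasing in temperature over the whole range, which is
#' what couples red-component texture to thermal heterogeneity.
#'
#' @return data.frame with columns `temp_c`, `r`, `g`, `b` (0..255).
#' @export
iron_palette <- function() {
  data.frame(
    temp_c = c(10, 18, 26, 34, 42, 50),
    r = c(0, 32, 128, 220, 255, 255),
    g = c(0, 0, 16, 80, 180, 255),
    b = c(0, 96, 128, 16, 32, 255)
  )
}

#' Render a temperature field as a pseudo-color image
#'
#' Per-pixel piecewise-linear interpolation of the palette control points,
#' rounded to integer 8-bit channels. Temperatures outside the palette range
#' are clamped with a warning.
#'
#' @param field numeric temperature matrix (degC).
#' @param palette palette spec (see [iron_palette()]).
#' @return a `pseudocolor_image`.
#' @export
render_pseudocolor <- function(field, palette = iron_palette()) {
  rng <- range(palette$temp_c)
  if (any(field < rng[1] | field > rng[2])) {
    warning("temperatures outside palette range were clamped")
    field <- pmin(pmax(field, rng[1]), rng[2])
  }
  chan <- function(col) {
    v <- stats::approx(palette$temp_c, palette[[col]], xout = as.vector(field))$y
    matrix(as.integer(round(v)), nrow(field), ncol(field))
  }
  pseudocolor_image(chan("r"), chan("g"), chan("b"))
}

#' Generate a synthetic cohort
#'
#' Horse bodyweights are drawn from the real cohort's moments
#' (normal(566.7, 13.7) kg, truncated to 545-590 kg so every combination's
#' ratio stays inside its design band), heights from normal(160.3, 3.9) cm,
#' saddle weights uniform(4.1, 4.5) kg. Rider bodyweights are uniform over
#' each group's observed range: L 58-60, M 75-77, H 91-92 kg.
#'
#' @param config a [sim_config()].
#' @return list with data.frames `riders` and `horses` in the cohort CSV
#'   layouts.
#' @export
generate_cohort <- function(config) {
  set.seed(derive_seed(config$seed, "cohort"))
  n_r <- config$riders_per_group
  rider_ids <- make.unique(
    rep(LETTERS, length.out = 3 * n_r), sep = ""
  )[seq_len(3 * n_r)]
  group <- rep(c("L", "M", "H"), each = n_r)
  lo <- c(L = 58, M = 75, H = 91)[group]
  hi <- c(L = 60, M = 77, H = 92)[group]
  bw <- stats::runif(3 * n_r, lo, hi)
  height <- stats::rnorm(3 * n_r, c(L = 159.5, M = 168, H = 173)[group], 1.5)
  riders <- data.frame(
    rider_id = rider_ids, bodyweight_kg = bw, height_cm = height,
    group = group, stringsAsFactors = FALSE
  )
  hb <- stats::rnorm(config$n_horses, 566.7, 13.7)
  hb <- pmin(pmax(hb, 545), 590)
  horses <- data.frame(
    horse_id = paste0("H", seq_len(config$n_horses)),
    bodyweight_kg = hb,
    height_cm = stats::rnorm(config$n_horses, 160.3, 3.9),
    saddle_kg = stats::runif(config$n_horses, 4.1, 4.5),
    stringsAsFactors = FALSE
  )
  list(riders = riders, horses = horses)
}

#' Default ROI layout for synthetic images
#'
#' Four non-overlapping rectangles in a fixed geometry mirroring the
#' anatomical layout: ROI 1 a cranial (withers) patch, ROI 2 a narrow
#' midline strip (thoracic spine), ROIs 3/4 left/right lateral patches
#' (back musculature). Bounds are proportional to the image size.
#'
#' @param image_size c(rows, cols).
#' @return named list of `roi_mask` (`ROI1` .. `ROI4`).
#' @export
default_roi_masks <- function(image_size = c(120, 160)) {
  nr <- image_size[1]
  nc <- image_size[2]
  px <- function(f, n) pmax(1L, pmin(n, as.integer(round(f * n))))
  list(
    ROI1 = roi_rect(nr, nc, px(c(0.08, 0.33), nr), px(c(0.34, 0.66), nc),
                    1L, "withers"),
    ROI2 = roi_rect(nr, nc, px(c(0.40, 0.92), nr), px(c(0.45, 0.55), nc),
                    2L, "thoracic spine"),
    ROI3 = roi_rect(nr, nc, px(c(0.40, 0.92), nr), px(c(0.12, 0.38), nc),
                    3L, "left back musculature"),
    ROI4 = roi_rect(nr, nc, px(c(0.40, 0.92), nr), px(c(0.62, 0.88), nc),
                    4L, "right back musculature")
  )
}

# Smooth correlated random field: white noise low-pass filtered with a
# circular Gaussian kernel via FFT, standardized to the requested sd.
smooth_random_field <- function(nr, nc, corr_length, sd_target) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  kern <- exp(-outer(dr^2, dc^2, `+`) / (2 * corr_length^2))
  kern <- kern / sum(kern)
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
  if (stats::sd(sm) > 0) sm <- (sm - mean(sm)) / stats::sd(sm) * sd_target
  sm
}

#' Generate one temperature field
#'
#' A smooth anatomical component (seeded per horse, shared between the pre-
#' and post-exercise image of a session) plus per-pixel measurement noise
#' (seeded per rider x horse x timepoint). Post-exercise fields additionally
#' receive the uniform exercise warming everywhere and extra high-frequency
#' noise of group-dependent sd inside the muscle-rich ROIs 1, 3 and 4; the
#' spine strip (ROI 2) warms but gains no group-dependent heterogeneity.
#'
#' @param config a [sim_config()].
#' @param rider_id,horse_id identifiers (drive the derived seeds).
#' @param timepoint "pre" or "post".
#' @param group "L", "M" or "H".
#' @param masks ROI masks (default [default_roi_masks()] for the configured
#'   size).
#' @return numeric temperature matrix (degC).
#' @export
generate_temperature_field <- function(config, rider_id, horse_id, timepoint,
                                       group,
                                       masks = default_roi_masks(config$image_size)) {
  stopifnot(timepoint %in% c("pre", "post"))
  nr <- config$image_size[1]
  nc <- config$image_size[2]
  set.seed(derive_seed(config$seed, paste0("anatomy/", horse_id)))
  field <- config$baseline_temp +
    smooth_random_field(nr, nc, config$corr_length, config$smooth_sd)
  set.seed(derive_seed(
    config$seed, paste0("session/", rider_id, "/", horse_id, "/", timepoint)
  ))
  field <- field + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  if (timepoint == "post") {
    field <- field + config$exercise_warming
    het <- config$heterogeneity_sd[[group]]
    if (het > 0) {
      muscle <- masks[vapply(masks, function(m) m$label != 2L, logical(1))]
      for (m in muscle) {
        idx <- which(m$membership)
        field[idx] <- field[idx] + stats::rnorm(length(idx), 0, het)
      }
    }
  }
  field
}

#' Generate a full synthetic study
#'
#' Builds the cohort, the rider x horse combination table, and for every
#' combination a pre- and a post-exercise temperature field with its
#' pseudo-color rendering, plus the shared ROI masks and a metadata table.
#' With the default configuration this yields 72 combinations and 144
#' images. When `dir` is given everything is also written to disk (PNG
#' images, CSV fields, mask geometry JSON, metadata CSV, manifest JSON).
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if missing).
#' @return list of class `synthetic_study` with elements `config`, `riders`,
#'   `horses`, `combinations`, `metadata`, `masks`, `fields`, `images`
#'   (fields/images keyed by image id `rider_horse_timepoint`).
#' @export
generate_study <- function(config = sim_config(), dir = NULL) {
  cohort <- generate_cohort(config)
  combos <- build_combination_table(cohort$riders, cohort$horses)
  masks <- default_roi_masks(config$image_size)
  meta <- do.call(rbind, lapply(c("pre", "post"), function(tp) {
    data.frame(
      image_id = paste(combos$rider_id, combos$horse_id, tp, sep = "_"),
      rider_id = combos$rider_id, horse_id = combos$horse_id,
      timepoint = tp, group = combos$group, ratio_pct = combos$ratio_pct,
      stringsAsFactors = FALSE
    )
  }))
  meta <- meta[order(meta$rider_id, meta$horse_id,
                     match(meta$timepoint, c("pre", "post"))), ]
  rownames(meta) <- NULL
  fields <- vector("list", nrow(meta))
  images <- vector("list", nrow(meta))
  names(fields) <- names(images) <- meta$image_id
  for (i in seq_len(nrow(meta))) {
    f <- generate_temperature_field(
      config, meta$rider_id[i], meta$horse_id[i], meta$timepoint[i],
      meta$group[i], masks
    )
    fields[[i]] <- f
    images[[i]] <- render_pseudocolor(f, config$palette)
  }
  study <- structure(
    list(
      config = config, riders = cohort$riders, horses = cohort$horses,
      combinations = combos, metadata = meta, masks = masks,
      fields = fields, images = images
    ),
    class = "synthetic_study"
  )
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Write a synthetic study to disk
#'
#' @param study a `synthetic_study`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(dir, "images")
  field_dir <- file.path(dir, "fields")
  dir.create(img_dir, showWarnings = FALSE)
  dir.create(field_dir, showWarnings = FALSE)
  for (id in names(study$images)) {
    write_image(study$images[[id]], file.path(img_dir, paste0(id, ".png")))
    write_temperature_field(
      study$fields[[id]], file.path(field_dir, paste0(id, ".csv"))
    )
  }
  write_roi_masks(study$masks, file.path(dir, "masks.json"))
  write_cohort_csv(study$metadata, file.path(dir, "metadata.csv"))
  write_cohort_csv(study$riders, file.path(dir, "riders.csv"))
  write_cohort_csv(study$horses, file.path(dir, "horses.csv"))
  cfg <- study$config
  cfg$palette <- as.list(cfg$palette)
  manifest <- list(
    config = unclass(cfg),
    n_images = length(study$images),
    config_hash = derive_seed(0, jsonlite::toJSON(unclass(cfg), digits = NA))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic study back from disk
#'
#' @param dir directory written by [write_study()].
#' @return list with `metadata`, `masks`, `images`, `fields`.
#' @export
read_study <- function(dir) {
  meta <- read_cohort_csv(file.path(dir, "metadata.csv"))
  ids <- meta$image_id
  images <- lapply(ids, function(id) {
    read_image(file.path(dir, "images", paste0(id, ".png")))
  })
  fields <- lapply(ids, function(id) {
    read_temperature_field(file.path(dir, "fields", paste0(id, ".csv")))
  })
  names(images) <- names(fields) <- ids
  masks <- read_roi_masks(file.path(dir, "masks.json"),
                          nrow(fields[[1]]), ncol(fields[[1]]))
  list(metadata = meta, masks = masks, images = images, fields = fields)
}
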