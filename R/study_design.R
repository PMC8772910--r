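#' Round half-up to a fixed number of decimals
#'
#' Printed cohort tables use conventional half-up rounding (22.95 -> 23.0),
#' not the round-half-even rule of [base::round()]. All ratios and BMI values
#' are rounded this way before banding and summarising, so that group ranges
#' quote exactly the printed 1-decimal values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Body mass index from bodyweight and height
#'
#' @param weight_kg bodyweight in kg (riders are weighed with full equestrian
#'   equipment).
#' @param height_cm height in cm.
#' @return BMI in kg/m^2, rounded half-up to 1 decimal.
#' @examples
#' compute_bmi(58, 159)  # 22.9
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("bodyweight and height must be positive")
  }
  round_half_up(weight_kg / (height_cm / 100)^2, 1)
}

#' Classify BMI into weight-status bands
#'
#' Bands: underweight (< 18.5), normal (18.5-24.9), overweight (25.0-29.9),
#' obese (>= 30) kg/m^2.
#'
#' @param bmi BMI in kg/m^2.
#' @return character vector of band labels.
#' @export
classify_bmi <- function(bmi) {
  if (any(bmi <= 0)) stop("bmi must be positive")
  cut(bmi,
    breaks = c(0, 18.5, 25, 30, Inf),
    labels = c("underweight", "normal", "overweight", "obese"),
    right = FALSE
  ) |> as.character()
}

#' Rider:horse bodyweight ratio
#'
#' The combined rider-plus-saddle weight as a percentage of horse bodyweight.
#'
#' @param rider_bw rider bodyweight, kg.
#' @param saddle_bw saddle weight, kg (0 allowed for bareback scenarios).
#' @param horse_bw horse bodyweight, kg.
#' @return percentage, rounded half-up to 1 decimal.
#' @examples
#' compute_rh_ratio(58, 4.1, 585)  # 10.6
#' @export
compute_rh_ratio <- function(rider_bw, saddle_bw, horse_bw) {
  if (any(rider_bw <= 0) || any(saddle_bw < 0) || any(horse_bw <= 0)) {
    stop("weights must be positive (saddle may be zero)")
  }
  round_half_up(100 * (rider_bw + saddle_bw) / horse_bw, 1)
}

#' Assign a bodyweight-ratio group
#'
#' Bands follow the study design: light L = 10-12%, moderate M = >12 <=15%,
#' heavy H = >15 <18%. Ratios outside [10, 18) are labelled
#' `"out-of-design"` rather than rejected, so stress-testing simulations can
#' flow through.
#'
#' @param ratio rider:horse bodyweight ratio in percent.
#' @return character vector in {"L","M","H","out-of-design"}.
#' @export
assign_weight_group <- function(ratio) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  out <- rep("out-of-design", length(ratio))
  out[ratio >= 10 & ratio <= 12] <- "L"
  out[ratio > 12 & ratio <= 15] <- "M"
  out[ratio > 15 & ratio < 18] <- "H"
  out
}

#' Build the rider x horse combination table
#'
#' One row per rider x horse pair carrying the bodyweight ratio and group.
#'
#' @param riders data.frame with columns `rider_id`, `bodyweight_kg`,
#'   `height_cm`.
#' @param horses data.frame with columns `horse_id`, `bodyweight_kg`,
#'   `height_cm`, `saddle_kg`.
#' @return data.frame with columns `rider_id`, `horse_id`, `ratio_pct`,
#'   `group`, ordered riders-major.
#' @export
build_combination_table <- function(riders, horses) {
  stopifnot(nrow(riders) >= 1, nrow(horses) >= 1)
  if (anyDuplicated(riders$rider_id)) stop("duplicate rider ids")
  if (anyDuplicated(horses$horse_id)) stop("duplicate horse ids")
  grid <- expand.grid(
    horse = seq_len(nrow(horses)), rider = seq_len(nrow(riders)),
    KEEP.OUT.ATTRS = FALSE
  )
  ratio <- compute_rh_ratio(
    riders$bodyweight_kg[grid$rider],
    horses$saddle_kg[grid$horse],
    horses$bodyweight_kg[grid$horse]
  )
  data.frame(
    rider_id = as.character(riders$rider_id[grid$rider]),
    horse_id = as.character(horses$horse_id[grid$horse]),
    ratio_pct = ratio,
    group = assign_weight_group(ratio),
    stringsAsFactors = FALSE
  )
}

#' Per-group cohort summaries
#'
#' Mean and range of the bodyweight ratio per group, plus (when the rider and
#' horse tables are supplied) rider bodyweight and BMI summaries mirroring the
#' cohort description. Means are rounded half-up to 1 decimal; ranges are the
#' (min, max) of the rounded per-combination values. Empty groups are absent
#' from the output, never reported as zeros.
#'
#' @param combinations output of [build_combination_table()].
#' @param riders optional rider table (adds bodyweight/BMI summaries).
#' @return data.frame keyed by `group` with columns `n`, `ratio_mean`,
#'   `ratio_min`, `ratio_max` and, if riders are given with a `group` column,
#'   `rider_bw_mean`, `bmi_mean`.
#' @export
summarize_groups <- function(combinations, riders = NULL) {
  stopifnot("group" %in% names(combinations))
  groups <- intersect(c("L", "M", "H", "out-of-design"),
                      unique(combinations$group))
  rows <- lapply(groups, function(g) {
    v <- combinations$ratio_pct[combinations$group == g]
    data.frame(
      group = g, n = length(v),
      ratio_mean = round_half_up(mean(v), 1),
      ratio_min = min(v), ratio_max = max(v)
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(riders) && "group" %in% names(riders)) {
    bmi <- compute_bmi(riders$bodyweight_kg, riders$height_cm)
    out$rider_bw_mean <- vapply(out$group, function(g) {
      round_half_up(mean(riders$bodyweight_kg[riders$group == g]), 1)
    }, numeric(1))
    out$bmi_mean <- vapply(out$group, function(g) {
      round_half_up(mean(bmi[riders$group == g]), 1)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Rider cohort of the study
#'
#' The six riders (A-F) with bodyweights (kg, weighed with full equestrian
#' equipment), heights (cm) and a priori group membership: two riders per
#' light (L), moderate (M) and heavy (H) group.
#'
#' @return data.frame with columns `rider_id`, `bodyweight_kg`, `height_cm`,
#'   `group`.
#' @export
study_riders <- function() {
  data.frame(
    rider_id = c("A", "B", "C", "D", "E", "F"),
    bodyweight_kg = c(58, 60, 77, 75, 91, 92),
    height_cm = c(159, 160, 172, 164, 172, 174),
    group = rep(c("L", "M", "H"), each = 2),
    stringsAsFactors = FALSE
  )
}

#' Horse cohort of the study
#'
#' The twelve horses (1-12) with bodyweights, heights at the withers and the
#' weight of each horse's fitted saddle.
#'
#' @return data.frame with columns `horse_id`, `bodyweight_kg`, `height_cm`,
#'   `saddle_kg`.
#' @export
study_horses <- function() {
  data.frame(
    horse_id = as.character(1:12),
    bodyweight_kg = c(585, 550, 580, 575, 560, 550, 560, 545, 570, 580, 565, 580),
    height_cm = c(166, 154, 158, 164, 160, 156, 162, 157, 158, 162, 160, 166),
    saddle_kg = c(4.1, 4.5, 4.2, 4.5, 4.1, 4.4, 4.2, 4.2, 4.4, 4.4, 4.2, 4.2),
    stringsAsFactors = FALSE
  )
}

#' Read / write cohort and combination tables as CSV
#'
#' @param path file path.
#' @return `read_cohort_csv` returns a data.frame; writers return `path`
#'   invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("rider_id", "horse_id", "image_id"), names(out))) {
    out[[col]] <- as.character(out[[col]])
  }
  out
}

#' @rdname cohort_io
#' @param x data.frame to write.
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
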