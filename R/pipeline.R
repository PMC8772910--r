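#' Pipeline commands
#'
#' Thin orchestration layer over the simulation, extraction and analysis
#' modules, operating on a study directory so the pipeline can be driven
#' from the bundled command-line script (`inst/cli/thermotex`) or from R.
#'
#' @name pipeline
NULL

#' @describeIn pipeline Generate a synthetic study on disk (images, fields,
#'   masks, metadata, manifest).
#' @param config a [sim_config()].
#' @param dir study directory.
#' @return `run_simulate` returns the directory, invisibly.
#' @export
run_simulate <- function(config = sim_config(), dir) {
  generate_study(config, dir = dir)
  message("wrote synthetic study to ", dir)
  invisible(dir)
}

#' @describeIn pipeline Extract the wide feature table of a study directory
#'   and write it as `features.csv` (372 texture columns plus 12 conventional
#'   columns for the default four-ROI layout).
#' @param texture a [texture_config()].
#' @return `run_extract` returns the feature table, invisibly.
#' @export
run_extract <- function(dir, texture = texture_config()) {
  study <- read_study(dir)
  features <- extract_all_features(
    study$images, study$masks, study$fields, study$metadata, texture
  )
  write_cohort_csv(features, file.path(dir, "features.csv"))
  invisible(features)
}

#' @describeIn pipeline Run the two-stage screen on `features.csv` and write
#'   `screen.csv`, `group_results.csv` and `grid.csv`.
#' @param alpha significance level.
#' @return `run_analyze` returns the [analyze_study()] result, invisibly.
#' @export
run_analyze <- function(dir, alpha = 0.05) {
  path <- file.path(dir, "features.csv")
  if (!file.exists(path)) stop("no feature table at ", path, "; run extract first")
  features <- read_cohort_csv(path)
  res <- analyze_study(features, alpha = alpha)
  write_cohort_csv(res$screen, file.path(dir, "screen.csv"))
  write_cohort_csv(res$groups, file.path(dir, "group_results.csv"))
  write_cohort_csv(res$grid, file.path(dir, "grid.csv"))
  invisible(res)
}

#' @describeIn pipeline Write a plain-text summary (`report.txt`) of an
#'   analyzed study: cohort group summaries, selection counts per feature
#'   family / ROI / component, and difference-pattern counts.
#' @return `run_report` returns the report lines, invisibly.
#' @export
run_report <- function(dir) {
  grid_path <- file.path(dir, "grid.csv")
  if (!file.exists(grid_path)) stop("no analysis outputs in ", dir, "; run analyze first")
  grid <- read_cohort_csv(grid_path)
  meta <- read_cohort_csv(file.path(dir, "metadata.csv"))
  combos <- unique(meta[meta$timepoint == "pre",
                        c("rider_id", "horse_id", "ratio_pct", "group")])
  riders <- tryCatch(read_cohort_csv(file.path(dir, "riders.csv")),
                     error = function(e) NULL)
  summ <- summarize_groups(combos, riders)
  lines <- c(
    "Thermal-texture study report",
    "============================",
    "",
    sprintf("Images analysed: %d (%d combinations x 2 timepoints)",
            nrow(meta), nrow(combos)),
    "",
    "Cohort summary (bodyweight-ratio groups):",
    utils::capture.output(print(summ, row.names = FALSE)),
    "",
    "Features significant pre vs post in all three groups:"
  )
  sel <- grid[grid$carried & grid$family != "conventional", ]
  for (fam in c("HS", "GLRLM", "GLCM")) {
    lines <- c(lines, sprintf("  %-5s %d of %d", fam,
                              sum(sel$family == fam),
                              sum(grid$family == fam)))
  }
  if (nrow(sel) == 0) {
    lines <- c(lines, "", "No selections: no feature differed in all three groups.")
  } else {
    lines <- c(lines, "", "Selections by ROI:",
      vapply(sort(unique(sel$roi)), function(r) {
        sprintf("  %s: %d", r, sum(sel$roi == r))
      }, character(1)),
      "", "Selections by component:",
      vapply(c("R", "G", "B"), function(cc) {
        sprintf("  %s: %d", cc, sum(sel$component == cc, na.rm = TRUE))
      }, character(1))
    )
    pat <- grid[nzchar(grid$pattern) & grid$pattern != "none", ]
    if (nrow(pat)) {
      lines <- c(lines, "", "Group-difference patterns:",
        vapply(sort(unique(pat$pattern)), function(p) {
          sprintf("  %s: %d", p, sum(pat$pattern == p))
        }, character(1))
      )
    }
  }
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(lines)
}
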