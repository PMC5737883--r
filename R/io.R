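#' Write and read stimuli as plain text
#'
#' A stimulus is stored as a long-format CSV (`receptor`, `time_s`,
#' `luminance`) whose first line is a `#`-prefixed JSON header carrying
#' the sampling metadata and, when present, the originating
#' [stimulus_spec()]. The round trip preserves the luminance grid to full
#' double precision.
#'
#' @param stim A [spacetime_stimulus()].
#' @param path File path for the CSV.
#' @return `write_stimulus_csv()` returns `path` invisibly;
#'   `read_stimulus_csv()` returns the reconstructed
#'   [spacetime_stimulus()].
#' @export
write_stimulus_csv <- function(stim, path) {
  stopifnot(inherits(stim, "spacetime_stimulus"))
  meta <- list(
    receptor_spacing_deg = stim$receptor_spacing_deg,
    dt_s = stim$dt_s,
    direction = stim$direction,
    n_time = nrow(stim$luminance),
    n_receptors = ncol(stim$luminance),
    spec = if (!is.null(stim$spec)) unclass(stim$spec) else NULL
  )
  header <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  writeLines(header, path)
  df <- as_tibble(stim)[c("receptor", "time_s", "luminance")]
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  header <- readLines(path, n = 1)
  meta <- jsonlite::fromJSON(sub("^# ", "", header))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  lum <- matrix(df$luminance, nrow = meta$n_time, ncol = meta$n_receptors)
  spec <- NULL
  if (!is.null(meta$spec)) {
    spec <- meta$spec
    class(spec) <- "stimulus_spec"
  }
  spacetime_stimulus(lum, meta$receptor_spacing_deg, meta$dt_s,
                     spec = spec, direction = meta$direction)
}

#' Write and read a synthetic cohort with its ground truth
#'
#' Trial data go to `<stem>_trials.csv` (tidy long format) and the planted
#' ground truth plus generator parameters to `<stem>_truth.json`, written
#' at full precision so the ground-truth metadata round-trips losslessly.
#'
#' @param cohort Output of [gen_behavior()].
#' @param stem Path stem (without extension) for the two files.
#' @return `write_cohort()` returns `stem` invisibly; `read_cohort()`
#'   returns the cohort tibble with its `ground_truth` attribute restored.
#' @export
write_cohort <- function(cohort, stem) {
  readr::write_csv(cohort, paste0(stem, "_trials.csv"))
  truth <- list(
    ground_truth = attr(cohort, "ground_truth"),
    spec = {
      sp <- attr(cohort, "spec")
      if (!is.null(sp)) unclass(sp) else NULL
    }
  )
  jsonlite::write_json(truth, paste0(stem, "_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(stem)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(stem) {
  cohort <- readr::read_csv(paste0(stem, "_trials.csv"),
                            show_col_types = FALSE)
  truth <- jsonlite::fromJSON(paste0(stem, "_truth.json"))
  attr(cohort, "ground_truth") <- tibble::as_tibble(truth$ground_truth)
  if (!is.null(truth$spec)) {
    sp <- truth$spec
    sp$tuning_profile <- tibble::as_tibble(sp$tuning_profile)
    class(sp) <- "cohort_spec"
    attr(cohort, "spec") <- sp
  }
  cohort
}
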