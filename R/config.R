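#' Pipeline configuration
#'
#' Collects every tunable constant of the detection and assessment pipeline.
#' Defaults follow the published protocol: 0.75 s analysis windows, a one
#' sample (0.025 s at 40 Hz) window stride, a 1 s mean filter on the
#' probability trace, 0.5 probability and peak-height thresholds, the
#' 45 % relative peak-height threshold of the AP peak-count feature, and a
#' 360 degree cumulative-rotation limit for turning candidates.
#'
#' @param window_s Sliding-window length in seconds (default 0.75).
#' @param step_s Window stride in seconds (default 0.025, i.e. one sample at
#'   40 Hz; the closest realizable stride to 0.03 s at this rate).
#' @param mean_filter_s Mean-filter length for trace smoothing, in seconds;
#'   1, 1.25 and 1.5 s are the studied settings (default 1).
#' @param prob_threshold Task-probability threshold defining interval
#'   crossings (default 0.5).
#' @param peak_height_threshold Minimum height of a nontask-probability
#'   local maximum used as an interval anchor (default 0.5).
#' @param ap_peak_frac Relative height threshold of the AP peak-count
#'   feature, as a fraction of the interval maximum (default 0.45).
#' @param turn_limit_deg Cumulative-rotation limit for turning candidate
#'   selection (default 360).
#' @param turn_tolerance_frac Admissibility slack on `turn_limit_deg`
#'   (default 0.05, i.e. candidates up to 378 degrees are admissible).
#' @param peak_min_sep_s Minimum separation between probability peaks in the
#'   postprocessing rules (default 0.25 s).
#' @param feature_peak_min_sep_s Minimum separation between AP acceleration
#'   peaks in the feature extractor (default 0.2 s).
#' @param detector A [detector_config()].
#' @param classifier A [classifier_spec()].
#' @param seed Integer seed governing all randomness downstream.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 0.75, step_s = 0.025,
                            mean_filter_s = 1.0, prob_threshold = 0.5,
                            peak_height_threshold = 0.5, ap_peak_frac = 0.45,
                            turn_limit_deg = 360, turn_tolerance_frac = 0.05,
                            peak_min_sep_s = 0.25, feature_peak_min_sep_s = 0.2,
                            detector = detector_config(),
                            classifier = classifier_spec("knn"),
                            seed = 0L) {
  cfg <- structure(
    list(window_s = as.numeric(window_s), step_s = as.numeric(step_s),
         mean_filter_s = as.numeric(mean_filter_s),
         prob_threshold = as.numeric(prob_threshold),
         peak_height_threshold = as.numeric(peak_height_threshold),
         ap_peak_frac = as.numeric(ap_peak_frac),
         turn_limit_deg = as.numeric(turn_limit_deg),
         turn_tolerance_frac = as.numeric(turn_tolerance_frac),
         peak_min_sep_s = as.numeric(peak_min_sep_s),
         feature_peak_min_sep_s = as.numeric(feature_peak_min_sep_s),
         detector = detector, classifier = classifier,
         seed = as.integer(seed)),
    class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  pos <- c("window_s", "step_s", "mean_filter_s", "turn_limit_deg",
           "peak_min_sep_s", "feature_peak_min_sep_s")
  for (f in pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(f, " must be a positive number")
    }
  }
  unit <- c("prob_threshold", "peak_height_threshold", "ap_peak_frac")
  for (f in unit) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] > 1) {
      stop(f, " must lie in (0, 1]")
    }
  }
  if (cfg$turn_tolerance_frac < 0) stop("turn_tolerance_frac must be >= 0")
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Absent keys take the defaults of [pipeline_config()]; nested `detector`
#' and `classifier` blocks override the corresponding sub-configuration
#' fields. An empty file yields the all-defaults configuration.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must contain a mapping")
  det_args <- vals$detector %||% list()
  cls_args <- vals$classifier %||% list()
  vals$detector <- NULL; vals$classifier <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  vals$detector <- do.call(detector_config, det_args)
  vals$classifier <- do.call(classifier_spec, cls_args)
  do.call(pipeline_config, vals)
}
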