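# Loaders for the versioned parameter tables shipped under inst/extdata.
# All tables are plain CSV so site-specific values (e.g. locally measured
# angle graphs or effort thresholds) can be dropped in without recompiling.

.ef_cache <- new.env(parent = emptyenv())

ef_datafile <- function(name) {
  path <- system.file("extdata", name, package = "ergoforces")
  if (!nzchar(path)) stop("packaged data file not found: ", name)
  path
}

ef_table <- function(name) {
  if (!is.null(.ef_cache[[name]])) return(.ef_cache[[name]])
  tab <- utils::read.csv(ef_datafile(name), stringsAsFactors = FALSE)
  .ef_cache[[name]] <- tab
  tab
}

#' Population stature/weight percentile anchors
#'
#' Height and body-weight anchors for the 5th, 50th and 95th percentile of
#' the male and female population, used to scale the articulated human
#' model and to interpolate effort thresholds by worker height.
#'
#' @return data.frame with columns `sex`, `percentile`, `height_m`,
#'   `weight_kg`.
#' @export
stature_percentiles <- function() ef_table("stature_percentiles.csv")

#' Body-segment inertial parameters
#'
#' Per-segment mass fractions (\%W, percentage of total body weight),
#' centre-of-gravity position (\%CG, percentage of bone length from the
#' bone origin) and diagonal inertia tensors (kg m^2, global-axis
#' convention) for each population percentile and sex.
#'
#' @return data.frame, one row per segment and sex.
#' @export
segment_parameters <- function() ef_table("segment_parameters.csv")

#' @noRd
segment_length_fractions <- function() {
  tab <- ef_table("segment_lengths.csv")
  stats::setNames(tab$stature_fraction, tab$segment)
}

#' Effort threshold tables
#'
#' Force (kgf) and torque (kg m) scoring thresholds per joint and sex:
#' the 50th-percentile minimum (static standing load) and maximum
#' (calibration-experiment 99th percentile), with the multiplicative
#' coefficients transporting both to the 5th/95th percentiles.
#'
#' @param kind `"force"` or `"torque"`.
#' @return data.frame with columns `joint`, `sex`, `min`, `max`,
#'   `coef_p05`, `coef_p95`.
#' @export
effort_thresholds <- function(kind = c("force", "torque")) {
  kind <- match.arg(kind)
  tab <- ef_table(paste0(kind, "_thresholds.csv"))
  names(tab)[3:4] <- c("min", "max")
  tab
}

#' Angular speed/acceleration thresholds
#'
#' Per-joint slow and maximum angular speeds (deg/s) with the derived
#' acceleration thresholds (deg/s^2) used by the angular-acceleration
#' score.
#'
#' @return data.frame with columns `joint`, `slow_speed`, `max_speed`,
#'   `slow_accel`, `max_accel`.
#' @export
acceleration_thresholds <- function() ef_table("acceleration_thresholds.csv")

#' @noRd
grip_table <- function() ef_table("grip_scores.csv")

#' Per-joint factor score maxima
#'
#' Maximum attainable value of each of the five per-posture factor scores
#' (angle, angular acceleration, force, torque, grip) for every assessed
#' joint. The grip factor only applies to the wrist.
#'
#' @return data.frame with one row per joint.
#' @export
factor_maxima <- function() ef_table("factor_maxima.csv")

#' @noRd
risk_level_bands <- function() ef_table("risk_levels.csv")

#' @noRd
angle_graph_table <- function(path = NULL) {
  if (is.null(path)) return(ef_table("angle_graphs.csv"))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @noRd
shoulder_grid_table <- function(path = NULL) {
  if (is.null(path)) return(ef_table("shoulder_angle_grid.csv"))
  utils::read.csv(path, stringsAsFactors = FALSE)
}
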