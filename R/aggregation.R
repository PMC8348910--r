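# Workstation risk maps and job-rotation arithmetic: weighted combination
# of per-joint per-minute risks across captured situations and
# workstations.

#' Weighted combination of risk-map rows
#'
#' Per-joint weighted arithmetic mean of per-minute risks. Used both to
#' combine several captured situations of one workstation and to
#' evaluate a job rotation (time-weighted across workstations; task
#' order is not considered).
#'
#' @param rows data.frame or matrix with one row per situation and one
#'   numeric column per joint (a `label` column is allowed and ignored
#'   in the arithmetic).
#' @param weights nonnegative weights, one per row. Auto-normalised with
#'   a warning when they do not sum to 1 (within 1e-6).
#' @param label label for the combined row.
#' @return one-row data.frame with `label` and the combined per-joint
#'   risks.
#' @export
combine_rows <- function(rows, weights, label = "combined") {
  rows <- as.data.frame(rows)
  lab_col <- names(rows) %in% c("label", "weight")
  vals <- rows[, !lab_col, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    stop("risk columns must be numeric")
  }
  if (length(weights) != nrow(vals)) stop("one weight per row required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (abs(s - 1) > 1e-6) {
    warning("weights sum to ", format(s), "; normalising")
  }
  weights <- weights / s
  comb <- colSums(sweep(as.matrix(vals), 1, weights, "*"))
  cbind(data.frame(label = label, stringsAsFactors = FALSE),
        as.data.frame(as.list(comb)))
}

#' Build a workstation risk map
#'
#' One row per workstation (or combined situation) with the per-joint
#' per-minute risks, each annotated with its level band for colour
#' display. Accepts `risk_profile` objects or ready-made rows.
#'
#' @param profiles list of `risk_profile` objects, or a data.frame of
#'   per-joint risk rows.
#' @param labels workstation labels (defaults to list names).
#' @return object of class `risk_map`: `values` (data.frame of risks, 1
#'   decimal on print), `levels`, `valuations` and `colors` aligned with
#'   it.
#' @export
build_risk_map <- function(profiles, labels = NULL) {
  if (is.data.frame(profiles)) {
    vals <- profiles[, setdiff(names(profiles), c("label", "weight")), drop = FALSE]
    labels <- labels %||% profiles$label %||% paste0("row", seq_len(nrow(profiles)))
  } else {
    if (inherits(profiles, "risk_profile")) profiles <- list(profiles)
    vals <- do.call(rbind, lapply(profiles, function(p) {
      stats::setNames(as.data.frame(as.list(p$summary$risk_per_minute)),
                      p$summary$joint)
    }))
    labels <- labels %||% names(profiles) %||% paste0("row", seq_len(nrow(vals)))
  }
  m <- as.matrix(vals)
  lv <- apply(m, c(1, 2), function(r) risk_level(r)$level)
  val <- apply(m, c(1, 2), function(r) risk_level(r)$valuation)
  col <- apply(m, c(1, 2), function(r) risk_level(r)$color)
  structure(list(labels = labels,
                 values = cbind(data.frame(label = labels), as.data.frame(vals)),
                 levels = lv, valuations = val, colors = col),
            class = "risk_map")
}

#' @export
print.risk_map <- function(x, ...) {
  v <- x$values
  num <- vapply(v, is.numeric, logical(1))
  v[num] <- lapply(v[num], round_half_up, 1)
  cat("<risk_map>\n")
  print(v, row.names = FALSE)
  invisible(x)
}

#' Time-weighted job rotation over a risk map
#'
#' @param map a `risk_map` or data.frame of rows.
#' @param weights workday time fractions per workstation.
#' @return one-row data.frame (see [combine_rows()]).
#' @export
rotation_row <- function(map, weights, label = "Rotation") {
  rows <- if (inherits(map, "risk_map")) map$values else map
  combine_rows(rows, weights, label = label)
}
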