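# Readers and writers for the plain-text interchange formats: capture
# CSV (wide, one row per frame), a BVH subset, action/support CSV,
# report CSV/JSON and YAML/JSON configuration.

#' Write a capture series to CSV
#'
#' Canonical capture format: a `#meta frame_rate=<Hz>` comment line, then
#' a header row and one row per frame with columns `<bone>_<Rx|Ry|Rz>`
#' in degrees.
#'
#' @param series a `capture_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_capture <- function(series, path) {
  stopifnot(inherits(series, "capture_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#meta frame_rate=%g", series$frame_rate), con)
  utils::write.csv(as.data.frame(series$angles), con, row.names = FALSE)
  invisible(path)
}

#' Read a capture series
#'
#' @param path capture file (CSV dialect above, or a BVH subset when the
#'   file extension is `.bvh`).
#' @param frame_rate override for the sampling rate; by default read
#'   from the `#meta` line (CSV) or the `Frame Time` field (BVH).
#' @param mapping for BVH input, a named character vector mapping BVH
#'   joint names to model bones (defaults cover common skeleton naming).
#' @return a `capture_series`.
#' @export
read_capture <- function(path, frame_rate = NULL, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.bvh$", path, ignore.case = TRUE)) {
    return(read_bvh(path, frame_rate = frame_rate, mapping = mapping))
  }
  first <- readLines(path, n = 1)
  fr <- frame_rate
  if (grepl("^#meta", first)) {
    m <- regmatches(first, regexec("frame_rate=([0-9.]+)", first))[[1]]
    if (length(m) == 2 && is.null(fr)) fr <- as.numeric(m[2])
  }
  if (is.null(fr)) fr <- 60
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!nrow(df)) stop("empty capture file: ", path)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    stop("malformed (non-numeric) capture column(s): ",
         paste(names(df)[bad], collapse = ", "))
  }
  required_joint_columns(df)
  capture_series(df, frame_rate = fr)
}

# reject captures missing whole joints that the assessment needs
required_joint_columns <- function(df) {
  need <- unique(RISK_JOINT_BONE)
  have <- unique(sub("_(Rx|Ry|Rz)$", "", names(df)))
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop("capture is missing joint column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

# default BVH joint-name mapping for common full-body skeleton exports
default_bvh_mapping <- function() {
  c(Hips = "pelvis", Spine = "lumbar", Spine1 = "thorax", Chest = "thorax",
    Neck = "head", Head = "head",
    RightArm = "arm_R", RightForeArm = "forearm_R", RightHand = "hand_R",
    LeftArm = "arm_L", LeftForeArm = "forearm_L", LeftHand = "hand_L",
    RightUpLeg = "thigh_R", RightLeg = "shin_R", RightFoot = "foot_R",
    LeftUpLeg = "thigh_L", LeftLeg = "shin_L", LeftFoot = "foot_L")
}

#' Read a BVH motion file (subset)
#'
#' Minimal BVH support: parses the HIERARCHY joint list and CHANNELS
#' declarations, maps known joint names onto model bones and loads their
#' rotation channels. Joints without a mapping are skipped with a
#' warning; translation channels are ignored.
#'
#' @inheritParams read_capture
#' @return a `capture_series`.
#' @export
read_bvh <- function(path, frame_rate = NULL, mapping = NULL) {
  mapping <- mapping %||% default_bvh_mapping()
  lines <- readLines(path)
  motion_at <- grep("^\\s*MOTION\\s*$", lines)
  if (!length(motion_at)) stop("not a BVH file (no MOTION section): ", path)
  hier <- lines[seq_len(motion_at[1] - 1)]
  joints <- character()
  channels <- list()
  current <- NA_character_
  for (ln in hier) {
    jm <- regmatches(ln, regexec("^\\s*(ROOT|JOINT)\\s+(\\S+)", ln))[[1]]
    if (length(jm) == 3) {
      current <- jm[3]
      joints <- c(joints, current)
    }
    cm <- regmatches(ln, regexec("^\\s*CHANNELS\\s+(\\d+)\\s+(.*)$", ln))[[1]]
    if (length(cm) == 3) {
      channels[[current]] <- strsplit(trimws(cm[3]), "\\s+")[[1]]
    }
  }
  unknown <- setdiff(joints, names(mapping))
  if (length(unknown)) {
    warning("ignoring unmapped BVH joint(s): ", paste(unknown, collapse = ", "))
  }
  body <- lines[(motion_at[1] + 1):length(lines)]
  ft_line <- grep("Frame Time:", body, value = TRUE)
  if (is.null(frame_rate)) {
    ft <- as.numeric(sub(".*Frame Time:\\s*", "", ft_line[1]))
    frame_rate <- 1 / ft
  }
  data_lines <- body[!grepl("Frames:|Frame Time:", body)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  vals <- do.call(rbind, lapply(data_lines, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  # column layout follows hierarchy order and each joint's channel list
  out <- list()
  col <- 1
  for (j in joints) {
    ch <- channels[[j]]
    for (c_name in ch) {
      if (j %in% names(mapping) && grepl("rotation$", c_name)) {
        axis <- switch(sub("rotation$", "", c_name),
                       X = "Rx", Y = "Ry", Z = "Rz")
        out[[paste0(mapping[[j]], "_", axis)]] <- vals[, col]
      }
      col <- col + 1
    }
  }
  capture_series(as.data.frame(out), frame_rate = frame_rate)
}

#' Read/write external-action tables
#'
#' CSV columns: `frame_start`, `frame_end`, `hand`, `fx`, `fy`, `fz`,
#' `tx`, `ty`, `tz`, `grasp`.
#'
#' @param path file path.
#' @return an `action_table`.
#' @export
read_actions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_start", "frame_end", "hand", "fx", "fy", "fz",
            "tx", "ty", "tz", "grasp")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("action file missing column(s): ",
                            paste(missing, collapse = ", "))
  do.call(action_table, df[need])
}

#' @rdname read_actions
#' @param actions an `action_table`.
#' @export
write_actions <- function(actions, path) {
  utils::write.csv(as.data.frame(actions), path, row.names = FALSE)
  invisible(path)
}

#' Read/write support-declaration tables
#'
#' CSV columns: `frame_start`, `frame_end`, `kind` (`seated`, `hand_L`,
#' `hand_R`).
#'
#' @param path file path.
#' @return a `support_table`.
#' @export
read_supports <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_start", "frame_end", "kind")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("support file missing column(s): ",
                            paste(missing, collapse = ", "))
  do.call(support_table, df[need])
}

#' @rdname read_supports
#' @param supports a `support_table`.
#' @export
write_supports <- function(supports, path) {
  utils::write.csv(as.data.frame(supports), path, row.names = FALSE)
  invisible(path)
}

#' Read an assessment configuration file
#'
#' YAML or JSON with optional blocks `anthropometry` (height, elbow_span,
#' sex, weight, preparation), `context` (cycle_time, nonrecovery_hours,
#' micropauses, repetitive_hours, additional) and `files` (angle_graphs,
#' shoulder_grid overrides).
#'
#' @param path configuration file (`.yml`, `.yaml` or `.json`).
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Write a risk report
#'
#' Serialises a `risk_profile` summary (and optionally the per-posture
#' series) to CSV or JSON depending on the file extension.
#'
#' @param profile a `risk_profile`.
#' @param path output `.csv` or `.json` file.
#' @param per_posture include the per-frame risk matrix (JSON only).
#' @return `path`, invisibly.
#' @export
write_report <- function(profile, path, per_posture = FALSE) {
  s <- profile$summary
  s$risk_per_minute <- round_half_up(s$risk_per_minute, 1)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(summary = s)
    if (per_posture) payload$risk_per_posture <- profile$risk_per_posture
    jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(s, path, row.names = FALSE)
  }
  invisible(path)
}
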