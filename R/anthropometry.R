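# Articulated human model: percentile scaling of segment lengths, masses,
# centre-of-gravity positions and inertia tensors.

BONES <- c("pelvis", "lumbar", "thorax", "head",
           "arm_R", "forearm_R", "hand_R",
           "arm_L", "forearm_L", "hand_L",
           "thigh_R", "shin_R", "foot_R",
           "thigh_L", "shin_L", "foot_L")

bone_segment <- function(bone) sub("_(R|L)$", "", bone)
bone_side <- function(bone) {
  s <- regmatches(bone, regexpr("(R|L)$", bone))
  ifelse(lengths(regmatches(bone, gregexpr("_(R|L)$", bone))) > 0, s, "")
}

# Skeleton geometry in the neutral standing pose. Offsets are expressed in
# the parent bone's local frame (metres once scaled by stature); `dir` is
# the unit bone axis in the bone's own frame. Global axes: y vertical up,
# x lateral (towards the right side), z anterior.
build_skeleton <- function(height, shoulder_width) {
  H <- height
  hipw <- 0.0955 * H            # half hip width
  sw <- shoulder_width / 2
  lf <- segment_length_fractions()
  foot_drop <- 0.039 * H        # ankle height lost over the foot bone
  foot_len <- lf[["foot"]] * H
  foot_dir <- c(0, -foot_drop, sqrt(foot_len^2 - foot_drop^2)) / foot_len

  row <- function(bone, parent, off, dir, len) {
    data.frame(bone = bone, parent = parent,
               off_x = off[1], off_y = off[2], off_z = off[3],
               dir_x = dir[1], dir_y = dir[2], dir_z = dir[3],
               length = len, stringsAsFactors = FALSE)
  }
  up <- c(0, 1, 0); dn <- c(0, -1, 0)
  sk <- rbind(
    row("pelvis", NA, c(0, 0.569 * H, 0), up, lf[["pelvis"]] * H),
    row("lumbar", "pelvis", c(0, 0.039 * H, 0), up, lf[["lumbar"]] * H),
    row("thorax", "lumbar", c(0, lf[["lumbar"]] * H, 0), up, lf[["thorax"]] * H),
    row("head", "thorax", c(0, lf[["thorax"]] * H, 0), up, lf[["head"]] * H),
    row("arm_R", "thorax", c(sw, 0.098 * H, 0), dn, lf[["arm"]] * H),
    row("forearm_R", "arm_R", c(0, -lf[["arm"]] * H, 0), dn, lf[["forearm"]] * H),
    row("hand_R", "forearm_R", c(0, -lf[["forearm"]] * H, 0), dn, lf[["hand"]] * H),
    row("arm_L", "thorax", c(-sw, 0.098 * H, 0), dn, lf[["arm"]] * H),
    row("forearm_L", "arm_L", c(0, -lf[["arm"]] * H, 0), dn, lf[["forearm"]] * H),
    row("hand_L", "forearm_L", c(0, -lf[["forearm"]] * H, 0), dn, lf[["hand"]] * H),
    row("thigh_R", "pelvis", c(hipw, -0.039 * H, 0), dn, lf[["thigh"]] * H),
    row("shin_R", "thigh_R", c(0, -lf[["thigh"]] * H, 0), dn, lf[["shin"]] * H),
    row("foot_R", "shin_R", c(0, -lf[["shin"]] * H, 0), foot_dir, foot_len),
    row("thigh_L", "pelvis", c(-hipw, -0.039 * H, 0), dn, lf[["thigh"]] * H),
    row("shin_L", "thigh_L", c(0, -lf[["thigh"]] * H, 0), dn, lf[["shin"]] * H),
    row("foot_L", "shin_L", c(0, -lf[["shin"]] * H, 0), foot_dir, foot_len)
  )
  rownames(sk) <- sk$bone
  sk
}

# Children-before-parents evaluation order for the load recursion.
skeleton_postorder <- function(sk) {
  depth <- function(b) {
    d <- 0
    while (!is.na(sk[b, "parent"])) { b <- sk[b, "parent"]; d <- d + 1 }
    d
  }
  sk$bone[order(-vapply(sk$bone, depth, numeric(1)))]
}

interp_weight <- function(height, sex) {
  tab <- stature_percentiles()
  tab <- tab[tab$sex == sex, ]
  if (height < min(tab$height_m) || height > max(tab$height_m)) {
    warning("height ", height, " m outside the tabulated [P05, P95] range; ",
            "extrapolating body weight linearly")
  }
  lin_interp(tab$height_m, tab$weight_kg, height)
}

interp_tensor <- function(weight, sex, segment) {
  par <- segment_parameters()
  row <- par[par$sex == sex & par$segment == segment, ]
  anchors <- stature_percentiles()
  anchors <- anchors[anchors$sex == sex, ]
  w <- anchors$weight_kg[match(c("P05", "P50", "P95"), anchors$percentile)]
  vapply(c("x", "y", "z"), function(ax) {
    v <- as.numeric(row[paste0(c("p05_", "p50_", "p95_"), ax)])
    lin_interp(w, v, weight)
  }, numeric(1))
}

#' Build a scaled articulated human model
#'
#' Scales the whole-body linkage (16 bones: pelvis, lumbar, thorax, head
#' and sided arm/forearm/hand, thigh/shin/foot) to a worker's
#' anthropometry. Segment lengths are proportional to stature; segment
#' masses come from tabulated percentage-of-body-weight values;
#' centre-of-gravity positions are a fixed fraction of each bone's
#' length; inertia tensors are interpolated between the tabulated
#' percentile tensors on body weight.
#'
#' @param height worker stature in metres, within [1.30, 2.10].
#' @param sex `"male"` or `"female"`.
#' @param elbow_span distance between the olecranons in the neutral
#'   posture, projected on the frontal plane (m). Sets the model shoulder
#'   width via a configurable linear factor. Defaults to a
#'   stature-proportional value.
#' @param weight body weight in kg; when omitted it is interpolated from
#'   the population percentile table at the given height.
#' @param preparation worker preparation level: 0 (sensitive), 1
#'   (average), 2 (trained) or 3 (specially trained). Scales the maximum
#'   effort thresholds during risk scoring.
#' @param shoulder_factor linear map from elbow span to shoulder width.
#' @return an object of class `human_model` with elements `sex`,
#'   `height`, `body_weight`, `shoulder_width`, `preparation`, a
#'   `segments` data frame (mass fraction, CG fraction, length and
#'   interpolated inertia diagonal per bone) and the scaled `skeleton`.
#' @examples
#' m <- build_human_model(1.759, "male")
#' m$body_weight  # 80.5 kg, the tabulated 50th-percentile value
#' @export
build_human_model <- function(height, sex = c("male", "female"),
                              elbow_span = NULL, weight = NULL,
                              preparation = 1, shoulder_factor = 0.85) {
  sex <- match.arg(sex)
  if (!is.numeric(height) || length(height) != 1 || is.na(height)) {
    stop("height must be a single number in metres")
  }
  if (height < 1.30 || height > 2.10) {
    stop("height ", height, " m outside the supported range [1.30, 2.10] m")
  }
  if (!preparation %in% 0:3) stop("preparation must be 0, 1, 2 or 3")
  if (is.null(elbow_span)) elbow_span <- 0.305 * height
  if (elbow_span <= 0) stop("elbow_span must be positive")
  body_weight <- if (is.null(weight)) interp_weight(height, sex) else weight
  shoulder_width <- shoulder_factor * elbow_span

  par <- segment_parameters()
  par <- par[par$sex == sex, ]
  lf <- segment_length_fractions()
  seg <- bone_segment(BONES)
  idx <- match(seg, par$segment)
  tensors <- t(vapply(seg, function(s) interp_tensor(body_weight, sex, s),
                      numeric(3)))
  segments <- data.frame(
    bone = BONES,
    segment = seg,
    weight_fraction = par$weight_pct[idx] / 100,
    cg_fraction = par$cg_pct[idx] / 100,
    length = lf[seg] * height,
    i_x = tensors[, 1], i_y = tensors[, 2], i_z = tensors[, 3],
    stringsAsFactors = FALSE
  )
  rownames(segments) <- segments$bone

  model <- list(
    sex = sex, height = height, body_weight = body_weight,
    elbow_span = elbow_span, shoulder_width = shoulder_width,
    preparation = preparation, segments = segments,
    skeleton = build_skeleton(height, shoulder_width)
  )
  class(model) <- "human_model"
  model
}

#' @export
print.human_model <- function(x, ...) {
  cat(sprintf("<human_model> %s, height %.3f m, weight %.2f kg, preparation %d\n",
              x$sex, x$height, x$body_weight, x$preparation))
  cat(sprintf("  %d bones, total segment mass %.2f kg\n",
              nrow(x$segments), sum(x$segments$weight_fraction) * x$body_weight))
  invisible(x)
}

#' Rescale a model to a population percentile
#'
#' Returns a model whose height, weight and inertia tensors take the
#' tabulated values for the requested sex/percentile, so that a captured
#' movement can be re-assessed as if performed by a worker of that
#' anthropometry.
#'
#' @param model a `human_model`.
#' @param sex `"male"` or `"female"`.
#' @param percentile `"P05"`, `"P50"` or `"P95"`.
#' @return a `human_model` at the exact tabulated anthropometry.
#' @export
scale_to_percentile <- function(model, sex = c("male", "female"),
                                percentile = c("P05", "P50", "P95")) {
  sex <- match.arg(sex)
  percentile <- match.arg(percentile)
  tab <- stature_percentiles()
  row <- tab[tab$sex == sex & tab$percentile == percentile, ]
  build_human_model(height = row$height_m, sex = sex,
                    weight = row$weight_kg,
                    preparation = model$preparation)
}

#' Gravity load of one body segment
#'
#' @param model a `human_model`.
#' @param segment bone name (e.g. `"head"`, `"hand_R"`).
#' @return 3-vector in kgf pointing down the vertical axis, with modulus
#'   mass fraction times body weight.
#' @export
segment_weight_force <- function(model, segment) {
  if (!segment %in% model$segments$bone) {
    # accept unsided limb names: both sides carry identical fractions
    hit <- which(model$segments$segment == segment)
    if (!length(hit)) stop("unknown segment: ", segment)
    segment <- model$segments$bone[hit[1]]
  }
  wf <- model$segments[segment, "weight_fraction"]
  c(0, -wf * model$body_weight, 0)
}
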