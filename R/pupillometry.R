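# Two-stage pupillometry: (1) every frame is classified open vs occluded
# by a lightweight feature-based classifier (the classifier contract is a
# binary label plus a confidence; the interface is pluggable so a deep
# model can be swapped in); (2) open frames are segmented for a circular
# pupil; open frames where no circle is found are flagged for user-seeded
# re-segmentation.

frame_features <- function(frame) {
  v <- as.numeric(frame)
  dark <- frame < 95 # between the pupil (~40) and iris (~150) bands
  c(dark_frac = mean(dark),
    mean_int = mean(v),
    sd_int = sd(v),
    q10 = unname(stats::quantile(v, 0.1)),
    row_dark_max = if (nrow(frame)) max(rowMeans(dark)) else 0,
    bright_frac = mean(v > 170))
}

#' Train the open/occluded frame classifier
#'
#' A regularized linear decision rule (linear discriminant) over simple
#' intensity features (dark-pixel fraction, histogram moments, row-wise
#' dark structure, bright eyelid fraction). The default training regime
#' mirrors a 70 + 70 frame training set with 15 + 15 held-out validation
#' frames per class.
#'
#' @param frames List of grayscale matrices.
#' @param labels Character vector (`"open"` / `"occluded"`), one per
#'   frame; at least 2 examples per class.
#' @param seed Integer seed recorded in the model metadata (training is
#'   deterministic given it).
#' @return An object of class `pupil_classifier`.
#' @export
train_pupil_classifier <- function(frames, labels, seed = 1L) {
  stopifnot(length(frames) == length(labels))
  labels <- factor(labels, levels = c("occluded", "open"))
  if (any(is.na(labels))) stop_fmt("labels must be 'open' or 'occluded'")
  if (any(table(labels) < 2L))
    stop_fmt("need at least 2 examples per class")
  X <- t(vapply(frames, frame_features, numeric(6)))
  keep <- apply(X, 2, function(col) stats::var(col) > 1e-12)
  if (!any(keep))
    stop_fmt("degenerate training set: all features constant")
  fit <- tryCatch(
    MASS::lda(X[, keep, drop = FALSE], grouping = labels),
    error = function(e)
      stop_fmt("classifier training failed (degenerate input): %s",
               conditionMessage(e)))
  structure(list(version = "features-lda-1", fit = fit, keep = keep,
                 meta = list(n_per_class = as.list(table(labels)),
                             seed = as.integer(seed))),
            class = "pupil_classifier")
}

#' @export
print.pupil_classifier <- function(x, ...) {
  cat(sprintf("Pupil frame classifier (%s), trained on %s/%s frames\n",
              x$version, x$meta$n_per_class$open,
              x$meta$n_per_class$occluded))
  invisible(x)
}

#' Classify one eye frame as open or occluded
#'
#' @param frame Grayscale matrix (0-255).
#' @param model A [train_pupil_classifier()] model.
#' @return List with `label` (`"open"` / `"occluded"`) and `confidence`
#'   in `[0, 1]` (posterior probability of the predicted class).
#' @export
classify_frame <- function(frame, model) {
  stopifnot(inherits(model, "pupil_classifier"))
  x <- frame_features(frame)[model$keep]
  p <- stats::predict(model$fit, matrix(x, nrow = 1))
  list(label = as.character(p$class),
       confidence = max(p$posterior))
}

dark_threshold <- function(frame) {
  v <- as.numeric(frame)
  km <- kmeans(v, centers = matrix(c(min(v), max(v)), ncol = 1))
  mean(km$centers)
}

#' Segment the pupil as a dark circular region
#'
#' Binarizes the frame at a dark/bright threshold (two-means of the
#' intensity histogram unless given), labels connected dark components,
#' and fits a circle (centroid + radius from area) to the largest one.
#' The candidate is rejected - returning no circle - when its radius
#' falls outside `radius_bounds`, when its pixels extend far beyond the
#' fitted radius, or when the fitted disk is insufficiently filled
#' (non-circular dark regions such as eyelid shadow bands fail these
#' checks). Absence of a circle is a valid result, not an error.
#'
#' @param frame Grayscale matrix (0-255).
#' @param radius_bounds Admissible radius range in px.
#' @param threshold Binarization threshold; estimated from the frame when
#'   `NULL`.
#' @param min_fill Minimum filled fraction of the fitted disk.
#' @return Named numeric `c(cx =, cy =, r =)` in px, or `NULL`.
#' @export
segment_pupil <- function(frame, radius_bounds = c(4, 40),
                          threshold = NULL, min_fill = 0.7) {
  if (diff(range(frame)) < 20) return(NULL) # blank frame
  thr <- threshold %||% dark_threshold(frame)
  mask <- (frame < thr) * 1L
  if (sum(mask) < pi * radius_bounds[1]^2) return(NULL)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  comp <- which.max(sizes)
  idx <- which(lab == comp, arr.ind = TRUE)
  area <- nrow(idx)
  r <- sqrt(area / pi)
  if (r < radius_bounds[1] || r > radius_bounds[2]) return(NULL)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  d <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
  if (max(d) > 1.6 * r) return(NULL) # elongated, not a disk
  fill <- sum(d <= r) / (pi * r^2)
  if (fill < min_fill) return(NULL)
  c(cx = cx, cy = cy, r = r)
}

#' Segment the pupil around a user-provided seed point
#'
#' Local re-segmentation for open frames where the automatic pass found
#' no circle: the user clicks the pupil center, and the fit is
#' constrained to dark pixels near the seed. Always returns a circle,
#' with an explicit low-confidence flag when the local dark/bright
#' contrast is too weak to trust it (e.g. a seed in flat background).
#'
#' @param frame Grayscale matrix (0-255).
#' @param click Numeric `c(x, y)` seed in px.
#' @param radius_bounds Admissible radius range in px.
#' @return List with `cx`, `cy`, `r`, `low_confidence`.
#' @export
seeded_segment <- function(frame, click, radius_bounds = c(4, 40)) {
  h <- nrow(frame); w <- ncol(frame)
  x0 <- min(max(click[1], 1), w); y0 <- min(max(click[2], 1), h)
  rmax <- radius_bounds[2]
  rows <- max(1, floor(y0 - rmax)):min(h, ceiling(y0 + rmax))
  cols <- max(1, floor(x0 - rmax)):min(w, ceiling(x0 + rmax))
  win <- frame[rows, cols, drop = FALSE]
  thr <- if (diff(range(win)) < 20) -Inf else dark_threshold(win)
  idx <- which(win < thr, arr.ind = TRUE)
  low <- FALSE
  if (nrow(idx) < pi * radius_bounds[1]^2) {
    low <- TRUE
    r <- radius_bounds[1]
    cx <- x0; cy <- y0
  } else {
    # two centroid refinements restricted to dark pixels near the seed
    cy <- y0 - rows[1] + 1; cx <- x0 - cols[1] + 1
    for (it in 1:2) {
      d <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
      near <- idx[d <= rmax, , drop = FALSE]
      if (nrow(near) == 0L) { low <- TRUE; break }
      cy <- mean(near[, 1]); cx <- mean(near[, 2])
      r <- sqrt(nrow(near) / pi)
    }
    inside <- win[idx]
    contrast <- mean(win) - mean(inside)
    if (contrast < 20 || r < radius_bounds[1]) low <- TRUE
    r <- min(max(r, radius_bounds[1]), radius_bounds[2])
    cx <- cx + cols[1] - 1; cy <- cy + rows[1] - 1
  }
  list(cx = unname(cx), cy = unname(cy), r = unname(r),
       low_confidence = low)
}

#' Run the two-stage pupillometry pipeline over a set of frames
#'
#' @param frames List of grayscale matrices.
#' @param model A [train_pupil_classifier()] model.
#' @param radius_bounds Passed to [segment_pupil()].
#' @param seeds Optional data frame of user click points (`frame`, `x`,
#'   `y`) applied to frames the automatic pass left ambiguous.
#' @return Data frame (one row per frame): `frame`, `label`,
#'   `confidence`, `cx`, `cy`, `r`, `status` with status one of
#'   `segmented`, `occluded`, `ambiguous`, `manually_seeded`, `no_pupil`.
#' @export
process_frames <- function(frames, model, radius_bounds = c(4, 40),
                           seeds = NULL) {
  n <- length(frames)
  out <- data.frame(frame = seq_len(n), label = character(n),
                    confidence = numeric(n), cx = NA_real_,
                    cy = NA_real_, r = NA_real_,
                    status = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cl <- classify_frame(frames[[i]], model)
    out$label[i] <- cl$label
    out$confidence[i] <- cl$confidence
    if (cl$label == "occluded") { out$status[i] <- "occluded"; next }
    seg <- segment_pupil(frames[[i]], radius_bounds)
    if (!is.null(seg)) {
      out$cx[i] <- seg[["cx"]]; out$cy[i] <- seg[["cy"]]
      out$r[i] <- seg[["r"]]
      out$status[i] <- "segmented"
    } else out$status[i] <- "ambiguous"
  }
  if (!is.null(seeds) && nrow(seeds)) {
    for (k in seq_len(nrow(seeds))) {
      i <- seeds$frame[k]
      if (i < 1 || i > n || out$status[i] != "ambiguous") next
      s <- seeded_segment(frames[[i]], c(seeds$x[k], seeds$y[k]),
                          radius_bounds)
      if (s$low_confidence) { out$status[i] <- "no_pupil"; next }
      out$cx[i] <- s$cx; out$cy[i] <- s$cy; out$r[i] <- s$r
      out$status[i] <- "manually_seeded"
    }
  }
  out
}

#' Normalize pupil radii to the session median
#'
#' `r_norm = r / median(all segmented radii in the session)`; frames
#' without a segmentation carry no value.
#'
#' @param results A [process_frames()] data frame (or any data frame
#'   with an `r` column).
#' @return The input with an `r_norm` column added.
#' @export
#' @examples
#' normalize_radii(data.frame(r = c(8, 10, 12)))$r_norm # 0.8 1.0 1.2
normalize_radii <- function(results) {
  med <- median(results$r, na.rm = TRUE)
  results$r_norm <- results$r / med
  results
}

#' List open frames in which no pupil circle was found
#'
#' These are the ~1-3% of open-eye frames the automatic pass fails on;
#' they are queued, in frame order, for user-seeded re-segmentation.
#'
#' @param results A [process_frames()] data frame.
#' @return Integer vector of frame numbers with label `open` and no
#'   segmentation.
#' @export
flag_ambiguous <- function(results) {
  sort(results$frame[results$label == "open" &
                       results$status == "ambiguous"])
}
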