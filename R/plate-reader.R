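# separable Gaussian blur with reflected edges
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur1 <- function(mat) {  # along rows (dimension 1) of mat
    n <- nrow(mat)
    padded <- rbind(mat[rev(seq_len(r) + 1L), , drop = FALSE], mat,
                    mat[n - seq_len(r), , drop = FALSE])
    out <- stats::filter(padded, k, sides = 2)
    matrix(out[r + seq_len(n), ], nrow = n)
  }
  t(blur1(t(blur1(m))))
}

# smooth a vector with a reflected running mean; window forced odd
running_mean <- function(v, window) {
  window <- max(3L, as.integer(window)); if (window %% 2 == 0) window <- window + 1L
  half <- window %/% 2
  n <- length(v)
  if (n <= half + 1) return(v)
  padded <- c(rev(v[seq_len(half) + 1L]), v, rev(v[n - seq_len(half)]))
  as.numeric(stats::filter(padded, rep(1 / window, window),
                           sides = 2))[half + seq_len(n)]
}

#' Estimate the plate background
#'
#' Robust background model for a light plate carrying dark spots: the 90th
#' percentile profile of each column and of each row (spots occupy a minority
#' of both on any sane layout, so a high percentile sees past them), smoothed
#' with a running mean, combined additively
#' (`column + row - global 90th percentile`) and clamped to `[0, 1]`.
#'
#' If more than half the pixels fall well below the estimated background the
#' estimate is unreliable (e.g. a scan that is one large dark blob); the
#' result then carries attribute `low_confidence = TRUE`.
#'
#' @param plate an `sqtlc_plate` or a numeric matrix in `[0, 1]`.
#' @param probs percentile used for the profiles (default 0.9).
#' @param window smoothing window in pixels (default 15).
#' @return A background matrix of the same shape, with attribute
#'   `low_confidence`.
#' @export
estimate_background <- function(plate, probs = 0.9, window = 15L) {
  px <- if (is.matrix(plate)) plate else plate$pixels
  col_p <- apply(px, 2, stats::quantile, probs = probs, names = FALSE)
  row_p <- apply(px, 1, stats::quantile, probs = probs, names = FALSE)
  glob <- stats::quantile(px, probs = probs, names = FALSE)
  col_p <- running_mean(col_p, window)
  row_p <- running_mean(row_p, window)
  bg <- outer(row_p, rep(1, ncol(px))) +
    outer(rep(1, nrow(px)), col_p) - glob
  bg <- pmin(pmax(bg, 0), 1)
  low <- mean(px < bg - 0.1) > 0.5
  attr(bg, "low_confidence") <- low
  bg
}

#' Detect spots on a plate
#'
#' Mechanised spot finding: pixels whose deficit below the estimated
#' background reaches `contrast_floor` are thresholded, connected components
#' are labelled, and components of at least `min_area` pixels become
#' detections.  Centroids are contrast-weighted; a component containing two or
#' more well-separated local contrast maxima (two spots merged into one
#' region) is flagged `multi_peak`.  Deterministic.
#'
#' @param plate an `sqtlc_plate`.
#' @param min_area minimum component area in pixels (default 20).
#' @param contrast_floor minimum deficit below background (default 0.05).
#' @param background optional precomputed background matrix (else estimated).
#' @return A data frame of class `spot_detections`: `id`, `cx`, `cy`, `area`,
#'   `peak_contrast`, `integrated_contrast`, `rf`, `n_peaks`, `flags`, and a
#'   list column `region` of linear pixel indices.  Empty when nothing is
#'   found.
#' @export
detect_spots <- function(plate, min_area = 20L, contrast_floor = 0.05,
                         background = NULL) {
  px <- plate$pixels
  if (is.null(background)) background <- estimate_background(px)
  contrast <- background - px
  mask <- contrast >= contrast_floor
  empty <- data.frame(id = integer(), cx = numeric(), cy = numeric(),
                      area = integer(), peak_contrast = numeric(),
                      integrated_contrast = numeric(), rf = numeric(),
                      n_peaks = integer(), flags = character())
  empty$region <- list()
  class(empty) <- c("spot_detections", "data.frame")
  if (!any(mask)) return(empty)
  labels <- EBImage::bwlabel(mask)
  labels <- matrix(as.integer(labels), nrow = nrow(px))
  n_lab <- max(labels)
  rows <- list()
  for (lab in seq_len(n_lab)) {
    idx <- which(labels == lab)
    if (length(idx) < min_area) next
    yy <- (idx - 1L) %% nrow(px) + 1L
    xx <- (idx - 1L) %/% nrow(px) + 1L
    w <- contrast[idx]
    cx <- sum(xx * w) / sum(w)
    cy <- sum(yy * w) / sum(w)
    pk <- max(w)
    npk <- count_region_peaks(contrast, yy, xx, pk)
    rows[[length(rows) + 1L]] <- data.frame(
      id = lab, cx = cx, cy = cy, area = length(idx),
      peak_contrast = pk, integrated_contrast = sum(w),
      rf = NA_real_, n_peaks = npk,
      flags = if (npk > 1) "multi_peak" else "")
    rows[[length(rows)]]$region <- list(idx)
  }
  if (!length(rows)) return(empty)
  det <- do.call(rbind, rows)
  det$rf <- compute_rf(det$cy, plate$layout)
  class(det) <- c("spot_detections", "data.frame")
  det
}

# count well-separated local maxima inside one labelled region
count_region_peaks <- function(contrast, yy, xx, peak,
                               rel_height = 0.6, min_sep = 5) {
  keep <- logical(length(yy))
  h <- nrow(contrast); w <- ncol(contrast)
  for (i in seq_along(yy)) {
    v <- contrast[yy[i], xx[i]]
    if (v < rel_height * peak) next
    y0 <- max(1, yy[i] - 1); y1 <- min(h, yy[i] + 1)
    x0 <- max(1, xx[i] - 1); x1 <- min(w, xx[i] + 1)
    nb <- contrast[y0:y1, x0:x1]
    keep[i] <- sum(nb >= v) == 1  # strict maximum in its 3x3 neighbourhood
  }
  if (!any(keep)) return(1L)
  py <- yy[keep]; px_ <- xx[keep]
  ord <- order(-contrast[cbind(py, px_)])
  sel_y <- sel_x <- numeric(0)
  for (j in ord) {
    if (!length(sel_y) ||
        all(sqrt((sel_y - py[j])^2 + (sel_x - px_[j])^2) > min_sep)) {
      sel_y <- c(sel_y, py[j]); sel_x <- c(sel_x, px_[j])
    }
  }
  max(1L, length(sel_y))
}

#' Retention factor of a spot
#'
#' `rf = (origin_y - centroid_y) / (origin_y - front_y)`: migration distance
#' of the spot over migration distance of the solvent front, both measured
#' from the application origin.  Values outside `[0, 1]` are returned as-is
#' (spot beyond the front or behind the origin) and should be flagged by the
#' caller.
#'
#' @param centroid_y spot centroid row(s) (1-based from the top).
#' @param layout a [lane_layout()] with `origin_y != front_y`.
#' @return Numeric retention factor(s).
#' @export
compute_rf <- function(centroid_y, layout) {
  if (layout$origin_y == layout$front_y)
    stop("degenerate layout: origin_y == front_y", call. = FALSE)
  (layout$origin_y - centroid_y) / (layout$origin_y - layout$front_y)
}

#' Assign detections to lanes
#'
#' Each detection is attributed to the nearest application column within
#' `lane_half_width`; others stay unassigned (`lane = NA`).  When two lanes
#' are equidistant the lower index wins and the detection is flagged
#' `lane_tie`.  Within a lane the detection with the highest integrated
#' contrast is the primary spot; extras are flagged `extra_spot` (the
#' degradation-product bookkeeping count).
#'
#' @param detections a `spot_detections` data frame.
#' @param layout a [lane_layout()].
#' @return The detections with columns `lane` and `primary` added and flags
#'   updated.
#' @export
assign_lanes <- function(detections, layout) {
  xs <- layout$application_xs
  stopifnot(length(xs) >= 1)
  det <- detections
  det$lane <- NA_integer_
  det$primary <- FALSE
  if (nrow(det) == 0) return(det)
  for (i in seq_len(nrow(det))) {
    d <- abs(xs - det$cx[i])
    j <- which(d == min(d))
    if (length(j) > 1) det$flags[i] <- paste_flag(det$flags[i], "lane_tie")
    j <- j[1]
    if (d[j] <= layout$lane_half_width) det$lane[i] <- j
  }
  for (lane in unique(stats::na.omit(det$lane))) {
    in_lane <- which(det$lane == lane)
    best <- in_lane[which.max(det$integrated_contrast[in_lane])]
    det$primary[best] <- TRUE
    for (i in setdiff(in_lane, best))
      det$flags[i] <- paste_flag(det$flags[i], "extra_spot")
  }
  det
}

paste_flag <- function(flags, new) {
  ifelse(flags == "", new, paste(flags, new, sep = ";"))
}
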