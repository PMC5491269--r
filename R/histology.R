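#' Segment collagen bundles from a stained image
#'
#' Thresholds the stain channel, cleans it by morphological opening, labels
#' connected components, and returns one record per bundle with its centroid,
#' area and principal-axis orientation from second-order central image
#' moments. Coordinates are pixel centers, origin top-left, x rightward,
#' y downward; orientations are degrees counterclockwise from +x as
#' displayed, axial in `[0, 180)`.
#'
#' @param image 2-D nonnegative numeric matrix (rows = y, cols = x), or an
#'   already-binary mask.
#' @param min_area minimum component area in px^2; smaller components are
#'   dropped.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold fixed threshold used when `threshold_method = "fixed"`.
#' @param opening_radius disk radius for the morphological opening (0 skips
#'   it).
#' @return data.frame with columns `bundle_id`, `cx`, `cy`, `area`,
#'   `orientation` (degrees, `[0, 180)`), `eccentricity`; zero rows if the
#'   image has no foreground.
#' @examples
#' img <- matrix(0, 60, 120)
#' img[25:34, 20:99] <- 1   # horizontal 80 x 10 bar
#' segment_bundles(img)
#' @export
segment_bundles <- function(image, min_area = 40,
                            threshold_method = c("otsu", "fixed"),
                            threshold = 0.5, opening_radius = 1) {
  threshold_method <- match.arg(threshold_method)
  if (length(dim(image)) != 2) stop("image must be a 2-D matrix")
  if (any(image < 0)) stop("image must be nonnegative")
  if (all(image == 0)) return(empty_bundle_table())

  if (all(image %in% c(0, 1))) {
    mask <- image == 1
  } else {
    img01 <- image / max(image)
    thr <- if (threshold_method == "otsu")
      EBImage::otsu(EBImage::Image(t(img01))) else threshold
    mask <- img01 > thr
  }
  ebi <- EBImage::Image(t(mask) * 1)
  if (opening_radius > 0)
    ebi <- EBImage::opening(ebi, EBImage::makeBrush(2 * opening_radius + 1, "disc"))
  lbl <- EBImage::bwlabel(ebi)
  labels <- EBImage::imageData(lbl)   # [x, y]
  n_obj <- max(labels)
  if (n_obj == 0) return(empty_bundle_table())

  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  xs <- idx[, 1]; ys <- idx[, 2]
  recs <- lapply(seq_len(n_obj), function(k) {
    sel <- lab == k
    region_moments(xs[sel], ys[sel])
  })
  out <- do.call(rbind, recs)
  out <- out[out$area >= min_area, , drop = FALSE]
  if (nrow(out) == 0) return(empty_bundle_table())
  out$bundle_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("bundle_id", "cx", "cy", "area", "orientation", "eccentricity")]
}

empty_bundle_table <- function() {
  data.frame(bundle_id = integer(), cx = numeric(), cy = numeric(),
             area = numeric(), orientation = numeric(),
             eccentricity = numeric())
}

# Centroid, area, principal-axis orientation and eccentricity of a pixel set.
# y is flipped so the returned angle is CCW from +x on the displayed image.
region_moments <- function(xs, ys) {
  cx <- mean(xs); cy <- mean(ys)
  dx <- xs - cx; dy <- -(ys - cy)
  mxx <- mean(dx * dx); myy <- mean(dy * dy); mxy <- mean(dx * dy)
  theta <- fold_axial(0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi)
  tr <- mxx + myy
  det_ <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (tr + det_) / 2; l2 <- (tr - det_) / 2
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  data.frame(cx = cx, cy = cy, area = length(xs),
             orientation = theta, eccentricity = ecc)
}

#' Recover the epidermal boundary and dermis geometry from a mask
#'
#' Traces the epidermal edge of the dermis mask as an ordered left-to-right
#' polyline (one vertex per occupied column, at the boundary pixel nearest
#' the declared epidermis side) and measures the dermis area and the
#' epidermal contour length. Contour length is the arc length of the
#' polyline decimated to every `chord_step`-th vertex (chord summation
#' suppresses the pixel-staircase inflation of digitized boundaries) plus
#' one pixel of end extent, so a straight edge spanning `W` columns measures
#' exactly `W` px and smooth curves are measured to a few tenths of a
#' percent.
#'
#' @param dermis_mask logical/0-1 matrix (rows = y, cols = x).
#' @param side which image edge the epidermis faces: `"top"` (default),
#'   `"bottom"`.
#' @param largest_component if the mask is disconnected, set `TRUE` to keep
#'   only the largest connected component instead of erroring.
#' @param chord_step column stride of the chord summation for the contour
#'   length.
#' @return an object of class `dermis_geometry`: list with `dermis_mask`,
#'   `epidermis_polyline` (data.frame x, y), `contour_length` (px) and
#'   `dermis_area` (px^2).
#' @export
extract_epidermis <- function(dermis_mask, side = c("top", "bottom"),
                              largest_component = FALSE, chord_step = 4) {
  side <- match.arg(side)
  mask <- dermis_mask > 0
  if (!any(mask)) stop("dermis mask is empty")
  lbl <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  n_comp <- max(lbl)
  if (n_comp > 1) {
    if (!largest_component)
      stop("dermis mask has ", n_comp, " connected components; ",
           "set largest_component = TRUE to keep the largest one")
    labels <- t(EBImage::imageData(lbl))
    keep <- which.max(tabulate(labels[labels > 0]))
    mask <- labels == keep
  }
  cols <- which(colSums(mask) > 0)
  yv <- vapply(cols, function(j) {
    rows <- which(mask[, j])
    if (side == "top") min(rows) else max(rows)
  }, numeric(1))
  poly <- data.frame(x = cols, y = yv)
  idx <- unique(c(seq(1, nrow(poly), by = max(1, chord_step)), nrow(poly)))
  arc <- if (length(idx) > 1)
    sum(sqrt(diff(poly$x[idx])^2 + diff(poly$y[idx])^2)) else 0
  structure(list(dermis_mask = mask,
                 epidermis_polyline = poly,
                 contour_length = arc + 1,
                 dermis_area = sum(mask)),
            class = "dermis_geometry")
}

#' @export
print.dermis_geometry <- function(x, ...) {
  cat("dermis_geometry: area", x$dermis_area, "px^2, epidermal contour",
      round(x$contour_length, 1), "px,", nrow(x$epidermis_polyline),
      "polyline vertices\n")
  invisible(x)
}

# Axial tangent direction (degrees) of each polyline segment; y-down coords.
polyline_tangents <- function(poly) {
  dx <- diff(poly$x); dy <- diff(poly$y)
  fold_axial(atan2(-dy, dx) * 180 / pi)
}

#' Bundle angles relative to the epidermis
#'
#' Re-expresses each bundle's orientation relative to the epidermis tangent,
#' the reference direction the alignment score is defined against (an
#' epidermis-parallel bundle scores 0 degrees). With `reference = "global"`
#' the axial mean tangent of the whole polyline is used; with `"local"` the
#' tangent at the polyline vertex nearest each bundle centroid. All
#' arithmetic is axial; results are folded to `[0, 90]` when
#' `fold = TRUE` (default), else kept in `[0, 180)`.
#'
#' @param bundles data.frame from [segment_bundles()] (needs `orientation`,
#'   and `cx`, `cy` for the local reference).
#' @param geom a [extract_epidermis()] result.
#' @param reference `"global"` or `"local"`.
#' @param fold fold the relative angle to `[0, 90]`.
#' @return numeric vector of epidermis-relative angles in degrees.
#' @export
bundle_angles <- function(bundles, geom, reference = c("global", "local"),
                          fold = TRUE) {
  reference <- match.arg(reference)
  if (nrow(bundles) == 0) stop("bundle table is empty")
  tang <- polyline_tangents(geom$epidermis_polyline)
  if (reference == "global") {
    ref <- axial_mean(tang)
    rel <- bundles$orientation - ref
  } else {
    poly <- geom$epidermis_polyline
    mid_x <- (poly$x[-1] + poly$x[-nrow(poly)]) / 2
    mid_y <- (poly$y[-1] + poly$y[-nrow(poly)]) / 2
    nearest <- vapply(seq_len(nrow(bundles)), function(i) {
      which.min((mid_x - bundles$cx[i])^2 + (mid_y - bundles$cy[i])^2)
    }, integer(1))
    rel <- bundles$orientation - tang[nearest]
  }
  if (fold) axial_diff(rel, 0) else fold_axial(rel)
}

#' Dermis thickness: area over epidermal contour length
#'
#' For a rectangular dermis band this equals the band height; for curved
#' sections it is the average depth of the dermis below the epidermis.
#'
#' @param geom a [extract_epidermis()] result.
#' @return thickness in px.
#' @export
dermis_thickness <- function(geom) {
  if (geom$contour_length <= 0) stop("contour length must be > 0")
  geom$dermis_area / geom$contour_length
}

#' Total collagen: stained fraction of the dermis
#'
#' @param geom a [extract_epidermis()] result.
#' @param stain_mask logical/0-1 matrix of stain-positive pixels, same shape
#'   as the dermis mask.
#' @return fraction in `[0, 1]`.
#' @export
collagen_fraction <- function(geom, stain_mask) {
  if (!all(dim(stain_mask) == dim(geom$dermis_mask)))
    stop("stain mask and dermis mask shapes differ")
  sum((stain_mask > 0) & geom$dermis_mask) / sum(geom$dermis_mask)
}

#' Per-sample histology metrics from a slide
#'
#' Convenience wrapper running segmentation, epidermis extraction, the
#' epidermis-relative angles and the two-peak alignment score, returning the
#' three per-sample dermal metrics.
#'
#' @param image stained image matrix.
#' @param dermis_mask dermis mask matrix.
#' @param min_area,threshold_method,opening_radius passed to
#'   [segment_bundles()].
#' @param reference passed to [bundle_angles()].
#' @param seed seed for the mixture-fit restarts.
#' @param ... passed to [fit_two_peaks()].
#' @return list with `thickness`, `collagen_fraction`, `alignment_score`,
#'   `n_bundles`, plus the intermediate `bundles`, `geometry`, `angles`,
#'   `decomposition`.
#' @export
histology_metrics <- function(image, dermis_mask, min_area = 40,
                              threshold_method = "otsu", opening_radius = 1,
                              reference = "global", seed = 1, ...) {
  geom <- extract_epidermis(dermis_mask)
  bundles <- segment_bundles(image, min_area = min_area,
                             threshold_method = threshold_method,
                             opening_radius = opening_radius)
  if (nrow(bundles) == 0) stop("no bundles segmented from the image")
  ang <- bundle_angles(bundles, geom, reference = reference, fold = FALSE)
  dec <- fit_two_peaks(ang, seed = seed, ...)
  stain <- matrix(FALSE, nrow(image), ncol(image))
  if (all(image %in% c(0, 1))) {
    stain <- image == 1
  } else {
    stain <- image / max(image) > EBImage::otsu(EBImage::Image(t(image / max(image))))
  }
  list(thickness = dermis_thickness(geom),
       collagen_fraction = collagen_fraction(geom, stain),
       alignment_score = alignment_score(dec),
       n_bundles = nrow(bundles),
       bundles = bundles, geometry = geom, angles = ang,
       decomposition = dec)
}

#' Match segmented bundles to a ground-truth table
#'
#' Greedy one-to-one matching by centroid proximity (closest pairs first),
#' used for segmentation QC against the synthetic generator's truth table.
#'
#' @param bundles [segment_bundles()] output.
#' @param truth data.frame with `cx`, `cy`, `theta_deg` (a
#'   `synthetic_slide$truth_bundles`).
#' @param max_dist maximum centroid distance (px) for a valid match.
#' @return data.frame with one row per matched pair: `truth_id`, `seg_id`,
#'   `dist`, `angle_err` (axial degrees), plus attributes `recovery`
#'   (matched / truth rows).
#' @export
match_bundles <- function(bundles, truth, max_dist = 10) {
  if (nrow(bundles) == 0 || nrow(truth) == 0)
    return(structure(data.frame(truth_id = integer(), seg_id = integer(),
                                dist = numeric(), angle_err = numeric()),
                     recovery = 0))
  d <- outer(seq_len(nrow(truth)), seq_len(nrow(bundles)),
             Vectorize(function(i, j)
               sqrt((truth$cx[i] - bundles$cx[j])^2 +
                    (truth$cy[i] - bundles$cy[j])^2)))
  pairs <- list()
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > max_dist) break
    i <- (m - 1) %% nrow(d) + 1; j <- (m - 1) %/% nrow(d) + 1
    pairs[[length(pairs) + 1]] <- data.frame(
      truth_id = i, seg_id = bundles$bundle_id[j], dist = d[m],
      angle_err = axial_diff(truth$theta_deg[i], bundles$orientation[j]))
    d[i, ] <- Inf; d[, j] <- Inf
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(truth_id = integer(), seg_id = integer(),
               dist = numeric(), angle_err = numeric())
  attr(out, "recovery") <- nrow(out) / nrow(truth)
  out
}
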