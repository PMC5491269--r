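#' Specify a two-component axial orientation mixture
#'
#' Healthy dermis shows a basket-weave: two interleaved collagen bundle
#' populations at distinct axes, i.e. a balanced bimodal axial distribution.
#' Fibrotic dermis skews toward one axis (unimodal). The mixture weight `w`
#' of the dominant component is the ground-truth counterpart of the
#' alignment score.
#'
#' @param mu1,mu2 component axis locations in degrees, `[0, 180)`. For a
#'   declared unimodal spec (`w = 1`) `mu2` is ignored.
#' @param kappa axial concentration shared by both components (> 0).
#' @param w weight of component 1, in `[0, 1]`.
#' @return an object of class `orientation_mixture_spec`.
#' @examples
#' basket_weave <- orientation_mixture_spec(45, 135, kappa = 8, w = 0.5)
#' fibrotic     <- orientation_mixture_spec(40, 130, kappa = 8, w = 0.79)
#' @export
orientation_mixture_spec <- function(mu1, mu2 = NULL, kappa = 8, w = 0.5) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  if (is.null(mu2)) {
    if (w != 1) stop("mu2 may be omitted only for a unimodal spec (w = 1)")
    mu2 <- mu1
  }
  mu1 <- fold_axial(mu1); mu2 <- fold_axial(mu2)
  if (w < 1 && axial_diff(mu1, mu2) == 0)
    stop("mu1 and mu2 coincide; declare the spec unimodal with w = 1")
  structure(list(mu1 = mu1, mu2 = mu2, kappa = kappa, w = w),
            class = "orientation_mixture_spec")
}

#' Sample bundle orientations from a mixture spec
#'
#' @param spec an [orientation_mixture_spec()].
#' @param n number of orientations.
#' @return axial angles in degrees, `[0, 180)`. Uses the current RNG stream.
#' @export
sample_orientations <- function(spec, n) {
  stopifnot(inherits(spec, "orientation_mixture_spec"))
  from1 <- stats::runif(n) < spec$w
  out <- numeric(n)
  if (any(from1))  out[from1]  <- rvm_axial(sum(from1), spec$mu1, spec$kappa)
  if (any(!from1)) out[!from1] <- rvm_axial(sum(!from1), spec$mu2, spec$kappa)
  out
}

# Render one anti-aliased capsule (rounded-end bar) into `img` (rows = y,
# cols = x, origin top-left). Orientation theta in degrees, counterclockwise
# from +x on the displayed image, i.e. direction (cos t, -sin t) in (x, y).
render_capsule <- function(img, cx, cy, length_px, width_px, theta_deg) {
  t <- theta_deg * pi / 180
  ux <- cos(t); uy <- -sin(t)
  hl <- length_px / 2; hw <- width_px / 2
  pad <- hw + 1.5
  x0 <- max(1L, floor(cx - hl - pad)); x1 <- min(ncol(img), ceiling(cx + hl + pad))
  y0 <- max(1L, floor(cy - hl - pad)); y1 <- min(nrow(img), ceiling(cy + hl + pad))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  px <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  py <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
  s <- pmin(pmax(px * ux + py * uy, -hl + hw), hl - hw)  # clamp to the spine
  d <- sqrt((px - s * ux)^2 + (py - s * uy)^2)
  v <- pmin(pmax(hw + 0.5 - d, 0), 1)                    # 1-px soft edge
  img[ys, xs] <- pmax(img[ys, xs], v)
  img
}

# Shortest distance between two segments (capsule spines), for overlap tests
segseg_dist <- function(p1, d1, h1, p2, d2, h2) {
  # segments p +/- h*d, d unit vectors
  a1 <- p1 - h1 * d1; b1 <- p1 + h1 * d1
  a2 <- p2 - h2 * d2; b2 <- p2 + h2 * d2
  u <- b1 - a1; v <- b2 - a2; w <- a1 - a2
  a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  den <- a * c - b * b
  s <- if (den > 1e-12) min(max((b * e - c * d) / den, 0), 1) else 0
  t <- if (c > 1e-12) min(max((b * s + e) / c, 0), 1) else 0
  s <- if (a > 1e-12) min(max((b * t - d) / a, 0), 1) else 0
  p <- a1 + s * u; q <- a2 + t * v
  sqrt(sum((p - q)^2))
}

#' Generate a synthetic stained-slide image with ground truth
#'
#' Emulates a picrosirius-red-like section: a gently curved, near-horizontal
#' epidermis at the top of the canvas bounds a dermis band into which
#' elongated collagen bundles (anti-aliased capsules) are placed. Bundle
#' orientations are i.i.d. draws from the axial mixture `spec`; the true
#' bundle table, dermis mask and epidermis polyline are returned alongside
#' the image so segmentation and scoring can be validated pixel for pixel.
#'
#' Coordinates are pixel centers, origin top-left, x rightward, y downward;
#' orientations are degrees counterclockwise from +x as displayed, axial in
#' `[0, 180)`.
#'
#' @param spec an [orientation_mixture_spec()].
#' @param n_bundles number of bundles (>= 1).
#' @param geometry list with elements `length` (range, px), `width`
#'   (range, px) for bundle size sampling.
#' @param canvas `c(H, W)` image size in pixels.
#' @param seed integer seed; same `(spec, seed)` reproduces the slide
#'   bit for bit.
#' @param overlap if `FALSE` (default), bundles are placed by rejection
#'   sampling so capsules do not touch (>= `gap` px apart).
#' @param gap minimum clearance between capsule surfaces when
#'   `overlap = FALSE`.
#' @param epidermis_y baseline depth of the epidermis, px from the top.
#' @param epidermis_amp amplitude of the gentle epidermal undulation, px.
#' @param max_tries placement attempts per bundle before erroring.
#' @return an object of class `synthetic_slide`: list with `image` (H x W
#'   matrix in `[0, 1]`), `dermis_mask` (logical H x W), `epidermis_polyline`
#'   (data.frame x, y, one vertex per column), `truth_bundles` (data.frame
#'   bundle_id, cx, cy, length_px, width_px, theta_deg) and `seed`.
#' @examples
#' sl <- generate_slide(orientation_mixture_spec(45, 135, 8, 0.5),
#'                      n_bundles = 30, canvas = c(300, 400), seed = 1)
#' range(sl$truth_bundles$theta_deg)
#' @export
generate_slide <- function(spec, n_bundles,
                           geometry = list(length = c(30, 50), width = c(5, 8)),
                           canvas = c(600, 800), seed,
                           overlap = FALSE, gap = 2,
                           epidermis_y = 30, epidermis_amp = 6,
                           max_tries = 4000) {
  stopifnot(inherits(spec, "orientation_mixture_spec"))
  if (missing(seed)) stop("seed is required")
  if (n_bundles < 1) stop("n_bundles must be >= 1")
  H <- canvas[1]; W <- canvas[2]
  max_len <- max(geometry$length)
  if (H - epidermis_y - epidermis_amp < max_len + 10 || W < max_len + 10)
    stop("canvas too small for the requested bundle length below the epidermis")

  with_seed(seed, {
    # epidermis: gently curved near-horizontal polyline, one vertex per column
    xs <- seq_len(W)
    phase <- stats::runif(1, 0, 2 * pi)
    ye <- epidermis_y + epidermis_amp * sin(2 * pi * xs / W + phase)
    epi <- data.frame(x = xs, y = ye)

    dermis <- outer(seq_len(H), ye, function(y, b) y > b)  # H x W logical

    thetas <- sample_orientations(spec, n_bundles)
    lens <- stats::runif(n_bundles, geometry$length[1], geometry$length[2])
    wids <- stats::runif(n_bundles, geometry$width[1], geometry$width[2])

    cxs <- cys <- numeric(n_bundles)
    dirs <- cbind(cos(thetas * pi / 180), -sin(thetas * pi / 180))
    for (i in seq_len(n_bundles)) {
      margin <- lens[i] / 2 + wids[i] / 2 + 2
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- stats::runif(1, margin, W - margin)
        top <- max(ye[max(1, floor(cx - margin)):min(W, ceiling(cx + margin))])
        cy <- stats::runif(1, top + margin, H - margin)
        if (overlap) { placed <- TRUE } else {
          ok <- TRUE
          if (i > 1) for (j in seq_len(i - 1)) {
            lim <- (wids[i] + wids[j]) / 2 + gap
            if (abs(cx - cxs[j]) < (lens[i] + lens[j]) / 2 + lim &&
                abs(cy - cys[j]) < (lens[i] + lens[j]) / 2 + lim) {
              d <- segseg_dist(c(cx, cy), dirs[i, ], (lens[i] - wids[i]) / 2,
                               c(cxs[j], cys[j]), dirs[j, ], (lens[j] - wids[j]) / 2)
              if (d < lim) { ok <- FALSE; break }
            }
          }
          placed <- ok
        }
        if (placed) { cxs[i] <- cx; cys[i] <- cy; break }
      }
      if (!placed) stop("could not place bundle ", i,
                        " without overlap; enlarge the canvas or allow overlap")
    }

    img <- matrix(0, H, W)
    for (i in seq_len(n_bundles))
      img <- render_capsule(img, cxs[i], cys[i], lens[i], wids[i], thetas[i])

    structure(list(
      image = img,
      dermis_mask = dermis,
      epidermis_polyline = epi,
      truth_bundles = data.frame(
        bundle_id = seq_len(n_bundles), cx = cxs, cy = cys,
        length_px = lens, width_px = wids, theta_deg = thetas),
      seed = seed
    ), class = "synthetic_slide")
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat("synthetic_slide:", nrow(x$image), "x", ncol(x$image), "px,",
      nrow(x$truth_bundles), "bundles, seed", x$seed, "\n")
  invisible(x)
}

#' Write / read a synthetic slide as plain files
#'
#' The image is written as a single-channel PNG (or TIFF by extension), the
#' truth table and epidermis polyline as CSVs.
#'
#' @param slide a `synthetic_slide`.
#' @param image_path output image path (`.png` or `.tif`/`.tiff`).
#' @param truth_path,epidermis_path CSV paths; defaults are derived from
#'   `image_path`.
#' @return `write_slide()` returns the written paths invisibly.
#' @export
write_slide <- function(slide, image_path,
                        truth_path = sub("\\.[^.]+$", "_truth.csv", image_path),
                        epidermis_path = sub("\\.[^.]+$", "_epidermis.csv", image_path)) {
  write_image(slide$image, image_path)
  utils::write.csv(slide$truth_bundles, truth_path, row.names = FALSE)
  utils::write.csv(slide$epidermis_polyline, epidermis_path, row.names = FALSE)
  invisible(c(image = image_path, truth = truth_path, epidermis = epidermis_path))
}

#' Read a grayscale image into a matrix
#'
#' @param path a `.png`, `.tif` or `.tiff` file.
#' @return numeric matrix (rows = y, cols = x) in `[0, 1]`; multi-channel
#'   images are averaged to grayscale.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  a
}

#' @rdname read_image
#' @param img numeric matrix in `[0, 1]`.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(img, 0), 1)
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}
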