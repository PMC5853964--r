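## Starch-granule morphometry: binarize micrographs, split touching
## granules by distance-transform watershed, measure particle areas, and
## summarize the size distribution with the two-pass area cutoffs
## (0.785 um^2 ~ 1 um diameter; 78.5 um^2 ~ 10 um diameter).

#' Area of a circle of given diameter
#'
#' Helper for converting diameter cutoffs (in micrometres) to the
#' particle-area thresholds used by [granule_stats()]:
#' `circle_area(1) ~ 0.785`, `circle_area(10) ~ 78.5` square
#' micrometres.
#'
#' @param diameter circle diameter.
#' @return area `pi * (diameter / 2)^2` in squared units of `diameter`.
#' @export
circle_area <- function(diameter) pi * (diameter / 2)^2

as_gray_matrix <- function(img) {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  img <- as.matrix(img)
  if (!all(is.finite(img))) stop("image intensities must be finite", call. = FALSE)
  mx <- max(img)
  if (mx > 1) img <- img / ifelse(mx > 255, 65535, 255)
  img
}

#' Binarize a grayscale micrograph
#'
#' Thresholds a grayscale image into a granule mask. The default rule is
#' Otsu's automatic global threshold; a fixed threshold may be supplied
#' instead. Granules are assumed dark on a light background (iodine
#' stained, bright field); set `invert = TRUE` for inverted-contrast
#' images.
#'
#' @param img numeric matrix (any integer range; rescaled to `[0, 1]`)
#'   or an `EBImage::Image`.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold intensity threshold in `[0, 1]` when
#'   `method = "fixed"`.
#' @param invert flip image contrast before thresholding.
#' @return logical matrix; `TRUE` marks granule (foreground) pixels. A
#'   blank (constant) image yields an empty mask with a notice.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL,
                     invert = FALSE) {
  method <- match.arg(method)
  img <- as_gray_matrix(img)
  if (invert) img <- max(img) + min(img) - img
  if (diff(range(img)) < 1e-8) {
    message("binarize: blank image; returning empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  thr <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(img))
  } else {
    if (is.null(threshold)) stop("`threshold` required for method = 'fixed'",
                                 call. = FALSE)
    threshold
  }
  img < thr
}

#' Split touching granules by distance-transform watershed
#'
#' Computes the Euclidean distance map of the mask and applies a
#' watershed transform, so each foreground pixel receives exactly one
#' particle label and moderately overlapping convex particles are
#' separated.
#'
#' @param mask logical matrix from [binarize()].
#' @param tolerance minimum object-height difference in the distance map
#'   for two catchment basins to remain distinct (default 1 pixel).
#' @param ext neighbourhood radius used by the watershed (default 1).
#' @return integer matrix of particle labels (0 = background).
#' @export
split_touching <- function(mask, tolerance = 1, ext = 1) {
  mask <- as.matrix(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- EBImage::watershed(d, tolerance = tolerance, ext = ext)
  m <- EBImage::imageData(labels)
  storage.mode(m) <- "integer"
  m
}

#' Measure particle areas
#'
#' Converts a labelled particle image to physical areas. Particles
#' touching the image border are excluded by default because their
#' visible area underestimates the granule.
#'
#' @param labels integer label matrix from [split_touching()].
#' @param scale micrometres per pixel (> 0).
#' @param exclude_border drop border-touching labels (default `TRUE`).
#' @param image_id identifier recorded with the measurements.
#' @return data frame of class `particle_set` with columns `label`,
#'   `pixels`, `area` (um^2); attributes `image_id` and `scale`.
#' @export
measure_particles <- function(labels, scale, exclude_border = TRUE,
                              image_id = "image") {
  if (!is.numeric(scale) || scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  labels <- as.matrix(labels)
  ids <- sort(unique(labels[labels > 0]))
  if (exclude_border && length(ids)) {
    edge <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
    ids <- setdiff(ids, edge)
  }
  if (length(ids)) {
    px <- tabulate(labels, nbins = max(ids))[ids]
    out <- data.frame(label = ids, pixels = px, area = px * scale^2)
  } else {
    out <- data.frame(label = integer(), pixels = integer(), area = numeric())
  }
  structure(out, class = c("particle_set", "data.frame"),
            image_id = image_id, scale = scale)
}

#' Granule size statistics over one or more images
#'
#' Two-pass particle analysis. Pass 1 counts all particles with area at
#' least `small_min_area` (diameter >= 1 um by default: A- plus
#' B-granules); pass 2 counts particles with area between
#' `small_min_area` and `small_max_area` inclusive (1-10 um diameter:
#' the small-granule class including B-granules). The per-image
#' percentage of small granules is `100 * pass2 / pass1`; the sample
#' value is the mean over images. Class mean areas are computed over the
#' pooled particles of each class.
#'
#' @param particles a `particle_set` or list of them (one per image).
#' @param small_min_area lower area cutoff in um^2, inclusive (default
#'   0.785, a 1 um diameter circle).
#' @param small_max_area upper area cutoff of the small class in um^2,
#'   inclusive (default 78.5, a 10 um diameter circle).
#' @return list of class `granule_stats`: `per_image` (image_id,
#'   n_total, n_small, pct_small), `pct_small` (sample mean),
#'   `mean_small_area`, `mean_large_area`, `n_images` (images with at
#'   least one qualifying particle; others are excluded with a notice).
#' @export
granule_stats <- function(particles, small_min_area = 0.785,
                          small_max_area = 78.5) {
  if (inherits(particles, "particle_set")) particles <- list(particles)
  if (!length(particles)) stop("at least one image is required", call. = FALSE)
  per <- lapply(particles, function(p) {
    a <- p$area
    n_total <- sum(a >= small_min_area)
    n_small <- sum(a >= small_min_area & a <= small_max_area)
    data.frame(image_id = attr(p, "image_id") %||% "image",
               n_total = n_total, n_small = n_small,
               pct_small = if (n_total > 0) 100 * n_small / n_total else NA_real_)
  })
  per <- do.call(rbind, per)
  if (any(per$n_total == 0))
    message("granule_stats: ", sum(per$n_total == 0),
            " image(s) with no qualifying particles excluded from the mean")
  keep <- per$n_total > 0
  pooled <- unlist(lapply(particles, function(p) p$area))
  small <- pooled[pooled >= small_min_area & pooled <= small_max_area]
  large <- pooled[pooled > small_max_area]
  structure(list(
    per_image = per,
    pct_small = mean(per$pct_small[keep]),
    mean_small_area = if (length(small)) mean(small) else NA_real_,
    mean_large_area = if (length(large)) mean(large) else NA_real_,
    n_images = sum(keep),
    small_min_area = small_min_area,
    small_max_area = small_max_area
  ), class = "granule_stats")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.granule_stats <- function(x, ...) {
  cat("Granule size statistics over", x$n_images, "image(s)\n")
  cat(sprintf("  %% small granules (%.3g-%.3g um^2): %.1f%%\n",
              x$small_min_area, x$small_max_area, x$pct_small))
  cat(sprintf("  mean small-granule area: %.1f um^2; mean large-granule area: %.1f um^2\n",
              x$mean_small_area, x$mean_large_area))
  invisible(x)
}

#' Run the full granule-measurement pipeline on one image
#'
#' Convenience wrapper: [binarize()], [split_touching()],
#' [measure_particles()].
#'
#' @param img grayscale image matrix.
#' @param scale micrometres per pixel.
#' @param image_id identifier for the image.
#' @param ... passed to [binarize()].
#' @return a `particle_set`.
#' @export
measure_image <- function(img, scale, image_id = "image", ...) {
  mask <- binarize(img, ...)
  labels <- split_touching(mask)
  measure_particles(labels, scale = scale, image_id = image_id)
}

#' Starch swelling power
#'
#' Weight of the swollen starch pellet (starch plus retained water after
#' heating in excess water) divided by the starch dry weight;
#' dimensionless, lower bound 1.
#'
#' @param dry_weight starch dry weight (mg, > 0).
#' @param swollen_weight swollen pellet weight (mg, >= `dry_weight`).
#' @return numeric ratio.
#' @export
swelling_power <- function(dry_weight, swollen_weight) {
  if (any(dry_weight <= 0)) stop("`dry_weight` must be > 0", call. = FALSE)
  if (any(swollen_weight < dry_weight))
    stop("`swollen_weight` must be at least `dry_weight`", call. = FALSE)
  swollen_weight / dry_weight
}
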