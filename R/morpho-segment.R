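#' Configuration for junction-image morphometry
#'
#' Parameters of the image-to-cells pipeline: a grayscale maximum filter and
#' Gaussian blur regularize the junction staining, a threshold binarizes it,
#' the inverted mask is labeled into cell interiors, and junction pixels are
#' assigned to the nearest interior (Voronoi influence zones). A second pass
#' fills holes, dilates labels, and excludes edge-touching and undersized
#' cells.
#'
#' @param max_filter_radius_px Radius of the disc maximum filter, pixels.
#' @param gaussian_sigma_px Sd of the Gaussian blur, pixels.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold on the 0--1 intensity scale when
#'   `threshold_method = "fixed"`.
#' @param connectivity Pixel connectivity for interior labeling, 4 or 8.
#' @param label_dilation_px Label dilation radius applied during
#'   post-filtering; labels grow into unassigned pixels only.
#' @param min_cell_area_px Labels smaller than this are discarded.
#' @param geodesic_metric `"chamfer_1_sqrt2"` (axial steps cost 1, diagonal
#'   steps sqrt(2)) or `"unit_8conn"` (all steps cost 1).
#' @return An object of class `morphometry_config`.
#' @export
morphometry_config <- function(max_filter_radius_px = 2,
                               gaussian_sigma_px = 2,
                               threshold_method = c("otsu", "fixed"),
                               fixed_threshold = 0.5,
                               connectivity = 4,
                               label_dilation_px = 1,
                               min_cell_area_px = 50,
                               geodesic_metric = c("chamfer_1_sqrt2",
                                                   "unit_8conn")) {
  threshold_method <- match.arg(threshold_method)
  geodesic_metric <- match.arg(geodesic_metric)
  check_scalar(max_filter_radius_px, "max_filter_radius_px", lower = 1,
               integerish = TRUE)
  check_scalar(gaussian_sigma_px, "gaussian_sigma_px", lower = 0,
               strict_lower = TRUE)
  check_scalar(fixed_threshold, "fixed_threshold")
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8")
  check_scalar(label_dilation_px, "label_dilation_px", lower = 0,
               integerish = TRUE)
  check_scalar(min_cell_area_px, "min_cell_area_px", lower = 0,
               integerish = TRUE)
  structure(
    list(max_filter_radius_px = as.integer(max_filter_radius_px),
         gaussian_sigma_px = gaussian_sigma_px,
         threshold_method = threshold_method,
         fixed_threshold = fixed_threshold,
         connectivity = as.integer(connectivity),
         label_dilation_px = as.integer(label_dilation_px),
         min_cell_area_px = as.integer(min_cell_area_px),
         geodesic_metric = geodesic_metric),
    class = "morphometry_config")
}

chamfer_diag_weight <- function(config) {
  if (config$geodesic_metric == "chamfer_1_sqrt2") sqrt(2) else 1
}

as_image_matrix <- function(image) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (!is.matrix(image) || !is.numeric(image))
    abort("`image` must be a numeric matrix (or EBImage Image)")
  if (nrow(image) < 64 || ncol(image) < 64)
    abort("`image` must be at least 64 x 64 pixels")
  if (!all(is.finite(image))) abort("`image` contains non-finite values")
  image
}

#' Binarize a junction-stained image
#'
#' Applies a grayscale maximum filter of the configured radius, Gaussian
#' smoothing, and a threshold (Otsu by default). The returned mask is 1 on
#' junction signal, 0 on cell interiors.
#'
#' @param image Numeric matrix of intensities (any non-degenerate range).
#' @param config A [morphometry_config()].
#' @return Integer matrix mask, 1 = junction.
#' @export
preprocess_junctions <- function(image, config = morphometry_config()) {
  img <- as_image_matrix(image)
  rng <- range(img)
  if (rng[1] == rng[2])
    abort("no junction signal: image intensity is constant")
  img <- (img - rng[1]) / (rng[2] - rng[1])
  e <- EBImage::as.Image(img)
  brush <- EBImage::makeBrush(2L * config$max_filter_radius_px + 1L, "disc")
  e <- EBImage::dilate(e, brush)            # grayscale max filter
  e <- EBImage::gblur(e, sigma = config$gaussian_sigma_px)
  thr <- if (config$threshold_method == "otsu") {
    EBImage::otsu(e, range = range(EBImage::imageData(e)))
  } else {
    config$fixed_threshold
  }
  mask <- matrix(as.integer(EBImage::imageData(e) > thr),
                 nrow(img), ncol(img))
  if (all(mask == 1L) || all(mask == 0L))
    abort("no junction signal: thresholding produced a trivial mask")
  mask
}

new_cell_label_map <- function(labels, config) {
  structure(list(labels = labels, config = config), class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("<cell_label_map> %d x %d px, %d labels\n",
              nrow(x$labels), ncol(x$labels), max(x$labels)))
  invisible(x)
}

#' Partition a junction mask into labeled cells
#'
#' Labels the connected components of the inverted mask (cell interiors)
#' under the configured connectivity, then assigns every junction pixel to
#' the chamfer-nearest interior label (geometric Voronoi influence zones),
#' so that label ownership is a total function on the frame.
#'
#' @param mask Binary junction mask from [preprocess_junctions()].
#' @param config A [morphometry_config()].
#' @return A `cell_label_map`.
#' @export
partition_cells <- function(mask, config = morphometry_config()) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L)))
    abort("`mask` must be a binary matrix")
  if (all(mask == 1L)) abort("mask is all foreground; no cell interiors")
  interiors <- cpp_label_components(matrix(as.integer(mask == 0L),
                                           nrow(mask), ncol(mask)),
                                    config$connectivity)
  if (max(interiors) == 0L) abort("no interior components found")
  labels <- cpp_influence_zones(interiors, chamfer_diag_weight(config), Inf)
  new_cell_label_map(labels, config)
}

#' Post-filter a cell label map
#'
#' Fills holes inside labels, dilates labels into unassigned pixels by the
#' configured radius (never overwriting other labels), removes labels that
#' touch the image border or fall below the minimum area, and renumbers the
#' survivors contiguously in their original order.
#'
#' @param labelmap A `cell_label_map` from [partition_cells()].
#' @param config A [morphometry_config()]; defaults to the map's own.
#' @return A filtered `cell_label_map` (possibly empty, with a message).
#' @export
postfilter_labels <- function(labelmap, config = NULL) {
  stopifnot(inherits(labelmap, "cell_label_map"))
  config <- config %||% labelmap$config
  lab <- labelmap$labels
  lab <- matrix(as.integer(EBImage::imageData(
    EBImage::fillHull(EBImage::as.Image(lab)))), nrow(lab), ncol(lab))
  if (config$label_dilation_px > 0 && any(lab == 0L))
    lab <- cpp_influence_zones(lab, chamfer_diag_weight(config),
                               config$label_dilation_px)
  edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  lab[lab %in% edge] <- 0L
  if (config$min_cell_area_px > 0 && max(lab) > 0L) {
    areas <- tabulate(lab, nbins = max(lab))
    small <- which(areas > 0L & areas < config$min_cell_area_px)
    lab[lab %in% small] <- 0L
  }
  kept <- sort(unique(lab[lab > 0L]))
  if (length(kept) == 0L) {
    inform("post-filtering removed every label")
    lab[] <- 0L
  } else {
    remap <- integer(max(kept))
    remap[kept] <- seq_along(kept)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  new_cell_label_map(lab, config)
}
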