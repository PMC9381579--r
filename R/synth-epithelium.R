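#' Specification for a synthetic junction-stained epithelium
#'
#' Describes a simulated monolayer image of the kind produced by ZO-1
#' immunostaining: a Voronoi tessellation of cell seeds rendered as a bright
#' junction band over dark cell interiors, with optional blur and noise.
#' Regularity and irregularity are controlled independently:
#' `lloyd_iterations` centroidal relaxation steps make the tessellation
#' honeycomb-like, then Gaussian seed jitter of sd `jitter_sigma_px`
#' re-introduces shape and size heterogeneity.
#'
#' @param width_px,height_px Image size in pixels.
#' @param n_cells Number of cell seeds.
#' @param lloyd_iterations Number of centroidal (Lloyd) relaxation steps.
#' @param jitter_sigma_px Sd of Gaussian seed displacement applied after
#'   relaxation, in pixels. 0 gives the most regular monolayer.
#' @param junction_width_px Width of the rendered junction band, pixels.
#' @param background_margin_px Width of the dark frame around the
#'   tessellation; ground-truth polygons are clipped to the inner rectangle.
#' @param noise_sd Sd of additive Gaussian intensity noise (image is on
#'   a 0--1 scale).
#' @param blur_sigma_px Sd of the Gaussian blur applied to the rendered
#'   image, pixels. 0 disables blurring.
#' @param rng_seed Integer seed; identical specs give bit-identical output.
#' @return An object of class `epithelium_spec`.
#' @export
epithelium_spec <- function(width_px = 512, height_px = 512, n_cells = 150,
                            lloyd_iterations = 20, jitter_sigma_px = 0,
                            junction_width_px = 3, background_margin_px = 8,
                            noise_sd = 0.02, blur_sigma_px = 1,
                            rng_seed = 1L) {
  check_scalar(width_px, "width_px", lower = 64, integerish = TRUE)
  check_scalar(height_px, "height_px", lower = 64, integerish = TRUE)
  check_scalar(n_cells, "n_cells", lower = 1, integerish = TRUE)
  check_scalar(lloyd_iterations, "lloyd_iterations", lower = 0,
               integerish = TRUE)
  check_scalar(jitter_sigma_px, "jitter_sigma_px", lower = 0)
  check_scalar(junction_width_px, "junction_width_px", lower = 0,
               strict_lower = TRUE)
  if (junction_width_px >= min(width_px, height_px) / 4)
    abort("`junction_width_px` must be < min(width, height) / 4")
  check_scalar(background_margin_px, "background_margin_px", lower = 0,
               integerish = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(blur_sigma_px, "blur_sigma_px", lower = 0)
  check_scalar(rng_seed, "rng_seed", integerish = TRUE)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         n_cells = as.integer(n_cells),
         lloyd_iterations = as.integer(lloyd_iterations),
         jitter_sigma_px = jitter_sigma_px,
         junction_width_px = junction_width_px,
         background_margin_px = as.integer(background_margin_px),
         noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
         rng_seed = as.integer(rng_seed)),
    class = "epithelium_spec")
}

# nearest and second-nearest seed for a set of points (squared Euclidean)
nearest_two_seeds <- function(px, py, sx, sy) {
  cpp_nearest_two(px, py, sx, sy)
}

# Sutherland-Hodgman clip of a convex polygon (n x 2 matrix) by the
# half-plane {x : a . x <= b}
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  s <- as.numeric(poly %*% a) - b
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- s[i] <= 0; pj_in <- s[j] <= 0
    if (pi_in) out <- rbind(out, poly[i, ])
    if (xor(pi_in, pj_in)) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cell of seed i clipped to the rectangle [x0,x1] x [y0,y1],
# via half-plane intersection against every other seed
voronoi_cell_polygon <- function(i, sx, sy, x0, x1, y0, y1) {
  poly <- cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  si <- c(sx[i], sy[i])
  for (j in seq_along(sx)) {
    if (j == i) next
    sj <- c(sx[j], sy[j])
    a <- sj - si
    b <- (sum(sj^2) - sum(si^2)) / 2
    poly <- clip_halfplane(poly, a, b)
    if (nrow(poly) == 0L) break
  }
  poly
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

polygon_perimeter <- function(poly) {
  n <- nrow(poly)
  if (n < 2L) return(0)
  j <- c(2:n, 1L)
  sum(sqrt(rowSums((poly[j, , drop = FALSE] - poly)^2)))
}

# exact shape descriptors of a (convex) planar polygon; the geodesic
# diameter of a convex region equals its largest vertex-to-vertex distance
polygon_metrics <- function(poly) {
  hull <- poly[chull(poly), , drop = FALSE]
  per <- polygon_perimeter(poly)
  hull_per <- polygon_perimeter(hull)
  d <- 0
  if (nrow(poly) >= 2L) d <- max(dist(poly))
  tibble(area_px = polygon_area(poly), perimeter_px = per,
         convex_perimeter_px = hull_per,
         convexity = if (per > 0) hull_per / per else NA_real_,
         geodesic_diameter_px = d)
}

#' Simulate a junction-stained epithelium image with geometric ground truth
#'
#' Places `n_cells` seeds uniformly at random, applies Lloyd relaxation and
#' Gaussian jitter, rasterizes the Voronoi tessellation of the final seeds
#' (bright junction band of the configured width, dark interiors), then
#' blurs and adds noise. The exact Voronoi polygons, clipped to the image
#' minus the background margin, are returned together with their
#' geometrically computed shape metrics.
#'
#' @param spec An [epithelium_spec()].
#' @param max_retries Number of times the seed jitter is redrawn if two
#'   seeds land closer than twice the junction width.
#' @return A list of class `epithelium` with elements `image` (height x
#'   width numeric matrix on 0--1), `truth` (seeds, polygons, and a tibble
#'   of per-cell metrics), and `spec`.
#' @export
simulate_epithelium <- function(spec, max_retries = 50L) {
  stopifnot(inherits(spec, "epithelium_spec"))
  W <- spec$width_px; H <- spec$height_px; n <- spec$n_cells
  with_seed(spec$rng_seed, {
    sx <- runif(n, 0, W); sy <- runif(n, 0, H)

    # centroidal relaxation on a coarse grid keeps the cost flat
    if (spec$lloyd_iterations > 0 && n > 1) {
      stride <- max(1L, floor(min(W, H) / 128))
      gx <- seq(stride / 2, W, by = stride)
      gy <- seq(stride / 2, H, by = stride)
      grid <- expand.grid(x = gx, y = gy)
      for (it in seq_len(spec$lloyd_iterations)) {
        owner <- nearest_two_seeds(grid$x, grid$y, sx, sy)$i1
        cx <- tapply(grid$x, factor(owner, levels = seq_len(n)), mean)
        cy <- tapply(grid$y, factor(owner, levels = seq_len(n)), mean)
        keep <- !is.na(cx)
        sx[keep] <- cx[keep]; sy[keep] <- cy[keep]
      }
    }

    # jitter with a bounded resample on seed collisions
    if (n > 1) {
      base_x <- sx; base_y <- sy
      for (attempt in seq_len(max_retries + 1L)) {
        sx <- base_x + rnorm(n, 0, spec$jitter_sigma_px)
        sy <- base_y + rnorm(n, 0, spec$jitter_sigma_px)
        sx <- pmin(pmax(sx, 0), W); sy <- pmin(pmax(sy, 0), H)
        if (min(dist(cbind(sx, sy))) >= 2 * spec$junction_width_px) break
        if (attempt == max_retries + 1L)
          abort("seeds collide after jitter; increase spacing or reduce jitter")
        inform("seed collision after jitter; resampling displacement")
      }
    }

    # exact truth polygons, clipped to the image minus the margin
    m <- spec$background_margin_px
    polys <- lapply(seq_len(n), voronoi_cell_polygon, sx = sx, sy = sy,
                    x0 = m, x1 = W - m, y0 = m, y1 = H - m)
    metrics <- purrr::map_dfr(polys, polygon_metrics)
    metrics <- mutate(metrics, cell_id = seq_len(n), .before = 1)

    # rasterize: pixel (r, c) has center (c - 0.5, r - 0.5)
    px <- rep(seq_len(W) - 0.5, each = H)
    py <- rep(seq_len(H) - 0.5, times = W)
    nn <- nearest_two_seeds(px, py, sx, sy)
    img <- matrix(0.1, H, W)
    if (n > 1) {
      seed_d <- as.matrix(dist(cbind(sx, sy)))
      sep <- seed_d[cbind(nn$i1, nn$i2)]
      # distance from the pixel center to the bisector of its two nearest
      # seeds; pixels closer than half the band width are junction
      bis <- (nn$d2 - nn$d1) / (2 * sep)
      img[bis < spec$junction_width_px / 2] <- 0.9
    }
    if (m > 0) {
      img[c(seq_len(m), H - seq_len(m) + 1L), ] <- 0.05
      img[, c(seq_len(m), W - seq_len(m) + 1L)] <- 0.05
    }
    if (spec$blur_sigma_px > 0)
      img <- as.matrix(EBImage::gblur(EBImage::as.Image(img),
                                      sigma = spec$blur_sigma_px))
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    img <- pmin(pmax(img, 0), 1)

    structure(
      list(image = img,
           truth = list(seeds = tibble(cell_id = seq_len(n), x = sx, y = sy),
                        polygons = polys, metrics = metrics),
           spec = spec),
      class = "epithelium")
  })
}

#' Write a simulated epithelium to disk
#'
#' Writes the image as 16-bit grayscale TIFF, the ground-truth metrics as
#' TSV, and a JSON manifest recording the generating spec.
#'
#' @param x An `epithelium` from [simulate_epithelium()].
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_epithelium <- function(x, dir) {
  stopifnot(inherits(x, "epithelium"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(x$image, file.path(dir, "epithelium.tif"),
                  bits.per.sample = 16L)
  readr::write_tsv(x$truth$metrics, file.path(dir, "truth_metrics.tsv"))
  write_manifest(run_manifest("epithelium", x$spec, x$spec$rng_seed,
                              list(n_cells = x$spec$n_cells)),
                 file.path(dir, "manifest.json"))
  invisible(dir)
}
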