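# Independent oracles and fixture builders shared across tests.

# Exact geodesic diameter by all-pairs Dijkstra on the pixel adjacency
# graph (igraph), under the same chamfer weights as the implementation.
oracle_geodesic <- function(mask, wdiag = sqrt(2)) {
  idx <- which(mask)
  if (length(idx) < 2) return(0)
  H <- nrow(mask)
  id_of <- integer(length(mask))
  id_of[idx] <- seq_along(idx)
  edges <- integer(0)
  w <- numeric(0)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))
  pos_r <- (idx - 1) %% H + 1
  pos_c <- (idx - 1) %/% H + 1
  for (k in 1:4) {
    nr <- pos_r + offs[k, 1]
    nc <- pos_c + offs[k, 2]
    ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= ncol(mask)
    nidx <- (nc - 1) * H + nr
    ok[ok] <- mask[nidx[ok]]
    edges <- c(edges, rbind(id_of[idx[ok]], id_of[nidx[ok]]))
    w <- c(w, rep(if (all(offs[k, ] != 0)) wdiag else 1, sum(ok)))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  d <- igraph::distances(g, weights = w)
  if (any(is.infinite(d))) stop("oracle mask is not connected")
  max(d)
}

# largest connected component of a logical matrix
largest_component <- function(m) {
  lab <- rpekit:::cpp_label_components(matrix(as.integer(m), nrow(m)), 8)
  if (max(lab) == 0) return(m & FALSE)
  sizes <- tabulate(lab)
  lab == which.max(sizes)
}

# a zoo of connected test shapes (<= 2000 px): bars, L/U shapes, spirals,
# random disc blobs, and rasterized Voronoi cells
make_shape <- function(kind, seed) {
  set.seed(seed)
  switch(kind,
    bar = {
      m <- matrix(FALSE, 12, 60)
      h <- sample(1:4, 1)
      m[5:(4 + h), 3:58] <- TRUE
      m
    },
    L = {
      m <- matrix(FALSE, 30, 30)
      wds <- sample(3:6, 1)
      m[3:28, 3:(2 + wds)] <- TRUE
      m[(29 - wds):28, 3:28] <- TRUE
      m
    },
    U = {
      m <- matrix(FALSE, 24, 24)
      m[3:22, 3:5] <- TRUE
      m[20:22, 3:21] <- TRUE
      m[3:22, 19:21] <- TRUE
      m
    },
    spiral = {
      m <- matrix(FALSE, 41, 41)
      t <- seq(0, 6 * pi, length.out = 4000)
      r <- 1 + t
      x <- round(21 + r * cos(t) * 18 / max(r))
      y <- round(21 + r * sin(t) * 18 / max(r))
      ok <- x >= 1 & x <= 41 & y >= 1 & y <= 41
      m[cbind(y[ok], x[ok])] <- TRUE
      largest_component(m)
    },
    blob = {
      m <- matrix(FALSE, 40, 40)
      xs <- matrix(rep(1:40, 40), 40)
      ys <- t(xs)
      for (j in seq_len(sample(2:4, 1))) {
        cx <- sample(10:30, 1); cy <- sample(10:30, 1)
        r <- sample(3:8, 1)
        m <- m | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
      }
      largest_component(m)
    },
    voronoi_cell = {
      spec <- epithelium_spec(width_px = 128, height_px = 128,
                              n_cells = 12, lloyd_iterations = 5,
                              jitter_sigma_px = 4, noise_sd = 0,
                              blur_sigma_px = 0, rng_seed = seed)
      epi <- simulate_epithelium(spec)
      lab <- raster_truth_labels(epi)
      interior <- setdiff(unique(as.vector(lab)),
                          unique(c(lab[1, ], lab[128, ], lab[, 1],
                                   lab[, 128])))
      l <- interior[sample(length(interior), 1)]
      px <- which(lab == l, arr.ind = TRUE)
      m <- matrix(FALSE, diff(range(px[, 1])) + 1, diff(range(px[, 2])) + 1)
      m[cbind(px[, 1] - min(px[, 1]) + 1, px[, 2] - min(px[, 2]) + 1)] <- TRUE
      largest_component(m)
    },
    stop("unknown shape kind"))
}

# noise-free label map from generator truth: every pixel owned by its
# nearest seed (the rasterized truth polygons, no junction band)
raster_truth_labels <- function(epi) {
  W <- epi$spec$width_px
  H <- epi$spec$height_px
  px <- rep(seq_len(W) - 0.5, each = H)
  py <- rep(seq_len(H) - 0.5, times = W)
  nn <- rpekit:::cpp_nearest_two(px, py, epi$truth$seeds$x,
                                 epi$truth$seeds$y)
  matrix(nn$i1, H, W)
}

# label map object around a plain integer matrix
as_label_map <- function(labels, config = morphometry_config()) {
  rpekit:::new_cell_label_map(labels, config)
}

# brute-force row predicate for the DEG filter
brute_deg <- function(stats, fc_min, alpha, alpha_column, expressed) {
  out <- character(0)
  for (i in seq_len(nrow(stats))) {
    r <- stats[i, ]
    if (abs(r$log2fc) >= log2(fc_min) && r[[alpha_column]] < alpha &&
        (is.null(expressed) || r$gene_id %in% expressed))
      out <- c(out, r$gene_id)
  }
  unique(out)
}

# brute-force row predicate for the splice filter (default config rules)
brute_splice <- function(events, cfg) {
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    p1 <- events$psi_g1[[i]]; p2 <- events$psi_g2[[i]]
    m1 <- mean(p1, na.rm = TRUE); m2 <- mean(p2, na.rm = TRUE)
    if (is.nan(m1) || is.nan(m2)) next
    tot <- c(events$ijc_g1[[i]] + events$sjc_g1[[i]],
             events$ijc_g2[[i]] + events$sjc_g2[[i]])
    support <- if (all(is.na(tot))) 0 else max(tot, na.rm = TRUE)
    keep[i] <- support >= cfg$min_count &&
      !is.na(events$fdr[i]) && events$fdr[i] < cfg$alpha_fdr &&
      !is.na(events$inc_level_difference[i]) &&
      abs(events$inc_level_difference[i]) > cfg$min_delta_psi &&
      max(m1, m2) >= cfg$min_psi
  }
  events$event_key[keep]
}

# hand-built single-row event table with chosen statistics
make_event <- function(event_type = "SE", psi1 = c(0.9, 0.85, 0.9),
                       psi2 = c(0.2, 0.25, 0.2), fdr = 1e-6,
                       pvalue = 1e-7, depth = 100, gene_id = "G1",
                       chrom = "chr1", start = 100L) {
  coords <- setNames(as.integer(seq(start, by = 200,
                                    length.out = length(rpekit:::rmats_coord_cols(event_type)))),
                     rpekit:::rmats_coord_cols(event_type))
  inc1 <- round(psi1 * depth); inc2 <- round(psi2 * depth)
  tab <- tibble::tibble(
    event_type = event_type, event_id = "0", gene_id = gene_id,
    gene_symbol = gene_id, chrom = chrom, strand = "+",
    coords = list(coords),
    ijc_g1 = list(as.integer(inc1)), sjc_g1 = list(as.integer(depth - inc1)),
    ijc_g2 = list(as.integer(inc2)), sjc_g2 = list(as.integer(depth - inc2)),
    psi_g1 = list(psi1), psi_g2 = list(psi2),
    pvalue = pvalue, fdr = fdr,
    inc_level_difference = mean(psi1, na.rm = TRUE) -
      mean(psi2, na.rm = TRUE))
  tab$event_key <- event_keys(tab)
  tab
}

# small, fast epithelium spec used by several tests
small_epithelium <- function(seed, n_cells = 40, jitter = 0,
                             noise_sd = 0.02, blur = 1) {
  epithelium_spec(width_px = 256, height_px = 256, n_cells = n_cells,
                  lloyd_iterations = 15, jitter_sigma_px = jitter,
                  background_margin_px = 6, noise_sd = noise_sd,
                  blur_sigma_px = blur, rng_seed = seed)
}
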