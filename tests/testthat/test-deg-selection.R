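# Differential-expression selection: filters, z-profiles, clustering,
# and the centroid-margin selection rule.

toy_tpm <- function(values, groups = c("g1", "g1", "g2", "g2")) {
  n <- nrow(values)
  tpm <- tibble::tibble(gene_id = sprintf("G%03d", seq_len(n)))
  for (j in seq_len(ncol(values))) tpm[[paste0("s", j)]] <- values[, j]
  list(tpm = tpm,
       groups = tibble::tibble(sample = paste0("s", seq_len(ncol(values))),
                               group = groups))
}

test_that("the TPM floor is inclusive at the cutoff and respects the mode", {
  x <- toy_tpm(rbind(c(0, 0, 0, 5), c(4.99, 4.99, 4.99, 4.99),
                     c(9, 1, 1, 1)))
  expect_setequal(tpm_filter(x$tpm, 5), c("G001", "G003"))
  # group mode: gene 1 group means are (0, 2.5) -> fails the floor
  expect_setequal(tpm_filter(x$tpm, 5, "group", x$groups), "G003")
})

test_that("the fold-change/significance filter honours boundary semantics", {
  stats <- tibble::tibble(
    contrast = "a_vs_b",
    gene_id = c("G1", "G2", "G3", "G4"),
    log2fc = c(1.0, 3, -1.0, 0.99),
    pval = c(0.01, 0.1, 0.001, 0.001),
    fdr = c(0.049, 0.2, 0.05, 0.001))
  got <- deg_filter(stats, deg_filter_config(), c("G1", "G2", "G3", "G4"))
  # |log2FC| >= 1 inclusive, FDR < 0.05 strict
  expect_setequal(got$union, "G1")
  # expression floor also gates membership
  expect_length(deg_filter(stats, deg_filter_config(), "G2")$union, 0)
})

test_that("filters match brute-force enumeration including boundary rows", {
  set.seed(7)
  n <- 1000
  stats <- tibble::tibble(
    contrast = sample(c("a_vs_b", "a_vs_c"), n, TRUE),
    gene_id = sprintf("G%04d", seq_len(n)),
    log2fc = round(rnorm(n, 0, 1.2), 2),
    pval = round(runif(n), 3),
    fdr = round(runif(n), 3))
  # force exact boundary rows
  stats$log2fc[1:10] <- 1.0
  stats$fdr[5:15] <- 0.05
  stats$pval[8:18] <- 0.05
  expressed <- sprintf("G%04d", sample(n, 800))
  for (col in c("fdr", "pval")) {
    cfg <- deg_filter_config(alpha_column = col)
    got <- deg_filter(stats, cfg, expressed)$union
    expect_setequal(got, brute_deg(stats, 2, 0.05, col, expressed))
  }
  # idempotence: re-filtering the selected rows changes nothing
  sel <- deg_filter(stats, deg_filter_config(), expressed)
  again <- deg_filter(stats[stats$gene_id %in% sel$union, ],
                      deg_filter_config(), expressed)
  expect_setequal(again$union, sel$union)
})

test_that("two-group z-profiles are exactly (-1, +1) under population sd", {
  x <- toy_tpm(rbind(c(10, 10, 100, 100)))
  z <- zscore_profiles(x$tpm, x$groups)
  expect_equal(unname(unlist(z[1, c("g1", "g2")])), c(-1, 1))
})

test_that("constant genes are flagged and dropped from z-scoring", {
  x <- toy_tpm(rbind(c(10, 10, 10, 10), c(1, 1, 50, 50)))
  expect_message(z <- zscore_profiles(x$tpm, x$groups), "constant")
  expect_equal(z$gene_id, "G002")
  expect_equal(attr(z, "constant_genes"), "G001")
})

test_that("z-profiles have mean zero and unit population sd per gene", {
  spec <- count_table_spec(n_genes = 100, rng_seed = 3)
  sim <- simulate_count_table(spec)
  z <- suppressMessages(zscore_profiles(sim$tpm, sim$groups))
  zm <- as.matrix(z[-1])
  expect_true(all(abs(rowMeans(zm)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(zm^2)) - 1) < 1e-9))
})

test_that("clustering separates planted archetypes and is order-invariant", {
  set.seed(5)
  arch1 <- c(-1, -1, 1, 1)
  arch2 <- c(1, -1, -1, 1)
  z <- rbind(matrix(rep(arch1, 30), 30, byrow = TRUE) +
               matrix(rnorm(120, 0, 0.05), 30),
             matrix(rep(arch2, 30), 30, byrow = TRUE) +
               matrix(rnorm(120, 0, 0.05), 30))
  ztab <- tibble::as_tibble(as.data.frame(z))
  names(ztab) <- c("g1", "g2", "g3", "g4")
  ztab <- dplyr::mutate(ztab, gene_id = sprintf("G%02d", 1:60),
                        .before = 1)
  cl <- cluster_genes(ztab, 2)
  grp <- cl$assignments$cluster
  expect_equal(length(unique(grp[1:30])), 1L)
  expect_equal(length(unique(grp[31:60])), 1L)
  expect_true(grp[1] != grp[31])
  # permuting gene order leaves the partition (as a set of sets) intact
  perm <- sample(60)
  cl2 <- cluster_genes(ztab[perm, ], 2)
  part1 <- unname(split(cl$assignments$gene_id, cl$assignments$cluster))
  part2 <- unname(split(cl2$assignments$gene_id, cl2$assignments$cluster))
  expect_true(setequal(lapply(part1, sort), lapply(part2, sort)))
})

test_that("K equal to the gene count gives singleton clusters", {
  x <- toy_tpm(matrix(2^runif(40, 1, 8), 10, 4))
  z <- zscore_profiles(x$tpm, x$groups)
  cl <- cluster_genes(z, nrow(z))
  expect_equal(sort(unique(cl$assignments$cluster)), seq_len(nrow(z)))
})

test_that("the centroid-margin rule selects mutation-specific clusters only", {
  centroids <- rbind(c(0, 0, 2, 0),     # affected-specific -> selected
                     c(2, 0, 2, 0),     # shared with a control -> rejected
                     c(0.5, 0.5, 1.2, 0.5))  # margin 0.7 < 1 -> rejected
  colnames(centroids) <- c("control", "asympto", "affected", "isogenic")
  cl <- structure(list(K = 3L,
                       assignments = tibble::tibble(
                         gene_id = sprintf("G%d", 1:6),
                         cluster = rep(1:3, each = 2)),
                       centroids = centroids,
                       z = NULL, linkage = "ward.D2"),
                  class = "gene_clusters")
  sel <- select_clusters(cl, "affected", delta = 1)
  expect_equal(sel$selected, 1L)
  expect_setequal(sel$selected_genes, c("G1", "G2"))
})

test_that("the selected gene list shrinks monotonically in delta", {
  spec <- count_table_spec(n_genes = 800, planted_sets = list(
    list(genes = 1:80, offsets = c(0, 0, 3, 0), label = "ms")),
    rng_seed = 19)
  sim <- simulate_count_table(spec)
  st <- welch_de_stats(sim$tpm, sim$groups,
                       list(c("affected", "control")))
  sizes <- sapply(c(0.5, 1, 1.5, 2), function(d) {
    sel <- suppressMessages(select_mutation_specific_genes(
      sim$tpm, sim$groups, st, "affected", K = 8, delta = d))
    length(sel$selected_genes)
  })
  expect_true(all(diff(sizes) <= 0))
})
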