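# Mutation-specific differential-expression selection: expression floor,
# fold-change/significance filter, z-score profiles, hierarchical
# clustering, and centroid-margin cluster selection.

#' Filter configuration for differential-expression selection
#'
#' @param fc_min Minimum fold change (linear scale); a gene passes when
#'   `|log2FC| >= log2(fc_min)`. The boundary is inclusive.
#' @param alpha Significance threshold; the test column must be strictly
#'   below it.
#' @param alpha_column Which statistic `alpha` applies to: `"fdr"`
#'   (Benjamini--Hochberg adjusted, default) or `"pval"`.
#' @param tpm_min Expression floor in TPM (inclusive).
#' @param tpm_mode `"sample"` keeps genes whose maximum TPM over samples
#'   clears the floor; `"group"` uses the maximum over group means.
#' @return A `deg_filter_config`.
#' @export
deg_filter_config <- function(fc_min = 2, alpha = 0.05,
                              alpha_column = c("fdr", "pval"), tpm_min = 5,
                              tpm_mode = c("sample", "group")) {
  alpha_column <- match.arg(alpha_column)
  tpm_mode <- match.arg(tpm_mode)
  check_scalar(fc_min, "fc_min", lower = 1)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(tpm_min, "tpm_min", lower = 0)
  structure(list(fc_min = fc_min, alpha = alpha,
                 alpha_column = alpha_column, tpm_min = tpm_min,
                 tpm_mode = tpm_mode),
            class = "deg_filter_config")
}

sample_columns <- function(tpm) setdiff(names(tpm), "gene_id")

check_expression_table <- function(tpm, groups = NULL) {
  if (!"gene_id" %in% names(tpm)) abort("expression table needs a `gene_id` column")
  samples <- sample_columns(tpm)
  if (length(samples) == 0L) abort("expression table has no sample columns")
  vals <- as.matrix(tpm[samples])
  if (any(vals < 0)) abort("TPM values must be non-negative")
  if (!is.null(groups)) {
    if (!all(c("sample", "group") %in% names(groups)))
      abort("`groups` needs `sample` and `group` columns")
    missing <- setdiff(samples, groups$sample)
    if (length(missing))
      abort(sprintf("samples without group assignment: %s",
                    paste(missing, collapse = ", ")))
    if (anyDuplicated(groups$sample))
      abort("each sample must be assigned to exactly one group")
  }
  invisible(tpm)
}

#' Expression floor on a TPM table
#'
#' Keeps genes whose TPM clears `tpm_min` in at least one sample
#' (`mode = "sample"`) or in at least one group mean (`mode = "group"`).
#' The cutoff is inclusive.
#'
#' @param tpm Tibble with `gene_id` and one numeric column per sample.
#' @param tpm_min Minimum TPM.
#' @param mode `"sample"` or `"group"`.
#' @param groups Sample-to-group table, required for `mode = "group"`.
#' @return Character vector of retained gene ids.
#' @export
tpm_filter <- function(tpm, tpm_min = 5, mode = c("sample", "group"),
                       groups = NULL) {
  mode <- match.arg(mode)
  check_expression_table(tpm, groups)
  vals <- as.matrix(tpm[sample_columns(tpm)])
  keep <- if (mode == "sample") {
    apply(vals, 1, max) >= tpm_min
  } else {
    if (is.null(groups)) abort("`groups` is required for group-level filtering")
    g <- groups$group[match(colnames(vals), groups$sample)]
    gm <- sapply(split(seq_len(ncol(vals)), g),
                 function(j) rowMeans(vals[, j, drop = FALSE]))
    apply(as.matrix(gm), 1, max) >= tpm_min
  }
  out <- tpm$gene_id[keep]
  if (length(out) == 0L) warn("no genes pass the expression floor")
  out
}

#' Fold-change and significance filter per contrast
#'
#' A gene is differentially expressed in a contrast when
#' `|log2FC| >= log2(fc_min)`, its `alpha_column` statistic is strictly
#' below `alpha`, and it belongs to the expressed set.
#'
#' @param stats Tibble with columns `contrast`, `gene_id`, `log2fc`,
#'   `pval`, `fdr`.
#' @param config A [deg_filter_config()].
#' @param expressed Character vector of genes passing [tpm_filter()];
#'   `NULL` skips the expression condition.
#' @return List with `per_contrast` (named list of gene-id vectors) and
#'   their `union`.
#' @export
deg_filter <- function(stats, config = deg_filter_config(),
                       expressed = NULL) {
  needed <- c("contrast", "gene_id", "log2fc", config$alpha_column)
  for (col in needed) {
    if (!col %in% names(stats))
      abort(sprintf("stats table is missing column `%s`", col))
  }
  per <- lapply(split(stats, stats$contrast), function(d) {
    ok <- abs(d$log2fc) >= log2(config$fc_min) &
      d[[config$alpha_column]] < config$alpha
    g <- d$gene_id[ok & !is.na(ok)]
    if (!is.null(expressed)) g <- intersect(g, expressed)
    g
  })
  list(per_contrast = per, union = unique(unlist(per, use.names = FALSE)))
}

#' Group-mean z-score profiles
#'
#' Averages `log2(TPM + 1)` over the replicates of each group, then
#' standardizes each gene across groups to mean 0 and sd 1 (population
#' sd, i.e. dividing by n groups). Genes constant across groups cannot be
#' standardized; they are dropped and reported.
#'
#' @param tpm Expression table (`gene_id` + sample columns).
#' @param groups Sample-to-group table.
#' @param genes Genes to profile; default all.
#' @return Tibble `gene_id` + one z column per group, ordered as the
#'   groups appear in `groups`. Dropped constant genes are in
#'   `attr(, "constant_genes")`.
#' @export
zscore_profiles <- function(tpm, groups, genes = NULL) {
  check_expression_table(tpm, groups)
  if (!is.null(genes)) tpm <- filter(tpm, .data$gene_id %in% genes)
  if (nrow(tpm) == 0L) abort("no genes to profile")
  vals <- log2(as.matrix(tpm[sample_columns(tpm)]) + 1)
  g <- groups$group[match(colnames(vals), groups$sample)]
  lev <- unique(groups$group)
  if (length(lev) < 2L) abort("need at least two groups")
  means <- sapply(lev, function(l)
    rowMeans(vals[, g == l, drop = FALSE]))
  means <- matrix(means, nrow = nrow(tpm),
                  dimnames = list(NULL, lev))
  mu <- rowMeans(means)
  sd_pop <- sqrt(rowMeans((means - mu)^2))
  constant <- sd_pop < 1e-12
  z <- (means - mu) / sd_pop
  out <- as_tibble(as.data.frame(z[!constant, , drop = FALSE]))
  out <- mutate(out, gene_id = tpm$gene_id[!constant], .before = 1)
  if (any(constant))
    inform(sprintf("dropped %d constant gene(s) from z-scoring",
                   sum(constant)))
  attr(out, "constant_genes") <- tpm$gene_id[constant]
  out
}

#' Hierarchical clustering of z-score profiles
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances
#' between per-gene z-profiles, cut into exactly `K` clusters. With
#' continuous profiles the merge sequence has no ties, so the partition is
#' invariant to gene input order; exact ties resolve by the index order of
#' [stats::hclust()].
#'
#' @param z Tibble from [zscore_profiles()].
#' @param K Number of clusters (>= 2).
#' @param linkage Linkage passed to [stats::hclust()]; default `"ward.D2"`.
#' @return A `gene_clusters` object: assignments, centroids, `K`, and the
#'   profile matrix.
#' @export
cluster_genes <- function(z, K, linkage = "ward.D2") {
  check_scalar(K, "K", lower = 2, integerish = TRUE)
  zm <- as.matrix(z[setdiff(names(z), "gene_id")])
  rownames(zm) <- z$gene_id
  if (nrow(zm) < K) abort("fewer genes than clusters requested")
  hc <- hclust(dist(zm), method = linkage)
  assign <- cutree(hc, k = K)
  centroids <- t(sapply(seq_len(K), function(k)
    colMeans(zm[assign == k, , drop = FALSE])))
  structure(
    list(K = as.integer(K),
         assignments = tibble(gene_id = z$gene_id,
                              cluster = as.integer(assign)),
         centroids = centroids, z = zm, linkage = linkage),
    class = "gene_clusters")
}

#' @export
print.gene_clusters <- function(x, ...) {
  cat(sprintf("<gene_clusters> %d genes in %d clusters (%s linkage)\n",
              nrow(x$assignments), x$K, x$linkage))
  if (!is.null(x$selected))
    cat(sprintf("  selected clusters: %s (%d genes)\n",
                paste(x$selected, collapse = ", "),
                length(x$selected_genes)))
  invisible(x)
}

#' @export
tidy.gene_clusters <- function(x, ...) {
  out <- x$assignments
  if (!is.null(x$selected))
    out <- mutate(out, selected = .data$cluster %in% x$selected)
  out
}

#' @export
glance.gene_clusters <- function(x, ...) {
  tibble(n_genes = nrow(x$assignments), K = x$K,
         n_selected_clusters = length(x$selected %||% integer(0)),
         n_selected_genes = length(x$selected_genes %||% character(0)))
}

#' Select clusters with a mutation-specific centroid profile
#'
#' Formalizes the hand selection of heat-map clusters: a cluster is
#' selected when its centroid z-profile separates the affected group from
#' every control group by at least `delta`, i.e.
#' `|z(affected) - z(g)| >= delta` for all control groups `g`.
#'
#' @param clusters A `gene_clusters` from [cluster_genes()].
#' @param affected_group Group whose specific response is sought.
#' @param control_groups Groups it must differ from; default all others.
#' @param delta Minimum centroid z separation (default 1).
#' @return The `gene_clusters` object with `selected` (cluster ids),
#'   `selected_genes`, and the rule parameters attached.
#' @export
select_clusters <- function(clusters, affected_group,
                            control_groups = NULL, delta = 1) {
  stopifnot(inherits(clusters, "gene_clusters"))
  check_scalar(delta, "delta", lower = 0)
  grps <- colnames(clusters$centroids)
  if (!affected_group %in% grps)
    abort(sprintf("affected group `%s` not found among profiles",
                  affected_group))
  control_groups <- control_groups %||% setdiff(grps, affected_group)
  if (!all(control_groups %in% grps))
    abort("unknown control group(s)")
  margin <- abs(clusters$centroids[, affected_group] -
                  clusters$centroids[, control_groups, drop = FALSE])
  sel <- which(apply(margin >= delta, 1, all))
  clusters$selected <- as.integer(sel)
  clusters$selected_genes <-
    clusters$assignments$gene_id[clusters$assignments$cluster %in% sel]
  clusters$selection <- list(affected_group = affected_group,
                             control_groups = control_groups, delta = delta)
  clusters
}

#' End-to-end mutation-specific gene selection
#'
#' Chains the expression floor, per-contrast fold-change/significance
#' filter, z-scoring, hierarchical clustering, and centroid-margin cluster
#' selection. With fewer differentially expressed genes than `K`, the
#' clustering step shrinks `K` to the gene count; with fewer than 2 genes
#' the selection is empty.
#'
#' @param tpm Expression table (`gene_id` + sample columns).
#' @param groups Sample-to-group table.
#' @param stats Per-contrast statistics table (see [deg_filter()]).
#' @param affected_group Group whose specific signature is sought.
#' @param contrasts Contrasts whose DEG union feeds the clustering;
#'   default all contrasts in `stats`.
#' @param config A [deg_filter_config()].
#' @param K Number of clusters.
#' @param delta Centroid margin for [select_clusters()].
#' @param control_groups Control groups for the margin rule.
#' @return A `deg_selection` list: `expressed`, `degs`, `clusters`
#'   (possibly `NULL`), and `selected_genes`.
#' @export
select_mutation_specific_genes <- function(tpm, groups, stats,
                                           affected_group,
                                           contrasts = NULL,
                                           config = deg_filter_config(),
                                           K = 15, delta = 1,
                                           control_groups = NULL) {
  expressed <- suppressWarnings(
    tpm_filter(tpm, config$tpm_min, config$tpm_mode, groups))
  if (!is.null(contrasts)) stats <- filter(stats, .data$contrast %in% contrasts)
  degs <- deg_filter(stats, config, expressed)
  clusters <- NULL
  selected <- character(0)
  if (length(degs$union) >= 2L) {
    z <- zscore_profiles(tpm, groups, degs$union)
    K_eff <- min(K, nrow(z))
    if (nrow(z) >= 2L && K_eff >= 2L) {
      clusters <- cluster_genes(z, K_eff)
      clusters <- select_clusters(clusters, affected_group,
                                  control_groups, delta)
      selected <- clusters$selected_genes
    }
  }
  structure(list(expressed = expressed, degs = degs, clusters = clusters,
                 selected_genes = selected,
                 params = list(K = K, delta = delta,
                               affected_group = affected_group,
                               config = config)),
            class = "deg_selection")
}

#' @export
print.deg_selection <- function(x, ...) {
  cat(sprintf("<deg_selection> %d expressed, %d DEGs, %d selected genes\n",
              length(x$expressed), length(x$degs$union),
              length(x$selected_genes)))
  invisible(x)
}

#' @export
glance.deg_selection <- function(x, ...) {
  tibble(n_expressed = length(x$expressed),
         n_degs = length(x$degs$union),
         n_selected = length(x$selected_genes),
         K = x$params$K, delta = x$params$delta)
}
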