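# Synthetic 3-replicate expression tables with planted group-specific
# gene sets, plus the Welch-test contrast statistics consumed by the
# selection layer.

#' Specification for a synthetic count/TPM table
#'
#' Emulates a bulk RNA-seq design of a few groups with triplicate
#' biological repeats. Counts are negative-binomial around per-gene
#' baseline log2 means; `planted_sets` shift the group means of chosen
#' genes by per-group log2 offsets, defining the ground-truth
#' differential-expression patterns.
#'
#' @param n_genes Number of genes.
#' @param groups Ordered group labels.
#' @param reps_per_group Biological replicates per group.
#' @param baseline_log_mean,baseline_log_sd Mean and sd of the per-gene
#'   baseline expression on the log2 scale.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   0 gives deterministic counts equal to the rounded means.
#' @param planted_sets List of `list(genes =, offsets =, label =)`:
#'   gene indices, a log2 offset per group, and a truth label. Sets must
#'   be disjoint.
#' @param rng_seed Integer seed.
#' @return A `count_table_spec`.
#' @export
count_table_spec <- function(n_genes = 5000,
                             groups = c("control", "asymptomatic",
                                        "affected", "isogenic"),
                             reps_per_group = 3,
                             baseline_log_mean = 6, baseline_log_sd = 2,
                             dispersion = 0.01, planted_sets = list(),
                             rng_seed = 1L) {
  check_scalar(n_genes, "n_genes", lower = 1, integerish = TRUE)
  if (length(groups) < 2L || anyDuplicated(groups))
    abort("`groups` must be >= 2 distinct labels")
  check_scalar(reps_per_group, "reps_per_group", lower = 1,
               integerish = TRUE)
  check_scalar(dispersion, "dispersion", lower = 0)
  check_scalar(rng_seed, "rng_seed", integerish = TRUE)
  seen <- integer(0)
  for (s in planted_sets) {
    if (!all(c("genes", "offsets") %in% names(s)))
      abort("each planted set needs `genes` and `offsets`")
    if (length(s$offsets) != length(groups))
      abort("planted offsets must have one value per group")
    if (!all(is.finite(s$offsets))) abort("planted offsets must be finite")
    if (any(s$genes < 1 | s$genes > n_genes))
      abort("planted gene indices out of range")
    if (length(intersect(seen, s$genes)))
      abort("planted sets must be disjoint")
    seen <- c(seen, s$genes)
  }
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 reps_per_group = as.integer(reps_per_group),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion, planted_sets = planted_sets,
                 rng_seed = as.integer(rng_seed)),
            class = "count_table_spec")
}

#' Simulate a count and TPM table with planted patterns
#'
#' Draws per-gene, per-sample counts from the model in
#' [count_table_spec()] and converts them to TPM under a unit gene-length
#' convention (TPM is the per-sample count scaled to a million), so the
#' expression floor and fold-change filters behave exactly as on real
#' length-normalized data.
#'
#' @param spec A [count_table_spec()].
#' @return A list of class `expression_sim`: `counts` and `tpm` tibbles
#'   (`gene_id` + sample columns), `groups` (sample-to-group table),
#'   `truth` (per-gene planted label or `NA`), and `spec`.
#' @export
simulate_count_table <- function(spec) {
  stopifnot(inherits(spec, "count_table_spec"))
  n <- spec$n_genes
  G <- length(spec$groups)
  samples <- paste(rep(spec$groups, each = spec$reps_per_group),
                   rep(seq_len(spec$reps_per_group), times = G), sep = "_")
  sample_group <- rep(spec$groups, each = spec$reps_per_group)
  with_seed(spec$rng_seed, {
    baseline <- rnorm(n, spec$baseline_log_mean, spec$baseline_log_sd)
    offsets <- matrix(0, n, G, dimnames = list(NULL, spec$groups))
    truth_label <- rep(NA_character_, n)
    for (k in seq_along(spec$planted_sets)) {
      s <- spec$planted_sets[[k]]
      offsets[s$genes, ] <- matrix(s$offsets, length(s$genes), G,
                                   byrow = TRUE)
      truth_label[s$genes] <- s$label %||% paste0("set", k)
    }
    mu <- 2^(baseline + offsets[, sample_group, drop = FALSE])
    counts <- if (spec$dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
             n, length(samples))
    } else {
      round(mu)
    }
    colnames(counts) <- samples
    tpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
    gene_id <- sprintf("GENE%05d", seq_len(n))
    structure(
      list(counts = bind_cols(tibble(gene_id = gene_id),
                              as_tibble(as.data.frame(counts))),
           tpm = bind_cols(tibble(gene_id = gene_id),
                           as_tibble(as.data.frame(tpm))),
           groups = tibble(sample = samples, group = sample_group),
           truth = tibble(gene_id = gene_id, planted_set = truth_label),
           spec = spec),
      class = "expression_sim")
  })
}

#' Per-contrast differential-expression statistics by Welch test
#'
#' Stand-in for the statistics an external count-model fit would provide:
#' for each contrast, the log2 fold change is the difference of group
#' means of `log2(TPM + 1)` and the p-value comes from a Welch two-sample
#' t-test on the same values, with Benjamini--Hochberg adjustment across
#' genes within each contrast.
#'
#' @param tpm Expression table (`gene_id` + sample columns).
#' @param groups Sample-to-group table.
#' @param contrasts List of 2-vectors `c(numerator_group,
#'   denominator_group)`; the contrast label is `"a_vs_b"`.
#' @return Tibble with `contrast`, `gene_id`, `log2fc`, `pval`, `fdr`.
#' @export
welch_de_stats <- function(tpm, groups, contrasts) {
  check_expression_table(tpm, groups)
  vals <- log2(as.matrix(tpm[sample_columns(tpm)]) + 1)
  g <- groups$group[match(colnames(vals), groups$sample)]
  purrr::map_dfr(contrasts, function(ct) {
    if (length(ct) != 2L || !all(ct %in% g))
      abort("each contrast must name two known groups")
    x <- vals[, g == ct[1], drop = FALSE]
    y <- vals[, g == ct[2], drop = FALSE]
    n1 <- ncol(x); n2 <- ncol(y)
    m1 <- rowMeans(x); m2 <- rowMeans(y)
    v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    # zero-variance genes: identical values give p = 1, separated
    # constants give p = 0
    degen <- !is.finite(p)
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    tibble(contrast = paste(ct[1], "vs", ct[2], sep = "_"),
           gene_id = tpm$gene_id, log2fc = m1 - m2, pval = p,
           fdr = p.adjust(p, "BH"))
  })
}

#' Write an expression simulation to disk
#'
#' @param x An `expression_sim`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_expression_sim <- function(x, dir) {
  stopifnot(inherits(x, "expression_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(x$tpm, file.path(dir, "tpm.tsv"))
  readr::write_tsv(x$groups, file.path(dir, "groups.tsv"))
  readr::write_tsv(x$truth, file.path(dir, "truth.tsv"))
  write_manifest(run_manifest("expression", x$spec, x$spec$rng_seed,
                              list(n_genes = x$spec$n_genes)),
                 file.path(dir, "manifest.json"))
  invisible(dir)
}
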