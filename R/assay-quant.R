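# Closed-form assay quantifications: transepithelial resistance,
# phagocytosis fluorescence ratios, western band folds, marker-positive
# fractions, ONL density, and delta-Ct expression folds. All are
# vectorized pure maps.

#' Normalize transepithelial resistance readings
#'
#' Subtracts the blank insert reading and scales by the membrane area:
#' `(raw - blank) * area`, reported in Ohm cm^2. Sub-blank wells yield
#' negative values, which are returned as-is with a warning.
#'
#' @param raw_ohm Raw resistance readings, Ohm.
#' @param blank_ohm Blank (medium-only insert) readings, Ohm.
#' @param area_cm2 Membrane area, cm^2.
#' @return Numeric vector of TER values in Ohm cm^2.
#' @export
ter_normalize <- function(raw_ohm, blank_ohm, area_cm2) {
  if (missing(blank_ohm) || is.null(blank_ohm) || anyNA(blank_ohm))
    abort("blank resistance reading is required")
  if (any(area_cm2 <= 0)) abort("`area_cm2` must be positive")
  out <- (raw_ohm - blank_ohm) * area_cm2
  if (any(out < 0))
    warn(sprintf("%d TER value(s) below blank (negative Ohm cm^2)",
                 sum(out < 0)))
  out
}

#' Phagocytosis fluorescence ratios
#'
#' The quenched FITC signal measures internalized particles; the bound
#' signal is the total minus the quenched signal. Both are reported
#' relative to the DAPI signal of the same well:
#' `internalized = quenched / dapi`, `bound = (total - quenched) / dapi`.
#' Wells where quenching exceeds the total give a negative bound signal,
#' which is clamped to 0 with a warning.
#'
#' @param total_fitc Total FITC fluorescence.
#' @param quenched_fitc FITC fluorescence after trypan-blue quenching.
#' @param dapi DAPI fluorescence (must be positive).
#' @return Tibble with `internalized_ratio` and `bound_ratio`.
#' @export
phagocytosis_ratios <- function(total_fitc, quenched_fitc, dapi) {
  if (any(dapi <= 0)) abort("`dapi` must be positive")
  bound <- (total_fitc - quenched_fitc) / dapi
  neg <- bound < 0
  if (any(neg)) {
    warn(sprintf("%d bound signal(s) below 0 clamped (quench > total)",
                 sum(neg)))
    bound[neg] <- 0
  }
  tibble(internalized_ratio = quenched_fitc / dapi, bound_ratio = bound)
}

#' Western-blot band ratio and fold over a reference group
#'
#' `ratio = target / loading` (e.g. band intensity over GAPDH), and
#' `fold = ratio / reference_mean_ratio` where the reference is the
#' arithmetic mean ratio of the reference group.
#'
#' @param target Target band intensities.
#' @param loading Loading-control band intensities (positive).
#' @param reference_mean_ratio Mean ratio of the reference group.
#' @return Tibble with `ratio` and `fold`.
#' @export
band_ratio_fold <- function(target, loading, reference_mean_ratio) {
  if (any(loading <= 0)) abort("`loading` must be positive")
  if (any(reference_mean_ratio == 0))
    abort("reference group mean ratio is zero")
  ratio <- target / loading
  tibble(ratio = ratio, fold = ratio / reference_mean_ratio)
}

#' Marker-positive cell fraction
#'
#' Percentage of marker-positive nuclei among DAPI-positive nuclei.
#'
#' @param n_marker Marker-positive counts.
#' @param n_dapi DAPI-positive counts (positive, `>= n_marker`).
#' @return Percentages.
#' @export
marker_fraction <- function(n_marker, n_dapi) {
  if (any(n_dapi <= 0)) abort("`n_dapi` must be positive")
  if (any(n_marker < 0) || any(n_marker > n_dapi))
    abort("`n_marker` must be between 0 and `n_dapi`")
  100 * n_marker / n_dapi
}

#' Nuclear density of a tissue region
#'
#' Cell count divided by region area, e.g. DAPI-positive nuclei per mm^2
#' of presumptive outer nuclear layer.
#'
#' @param n_dapi Nuclei counts.
#' @param region_area Region areas (positive, any consistent unit).
#' @return Densities in cells per unit area.
#' @export
onl_density <- function(n_dapi, region_area) {
  if (any(region_area <= 0)) abort("`region_area` must be positive")
  n_dapi / region_area
}

#' Relative expression fold by the delta-Ct method
#'
#' `dCt = ct_target - ct_housekeeping`; the fold relative to a reference
#' condition is `2^-(dCt - ref_delta_ct)`, assuming doubling per cycle
#' without efficiency correction.
#'
#' @param ct_target Target-gene Ct values.
#' @param ct_housekeeping Housekeeping-gene Ct values (e.g. 18S).
#' @param ref_delta_ct Reference condition delta-Ct (default 0 reports
#'   `2^-dCt` itself).
#' @return Fold changes.
#' @export
dct_fold <- function(ct_target, ct_housekeeping, ref_delta_ct = 0) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_housekeeping)))
    abort("Ct values must be finite")
  dct <- ct_target - ct_housekeeping
  2^(-(dct - ref_delta_ct))
}

#' Omnibus group comparison for assay readouts
#'
#' Kruskal--Wallis (default) or one-way ANOVA across groups with the
#' matching post-hoc procedure (Dunn's rank test with Benjamini--Hochberg
#' adjustment, or Tukey's HSD), plus mean and SD per group.
#'
#' @param values Numeric readouts.
#' @param group Group labels (>= 2 groups, each n >= 3).
#' @param method `"kruskal"` or `"anova"`.
#' @return An `assay_group_test` with `tidy()` (per-group summaries),
#'   `glance()` (omnibus test), and a `posthoc` tibble.
#' @export
group_test <- function(values, group, method = c("kruskal", "anova")) {
  method <- match.arg(method)
  g <- factor(group)
  if (nlevels(g) < 2L) abort("need at least two groups")
  if (any(table(g) < 3L)) abort("every group needs n >= 3")
  per_group <- tibble(group = levels(g),
                      n = as.integer(table(g)),
                      mean = as.numeric(tapply(values, g, mean)),
                      sd = as.numeric(tapply(values, g, sd)))
  if (method == "kruskal") {
    omni <- kruskal.test(values, g)
    posthoc <- dunn_posthoc(values, g)
  } else {
    fit <- aov(values ~ g)
    s <- summary(fit)[[1]]
    omni <- list(statistic = c(F = s$`F value`[1]),
                 parameter = c(df1 = s$Df[1], df2 = s$Df[2]),
                 p.value = s$`Pr(>F)`[1], method = "One-way ANOVA")
    tk <- TukeyHSD(fit)$g
    posthoc <- tibble(comparison = rownames(tk),
                      estimate = tk[, "diff"], p.adj = tk[, "p adj"])
  }
  structure(list(method = method, omnibus = omni, groups = per_group,
                 posthoc = posthoc),
            class = "assay_group_test")
}

# Dunn's post-hoc test: pairwise z statistics on pooled ranks with a
# tie correction, BH-adjusted
dunn_posthoc <- function(values, g) {
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  mean_r <- tapply(r, g, mean)
  n <- table(g)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    (mean_r[[p[1]]] - mean_r[[p[2]]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  tibble(comparison = apply(pairs, 2, paste, collapse = "-"),
         estimate = z, p.adj = p.adjust(p, "BH"))
}

#' @export
print.assay_group_test <- function(x, ...) {
  cat(sprintf("<assay_group_test> %s: p = %.4g\n", x$method,
              x$omnibus$p.value))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.assay_group_test <- function(x, ...) x$groups

#' @export
glance.assay_group_test <- function(x, ...) {
  tibble(method = x$method, statistic = unname(x$omnibus$statistic[1]),
         p.value = x$omnibus$p.value)
}
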