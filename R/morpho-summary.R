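# Group-level summaries of per-cell shape metrics.

#' Histogram and summary of one shape metric
#'
#' Drops excluded cells (their number is reported in the result), bins the
#' remaining values, and computes median, interquartile range, and
#' coefficient of variation. Mirrors the per-group shape-distribution plots
#' used to compare monolayer regularity between cell lines.
#'
#' @param records Tibble from [measure_shapes()] (optionally row-bound
#'   across images).
#' @param metric Column to summarize, e.g. `"convexity"`.
#' @param bins Number of bins, or a numeric vector of break points.
#' @param group Label attached to the result.
#' @return An object of class `shape_distribution`: a list with `bins`
#'   (tibble of bin edges, counts, relative frequencies) and `summary`.
#' @export
summarize_distribution <- function(records, metric = "convexity", bins = 20,
                                   group = "all") {
  if (!metric %in% names(records))
    abort(sprintf("metric `%s` not found in records", metric))
  if ("excluded" %in% names(records)) {
    n_excluded <- sum(records$excluded)
    records <- filter(records, !.data$excluded)
  } else n_excluded <- 0L
  x <- records[[metric]]
  x <- x[is.finite(x)]
  if (length(x) == 0L) abort("no usable cells after exclusions")
  if (n_excluded > 0)
    inform(sprintf("dropped %d excluded cell(s) from the %s distribution",
                   n_excluded, metric))
  breaks <- if (length(bins) == 1L) {
    seq(min(x), max(x), length.out = bins + 1L)
  } else sort(bins)
  if (breaks[1] == breaks[length(breaks)])
    breaks <- breaks[1] + c(-0.5, 0.5)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  structure(
    list(group = group, metric = metric,
         bins = tibble(bin_lo = utils::head(h$breaks, -1),
                       bin_hi = h$breaks[-1], count = h$counts,
                       freq = h$counts / sum(h$counts)),
         summary = tibble(group = group, metric = metric, n = length(x),
                          n_excluded = n_excluded, median = median(x),
                          iqr = IQR(x), cv = sd(x) / mean(x))),
    class = "shape_distribution")
}

#' @export
print.shape_distribution <- function(x, ...) {
  cat(sprintf("<shape_distribution> %s | %s: n = %d, median = %.4g, IQR = %.4g\n",
              x$group, x$metric, x$summary$n, x$summary$median,
              x$summary$iqr))
  invisible(x)
}

#' @export
tidy.shape_distribution <- function(x, ...) x$bins

#' @export
glance.shape_distribution <- function(x, ...) x$summary

#' @importFrom ggplot2 autoplot ggplot aes geom_col labs
#' @export
autoplot.shape_distribution <- function(object, ...) {
  ggplot(object$bins,
         aes(x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$freq)) +
    geom_col(width = object$bins$bin_hi[1] - object$bins$bin_lo[1],
             fill = "grey35") +
    labs(x = object$metric, y = "relative frequency",
         title = sprintf("%s distribution (%s)", object$metric,
                         object$group))
}

#' Rank-based comparison of a shape metric between groups
#'
#' Pools per-cell values and runs a Kruskal--Wallis omnibus test across
#' groups, reporting group sizes, medians, and IQRs alongside the test.
#'
#' @param records Tibble of shape records with a grouping column.
#' @param metric Metric column to compare.
#' @param group Name of the grouping column (default `"group"`).
#' @return Object of class `shape_group_test` with `tidy()` and `glance()`
#'   methods.
#' @export
compare_groups <- function(records, metric = "convexity", group = "group") {
  if (!group %in% names(records))
    abort(sprintf("grouping column `%s` not found", group))
  if ("excluded" %in% names(records))
    records <- filter(records, !.data$excluded)
  records <- filter(records, is.finite(.data[[metric]]))
  g <- factor(records[[group]])
  if (nlevels(g) < 2L) abort("need at least two groups to compare")
  sizes <- table(g)
  if (any(sizes < 3L)) abort("every group needs at least 3 cells")
  kw <- kruskal.test(records[[metric]], g)
  per_group <- records |>
    group_by(group = g) |>
    summarise(n = n(), median = median(.data[[metric]]),
              iqr = IQR(.data[[metric]]), .groups = "drop")
  structure(list(metric = metric, test = kw, groups = per_group),
            class = "shape_group_test")
}

#' @export
print.shape_group_test <- function(x, ...) {
  cat(sprintf("<shape_group_test> %s: Kruskal-Wallis chi-sq = %.3f, df = %d, p = %.3g\n",
              x$metric, unname(x$test$statistic),
              unname(x$test$parameter), x$test$p.value))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.shape_group_test <- function(x, ...) x$groups

#' @export
glance.shape_group_test <- function(x, ...) {
  tibble(metric = x$metric, statistic = unname(x$test$statistic),
         df = unname(x$test$parameter), p.value = x$test$p.value,
         method = x$test$method)
}
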