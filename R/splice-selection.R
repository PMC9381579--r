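# Alternative-splicing event selection from rMATS-format junction-count
# tables: dialect parsing, significance filtering, multi-comparison set
# logic, and event-type composition.

SPLICE_TYPES <- c("SE", "MXE", "RI", "A5SS", "A3SS")

rmats_coord_cols <- function(type) {
  switch(type,
    SE   = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
             "downstreamES", "downstreamEE"),
    MXE  = c("..1stExonStart_0base", "..1stExonEnd", "..2ndExonStart_0base",
             "..2ndExonEnd", "upstreamES", "upstreamEE", "downstreamES",
             "downstreamEE"),  # names as repaired from rMATS's digit-led headers
    RI   = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
             "downstreamES", "downstreamEE"),
    A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
             "flankingES", "flankingEE"),
    A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
             "flankingES", "flankingEE"),
    abort(sprintf("unknown event type `%s`", type)))
}

parse_num_list <- function(x) {
  lapply(strsplit(x, ","), function(v) {
    v[v == "NA"] <- NA
    as.numeric(v)
  })
}

parse_int_list <- function(x) {
  lapply(strsplit(x, ","), function(v) {
    v[v == "NA"] <- NA
    as.integer(v)
  })
}

#' Selection thresholds for splicing events
#'
#' Defaults follow the event-level filters used throughout: a minimum
#' junction-read support of 2 in at least one sample (inclusion +
#' skipping, inclusive), FDR strictly below 0.05, an absolute
#' inclusion-level difference strictly above 10%, and a minimum inclusion
#' level of 10% (inclusive) in at least one group. An optional TPM floor
#' on the host gene can be enabled for organoid-style selections.
#'
#' @param min_psi Minimum inclusion level (PSI).
#' @param min_delta_psi Minimum |inclusion-level difference| (strict).
#' @param alpha_fdr FDR threshold (strict).
#' @param min_count Minimum per-sample junction-read total (inclusive).
#' @param tpm_min Optional host-gene TPM floor; `NULL` disables it.
#' @param min_psi_rule `"either_group"` (default): at least one group mean
#'   PSI must reach `min_psi`; `"bounded_both"`: both group means must lie
#'   in `[min_psi, 1 - min_psi]`.
#' @return A `splice_selection_config`.
#' @export
splice_selection_config <- function(min_psi = 0.10, min_delta_psi = 0.10,
                                    alpha_fdr = 0.05, min_count = 2,
                                    tpm_min = NULL,
                                    min_psi_rule = c("either_group",
                                                     "bounded_both")) {
  min_psi_rule <- match.arg(min_psi_rule)
  check_scalar(min_psi, "min_psi", lower = 0, upper = 1)
  check_scalar(min_delta_psi, "min_delta_psi", lower = 0, upper = 1)
  check_scalar(alpha_fdr, "alpha_fdr", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(min_count, "min_count", lower = 0, integerish = TRUE)
  if (!is.null(tpm_min)) check_scalar(tpm_min, "tpm_min", lower = 0)
  structure(list(min_psi = min_psi, min_delta_psi = min_delta_psi,
                 alpha_fdr = alpha_fdr, min_count = as.integer(min_count),
                 tpm_min = tpm_min, min_psi_rule = min_psi_rule),
            class = "splice_selection_config")
}

#' Read rMATS junction-count event tables
#'
#' Parses one `*.MATS.JC.txt`-style tab-delimited file per event type into
#' a single tibble. Columns are located by header name, so column order is
#' free; `IncLevel1`/`IncLevel2` and the junction-count columns are
#' comma-separated per-replicate lists with `NA` for missing.
#'
#' @param paths Named character vector or list mapping event types (`SE`,
#'   `MXE`, `RI`, `A5SS`, `A3SS`) to file paths, or a single directory
#'   containing `<TYPE>.MATS.JC.txt` files.
#' @return Tibble with one row per event: identifiers, a type-specific
#'   coordinate list-column `coords`, a precomputed `event_key`,
#'   junction-count and PSI list-columns, `inc_level_difference`,
#'   `pvalue`, and `fdr`.
#' @export
read_rmats <- function(paths) {
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths[[1]])) {
    files <- file.path(paths[[1]], paste0(SPLICE_TYPES, ".MATS.JC.txt"))
    paths <- setNames(as.list(files[file.exists(files)]),
                      SPLICE_TYPES[file.exists(files)])
  }
  if (is.null(names(paths)) || !all(names(paths) %in% SPLICE_TYPES))
    abort("`paths` must be named with event types (SE, MXE, RI, A5SS, A3SS)")
  out <- purrr::imap(paths, function(path, type) {
    if (!file.exists(path)) abort(sprintf("file not found: %s", path))
    d <- readr::read_tsv(
      path, show_col_types = FALSE, na = character(0),
      name_repair = "universal_quiet",
      # comma-joined replicate lists must never be parsed as grouped numbers
      col_types = readr::cols(IJC_SAMPLE_1 = "c", SJC_SAMPLE_1 = "c",
                              IJC_SAMPLE_2 = "c", SJC_SAMPLE_2 = "c",
                              IncLevel1 = "c", IncLevel2 = "c"))
    ccols <- rmats_coord_cols(type)
    needed <- c("ID", "GeneID", "geneSymbol", "chr", "strand", ccols,
                "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2",
                "SJC_SAMPLE_2", "PValue", "FDR", "IncLevel1", "IncLevel2",
                "IncLevelDifference")
    missing <- setdiff(needed, names(d))
    if (length(missing))
      abort(sprintf("%s: missing column(s) %s", path,
                    paste(missing, collapse = ", ")))
    if (nrow(d) == 0L) return(NULL)
    coords <- lapply(seq_len(nrow(d)), function(i) {
      v <- suppressWarnings(as.integer(unlist(d[i, ccols])))
      if (anyNA(v))
        abort(sprintf("%s: malformed coordinates at data line %d", path, i))
      setNames(v, ccols)
    })
    tibble(
      event_type = type,
      event_id = as.character(d$ID),
      gene_id = as.character(d$GeneID),
      gene_symbol = as.character(d$geneSymbol),
      chrom = as.character(d$chr),
      strand = as.character(d$strand),
      coords = coords,
      ijc_g1 = parse_int_list(as.character(d$IJC_SAMPLE_1)),
      sjc_g1 = parse_int_list(as.character(d$SJC_SAMPLE_1)),
      ijc_g2 = parse_int_list(as.character(d$IJC_SAMPLE_2)),
      sjc_g2 = parse_int_list(as.character(d$SJC_SAMPLE_2)),
      psi_g1 = parse_num_list(as.character(d$IncLevel1)),
      psi_g2 = parse_num_list(as.character(d$IncLevel2)),
      pvalue = as.numeric(d$PValue),
      fdr = as.numeric(d$FDR),
      inc_level_difference = as.numeric(d$IncLevelDifference))
  })
  out <- bind_rows(out)
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(event_type = character(0), event_id = character(0),
                  gene_id = character(0), gene_symbol = character(0),
                  chrom = character(0), strand = character(0),
                  coords = list(), ijc_g1 = list(), sjc_g1 = list(),
                  ijc_g2 = list(), sjc_g2 = list(), psi_g1 = list(),
                  psi_g2 = list(), pvalue = numeric(0), fdr = numeric(0),
                  inc_level_difference = numeric(0))
  }
  mutate(out, event_key = event_keys(out))
}

#' Coordinate-exact event identity across comparisons
#'
#' Builds the key used to match events between comparisons: event type,
#' chromosome, strand, and the full type-specific coordinate tuple
#' (0-based starts, 1-based ends, as emitted by rMATS), with the gene id
#' appended as a tiebreak.
#'
#' @param events Tibble from [read_rmats()].
#' @return Character vector of keys.
#' @export
event_keys <- function(events) {
  if (nrow(events) == 0L) return(character(0))
  vapply(seq_len(nrow(events)), function(i) {
    paste(events$event_type[i], events$chrom[i], events$strand[i],
          paste(events$coords[[i]], collapse = ":"), events$gene_id[i],
          sep = "|")
  }, character(1))
}

#' Filter splicing events on support, significance, and effect size
#'
#' Keeps events satisfying every configured predicate: junction-read
#' support (inclusion + skipping) of at least `min_count` in at least one
#' sample, FDR strictly below `alpha_fdr`, absolute inclusion-level
#' difference strictly above `min_delta_psi`, the minimum-PSI rule, and
#' optionally a TPM floor on the host gene. Events whose PSI is missing in
#' every replicate of a group are dropped and counted in a message.
#'
#' @param events Tibble from [read_rmats()].
#' @param config A [splice_selection_config()].
#' @param tpm,groups Expression table and sample-to-group assignment,
#'   required when `config$tpm_min` is set.
#' @return The filtered events tibble.
#' @export
significant_events <- function(events, config = splice_selection_config(),
                               tpm = NULL, groups = NULL) {
  if (nrow(events) == 0L) return(events)
  mean_psi1 <- vapply(events$psi_g1, function(v) mean(v, na.rm = TRUE),
                      numeric(1))
  mean_psi2 <- vapply(events$psi_g2, function(v) mean(v, na.rm = TRUE),
                      numeric(1))
  no_psi <- is.nan(mean_psi1) | is.nan(mean_psi2)
  if (any(no_psi))
    inform(sprintf("dropped %d event(s) with no PSI in one group",
                   sum(no_psi)))

  max_support <- vapply(seq_len(nrow(events)), function(i) {
    tot <- c(events$ijc_g1[[i]] + events$sjc_g1[[i]],
             events$ijc_g2[[i]] + events$sjc_g2[[i]])
    if (all(is.na(tot))) 0L else max(tot, na.rm = TRUE)
  }, numeric(1))

  ok_count <- max_support >= config$min_count
  ok_fdr <- !is.na(events$fdr) & events$fdr < config$alpha_fdr
  ok_delta <- !is.na(events$inc_level_difference) &
    abs(events$inc_level_difference) > config$min_delta_psi
  ok_psi <- if (config$min_psi_rule == "either_group") {
    pmax(mean_psi1, mean_psi2) >= config$min_psi
  } else {
    mean_psi1 >= config$min_psi & mean_psi1 <= 1 - config$min_psi &
      mean_psi2 >= config$min_psi & mean_psi2 <= 1 - config$min_psi
  }
  keep <- !no_psi & ok_count & ok_fdr & ok_delta & ok_psi

  if (!is.null(config$tpm_min)) {
    if (is.null(tpm) || is.null(groups))
      abort("`tpm_min` is set but no expression table/groups were supplied")
    expressed <- tpm_filter(tpm, config$tpm_min, mode = "group",
                            groups = groups)
    keep <- keep & events$gene_id %in% expressed
  }
  events[keep & !is.na(keep), ]
}

#' Mutation-specific splicing events across comparisons
#'
#' Computes `(A` \eqn{\cap} `B) \ C` on event sets keyed by their full
#' coordinates: events significant in both the affected-vs-control and
#' affected-vs-asymptomatic comparisons but not in the
#' asymptomatic-vs-control comparison. With `exclude = NULL` the result is
#' the plain intersection (two-set mode); with `b = NULL` the single set
#' `a` is passed through, for designs with one informative comparison.
#' Duplicate keys within a set collapse with a warning.
#'
#' @param a,b Event tibbles from [significant_events()]; rows of `a` carry
#'   through to the result.
#' @param exclude Event tibble whose keys are removed from the result.
#' @return A `splice_intersection`: `events`, `unique_genes`, and
#'   per-input sizes.
#' @export
intersect_mutation_specific <- function(a, b = NULL, exclude = NULL) {
  dedupe <- function(x, label) {
    if (is.null(x)) return(NULL)
    if (anyDuplicated(x$event_key)) {
      warn(sprintf("%d duplicate event key(s) collapsed in `%s`",
                   sum(duplicated(x$event_key)), label))
      x <- x[!duplicated(x$event_key), ]
    }
    x
  }
  a <- dedupe(a, "a"); b <- dedupe(b, "b"); exclude <- dedupe(exclude, "exclude")
  keys <- a$event_key
  if (!is.null(b)) keys <- intersect(keys, b$event_key)
  if (!is.null(exclude)) keys <- setdiff(keys, exclude$event_key)
  events <- a[match(keys, a$event_key), ]
  structure(
    list(events = events,
         unique_genes = unique(events$gene_id),
         sizes = c(a = nrow(a), b = if (is.null(b)) NA_integer_ else nrow(b),
                   exclude = if (is.null(exclude)) NA_integer_
                             else nrow(exclude),
                   selected = nrow(events))),
    class = "splice_intersection")
}

#' @export
print.splice_intersection <- function(x, ...) {
  cat(sprintf("<splice_intersection> %d events on %d unique genes\n",
              nrow(x$events), length(x$unique_genes)))
  invisible(x)
}

#' @export
tidy.splice_intersection <- function(x, ...) x$events

#' @export
glance.splice_intersection <- function(x, ...) {
  tibble(n_events = nrow(x$events),
         n_unique_genes = length(x$unique_genes),
         n_a = unname(x$sizes["a"]), n_b = unname(x$sizes["b"]),
         n_exclude = unname(x$sizes["exclude"]))
}

#' Event-type composition of a selected event set
#'
#' Counts and percentages per event type (skipped exon, mutually exclusive
#' exons, retained intron, alternative 5'/3' splice site) plus the number
#' of distinct host genes — the numbers behind an event-type pie chart.
#'
#' @param x A `splice_intersection` or an events tibble.
#' @return Tibble with `event_type`, `count`, `percent`, and the unique
#'   gene count in `attr(, "n_unique_genes")`.
#' @export
splice_composition <- function(x) {
  events <- if (inherits(x, "splice_intersection")) x$events else x
  counts <- table(factor(events$event_type, levels = SPLICE_TYPES))
  total <- sum(counts)
  out <- tibble(event_type = SPLICE_TYPES,
                count = as.integer(counts),
                percent = if (total > 0) 100 * as.integer(counts) / total
                          else rep(0, length(SPLICE_TYPES)))
  attr(out, "n_unique_genes") <- length(unique(events$gene_id))
  out
}

#' @importFrom ggplot2 coord_polar theme_void geom_bar
#' @export
autoplot.splice_intersection <- function(object, ...) {
  comp <- splice_composition(object)
  comp <- filter(comp, .data$count > 0)
  ggplot(comp, aes(x = "", y = .data$percent, fill = .data$event_type)) +
    geom_col(width = 1) +
    coord_polar("y") +
    theme_void() +
    labs(fill = "event type",
         title = sprintf("%d events, %d unique genes",
                         nrow(object$events),
                         length(object$unique_genes)))
}
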