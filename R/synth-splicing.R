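# Synthetic rMATS-dialect splicing-event tables with planted significant
# events per comparison, plus the dialect writer used for round-tripping.

#' Specification for synthetic splicing-event tables
#'
#' One shared catalogue of events (types, coordinates, host genes) is
#' simulated for all comparisons, so that event identity is preserved
#' across comparisons and set logic on the results is meaningful.
#' Junction read counts are binomial around group inclusion levels;
#' planted events shift the first group's PSI by the requested amount in
#' the chosen comparisons.
#'
#' @param n_events Number of events in the catalogue.
#' @param type_mix Named proportions over `SE`, `MXE`, `RI`, `A5SS`,
#'   `A3SS`; must sum to 1.
#' @param comparisons Ordered comparison labels.
#' @param planted_significant Named list mapping a comparison label to
#'   `list(events =, delta_psi =)`: event indices and target |PSI
#'   difference| magnitudes in (0, 1] (recycled).
#' @param reps_per_side Replicates per side of each comparison.
#' @param mean_junction_depth Mean junction read depth per replicate.
#' @param rng_seed Integer seed.
#' @return A `splice_table_spec`.
#' @export
splice_table_spec <- function(n_events = 2000,
                              type_mix = c(SE = 0.5, MXE = 0.22, RI = 0.12,
                                           A5SS = 0.08, A3SS = 0.08),
                              comparisons = c("affected_vs_control",
                                              "affected_vs_asympto",
                                              "asympto_vs_control"),
                              planted_significant = list(),
                              reps_per_side = 3,
                              mean_junction_depth = 500,
                              rng_seed = 1L) {
  check_scalar(n_events, "n_events", lower = 1, integerish = TRUE)
  if (!setequal(names(type_mix), SPLICE_TYPES))
    abort("`type_mix` must name exactly SE, MXE, RI, A5SS, A3SS")
  if (abs(sum(type_mix) - 1) > 1e-9) abort("`type_mix` must sum to 1")
  if (length(comparisons) < 1L || anyDuplicated(comparisons))
    abort("`comparisons` must be distinct labels")
  for (cmp in names(planted_significant)) {
    if (!cmp %in% comparisons)
      abort(sprintf("planted comparison `%s` is not in `comparisons`", cmp))
    s <- planted_significant[[cmp]]
    if (any(s$events < 1 | s$events > n_events))
      abort("planted event indices out of range")
    if (any(s$delta_psi <= 0 | s$delta_psi > 1))
      abort("planted delta_psi magnitudes must be in (0, 1]")
  }
  check_scalar(reps_per_side, "reps_per_side", lower = 1,
               integerish = TRUE)
  check_scalar(mean_junction_depth, "mean_junction_depth", lower = 0,
               strict_lower = TRUE)
  check_scalar(rng_seed, "rng_seed", integerish = TRUE)
  structure(list(n_events = as.integer(n_events),
                 type_mix = type_mix[SPLICE_TYPES],
                 comparisons = comparisons,
                 planted_significant = planted_significant,
                 reps_per_side = as.integer(reps_per_side),
                 mean_junction_depth = mean_junction_depth,
                 rng_seed = as.integer(rng_seed)),
            class = "splice_table_spec")
}

# random type-specific coordinate tuple; 0-based starts, 1-based ends
# (half-open blocks), as written by rMATS
random_coords <- function(type, pos) {
  exon <- function(start) c(start, start + sample(80:300, 1))
  up <- exon(pos)
  mid1 <- exon(up[2] + sample(200:2000, 1))
  mid2 <- exon(mid1[2] + sample(200:2000, 1))
  down <- exon(mid2[2] + sample(200:2000, 1))
  v <- switch(type,
    SE   = c(mid1, up, down),
    MXE  = c(mid1, mid2, up, down),
    RI   = c(up[1], down[2], up, down),
    A5SS = c(up[1], mid1[2], up, down),
    A3SS = c(up[1], mid1[2], up, down))
  setNames(as.integer(v), rmats_coord_cols(type))
}

# two-proportion test on summed junction counts; the synthetic stand-in
# for the event-level significance an rMATS run would provide
junction_prop_test <- function(inc1, skip1, inc2, skip2) {
  x <- c(sum(inc1), sum(inc2))
  n <- c(sum(inc1) + sum(skip1), sum(inc2) + sum(skip2))
  if (any(n == 0)) return(1)
  suppressWarnings(prop.test(x, n)$p.value)
}

#' Simulate rMATS-style event tables per comparison
#'
#' @param spec A [splice_table_spec()].
#' @return A list of class `splice_sim`: `events` (named list of parsed
#'   event tibbles, one per comparison, in [read_rmats()] format),
#'   `truth` (tibble of event keys with one planted-flag column per
#'   comparison), and `spec`.
#' @export
simulate_splice_tables <- function(spec) {
  stopifnot(inherits(spec, "splice_table_spec"))
  n <- spec$n_events
  R <- spec$reps_per_side
  with_seed(spec$rng_seed, {
    types <- sample(SPLICE_TYPES, n, replace = TRUE, prob = spec$type_mix)
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_idx <- sort(sample(ceiling(n / 1.5), n, replace = TRUE))
    gene_id <- sprintf("SGENE%05d", gene_idx)
    gene_symbol <- sprintf("SYM%05d", gene_idx)
    coords <- lapply(seq_len(n), function(i)
      random_coords(types[i], sample(1e4:1e8, 1)))
    base_psi <- runif(n, 0.15, 0.85)

    skeleton <- tibble(event_type = types,
                       event_id = as.character(seq_len(n) - 1L),
                       gene_id = gene_id, gene_symbol = gene_symbol,
                       chrom = chrom, strand = strand, coords = coords)
    keys <- event_keys(skeleton)

    truth <- tibble(event_key = keys)
    events <- list()
    for (cmp in spec$comparisons) {
      psi1 <- base_psi
      psi2 <- base_psi
      planted <- rep(FALSE, n)
      pl <- spec$planted_significant[[cmp]]
      if (!is.null(pl)) {
        d <- rep_len(pl$delta_psi, length(pl$events))
        up <- base_psi[pl$events] + d <= 0.98
        psi1[pl$events] <- ifelse(up, base_psi[pl$events] + d,
                                  base_psi[pl$events] - d)
        planted[pl$events] <- TRUE
      }
      draw_side <- function(psi) {
        depth <- matrix(pmax(1L, rpois(n * R, spec$mean_junction_depth)),
                        n, R)
        inc <- matrix(rbinom(n * R, as.vector(depth), rep(psi, R)), n, R)
        list(inc = inc, skip = depth - inc)
      }
      s1 <- draw_side(psi1); s2 <- draw_side(psi2)
      obs1 <- lapply(seq_len(n), function(i)
        round(s1$inc[i, ] / (s1$inc[i, ] + s1$skip[i, ]), 3))
      obs2 <- lapply(seq_len(n), function(i)
        round(s2$inc[i, ] / (s2$inc[i, ] + s2$skip[i, ]), 3))
      pv <- vapply(seq_len(n), function(i)
        junction_prop_test(s1$inc[i, ], s1$skip[i, ],
                           s2$inc[i, ], s2$skip[i, ]), numeric(1))
      tab <- skeleton |>
        mutate(ijc_g1 = lapply(seq_len(n), function(i) s1$inc[i, ]),
               sjc_g1 = lapply(seq_len(n), function(i) s1$skip[i, ]),
               ijc_g2 = lapply(seq_len(n), function(i) s2$inc[i, ]),
               sjc_g2 = lapply(seq_len(n), function(i) s2$skip[i, ]),
               psi_g1 = obs1, psi_g2 = obs2,
               pvalue = pv, fdr = p.adjust(pv, "BH"),
               inc_level_difference =
                 vapply(seq_len(n), function(i)
                   mean(obs1[[i]]) - mean(obs2[[i]]), numeric(1)),
               event_key = keys)
      events[[cmp]] <- tab
      truth[[cmp]] <- planted
    }
    structure(list(events = events, truth = truth, spec = spec),
              class = "splice_sim")
  })
}

#' Write event tables in the rMATS junction-count dialect
#'
#' Serializes a parsed event tibble back to one `<TYPE>.MATS.JC.txt` file
#' per event type (tab-delimited, comma-joined replicate lists, `NA` for
#' missing PSI), so that [read_rmats()] round-trips the table.
#'
#' @param events Parsed event tibble (the [read_rmats()] format).
#' @param dir Output directory, created if missing.
#' @return Character vector of files written, invisibly.
#' @export
write_rmats <- function(events, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  join <- function(col) vapply(col, function(v) {
    v <- as.character(v)
    v[is.na(v)] <- "NA"
    paste(v, collapse = ",")
  }, character(1))
  files <- character(0)
  for (type in SPLICE_TYPES) {
    d <- events[events$event_type == type, ]
    if (nrow(d) == 0L) next
    ccols <- rmats_coord_cols(type)
    cm <- do.call(rbind, d$coords)
    out <- data.frame(ID = d$event_id, GeneID = d$gene_id,
                      geneSymbol = d$gene_symbol, chr = d$chrom,
                      strand = d$strand, check.names = FALSE)
    for (j in seq_along(ccols)) out[[sub("^\\.\\.", "", ccols[j])]] <- cm[, j]
    out$IJC_SAMPLE_1 <- join(d$ijc_g1)
    out$SJC_SAMPLE_1 <- join(d$sjc_g1)
    out$IJC_SAMPLE_2 <- join(d$ijc_g2)
    out$SJC_SAMPLE_2 <- join(d$sjc_g2)
    out$IncFormLen <- 2L
    out$SkipFormLen <- 1L
    out$PValue <- d$pvalue
    out$FDR <- d$fdr
    out$IncLevel1 <- join(d$psi_g1)
    out$IncLevel2 <- join(d$psi_g2)
    out$IncLevelDifference <- d$inc_level_difference
    path <- file.path(dir, paste0(type, ".MATS.JC.txt"))
    readr::write_tsv(out, path)
    files <- c(files, path)
  }
  invisible(files)
}

#' Write a splicing simulation to disk
#'
#' One sub-directory of rMATS-dialect files per comparison, the truth
#' flags as TSV, and a JSON manifest.
#'
#' @param x A `splice_sim`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_splice_sim <- function(x, dir) {
  stopifnot(inherits(x, "splice_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cmp in names(x$events))
    write_rmats(x$events[[cmp]], file.path(dir, cmp))
  readr::write_tsv(x$truth, file.path(dir, "truth.tsv"))
  write_manifest(run_manifest("splicing", x$spec, x$spec$rng_seed,
                              list(n_events = x$spec$n_events)),
                 file.path(dir, "manifest.json"))
  invisible(dir)
}
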