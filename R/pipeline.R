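# End-to-end orchestration: one config drives synthetic-data generation,
# morphometry, DEG selection, splice selection, and assay quantification,
# each stage writing tables plus a JSON manifest.

#' Default pipeline configuration
#'
#' Builds the configuration for [run_pipeline()]. Stage seeds are derived
#' from the global seed by hashing the stage name, so stages draw
#' independent reproducible streams. The demo problem sizes are a 512 x
#' 512 epithelium with 150 cells, a 5000-gene expression table with a
#' 300-gene planted mutation-specific set, 2000-event splicing tables
#' with planted mutation-specific and shared events, and the standard
#' assay fixtures.
#'
#' @param out_dir Output directory.
#' @param rng_seed Global integer seed.
#' @param stages Stages to run, a subset of `synthetic`, `morphometry`,
#'   `deg`, `splice`, `assay`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, rng_seed = 1L,
                            stages = c("synthetic", "morphometry", "deg",
                                       "splice", "assay")) {
  known <- c("synthetic", "morphometry", "deg", "splice", "assay")
  bad <- setdiff(stages, known)
  if (length(bad))
    abort(sprintf("unknown stage name(s): %s", paste(bad, collapse = ", ")))
  check_scalar(rng_seed, "rng_seed", integerish = TRUE)
  structure(list(out_dir = out_dir, rng_seed = as.integer(rng_seed),
                 stages = stages),
            class = "pipeline_config")
}

demo_specs <- function(config) {
  seed <- config$rng_seed
  list(
    epithelium = epithelium_spec(rng_seed = derive_seed(seed, "epithelium")),
    expression = count_table_spec(
      planted_sets = list(list(genes = 1:300,
                               offsets = c(0, 0, 3, 0),
                               label = "mutation_specific")),
      rng_seed = derive_seed(seed, "expression")),
    splicing = splice_table_spec(
      planted_significant = list(
        affected_vs_control = list(events = 1:150, delta_psi = 0.4),
        affected_vs_asympto = list(events = 1:150, delta_psi = 0.4),
        asympto_vs_control = list(events = 151:200, delta_psi = 0.4)),
      rng_seed = derive_seed(seed, "splicing")),
    assay_seed = derive_seed(seed, "assays"))
}

#' Run the analysis pipeline from one configuration
#'
#' Executes the requested stages in order: synthetic data generation,
#' then morphometry on the generated junction image, DEG cluster
#' selection on the generated expression table, splice-event selection
#' and intersection on the generated event tables, and assay
#' quantification of the generated fixtures. Every stage writes its
#' tables and a manifest (config hash, seed, row counts) under its own
#' sub-directory; a failing stage aborts with its name while earlier
#' outputs remain on disk.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of stage manifests (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- demo_specs(config)
  manifests <- list()
  stage_dir <- function(s) file.path(config$out_dir, s)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  if ("synthetic" %in% config$stages) {
    manifests$synthetic <- run_stage("synthetic", function() {
      d <- stage_dir("synthetic")
      epi <- simulate_epithelium(specs$epithelium)
      write_epithelium(epi, file.path(d, "epithelium"))
      expr <- simulate_count_table(specs$expression)
      write_expression_sim(expr, file.path(d, "expression"))
      spl <- simulate_splice_tables(specs$splicing)
      write_splice_sim(spl, file.path(d, "splicing"))
      fixtures <- simulate_assay_fixtures(specs$assay_seed)
      write_assay_fixtures(fixtures, file.path(d, "assays"))
      m <- run_manifest("synthetic", specs, config$rng_seed,
                        list(n_cells = specs$epithelium$n_cells,
                             n_genes = specs$expression$n_genes,
                             n_events = specs$splicing$n_events))
      write_manifest(m, file.path(d, "manifest.json"))
      m
    })
  }

  if ("morphometry" %in% config$stages) {
    manifests$morphometry <- run_stage("morphometry", function() {
      d <- stage_dir("morphometry")
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      img_path <- file.path(stage_dir("synthetic"), "epithelium",
                            "epithelium.tif")
      if (!file.exists(img_path))
        abort("no epithelium image; run the synthetic stage first")
      img <- tiff::readTIFF(img_path)
      mcfg <- morphometry_config()
      records <- measure_epithelium(img, mcfg)
      readr::write_tsv(records, file.path(d, "shape_records.tsv"))
      dist <- summarize_distribution(records, "convexity", group = "demo")
      readr::write_tsv(dist$bins, file.path(d, "convexity_distribution.tsv"))
      readr::write_tsv(dist$summary, file.path(d, "convexity_summary.tsv"))
      m <- run_manifest("morphometry", mcfg, config$rng_seed,
                        list(n_cells = nrow(records)))
      write_manifest(m, file.path(d, "manifest.json"))
      m
    })
  }

  if ("deg" %in% config$stages) {
    manifests$deg <- run_stage("deg", function() {
      d <- stage_dir("deg")
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      expr <- simulate_count_table(specs$expression)
      stats <- welch_de_stats(expr$tpm, expr$groups,
                              list(c("affected", "control"),
                                   c("affected", "asymptomatic")))
      sel <- select_mutation_specific_genes(expr$tpm, expr$groups, stats,
                                            affected_group = "affected")
      readr::write_tsv(tibble(gene_id = sel$selected_genes),
                       file.path(d, "selected_genes.tsv"))
      if (!is.null(sel$clusters))
        readr::write_tsv(tidy(sel$clusters),
                         file.path(d, "cluster_assignments.tsv"))
      m <- run_manifest("deg", sel$params, config$rng_seed,
                        list(n_expressed = length(sel$expressed),
                             n_degs = length(sel$degs$union),
                             n_selected = length(sel$selected_genes)))
      write_manifest(m, file.path(d, "manifest.json"))
      m
    })
  }

  if ("splice" %in% config$stages) {
    manifests$splice <- run_stage("splice", function() {
      d <- stage_dir("splice")
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      spl <- simulate_splice_tables(specs$splicing)
      scfg <- splice_selection_config()
      sig <- lapply(spl$events, significant_events, config = scfg)
      res <- intersect_mutation_specific(sig$affected_vs_control,
                                         sig$affected_vs_asympto,
                                         sig$asympto_vs_control)
      comp <- splice_composition(res)
      out <- select(res$events, -"coords", -dplyr::starts_with("ijc"),
                    -dplyr::starts_with("sjc"), -dplyr::starts_with("psi"))
      readr::write_tsv(out, file.path(d, "selected_events.tsv"))
      readr::write_csv(comp, file.path(d, "composition.csv"))
      m <- run_manifest("splice", scfg, config$rng_seed,
                        list(sizes = as.list(res$sizes),
                             n_unique_genes = length(res$unique_genes)))
      write_manifest(m, file.path(d, "manifest.json"))
      m
    })
  }

  if ("assay" %in% config$stages) {
    manifests$assay <- run_stage("assay", function() {
      d <- stage_dir("assay")
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      fx <- simulate_assay_fixtures(specs$assay_seed)
      ter <- mutate(fx$ter, ter_ohm_cm2 = suppressWarnings(
        ter_normalize(.data$raw_ohm, .data$blank_ohm, .data$area_cm2)))
      phago <- bind_cols(fx$phagocytosis, suppressWarnings(
        phagocytosis_ratios(fx$phagocytosis$total_fitc,
                            fx$phagocytosis$quenched_fitc,
                            fx$phagocytosis$dapi)))
      ctrl_ratio <- mean(with(fx$western[fx$western$group == "control", ],
                              target_band / loading_band))
      west <- bind_cols(fx$western,
                        band_ratio_fold(fx$western$target_band,
                                        fx$western$loading_band,
                                        ctrl_ratio))
      ref_dct <- mean(with(fx$qpcr[fx$qpcr$group == "control", ],
                           ct_target - ct_housekeeping))
      qp <- mutate(fx$qpcr, fold = dct_fold(.data$ct_target,
                                            .data$ct_housekeeping, ref_dct))
      cnt <- mutate(fx$counting,
                    marker_pct = marker_fraction(.data$n_marker,
                                                 .data$n_dapi),
                    density = onl_density(.data$n_dapi,
                                          .data$region_area_mm2))
      readr::write_csv(ter, file.path(d, "ter.csv"))
      readr::write_csv(phago, file.path(d, "phagocytosis.csv"))
      readr::write_csv(west, file.path(d, "western.csv"))
      readr::write_csv(qp, file.path(d, "qpcr.csv"))
      readr::write_csv(cnt, file.path(d, "counting.csv"))
      kw <- group_test(ter$ter_ohm_cm2, ter$group)
      m <- run_manifest("assay", list(), config$rng_seed,
                        list(n_rows = nrow(ter),
                             ter_kruskal_p = kw$omnibus$p.value))
      write_manifest(m, file.path(d, "manifest.json"))
      m
    })
  }

  write_manifest(list(seed = config$rng_seed, stages = config$stages,
                      manifests = manifests),
                 file.path(config$out_dir, "report.json"))
  invisible(manifests)
}

#' Run the full demo pipeline on synthetic data
#'
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return Invisibly, the stage manifests.
#' @export
demo_pipeline <- function(seed = 1L, out_dir = tempfile("rpekit_demo_")) {
  run_pipeline(pipeline_config(out_dir, rng_seed = seed))
}

#' Measure cell shapes from a junction-stained image
#'
#' Convenience wrapper chaining [preprocess_junctions()],
#' [partition_cells()], [postfilter_labels()], and [measure_shapes()].
#'
#' @param image Numeric intensity matrix.
#' @param config A [morphometry_config()].
#' @param pixel_size_um Optional pixel size for micrometre areas.
#' @return Tibble of per-cell shape records.
#' @export
measure_epithelium <- function(image, config = morphometry_config(),
                               pixel_size_um = NULL) {
  mask <- preprocess_junctions(image, config)
  labels <- partition_cells(mask, config)
  labels <- postfilter_labels(labels, config)
  if (max(labels$labels) == 0L)
    return(tibble(cell_id = integer(0), area_px = integer(0),
                  perimeter_px = numeric(0),
                  convex_perimeter_px = numeric(0), convexity = numeric(0),
                  geodesic_diameter_px = numeric(0),
                  touches_edge = logical(0), excluded = logical(0)))
  measure_shapes(labels, pixel_size_um)
}
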