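# Small seeded assay fixtures with closed-form expected answers, shaped
# like the raw measurement tables the quantification functions consume.

#' Simulate raw assay measurement tables
#'
#' Generates one tibble per assay (TER, phagocytosis, western blot, qPCR,
#' marker counting / ONL density) for a four-group design with the group
#' effects typical of a splicing-factor haploinsufficiency phenotype:
#' mutated cells lose barrier resistance, internalize about half as many
#' particles, and express about a fifth of the control protein level.
#' All raw values are drawn with modest Gaussian noise so normalized
#' results are recoverable in closed form from the raw columns.
#'
#' @param rng_seed Integer seed.
#' @param groups Group labels; the second is treated as the affected line.
#' @param n_per_group Replicates per group.
#' @return Named list of tibbles: `ter`, `phagocytosis`, `western`,
#'   `qpcr`, `counting`.
#' @export
simulate_assay_fixtures <- function(rng_seed = 1L,
                                    groups = c("control", "affected",
                                               "asymptomatic", "isogenic"),
                                    n_per_group = 9) {
  check_scalar(rng_seed, "rng_seed", integerish = TRUE)
  check_scalar(n_per_group, "n_per_group", lower = 3, integerish = TRUE)
  G <- length(groups)
  n <- G * n_per_group
  grp <- rep(groups, each = n_per_group)
  affected <- grp == groups[2]
  with_seed(rng_seed, {
    pos <- function(x) pmax(x, 0.1)
    ter <- tibble(
      group = grp, sample = paste0(grp, "_", seq_len(n)),
      raw_ohm = pos(rnorm(n, ifelse(affected, 102, 250), 8)),
      blank_ohm = pos(rnorm(n, 100, 2)),
      area_cm2 = 1.12)
    phago <- tibble(
      group = grp, sample = paste0(grp, "_", seq_len(n)),
      total_fitc = pos(rnorm(n, ifelse(affected, 550, 1000), 60)),
      dapi = pos(rnorm(n, 200, 15)))
    phago$quenched_fitc <- pos(pmin(
      rnorm(n, ifelse(affected, 300, 600), 40), phago$total_fitc))
    western <- tibble(
      group = grp, sample = paste0(grp, "_", seq_len(n)),
      target_band = pos(rnorm(n, ifelse(affected, 100, 500), 30)),
      loading_band = pos(rnorm(n, 250, 20)))
    qpcr <- tibble(
      group = grp, sample = paste0(grp, "_", seq_len(n)),
      ct_target = rnorm(n, ifelse(affected, 26.3, 24), 0.2),
      ct_housekeeping = rnorm(n, 10, 0.15))
    counting <- tibble(
      group = grp, sample = paste0(grp, "_", seq_len(n)),
      n_marker = rbinom(n, 300, ifelse(affected, 0.08, 0.15)),
      n_dapi = 300L,
      region_area_mm2 = 0.01)
    list(ter = ter, phagocytosis = phago, western = western, qpcr = qpcr,
         counting = counting)
  })
}

#' Write assay fixtures as CSV files
#'
#' @param fixtures List from [simulate_assay_fixtures()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_assay_fixtures <- function(fixtures, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(fixtures))
    readr::write_csv(fixtures[[nm]], file.path(dir, paste0(nm, ".csv")))
  invisible(dir)
}
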