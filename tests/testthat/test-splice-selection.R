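# Splice-event filtering, multi-comparison set logic, and composition.

test_that("threshold boundaries follow the stated strict/inclusive semantics", {
  # all predicates clear
  keep <- make_event(psi1 = c(0.30, 0.30, 0.30), psi2 = c(0.15, 0.15, 0.15),
                     fdr = 0.04, depth = 50)
  expect_equal(nrow(significant_events(keep)), 1L)
  # delta-PSI exactly 0.10 is dropped (strict >)
  border <- make_event(psi1 = c(0.30, 0.30, 0.30),
                       psi2 = c(0.20, 0.20, 0.20), fdr = 0.01, depth = 50)
  expect_equal(border$inc_level_difference, 0.10)
  expect_equal(nrow(significant_events(border)), 0L)
  # FDR exactly 0.05 is dropped (strict <)
  fb <- make_event(fdr = 0.05)
  expect_equal(nrow(significant_events(fb)), 0L)
  # min PSI inclusive at the cutoff (probed at 0.5 where it binds)
  cfg5 <- splice_selection_config(min_psi = 0.5)
  at <- make_event(psi1 = c(0.5, 0.5, 0.5), psi2 = c(0.2, 0.2, 0.2),
                   fdr = 0.01)
  expect_equal(nrow(significant_events(at, cfg5)), 1L)
  under <- make_event(psi1 = c(0.49, 0.49, 0.49), psi2 = c(0.2, 0.2, 0.2),
                      fdr = 0.01)
  expect_equal(nrow(significant_events(under, cfg5)), 0L)
})

test_that("the bounded-both PSI rule is available as a config switch", {
  ev <- make_event(psi1 = c(0.95, 0.95, 0.95), psi2 = c(0.5, 0.5, 0.5),
                   fdr = 0.01)
  expect_equal(nrow(significant_events(ev)), 1L)
  cfg <- splice_selection_config(min_psi_rule = "bounded_both")
  expect_equal(nrow(significant_events(ev, cfg)), 0L)
})

test_that("junction-count support and missing-PSI rules apply", {
  weak <- make_event(depth = 1, fdr = 0.01)
  weak$ijc_g1 <- list(c(1L, 0L, 0L)); weak$sjc_g1 <- list(c(0L, 0L, 0L))
  weak$ijc_g2 <- list(c(0L, 0L, 0L)); weak$sjc_g2 <- list(c(1L, 0L, 0L))
  expect_equal(nrow(significant_events(weak,
    splice_selection_config(min_count = 2))), 0L)
  gone <- make_event(psi1 = c(NA, NA, NA), fdr = 0.01)
  expect_message(out <- significant_events(gone), "no PSI")
  expect_equal(nrow(out), 0L)
})

test_that("the TPM floor on host genes requires an expression table", {
  ev <- make_event(gene_id = "G001")
  cfg <- splice_selection_config(tpm_min = 5)
  expect_error(significant_events(ev, cfg), "expression table")
  tpm <- tibble::tibble(gene_id = "G001", s1 = 10, s2 = 10, s3 = 1, s4 = 1)
  groups <- tibble::tibble(sample = paste0("s", 1:4),
                           group = c("a", "a", "b", "b"))
  expect_equal(nrow(significant_events(ev, cfg, tpm, groups)), 1L)
  tpm_low <- tibble::tibble(gene_id = "G001", s1 = 2, s2 = 2, s3 = 1, s4 = 1)
  expect_equal(nrow(suppressWarnings(
    significant_events(ev, cfg, tpm_low, groups))), 0L)
})

test_that("filtering matches brute-force enumeration with boundary rows", {
  spec <- splice_table_spec(n_events = 1000,
                            planted_significant = list(
                              affected_vs_control = list(events = 1:60,
                                                         delta_psi = 0.35)),
                            rng_seed = 8)
  sim <- simulate_splice_tables(spec)
  ev <- sim$events$affected_vs_control
  # force boundary statistics onto some rows
  ev$fdr[101:110] <- 0.05
  ev$inc_level_difference[111:120] <- 0.10
  cfg <- splice_selection_config()
  got <- suppressMessages(significant_events(ev, cfg))
  expect_setequal(got$event_key, brute_splice(ev, cfg))
  # idempotence
  again <- suppressMessages(significant_events(got, cfg))
  expect_setequal(again$event_key, got$event_key)
})

test_that("tightening any threshold never grows the selected set", {
  sim <- simulate_splice_tables(splice_table_spec(
    n_events = 600,
    planted_significant = list(affected_vs_control = list(
      events = 1:50, delta_psi = 0.3)),
    rng_seed = 12))
  ev <- sim$events$affected_vs_control
  base <- suppressMessages(significant_events(ev))$event_key
  tighter <- list(splice_selection_config(min_psi = 0.3),
                  splice_selection_config(min_delta_psi = 0.2),
                  splice_selection_config(alpha_fdr = 0.01),
                  splice_selection_config(min_count = 50))
  for (cfg in tighter) {
    got <- suppressMessages(significant_events(ev, cfg))$event_key
    expect_true(all(got %in% base))
  }
})

test_that("set logic matches hand-computed examples", {
  e1 <- make_event(chrom = "chr1", start = 100L)
  e2 <- make_event(chrom = "chr2", start = 500L)
  e3 <- make_event(chrom = "chr3", start = 900L)
  a <- dplyr::bind_rows(e1, e2)
  b <- dplyr::bind_rows(e2, e3)
  c2 <- e2
  expect_equal(nrow(intersect_mutation_specific(a, b, c2)$events), 0L)
  res <- intersect_mutation_specific(a, b, NULL)
  expect_equal(res$events$event_key, e2$event_key)
  # single-set pass-through
  expect_equal(nrow(intersect_mutation_specific(a)$events), 2L)
})

test_that("duplicate event keys collapse with a warning", {
  e <- make_event()
  expect_warning(res <- intersect_mutation_specific(dplyr::bind_rows(e, e)),
                 "duplicate")
  expect_equal(nrow(res$events), 1L)
})

test_that("intersection is invariant to input row order", {
  sim <- simulate_splice_tables(splice_table_spec(
    n_events = 300,
    planted_significant = list(
      affected_vs_control = list(events = 1:40, delta_psi = 0.35),
      affected_vs_asympto = list(events = 1:40, delta_psi = 0.35)),
    rng_seed = 3))
  sig <- suppressMessages(lapply(sim$events, significant_events))
  r1 <- intersect_mutation_specific(sig[[1]], sig[[2]], sig[[3]])
  set.seed(1)
  shuf <- lapply(sig, function(d) d[sample(nrow(d)), ])
  r2 <- intersect_mutation_specific(shuf[[1]], shuf[[2]], shuf[[3]])
  expect_setequal(r1$events$event_key, r2$events$event_key)
})

test_that("composition reports per-type percentages and unique genes", {
  evs <- dplyr::bind_rows(
    lapply(1:10, function(i) make_event("SE", chrom = paste0("chr", i),
                                        gene_id = sprintf("G%d", i %% 3))),
    lapply(1:10, function(i) make_event("MXE", chrom = paste0("chr", i),
                                        gene_id = "GX")))
  comp <- splice_composition(evs)
  expect_equal(comp$percent[comp$event_type == "SE"], 50)
  expect_equal(comp$percent[comp$event_type == "MXE"], 50)
  expect_equal(sum(comp$percent), 100, tolerance = 0.1)
  expect_equal(attr(comp, "n_unique_genes"), 4L)
})

test_that("a planted type mix is recovered within binomial error at n = 2000", {
  mix <- c(SE = 0.5, MXE = 0.22, RI = 0.12, A5SS = 0.08, A3SS = 0.08)
  sim <- simulate_splice_tables(splice_table_spec(
    n_events = 2000, type_mix = mix, comparisons = "a_vs_b",
    rng_seed = 77))
  comp <- splice_composition(sim$events$a_vs_b)
  for (t in names(mix)) {
    p_hat <- comp$percent[comp$event_type == t] / 100
    half_ci <- 2.58 * sqrt(mix[[t]] * (1 - mix[[t]]) / 2000)
    expect_lt(abs(p_hat - mix[[t]]), half_ci + 1e-12)
  }
})
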