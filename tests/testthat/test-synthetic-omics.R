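# Expression and splicing generators: closed-form means, planted-signal
# strength, dialect round-trip, and assay fixture identities.

test_that("zero-dispersion single-replicate counts equal the planted means", {
  spec <- count_table_spec(n_genes = 200, reps_per_group = 1,
                           dispersion = 0, baseline_log_mean = 8,
                           baseline_log_sd = 0.5,
                           planted_sets = list(list(genes = 1:50,
                                                    offsets = c(0, 0, 2, 0),
                                                    label = "up")),
                           rng_seed = 9)
  sim <- simulate_count_table(spec)
  counts <- as.matrix(sim$counts[-1])
  # reconstruct the model means from the spec's own generative form
  expected <- withr::with_seed(9, {
    b <- rnorm(200, 8, 0.5)
    mu <- matrix(2^b, 200, 4)
    mu[1:50, 3] <- 2^(b[1:50] + 2)
    mu
  })
  expect_true(all(abs(counts - expected) / expected < 0.01))
})

test_that("planted (0,0,+3,0) genes overwhelmingly clear the fold-change filter", {
  spec <- count_table_spec(planted_sets = list(
    list(genes = 1:300, offsets = c(0, 0, 3, 0), label = "ms")),
    rng_seed = 21)
  sim <- simulate_count_table(spec)
  st <- welch_de_stats(sim$tpm, sim$groups, list(c("affected", "control")))
  planted <- sprintf("GENE%05d", 1:300)
  frac <- mean(abs(st$log2fc[st$gene_id %in% planted]) >= 1)
  expect_gte(frac, 0.9)
})

test_that("welch statistics match a direct per-gene t-test", {
  spec <- count_table_spec(n_genes = 50, rng_seed = 2)
  sim <- simulate_count_table(spec)
  st <- welch_de_stats(sim$tpm, sim$groups, list(c("affected", "control")))
  vals <- log2(as.matrix(sim$tpm[-1]) + 1)
  g <- sim$groups$group
  for (i in c(1, 17, 50)) {
    ref <- t.test(vals[i, g == "affected"], vals[i, g == "control"])
    expect_equal(st$pval[i], ref$p.value, tolerance = 1e-12)
    expect_equal(st$log2fc[i],
                 mean(vals[i, g == "affected"]) -
                   mean(vals[i, g == "control"]),
                 tolerance = 1e-12)
  }
})

test_that("a null table yields few DEG false positives", {
  spec <- count_table_spec(n_genes = 1000, rng_seed = 31)
  sim <- simulate_count_table(spec)
  st <- welch_de_stats(sim$tpm, sim$groups, list(c("affected", "control")))
  cfg <- deg_filter_config(alpha_column = "pval")
  fp <- deg_filter(st, cfg, NULL)$union
  # loose null bound: the conjunction with |log2FC| >= 1 keeps the false
  # positive count well under alpha * n
  expect_lte(length(fp), 0.05 * 1000)
})

test_that("splice tables with no planted signal match brute-force filtering", {
  spec <- splice_table_spec(n_events = 500, rng_seed = 41)
  sim <- simulate_splice_tables(spec)
  cfg <- splice_selection_config()
  for (cmp in names(sim$events)) {
    got <- suppressMessages(significant_events(sim$events[[cmp]], cfg))
    expect_setequal(got$event_key, brute_splice(sim$events[[cmp]], cfg))
  }
})

test_that("an event built to clear every threshold survives the filters", {
  ev <- make_event(psi1 = c(0.9, 0.85, 0.9), psi2 = c(0.2, 0.25, 0.2),
                   fdr = 1e-6, depth = 100)
  expect_equal(nrow(significant_events(ev)), 1L)
})

test_that("a pure-SE mix reports a 100% skipped-exon composition", {
  spec <- splice_table_spec(n_events = 50,
                            type_mix = c(SE = 1, MXE = 0, RI = 0,
                                         A5SS = 0, A3SS = 0),
                            comparisons = "a_vs_b", rng_seed = 5)
  sim <- simulate_splice_tables(spec)
  comp <- splice_composition(sim$events$a_vs_b)
  expect_equal(comp$percent[comp$event_type == "SE"], 100)
  expect_true(all(comp$count[comp$event_type != "SE"] == 0))
})

test_that("rMATS dialect write-read round-trips the event table", {
  dir <- withr::local_tempdir()
  spec <- splice_table_spec(n_events = 120, comparisons = "a_vs_b",
                            planted_significant = list(
                              a_vs_b = list(events = 1:10,
                                            delta_psi = 0.3)),
                            rng_seed = 13)
  sim <- simulate_splice_tables(spec)
  orig <- sim$events$a_vs_b
  write_rmats(orig, dir)
  back <- read_rmats(dir)
  expect_setequal(back$event_key, orig$event_key)
  back <- back[match(orig$event_key, back$event_key), ]
  for (col in c("psi_g1", "psi_g2", "ijc_g1", "sjc_g2")) {
    expect_equal(back[[col]], orig[[col]], ignore_attr = TRUE)
  }
  expect_equal(back$fdr, orig$fdr)
  expect_equal(back$inc_level_difference, orig$inc_level_difference)
  expect_equal(back$coords, orig$coords)
})

test_that("reading a header-only table yields an empty tibble without error", {
  dir <- withr::local_tempdir()
  write_rmats(make_event(), dir)
  path <- file.path(dir, "SE.MATS.JC.txt")
  writeLines(readLines(path)[1], path)  # keep only the header row
  back <- read_rmats(c(SE = path))
  expect_equal(nrow(back), 0L)
})

test_that("PSI missing values parse as NA", {
  dir <- withr::local_tempdir()
  ev <- make_event(psi1 = c(0.9, 0.85, NA))
  ev$ijc_g1 <- list(c(90L, 85L, NA)); ev$sjc_g1 <- list(c(10L, 15L, NA))
  write_rmats(ev, dir)
  back <- read_rmats(c(SE = file.path(dir, "SE.MATS.JC.txt")))
  expect_equal(back$psi_g1[[1]], c(0.9, 0.85, NA))
})

test_that("assay fixtures regenerate identically under the same seed and obey identities", {
  a <- simulate_assay_fixtures(7)
  b <- simulate_assay_fixtures(7)
  expect_identical(a, b)
  # blank == well reading -> zero resistance
  expect_equal(ter_normalize(100, 100, 1.12), 0)
  # quenched == total -> no bound signal
  r <- phagocytosis_ratios(500, 500, 100)
  expect_equal(r$bound_ratio, 0)
})
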