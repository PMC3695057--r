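# Synthetic-data module: determinism, stated distributions, planting rules,
# conservation of counts.

test_that("UTR generation is deterministic, composition- and length-faithful", {
  cfg <- scenario_config(n_genes = 200, utr_length_mean = 120,
                         utr_length_sd = 30, rng_seed = 55)
  u1 <- generate_utr_set(cfg)
  u2 <- generate_utr_set(cfg)
  expect_identical(u1, u2)                     # same config+seed -> identical
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(u1, f1); write_fasta(u2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(length(u1), 200)
  expect_true(all(nchar(u1) >= 30))

  gc_only <- generate_utr_set(scenario_config(n_genes = 20, gc_fraction = 1,
                                              utr_length_mean = 50,
                                              utr_length_sd = 5,
                                              rng_seed = 2))
  expect_true(all(grepl("^[GC]+$", gc_only)))

  big <- generate_utr_set(scenario_config(n_genes = 1000,
                                          utr_length_mean = 800,
                                          utr_length_sd = 200,
                                          rng_seed = 3))
  se <- 200 / sqrt(1000)
  expect_lt(abs(mean(nchar(big)) - 800), 3 * se)
})

test_that("configuration invariants are enforced", {
  expect_error(scenario_config(gc_fraction = 1.2), "gc_fraction")
  expect_error(scenario_config(groups = c(naive = 1L, cond1 = 4L)), ">=2")
  expect_error(scenario_config(n_genes = 10, hub_spec = list(
    cond1 = list(mirna_id = NULL, direction = "down", target_fraction = 0.01,
                 target_log2_effect = 1, site_type = "8mer",
                 mirna_log2fc = 2))), ">= 1")
})

test_that("site planting follows the documented fraction and rounding rules", {
  set.seed(8)
  utrs <- stats::setNames(vapply(1:200, function(i) random_dna_str(100), ""),
                          sprintf("g%03d", 1:200))
  mir <- generate_mirna_set(1, rng_seed = 4)[[1]]

  none <- plant_seed_sites(utrs, mir, fraction = 0, rng_seed = 1)
  expect_identical(none$utrs, utrs)
  expect_equal(nrow(none$truth), 0)

  some <- plant_seed_sites(utrs, mir, fraction = 0.3, rng_seed = 1)
  expect_equal(nrow(some$truth), 60)           # 0.3 * 200
  # rounding: nearest, ties up -> 0.0025 * 200 = 0.5 -> 1
  tie <- plant_seed_sites(utrs, mir, fraction = 0.0025, rng_seed = 1)
  expect_equal(nrow(tie$truth), 1)
  # lengths unchanged (planting overwrites, never inserts)
  expect_equal(nchar(some$utrs), nchar(utrs))

  expect_error(plant_seed_sites(utrs, mir, fraction = 1.5), "0,1")

  all_planted <- plant_seed_sites(utrs, mir, fraction = 1, rng_seed = 2)
  got <- predict_targets(mir, all_planted$utrs)
  expect_true(all(names(utrs) %in% got$gene_id))
})

test_that("planted sites are present at the recorded positions", {
  set.seed(10)
  utrs <- stats::setNames(vapply(1:50, function(i) random_dna_str(80), ""),
                          sprintf("g%03d", 1:50))
  mir <- generate_mirna_set(1, rng_seed = 12)[[1]]
  planted <- plant_seed_sites(utrs, mir, fraction = 0.5, site_type = "8mer",
                              rng_seed = 3)
  word <- site_words(mir)[["8mer"]]
  for (i in seq_len(nrow(planted$truth))) {
    g <- planted$truth$gene_id[i]; s0 <- planted$truth$start[i]
    expect_equal(substr(planted$utrs[[g]], s0 + 1, s0 + 8), word)
    sites <- find_seed_sites(mir, planted$utrs[[g]], gene_id = g)
    expect_true(any(sites$start == s0 & sites$site_type == "8mer"))
  }
})

test_that("hub scenario conserves counts and encodes the planted structure", {
  cfg <- scenario_config(n_genes = 300, n_mirnas = 12,
                         utr_length_mean = 150, utr_length_sd = 30,
                         rng_seed = 71)
  b <- generate_hub_scenario(cfg)
  expect_equal(nrow(b$expression$values), 300)
  expect_equal(ncol(b$expression$values), sum(cfg$groups))
  expect_equal(nrow(b$mirna_counts$counts), 12)
  expect_equal(length(b$utrs), 300)
  expect_equal(length(b$mirnas), 12)
  expect_true(all(unlist(b$truth$targets) %in% names(b$utrs)))
  expect_true(all(b$truth$hubs$mirna_id %in% names(b$mirnas)))
  # the two hubs have disjoint planted target sets
  expect_equal(length(intersect(b$truth$targets[[1]], b$truth$targets[[2]])), 0)

  # determinism: identical bundle on regeneration
  b2 <- generate_hub_scenario(cfg)
  expect_identical(b$expression$values, b2$expression$values)
  expect_identical(b$mirna_counts$counts, b2$mirna_counts$counts)
  expect_identical(b$utrs, b2$utrs)

  # every planted target carries a detectable site for its hub
  for (cond in b$truth$hubs$condition) {
    hub <- b$truth$hubs$mirna_id[b$truth$hubs$condition == cond]
    got <- predict_targets(b$mirnas[[hub]], b$utrs)
    expect_true(all(b$truth$targets[[hub]] %in% got$gene_id))
  }
})

test_that("planted targets shift by the configured effect in the matching condition", {
  cfg <- scenario_config(n_genes = 400, n_mirnas = 8,
                         utr_length_mean = 100, utr_length_sd = 20,
                         rng_seed = 81)
  b <- generate_hub_scenario(cfg)
  g <- b$expression$groups
  lfc <- rowMeans(b$expression$values[, g == "cond1"]) -
         rowMeans(b$expression$values[, g == "naive"])
  hub1 <- b$truth$hubs$mirna_id[b$truth$hubs$condition == "cond1"]
  tgt <- b$truth$targets[[hub1]]
  # hub1 is down-regulated, so its targets move up by +1 log2 unit
  expect_equal(mean(lfc[tgt]), 1.0, tolerance = 0.1)
  expect_equal(mean(lfc[setdiff(names(b$utrs), unlist(b$truth$targets))]),
               0, tolerance = 0.1)
})

test_that("promoter planting records recoverable positions on both strands", {
  pwm <- score_pvalue_table(toy_pwm(width = 8, strength = 50))
  ps <- generate_promoter_set(30, length = 400, pwm, plant_fraction = 1,
                              rng_seed = 91)
  expect_equal(length(ps$promoters), 30)
  expect_equal(nrow(ps$truth), 30)
  expect_true(all(nchar(ps$promoters) == 400))
  word <- pwm_consensus(pwm)
  for (i in seq_len(nrow(ps$truth))) {
    id <- ps$truth$id[i]; off <- ps$truth$offset[i]
    expect_equal(substr(ps$promoters[[id]], off + 1, off + 8),
                 if (ps$truth$strand[i] == "+") word else dna_revcomp(word))
    hits <- scan_promoter(pwm, ps$promoters[[id]], p_max = 1e-4)
    expect_true(any(hits$offset == off & hits$strand == ps$truth$strand[i]))
  }
  expect_true(all(c("+", "-") %in% ps$truth$strand))

  none <- generate_promoter_set(10, length = 100, pwm, plant_fraction = 0,
                                rng_seed = 92)
  expect_equal(nrow(none$truth), 0)
  expect_error(generate_promoter_set(5, length = 4, pwm, 0.5), "wider")
})

test_that("scenario bundles round-trip through plain-text files", {
  cfg <- scenario_config(n_genes = 40, n_mirnas = 6, utr_length_mean = 60,
                         utr_length_sd = 10, rng_seed = 61)
  b <- generate_hub_scenario(cfg)
  dir <- tempfile("scenario_")
  write_scenario(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("utrs.fasta", "mirnas.fasta", "expression.tsv", "groups.tsv",
      "mirna_counts.tsv", "library_sizes.tsv", "metadata.json")))))
  utrs2 <- read_fasta(file.path(dir, "utrs.fasta"))
  expect_identical(unname(utrs2), unname(b$utrs))
  expr2 <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  expect_equal(expr2, b$expression$values, tolerance = 1e-12)
  counts2 <- read_matrix_tsv(file.path(dir, "mirna_counts.tsv"))
  expect_equal(counts2, b$mirna_counts$counts + 0)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$rng_seed, 61)
})
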