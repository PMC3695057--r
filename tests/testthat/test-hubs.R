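# Hub enrichment: observed statistic arithmetic, null resampling,
# empirical p-values, ranking.

## fixture: a miRNA plus a UTR universe where target status is forced
hub_fixture <- function(n_univ = 40, n_targets = 10, utr_len = 500,
                        seed = 3) {
  set.seed(seed)
  mir <- generate_mirna_set(1, rng_seed = seed)
  word <- site_words(mir[[1]])[["8mer"]]
  # site-free backbone: strip chance cores by using a 2-letter alphabet
  # disjoint from the word's core where possible is overkill; just redraw
  backbone <- function() {
    repeat {
      s <- random_dna_str(utr_len)
      if (nrow(find_seed_sites(mir[[1]], s)) == 0) return(s)
    }
  }
  utrs <- vapply(seq_len(n_univ), function(i) backbone(), "")
  names(utrs) <- sprintf("g%03d", seq_len(n_univ))
  tgt <- names(utrs)[seq_len(n_targets)]
  for (g in tgt) {
    s <- utrs[[g]]
    substr(s, 100, 100 + nchar(word) - 1) <- word
    utrs[[g]] <- s
  }
  list(mir = mirna_sequence(names(mir), mir[[1]]), utrs = utrs,
       targets = tgt)
}

test_that("observed statistic is T divided by mean UTR length in kb", {
  fx <- hub_fixture(utr_len = 500)
  gs <- c(fx$targets[1:2], setdiff(names(fx$utrs), fx$targets)[1:2])
  obs <- observed_statistic(fx$mir, gs, fx$utrs)
  expect_equal(obs$T, 2)
  expect_equal(obs$L_kb, 0.5)
  expect_equal(obs$X, 4)                      # 2 / 0.5 kb

  none <- observed_statistic(fx$mir, setdiff(names(fx$utrs), fx$targets)[1:4],
                             fx$utrs)
  expect_equal(none$X, 0)
})

test_that("appending site-free sequence to every UTR halves X", {
  fx <- hub_fixture(utr_len = 400)
  gs <- c(fx$targets[1:3], setdiff(names(fx$utrs), fx$targets)[1:3])
  before <- observed_statistic(fx$mir, gs, fx$utrs)
  # pad with a word-free base run: poly-C cannot contain the core unless
  # the core is all C, which the fixture's seed is not
  core <- site_words(fx$mir)[["6mer"]]
  pad_base <- setdiff(c("A", "C", "G", "T"), strsplit(core, "")[[1]])[1]
  padded <- fx$utrs
  padded[gs] <- paste0(padded[gs], strrep(pad_base, 400))
  after <- observed_statistic(fx$mir, gs, padded)
  expect_equal(after$T, before$T)
  expect_equal(after$X, before$X / 2, tolerance = 1e-12)
})

test_that("observed statistic validates its inputs", {
  fx <- hub_fixture()
  expect_error(observed_statistic(fx$mir, character(0), fx$utrs), "empty")
  expect_error(observed_statistic(fx$mir, c("g001", "nope"), fx$utrs),
               "nope")
})

test_that("null draws hit the forced values in degenerate universes", {
  fx <- hub_fixture(n_univ = 20, n_targets = 0, utr_len = 300)
  cfg <- hub_test_config(n_iterations = 50, rng_seed = 1)
  null0 <- null_distribution(fx$mir, 5, fx$utrs, cfg)
  expect_equal(null0, rep(0, 50))             # no gene is a target

  # every gene a target, all UTRs exactly 1000 nt -> X = set_size / set_size... = T / L = s / 1.0
  fx2 <- hub_fixture(n_univ = 15, n_targets = 15, utr_len = 1000)
  null1 <- null_distribution(fx2$mir, 6, fx2$utrs, cfg)
  expect_equal(null1, rep(6 / 1.0, 50))

  expect_error(null_distribution(fx$mir, 21, fx$utrs, cfg), "universe")
})

test_that("null draws are reproducible and stable in mean", {
  fx <- hub_fixture(n_univ = 60, n_targets = 20, utr_len = 300, seed = 8)
  cfg <- hub_test_config(n_iterations = 400, rng_seed = 99)
  n1 <- null_distribution(fx$mir, 15, fx$utrs, cfg)
  n2 <- null_distribution(fx$mir, 15, fx$utrs, cfg)
  expect_identical(n1, n2)                    # bit-identical at fixed seed

  cfg2 <- hub_test_config(n_iterations = 400, rng_seed = 100)
  n3 <- null_distribution(fx$mir, 15, fx$utrs, cfg2)
  expect_false(identical(n1, n3))
  expect_lt(abs(mean(n1) - mean(n3)),
            3 * (sd(n1) / sqrt(length(n1))) + 3 * (sd(n3) / sqrt(length(n3))))
})

test_that("empirical p-value is the add-one right tail", {
  expect_equal(empirical_pvalue(0, rep(0, 10)), 1)       # every draw >= 0
  expect_equal(empirical_pvalue(3, c(1, 2, 3, 4, 5)), 4 / 6)
  expect_equal(empirical_pvalue(10, c(1, 2, 3, 4, 5)), 1 / 6)
  # exact rational form (k+1)/(N+1); never zero
  null <- runif(999)
  p <- empirical_pvalue(0.5, null)
  k <- sum(null >= 0.5)
  expect_identical(p, (k + 1) / 1000)
  expect_gt(empirical_pvalue(Inf, null), 0)
})

test_that("hub_test reports a coherent result and honors keep_null", {
  fx <- hub_fixture(n_univ = 50, n_targets = 25, utr_len = 300, seed = 12)
  cfg <- hub_test_config(n_iterations = 200, rng_seed = 7)
  res <- hub_test(fx$mir, fx$targets[1:10], fx$utrs, cfg, keep_null = TRUE)
  expect_equal(res$T, 10)
  expect_equal(length(res$null_draws), 200)
  expect_equal(res$empirical_p,
               empirical_pvalue(res$X, res$null_draws))
  expect_equal(res$neg_log10_p, -log10(res$empirical_p))
  expect_gte(res$empirical_p, 1 / 201)
})

test_that("uniform gene relabeling leaves the test invariant at fixed seed", {
  fx <- hub_fixture(n_univ = 40, n_targets = 12, utr_len = 250, seed = 21)
  cfg <- hub_test_config(n_iterations = 150, rng_seed = 5)
  gs <- c(fx$targets[1:4], setdiff(names(fx$utrs), fx$targets)[1:4])
  p1 <- hub_test(fx$mir, gs, fx$utrs, cfg)$empirical_p
  relab <- stats::setNames(paste0("x_", names(fx$utrs)), names(fx$utrs))
  utrs2 <- stats::setNames(unname(fx$utrs), unname(relab[names(fx$utrs)]))
  p2 <- hub_test(fx$mir, unname(relab[gs]), utrs2, cfg)$empirical_p
  expect_identical(p1, p2)
})

test_that("identify_hubs pairs directions, ranks and flags deterministically", {
  b <- generate_hub_scenario(scenario_config(n_genes = 250, n_mirnas = 8,
                                             utr_length_mean = 300,
                                             utr_length_sd = 50,
                                             rng_seed = 31))
  norm <- quantile_normalize(b$expression)
  de1 <- significant_genes(differential_expression(norm, "cond1", "naive"))
  filt <- filter_low_counts(b$mirna_counts)
  md <- mirna_de(normalize_counts(filt), filt$groups, "cond1", "naive")
  cfg <- hub_test_config(n_iterations = 300, rng_seed = 17)
  hubs <- identify_hubs(md, de1$gene_id[de1$direction == "up"],
                        de1$gene_id[de1$direction == "down"],
                        b$utrs, b$mirnas, cfg)
  hub_id <- b$truth$hubs$mirna_id[b$truth$hubs$condition == "cond1"]
  expect_equal(hubs$mirna[1], hub_id)        # planted hub ranked first
  expect_true(hubs$significant[1])
  expect_equal(hubs$gene_set[hubs$mirna == hub_id], "up-regulated")
  # ranking is by p asc, then X desc, then id
  expect_true(!is.unsorted(hubs$empirical_p))
  # determinism end to end
  hubs2 <- identify_hubs(md, de1$gene_id[de1$direction == "up"],
                         de1$gene_id[de1$direction == "down"],
                         b$utrs, b$mirnas, cfg)
  expect_identical(hubs, hubs2)
})

test_that("identify_hubs handles minimal and empty inputs", {
  fx <- hub_fixture(n_univ = 20, n_targets = 5, utr_len = 200, seed = 2)
  md <- data.frame(mirna_id = fx$mir$id, direction = "up",
                   stringsAsFactors = FALSE)
  mirset <- stats::setNames(fx$mir$seq, fx$mir$id)
  cfg <- hub_test_config(n_iterations = 50, rng_seed = 1)
  one <- identify_hubs(md, character(0), names(fx$utrs)[1], fx$utrs,
                       mirset, cfg)
  expect_equal(nrow(one), 1)                  # single miRNA, single gene

  expect_warning(empty <- identify_hubs(md[0, , drop = FALSE], "g001",
                                        "g002", fx$utrs, mirset, cfg),
                 "empty")
  expect_equal(nrow(empty), 0)
})
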