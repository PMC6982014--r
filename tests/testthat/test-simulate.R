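test_that("configs validate before any generation", {
  expect_error(sim_config(fraction_regulated = 1.5), "fractions")
  expect_error(sim_config(effect_fold = 1), "effect_fold")
  expect_error(sim_config(noise_log2_sd = -0.1), "noise_log2_sd")
  expect_error(sim_config(loc_prob_alpha = 0), "Beta")
})

test_that("identical seeds give identical datasets", {
  cfg <- sim_config(seed = 9, n_proteins = 100)
  a <- simulate_tmt_experiment(cfg)
  b <- simulate_tmt_experiment(cfg)
  expect_identical(a$psms, b$psms)
  expect_identical(a$phospho_psms, b$phospho_psms)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  c <- simulate_tmt_experiment(sim_config(seed = 10, n_proteins = 100))
  expect_false(identical(a$psms, c$psms))
})

test_that("simulated tables satisfy their structural contracts", {
  sim <- simulate_tmt_experiment(sim_config(seed = 12, n_proteins = 300))
  expect_s3_class(sim$psms, "psm_table")
  expect_gt(mean(sim$psms$is_unique), 0.8)
  mods <- sim$phospho_psms$modifications
  expect_true(all(nzchar(mods)))
  probs <- as.numeric(sapply(strsplit(mods, ":"), `[`, 3))
  expect_true(all(probs >= 0 & probs <= 1))
  # simulator output round-trips through the plain dialect
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(sim$psms, path)
  back <- read_psm_table(path, sim$design)
  expect_equal(as.data.frame(back), as.data.frame(sim$psms),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("fraction_regulated = 0 yields an all-null truth", {
  sim <- simulate_tmt_experiment(sim_config(seed = 13, n_proteins = 200,
                                            fraction_regulated = 0))
  expect_true(all(sim$truth$protein_mult == 1))
})

test_that("the noiseless limit recovers the exact effect fold", {
  sim <- simulate_tmt_experiment(sim_config(
    seed = 14, n_proteins = 150, effect_fold = 2, noise_log2_sd = 0,
    fraction_regulated = 0.3))
  raw <- compute_peptide_ratios(sim$psms, sim$design, "Cd/CK")
  pq <- rollup_protein(raw)  # unnormalized rollup
  tr <- sim$truth$protein_mult[pq$protein_accession, "Cd"]
  reg <- pq$quantified & tr != 1
  expect_true(all(abs(pq$ratio[reg] - tr[reg]) < 1e-12))
  expect_true(all(pq$ratio[reg] %in% c(2, 0.5)))
  expect_true(all(abs(pq$ratio[pq$quantified & tr == 1] - 1) < 1e-12))
})

test_that("recovery summaries handle the trivial extremes", {
  sim <- simulate_tmt_experiment(sim_config(seed = 15, n_proteins = 100))
  accs <- rownames(sim$truth$protein_mult)
  tr <- sim$truth$protein_mult[, "Cd"] / sim$truth$protein_mult[, "CK"]
  calls <- data.frame(protein_accession = accs, contrast = "Cd/CK",
                      regulated = ifelse(tr > 1, "up",
                                         ifelse(tr < 1, "down", "ns")),
                      stringsAsFactors = FALSE)
  rec <- evaluate_recovery(calls, sim$truth)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$fdr, 0)
  expect_equal(rec$direction_accuracy, 1)
  # all-ns calls: zero sensitivity, perfect specificity
  calls$regulated <- "ns"
  rec <- evaluate_recovery(calls, sim$truth)
  expect_equal(rec$sensitivity, 0)
  expect_equal(rec$specificity, 1)
  # unknown entities are rejected
  calls$protein_accession[1] <- "NOPE"
  expect_error(evaluate_recovery(calls, sim$truth), "absent")
})

test_that("a global loading bias is absorbed by normalization", {
  sim <- simulate_tmt_experiment(sim_config(seed = 16, n_proteins = 200))
  pq0 <- quantify_proteins(sim$psms, sim$design, "Cd/CK")
  biased <- sim$psms
  cd_cols <- paste0("intensity_",
                    sim$design$channel[sim$design$condition == "Cd"])
  biased[cd_cols] <- biased[cd_cols] * 3
  pq1 <- quantify_proteins(as_psm_table(biased, sim$design),
                           sim$design, "Cd/CK")
  expect_equal(pq1$ratio, pq0$ratio, tolerance = 1e-6)
  expect_equal(pq1$regulated, pq0$regulated)
})
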