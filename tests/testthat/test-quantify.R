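test_that("replicate channels average into condition intensities", {
  design <- tmt_design(paste0("ch", 1:4), c("A", "A", "A", "B"),
                       c(1, 2, 3, 1))
  psms <- toy_psms(design, c("AAK", "BBK"), c("P1", "P1"), c(TRUE, TRUE),
                   list(c(100, 110, 120, 50), c(0, 0, 0, 10)))
  agg <- aggregate_replicates(psms, design)
  expect_equal(unname(agg[1, "A"]), 110)
  # zero-intensity channels are included in the mean; all-zero stays 0
  expect_equal(unname(agg[2, "A"]), 0)
  # single-replicate condition: identity
  expect_equal(unname(agg[, "B"]), c(50, 10))
})

test_that("peptide ratios divide condition intensities and drop zeros", {
  design <- toy_design1()
  psms <- toy_psms(design, c("p1", "p2", "p3"), rep("P1", 3), rep(TRUE, 3),
                   list(c(200, 100), c(150, 150), c(80, 0)))
  r <- compute_peptide_ratios(psms, design, "A/B")
  expect_equal(r$ratio, c(2, 1))
  expect_equal(attr(r, "n_excluded"), 1L)
  # contrast naming an unknown condition is a design error
  expect_error(compute_peptide_ratios(psms, design, "A/C"), "unknown")
})

test_that("PSMs of the same peptide collapse by median condition intensity", {
  design <- toy_design1()
  psms <- toy_psms(design, rep("p1", 3), rep("P1", 3), rep(TRUE, 3),
                   list(c(100, 100), c(120, 100), c(500, 100)))
  r <- compute_peptide_ratios(psms, design, "A/B")
  expect_equal(nrow(r), 1)
  expect_equal(r$ratio, 1.2)  # median(100,120,500)/median(100)
})

test_that("unique-peptide normalization scales to mean 1", {
  design <- toy_design1()
  mk <- function(ratios, uniq) {
    toy_psms(design, paste0("p", seq_along(ratios)),
             paste0("P", seq_along(ratios)), uniq,
             lapply(ratios, function(x) c(100 * x, 100)))
  }
  r <- compute_peptide_ratios(mk(c(2, 2, 2), rep(TRUE, 3)), design, "A/B")
  expect_equal(normalize_sample(r)$ratio, c(1, 1, 1))
  r <- compute_peptide_ratios(mk(c(1, 2, 3), rep(TRUE, 3)), design, "A/B")
  expect_equal(normalize_sample(r)$ratio, c(0.5, 1, 1.5))
  # scaling factor comes from unique peptides only, applies to all
  r <- compute_peptide_ratios(mk(c(1, 3, 4), c(TRUE, TRUE, FALSE)),
                              design, "A/B")
  expect_equal(normalize_sample(r)$ratio, c(0.5, 1.5, 2))
  # no unique peptides: the scaling factor cannot be formed
  r <- compute_peptide_ratios(mk(c(1, 2), c(FALSE, FALSE)), design, "A/B")
  expect_error(normalize_sample(r), "no unique peptides")
})

test_that("protein rollup takes the median of unique-peptide ratios", {
  design <- toy_design1()
  build <- function(ratios, uniq, accs) {
    psms <- toy_psms(design, paste0("p", seq_along(ratios)), accs, uniq,
                     lapply(ratios, function(x) c(100 * x, 100)))
    compute_peptide_ratios(psms, design, "A/B")
  }
  r <- build(c(1, 2, 4), rep(TRUE, 3), rep("P1", 3))
  expect_equal(rollup_protein(r)$ratio, 2)           # odd count
  r <- build(c(0.5, 0.8, 0.9, 1.0), rep(TRUE, 4), rep("P1", 4))
  expect_equal(rollup_protein(r)$ratio, 0.85)        # even: middle mean
  # a single unique peptide leaves the protein unquantified
  r <- build(c(2, 2), c(TRUE, FALSE), rep("P1", 2))
  out <- rollup_protein(r, min_unique_peptides = 2)
  expect_false(out$quantified)
  expect_true(is.na(out$ratio))
  # shared peptides never contribute to the median
  r <- build(c(1, 3, 100), c(TRUE, TRUE, FALSE), rep("P1", 3))
  expect_equal(rollup_protein(r)$ratio, 2)
})

test_that("rollup is invariant to peptide order and shared-peptide copies", {
  design <- toy_design1()
  ratios <- c(1.1, 0.9, 1.4, 0.7, 1.0)
  psms <- toy_psms(design, paste0("p", 1:5), rep("P1", 5), rep(TRUE, 5),
                   lapply(ratios, function(x) c(100 * x, 100)))
  base <- rollup_protein(compute_peptide_ratios(psms, design, "A/B"))
  for (seed in 1:3) {
    set.seed(seed)
    perm <- psms[sample(5), ]
    got <- rollup_protein(compute_peptide_ratios(
      as_psm_table(perm, design), design, "A/B"))
    expect_equal(got$ratio, base$ratio)
    expect_equal(got$p_value, base$p_value)
  }
  # duplicating a non-unique peptide changes nothing
  extra <- toy_psms(design, "shared", "P1", FALSE, list(c(900, 100)))
  dup <- as_psm_table(rbind(psms, extra, extra), design)
  got <- rollup_protein(compute_peptide_ratios(dup, design, "A/B"))
  expect_equal(got$ratio, base$ratio)
})

test_that("one-sample t-test matches the closed-form t oracle", {
  # worked example: log2 ratios 0.8, 1.0, 1.2
  x <- c(0.8, 1.0, 1.2)
  t_stat <- mean(x) / (sd(x) / sqrt(3))
  expect_equal(t_stat, 8.660254, tolerance = 1e-6)
  p_oracle <- 2 * pt(-abs(t_stat), df = 2)
  expect_equal(test_protein(2^x), p_oracle, tolerance = 1e-12)
  expect_equal(p_oracle, 0.01307, tolerance = 1e-3)
  # zero variance and short input are undefined, not errors
  expect_true(is.na(test_protein(c(2, 2, 2))))
  expect_true(is.na(test_protein(3)))
  # symmetric log ratios about 0 give p = 1
  expect_equal(test_protein(2^c(-0.5, 0, 0.5)), 1)
  # raw-space alternative tests ratios against mean 1
  expect_equal(test_protein(c(0.5, 1, 1.5), test_space = "raw"), 1)
  # 100 random samples against the closed form
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    r <- exp(rnorm(n, sd = 0.4))
    tt <- mean(log2(r)) / (sd(log2(r)) / sqrt(n))
    expect_equal(test_protein(r), 2 * pt(-abs(tt), n - 1),
                 tolerance = 1e-10)
  }
})

test_that("normalization leaves unique-peptide mean at 1 and absorbs scaling", {
  design <- toy_design2()
  set.seed(21)
  for (rep in 1:5) {
    n <- 40
    ints <- lapply(1:n, function(i) exp(rnorm(4, 8, 1)))
    psms <- toy_psms(design, paste0("p", 1:n), paste0("P", rep(1:8, 5)),
                     runif(n) < 0.8, ints)
    r <- normalize_sample(compute_peptide_ratios(psms, design, "A/B"))
    expect_equal(mean(r$ratio[r$is_unique]), 1, tolerance = 1e-9)
    # multiplying all numerator channels by c scales raw ratios by c
    # and leaves normalized ratios unchanged
    scaled <- psms
    acols <- paste0("intensity_", design$channel[design$condition == "A"])
    scaled[acols] <- scaled[acols] * 3
    scaled <- as_psm_table(scaled, design)
    raw0 <- compute_peptide_ratios(psms, design, "A/B")
    raw1 <- compute_peptide_ratios(scaled, design, "A/B")
    expect_equal(raw1$ratio, raw0$ratio * 3, tolerance = 1e-12)
    r1 <- normalize_sample(raw1)
    expect_equal(r1$ratio, r$ratio, tolerance = 1e-9)
  }
})
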