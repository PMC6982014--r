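test_that("hypergeometric enrichment matches the enumeration oracle", {
  # worked example: 2 of 5 foreground hits, 4 of 50 background
  bg <- sprintf("B%02d", 1:50)
  fg <- bg[1:5]
  ann <- annotation_map(bg[c(1, 2, 10, 11)], rep("CAT", 4))
  res <- enrich_categories(fg, bg, ann)
  expect_equal(res$k, 2)
  expect_equal(res$p_value, hyper_tail_oracle(2, 4, 50, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value, 0.04496, tolerance = 1e-4)
  # random spot checks across the small-N lattice
  set.seed(51)
  for (i in 1:200) {
    N <- sample(2:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 hyper_tail_oracle(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("enrichment respects set contracts", {
  bg <- sprintf("B%02d", 1:20)
  ann <- annotation_map(bg[1:6], rep(c("C1", "C2"), 3))
  # categories without a foreground hit are omitted
  res <- enrich_categories(bg[7:10], bg, ann)
  expect_equal(nrow(res), 0)
  # foreground = background: every category has k = K, n = N, p = 1
  res <- enrich_categories(bg, bg, ann)
  expect_true(all(res$p_value == 1))
  expect_equal(res$k, res$K)
  # foreground outside the background is an input error
  expect_error(enrich_categories(c("ZZ"), bg, ann), "subset")
  # enrichment p never increases with k at fixed N, K, n
  ps <- sapply(0:4, function(k) phyper(k - 1, 4, 46, 5, lower.tail = FALSE))
  expect_true(all(diff(ps) <= 0))
})

test_that("p-value matrix filtering and z-transform follow the recipe", {
  res <- data.frame(
    category = rep(c("kept", "dropped", "flat"), each = 3),
    p_value = c(0.001, 0.1, 0.01,  0.06, 0.07, 0.08,  0.04, 0.04, 0.04),
    cluster = rep(c("c1", "c2", "c3"), 3))
  em <- enrichment_matrix(res, alpha = 0.05)
  # the all-nonsignificant row is removed
  expect_false("dropped" %in% rownames(em$p))
  expect_true(all(c("kept", "flat") %in% rownames(em$p)))
  # x-row {1,2,3} z-transforms to {-1,0,1} (sample SD)
  em2 <- enrichment_matrix(data.frame(
    category = "c", p_value = c(0.1, 0.01, 0.001),
    cluster = c("a", "b", "c")), alpha = 0.05)
  expect_equal(unname(em2$z["c", ]), c(-1, 0, 1))
  # constant x-row becomes all zero
  expect_equal(unname(em$z["flat", ]), c(0, 0, 0))
  # a category absent from one cluster is imputed p = 1 there
  em3 <- enrichment_matrix(data.frame(
    category = c("c1", "c1", "c2"), p_value = c(0.01, 0.2, 0.03),
    cluster = c("a", "b", "a")), alpha = 0.05)
  expect_equal(em3$p["c2", "b"], 1)
  # z rows have mean 0 and sample SD 1 unless constant
  set.seed(52)
  big <- data.frame(category = rep(paste0("g", 1:10), each = 4),
                    p_value = runif(40, 1e-4, 0.2),
                    cluster = rep(paste0("cl", 1:4), 10))
  emb <- enrichment_matrix(big, alpha = 0.05)
  for (i in seq_len(nrow(emb$z))) {
    if (sd(emb$x[i, ]) > 0) {
      expect_equal(mean(emb$z[i, ]), 0, tolerance = 1e-9)
      expect_equal(sd(emb$z[i, ]), 1, tolerance = 1e-9)
    }
  }
})

test_that("row clustering is deterministic and permutation-invariant", {
  z <- rbind(a = c(1, 1, 0), b = c(1, 1, 0.01), c = c(-2, 3, 5))
  em <- list(z = z, x = abs(z), p = 10^-abs(z), alpha = 0.05)
  class(em) <- "enrichment_matrix"
  cl <- cluster_enrichment_rows(em)
  # the nearly identical pair merges first (brute-force distance check)
  d <- as.matrix(dist(z))
  diag(d) <- Inf
  expect_equal(sort(rownames(z)[arrayInd(which.min(d), dim(d))]),
               c("a", "b"))
  first_merge <- sort(rownames(z)[-cl$hclust$merge[1, ]])
  expect_equal(first_merge, c("a", "b"))
  # permuting rows preserves the dendrogram (cophenetic comparison)
  perm <- c(3, 1, 2)
  emp <- em; emp$z <- z[perm, ]
  clp <- cluster_enrichment_rows(emp)
  coph <- function(h) {
    m <- as.matrix(stats::cophenetic(h))
    m[order(rownames(m)), order(colnames(m))]
  }
  expect_equal(coph(cl$hclust), coph(clp$hclust))
  # single row: trivial order with a notice
  em1 <- em; em1$z <- z[1, , drop = FALSE]
  expect_message(tr <- cluster_enrichment_rows(em1), "trivial")
  expect_equal(tr$order, 1L)
})

test_that("heatmaps render with the clipped z colour scale", {
  set.seed(53)
  z <- matrix(rnorm(12, sd = 2), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  em <- structure(list(z = z, x = abs(z), p = 10^-abs(z), alpha = 0.05),
                  class = "enrichment_matrix")
  f <- withr::local_tempfile(fileext = ".png")
  render_heatmap(em, filename = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  # empty matrix: notice, no image
  em0 <- structure(list(z = z[0, , drop = FALSE]),
                   class = "enrichment_matrix")
  expect_message(out <- render_heatmap(em0, filename = tempfile()), "empty")
  expect_null(out)
})
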