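#' Category over-representation test (hypergeometric)
#'
#' For every category with at least one foreground hit, computes the
#' one-sided hypergeometric tail probability of drawing `k` or more
#' annotated proteins in a foreground of size `n` from a background of
#' size `N` containing `K` annotated proteins — the standard
#' over-representation (Fisher) test. The background should be the set of
#' quantified proteins of the experiment (detection-bias control), and
#' the foreground must be a subset of it. A Benjamini-Hochberg adjusted
#' column is emitted for information; downstream filtering uses raw
#' p-values.
#'
#' @param foreground character vector of differential protein accessions.
#' @param background character vector of quantified protein accessions.
#' @param annotation an `annotation_map` (see [read_annotation()]).
#' @param alternative `"greater"` for the one-sided hypergeometric test
#'   (default) or `"two.sided"` for the two-sided Fisher exact test.
#' @return Data frame with one row per category: `category`, `namespace`,
#'   `k`, `n`, `K`, `N`, `p_value`, `p_adjust`.
#' @export
enrich_categories <- function(foreground, background, annotation,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background))
    stop("input error: foreground must be a subset of the background")
  ann <- annotation[annotation$protein_accession %in% background, ,
                    drop = FALSE]
  N <- length(background)
  n <- length(foreground)
  cats <- sort(unique(ann$category[ann$protein_accession %in% foreground]))
  if (length(cats) == 0)
    return(data.frame(category = character(), namespace = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_value = numeric(),
                      p_adjust = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(cats, function(cat) {
    members <- unique(ann$protein_accession[ann$category == cat])
    K <- length(members)
    k <- sum(foreground %in% members)
    p <- if (alternative == "greater")
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    else
      stats::fisher.test(matrix(c(k, K - k, n - k, N - K - (n - k)), 2, 2),
                         alternative = "two.sided")$p.value
    ns <- ann$namespace[ann$category == cat][1]
    data.frame(category = cat, namespace = ns, k = k, n = n, K = K, N = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Build the filtered, z-transformed enrichment matrix
#'
#' Collates category p-values across clusters (e.g. "Cd/CK up",
#' "Cd/CK down", ...) into a category x cluster matrix, imputing p = 1
#' for category/cluster pairs without a result. Categories that are not
#' enriched at `p < alpha` in at least one cluster are removed. The
#' retained matrix is transformed as `x = -log10(p)` and each category
#' row is z-transformed (mean 0, sample-SD 1; constant rows become
#' all-zero).
#'
#' @param results either a data frame with a `cluster` column plus
#'   `category` and `p_value`, or a named list of [enrich_categories()]
#'   results (names are the cluster labels, in display order).
#' @param alpha filter level (a category is kept when its minimum p over
#'   clusters is strictly below `alpha`).
#' @return An object of class `enrichment_matrix`: a list with matrices
#'   `p`, `x`, `z` (categories x clusters) and the `alpha` used.
#' @export
enrichment_matrix <- function(results, alpha = 0.05) {
  if (is.data.frame(results)) {
    if (!"cluster" %in% names(results))
      stop("input error: data-frame input needs a 'cluster' column")
    parts <- split(results, factor(results$cluster,
                                   levels = unique(results$cluster)))
  } else parts <- results
  clusters <- names(parts)
  if (is.null(clusters) || any(!nzchar(clusters)))
    stop("input error: cluster labels are required")
  cats <- sort(unique(unlist(lapply(parts, function(d) d$category))))
  p <- matrix(1, nrow = length(cats), ncol = length(clusters),
              dimnames = list(cats, clusters))
  for (cl in clusters) {
    d <- parts[[cl]]
    p[match(d$category, cats), cl] <- d$p_value
  }
  keep <- apply(p, 1, min) < alpha
  p <- p[keep, , drop = FALSE]
  x <- -log10(p)
  z <- x
  for (i in seq_len(nrow(x))) {
    s <- stats::sd(x[i, ])
    z[i, ] <- if (is.na(s) || s == 0) 0 else (x[i, ] - mean(x[i, ])) / s
  }
  structure(list(p = p, x = x, z = z, alpha = alpha),
            class = "enrichment_matrix")
}

#' Hierarchically cluster the rows of an enrichment matrix
#'
#' One-way (row-wise) agglomerative clustering of the z-score rows,
#' average linkage on Euclidean distance by default. Deterministic for a
#' fixed input; with fewer than two rows the trivial order is returned
#' with a notice.
#'
#' @param em an `enrichment_matrix`.
#' @param method linkage method passed to [stats::hclust()].
#' @return List with `order` (row indices in leaf order), `labels`
#'   (category names in leaf order) and `hclust` (the merge tree, or NULL
#'   for fewer than two rows).
#' @export
cluster_enrichment_rows <- function(em, method = "average") {
  z <- em$z
  if (nrow(z) < 2) {
    message("fewer than two categories: trivial row order returned")
    return(list(order = seq_len(nrow(z)), labels = rownames(z),
                hclust = NULL))
  }
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = method)
  list(order = hc$order, labels = rownames(z)[hc$order], hclust = hc)
}

#' Render the enrichment z-score heatmap
#'
#' Draws the category x cluster z-score matrix with the colour scale
#' clipped to z in [-2, 2], rows in dendrogram order and columns in the
#' declared cluster order.
#'
#' @param em an `enrichment_matrix`.
#' @param filename output image path (`.png` or `.pdf`); NULL draws to
#'   the active device.
#' @param clustering optional result of [cluster_enrichment_rows()];
#'   computed if missing.
#' @return Invisibly, the pheatmap object, or NULL for an empty matrix.
#' @export
render_heatmap <- function(em, filename = NULL, clustering = NULL) {
  if (nrow(em$z) == 0) {
    message("empty enrichment matrix: no heatmap rendered")
    return(invisible(NULL))
  }
  if (is.null(clustering)) clustering <- cluster_enrichment_rows(em)
  z <- pmin(pmax(em$z, -2), 2)
  breaks <- seq(-2, 2, length.out = 101)
  ph <- pheatmap::pheatmap(
    z,
    breaks = breaks,
    cluster_rows = if (is.null(clustering$hclust)) FALSE else
      clustering$hclust,
    cluster_cols = FALSE,
    filename = filename,
    silent = TRUE)
  invisible(ph)
}
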