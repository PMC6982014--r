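#' Average replicate channels into per-condition intensities
#'
#' For an overall group comparison the replicate channels of each
#' condition are collapsed first: per PSM and condition, the intensity is
#' the arithmetic mean of that condition's replicate channels (zero
#' intensities included).
#'
#' @param psms a `psm_table` (see [read_psm_table()]).
#' @param design a [tmt_design()].
#' @return Numeric matrix, one row per PSM, one column per condition.
#' @export
aggregate_replicates <- function(psms, design) {
  validate_design(design)
  ints <- as.matrix(psms[paste0("intensity_", design$channel)])
  conds <- unique(design$condition)
  out <- vapply(conds, function(cond) {
    cols <- which(design$condition == cond)
    rowMeans(ints[, cols, drop = FALSE])
  }, numeric(nrow(psms)))
  out <- matrix(out, nrow = nrow(psms),
                dimnames = list(NULL, conds))
  out
}

#' Compute peptide fold-change ratios for one contrast
#'
#' PSMs with identical peptide sequence and modification state are
#' collapsed by the median of their per-condition intensities (robust to
#' outlier spectra); the peptide ratio is then the numerator condition's
#' intensity divided by the denominator's. Peptides with a zero numerator
#' or denominator intensity are excluded; the number excluded is attached
#' as attribute `n_excluded`.
#'
#' @param psms a `psm_table`.
#' @param design a [tmt_design()].
#' @param contrast contrast label, `"treatment/reference"`; the
#'   first-named condition is the numerator.
#' @return Data frame with columns `peptide_sequence`, `modifications`,
#'   `protein_accession`, `is_unique`, `contrast`, `num_intensity`,
#'   `den_intensity`, `ratio`, `normalized` (FALSE).
#' @export
compute_peptide_ratios <- function(psms, design, contrast) {
  ct <- parse_contrast(contrast, design)
  cond_int <- aggregate_replicates(psms, design)
  key <- paste(psms$protein_accession, psms$peptide_sequence,
               psms$modifications, sep = "\r")
  first <- !duplicated(key)
  idx <- split(seq_len(nrow(psms)), factor(key, levels = key[first]))
  num <- vapply(idx, function(i) stats::median(cond_int[i, ct$numerator]),
                numeric(1))
  den <- vapply(idx, function(i) stats::median(cond_int[i, ct$denominator]),
                numeric(1))
  out <- data.frame(
    peptide_sequence = psms$peptide_sequence[first],
    modifications = psms$modifications[first],
    protein_accession = psms$protein_accession[first],
    is_unique = psms$is_unique[first],
    contrast = contrast,
    num_intensity = num,
    den_intensity = den,
    ratio = num / den,
    normalized = FALSE,
    stringsAsFactors = FALSE)
  keep <- is.finite(out$ratio) & out$ratio > 0
  n_excluded <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Normalize peptide ratios by the average unique-peptide ratio
#'
#' Every ratio of the contrast is divided by the mean ratio of the unique
#' peptides, so that after normalization the unique-peptide ratios
#' average exactly 1. This removes global loading differences between the
#' pooled samples. The default scaling factor is the arithmetic mean of
#' the unique-peptide ratios; `method = "geometric"` uses the geometric
#' mean (log-space centring), which is less sensitive to the skew of
#' ratio distributions.
#'
#' @param ratios data frame from [compute_peptide_ratios()].
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return The input with `ratio` rescaled and `normalized = TRUE`; the
#'   scaling factor is attached as attribute `scale_factor`.
#' @export
normalize_sample <- function(ratios, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  u <- ratios$ratio[ratios$is_unique]
  if (length(u) == 0)
    stop("normalization error: no unique peptides to form the scaling factor")
  f <- if (method == "arithmetic") mean(u) else exp(mean(log(u)))
  ratios$ratio <- ratios$ratio / f
  ratios$normalized <- TRUE
  attr(ratios, "scale_factor") <- f
  ratios
}

#' One-sample two-sided t-test of peptide ratios against no change
#'
#' Ratios are log2-transformed and tested against mean 0 (i.e. fold
#' change 1) by default; `test_space = "raw"` tests the untransformed
#' ratios against mean 1. Log space symmetrizes up- and down-regulation.
#'
#' @param ratios numeric vector of positive peptide ratios.
#' @param test_space `"log2"` (default) or `"raw"`.
#' @return The two-sided p-value, or `NA_real_` when fewer than two
#'   ratios are available or their variance is zero.
#' @export
test_protein <- function(ratios, test_space = c("log2", "raw")) {
  test_space <- match.arg(test_space)
  x <- if (test_space == "log2") log2(ratios) else ratios
  mu <- if (test_space == "log2") 0 else 1
  if (length(x) < 2 || isTRUE(all.equal(stats::sd(x), 0)) ||
      stats::sd(x) == 0)
    return(NA_real_)
  stats::t.test(x, mu = mu, alternative = "two.sided")$p.value
}

#' Roll peptide ratios up to protein quantifications
#'
#' A protein's ratio is the median of its unique-peptide ratios; shared
#' peptides never contribute. Proteins with fewer than
#' `min_unique_peptides` unique peptides are reported as unquantified
#' (`ratio = NA`). The p-value is the one-sample t-test over the
#' protein's unique-peptide ratios ([test_protein()]).
#'
#' @param ratios normalized data frame from [normalize_sample()].
#' @param min_unique_peptides minimum unique peptides per quantified
#'   protein.
#' @param test_space passed to [test_protein()].
#' @return Data frame with one row per protein accession: `contrast`,
#'   `ratio`, `p_value`, `n_unique_peptides`, `quantified`.
#' @export
rollup_protein <- function(ratios, min_unique_peptides = 2,
                           test_space = c("log2", "raw")) {
  test_space <- match.arg(test_space)
  accs <- sort(unique(ratios$protein_accession))
  uniq <- ratios[ratios$is_unique, , drop = FALSE]
  by_acc <- split(uniq$ratio, factor(uniq$protein_accession, levels = accs))
  n_unique <- lengths(by_acc)
  quantified <- n_unique >= min_unique_peptides
  out <- data.frame(
    protein_accession = accs,
    contrast = ratios$contrast[1],
    ratio = ifelse(quantified,
                   vapply(by_acc, function(r)
                     if (length(r)) stats::median(r) else NA_real_,
                     numeric(1)),
                   NA_real_),
    p_value = vapply(seq_along(accs), function(i) {
      if (!quantified[i]) return(NA_real_)
      test_protein(by_acc[[i]], test_space)
    }, numeric(1)),
    n_unique_peptides = as.integer(n_unique),
    quantified = quantified,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Quantify proteins for one or more contrasts
#'
#' Runs the full protein route: replicate averaging, peptide ratio
#' computation, unique-peptide normalization, median rollup with
#' one-sample t-tests, and differential calling against the proteome
#' fold-change threshold. A Benjamini-Hochberg adjusted p-value column is
#' emitted for information; calls use the raw p-value.
#'
#' @param psms a `psm_table`.
#' @param design a [tmt_design()].
#' @param contrasts character vector of contrast labels
#'   (e.g. `c("Cd/CK", "CdN/Cd", "CdN/CK")`).
#' @param thresholds a [thresholds()] object.
#' @param normalization passed to [normalize_sample()].
#' @param test_space passed to [test_protein()].
#' @return Data frame, one row per protein x contrast, with `regulated`
#'   in `up/down/ns/unquantified`.
#' @export
quantify_proteins <- function(psms, design, contrasts = "Cd/CK",
                              thresholds = tmtphos::thresholds(),
                              normalization = c("arithmetic", "geometric"),
                              test_space = c("log2", "raw")) {
  normalization <- match.arg(normalization)
  test_space <- match.arg(test_space)
  res <- lapply(contrasts, function(ct) {
    ratios <- compute_peptide_ratios(psms, design, ct)
    ratios <- normalize_sample(ratios, normalization)
    rollup_protein(ratios, thresholds$min_unique_peptides, test_space)
  })
  out <- do.call(rbind, res)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  call <- classify_regulation(out$ratio, out$p_value,
                              tau = thresholds$fc_proteome,
                              alpha = thresholds$alpha)
  out$regulated <- ifelse(out$quantified, call, "unquantified")
  rownames(out) <- NULL
  out
}
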