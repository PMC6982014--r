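#' Filter phosphosite records by localization probability
#'
#' Retains records whose localization probability strictly exceeds
#' `loc_prob_min` (the conventional cutoff is > 0.75, so a site at
#' exactly 0.75 is discarded). Works on any data frame carrying a
#' `localization_prob` column; retained/discarded counts are attached as
#' attributes `n_retained` / `n_discarded`.
#'
#' @param sites data frame with a `localization_prob` column.
#' @param loc_prob_min minimum localization probability (strict).
#' @return The retained rows, with count attributes.
#' @export
filter_localization <- function(sites, loc_prob_min = 0.75) {
  keep <- sites$localization_prob > loc_prob_min
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

# One row per (PSM, phosphosite) for phosphopeptide PSMs, carrying the
# PSM's peptide identity and per-condition intensities.
site_records <- function(psms, design) {
  mods <- parse_modifications(psms$modifications)
  cond_int <- aggregate_replicates(psms, design)
  data.frame(
    protein_accession = psms$protein_accession[mods$psm_row],
    position = mods$position,
    amino_acid = mods$residue,
    localization_prob = mods$localization_prob,
    peptide_sequence = psms$peptide_sequence[mods$psm_row],
    modifications = psms$modifications[mods$psm_row],
    is_unique = psms$is_unique[mods$psm_row],
    cond_int[mods$psm_row, , drop = FALSE],
    stringsAsFactors = FALSE)
}

#' Quantify phosphosites for one or more contrasts
#'
#' Site identity is the triple (accession, position, residue);
#' multiply-phosphorylated peptides contribute to each of their sites
#' independently. Per site and condition the intensity is the median over
#' the supporting phosphopeptides' replicate-averaged intensities.
#' Site-level records are first filtered at `loc_prob_min` (strictly
#' greater), so filtering and quantification commute. The raw site ratio
#' is normalized by the average ratio of all unique phosphopeptides of
#' the contrast, exactly as in the protein route; the p-value is a
#' one-sample t-test over the supporting peptides' normalized ratios when
#' a site has two or more supporting peptides, else undefined.
#'
#' When a protein quantification table is supplied, each site's ratio is
#' additionally divided by its parent protein's fold change
#' ([normalize_site_by_protein()]), isolating phosphorylation changes
#' from protein-abundance changes. Differential calls use the phospho
#' fold-change threshold on the normalized ratio (raw ratio for sites
#' whose protein is unquantified).
#'
#' @param phospho_psms a `psm_table` of phosphopeptide PSMs whose
#'   `modifications` column carries at least one site.
#' @param design a [tmt_design()].
#' @param contrasts character vector of contrast labels.
#' @param protein_quant optional data frame from [quantify_proteins()]
#'   (unmodified-peptide route) used for protein normalization.
#' @param thresholds a [thresholds()] object.
#' @param normalization passed to [normalize_sample()].
#' @param test_space passed to [test_protein()].
#' @return Data frame, one row per site x contrast: `raw_ratio`,
#'   `normalized_ratio`, `p_value`, `localization_prob` (maximum over
#'   supporting records), `n_supporting_peptides`, `protein_normalized`,
#'   `regulated`.
#' @export
quantify_phosphosites <- function(phospho_psms, design, contrasts = "Cd/CK",
                                  protein_quant = NULL,
                                  thresholds = tmtphos::thresholds(),
                                  normalization = c("arithmetic", "geometric"),
                                  test_space = c("log2", "raw")) {
  normalization <- match.arg(normalization)
  test_space <- match.arg(test_space)
  res <- lapply(contrasts, function(ct)
    quantify_sites_one(phospho_psms, design, ct, thresholds,
                       normalization, test_space))
  out <- do.call(rbind, res)
  if (!is.null(protein_quant))
    out <- normalize_site_by_protein(out, protein_quant)
  else {
    out$normalized_ratio <- out$raw_ratio
    out$protein_normalized <- FALSE
  }
  out$regulated <- classify_regulation(out$normalized_ratio, out$p_value,
                                       tau = thresholds$fc_phospho,
                                       alpha = thresholds$alpha)
  rownames(out) <- NULL
  out
}

quantify_sites_one <- function(phospho_psms, design, contrast, thresholds,
                               normalization, test_space) {
  ct <- parse_contrast(contrast, design)
  recs <- site_records(phospho_psms, design)
  recs <- filter_localization(recs, thresholds$loc_prob_min)
  # normalization factor from peptide-level ratios of all phosphopeptides
  pep_ratios <- compute_peptide_ratios(phospho_psms, design, contrast)
  pep_ratios <- normalize_sample(pep_ratios, normalization)
  scale_factor <- attr(pep_ratios, "scale_factor")
  pep_key <- paste(pep_ratios$protein_accession, pep_ratios$peptide_sequence,
                   pep_ratios$modifications, sep = "\r")
  pep_norm_ratio <- stats::setNames(pep_ratios$ratio, pep_key)

  if (nrow(recs) == 0)
    return(empty_site_quant(contrast))
  key <- paste(recs$protein_accession, recs$position, recs$amino_acid,
               sep = "\r")
  first <- !duplicated(key)
  idx <- split(seq_len(nrow(recs)), factor(key, levels = key[first]))
  num <- vapply(idx, function(i) stats::median(recs[[ct$numerator]][i]),
                numeric(1))
  den <- vapply(idx, function(i) stats::median(recs[[ct$denominator]][i]),
                numeric(1))
  raw_ratio <- (num / den) / scale_factor
  loc_prob <- vapply(idx, function(i) max(recs$localization_prob[i]),
                     numeric(1))
  support <- vapply(idx, function(i)
    length(unique(paste(recs$peptide_sequence[i], recs$modifications[i]))),
    integer(1))
  p_value <- vapply(idx, function(i) {
    k <- unique(paste(recs$protein_accession[i], recs$peptide_sequence[i],
                      recs$modifications[i], sep = "\r"))
    r <- pep_norm_ratio[intersect(k, names(pep_norm_ratio))]
    if (length(r) < 2) return(NA_real_)
    test_protein(unname(r), test_space)
  }, numeric(1))
  out <- data.frame(
    protein_accession = recs$protein_accession[first],
    position = recs$position[first],
    amino_acid = recs$amino_acid[first],
    localization_prob = loc_prob,
    contrast = contrast,
    raw_ratio = raw_ratio,
    p_value = p_value,
    n_supporting_peptides = support,
    stringsAsFactors = FALSE)
  keep <- is.finite(out$raw_ratio) & out$raw_ratio > 0
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_site_quant <- function(contrast) {
  data.frame(protein_accession = character(), position = integer(),
             amino_acid = character(), localization_prob = numeric(),
             contrast = character(), raw_ratio = numeric(),
             p_value = numeric(), n_supporting_peptides = integer(),
             stringsAsFactors = FALSE)
}

#' Normalize phosphosite ratios by the parent protein's fold change
#'
#' Divides each site's raw ratio by its protein's fold change in the same
#' contrast (the standard phospho-occupancy correction on the ratio
#' scale, equivalent to subtraction in log space). Sites whose protein is
#' unquantified or absent from the protein table keep their raw ratio and
#' are flagged `protein_normalized = FALSE`; the number of such sites is
#' attached as attribute `n_unnormalized` and reported via `message()`.
#'
#' @param sites site quantification data frame (from
#'   [quantify_phosphosites()] or its internal raw route) with columns
#'   `protein_accession`, `contrast`, `raw_ratio`.
#' @param protein_quant data frame from [quantify_proteins()].
#' @return `sites` with columns `normalized_ratio` and
#'   `protein_normalized` added or overwritten.
#' @export
normalize_site_by_protein <- function(sites, protein_quant) {
  pq <- protein_quant[protein_quant$quantified, , drop = FALSE]
  if (any(pq$ratio <= 0, na.rm = TRUE))
    stop("contract violation: non-positive protein ratio")
  key <- paste(pq$protein_accession, pq$contrast, sep = "\r")
  prot_ratio <- stats::setNames(pq$ratio, key)
  skey <- paste(sites$protein_accession, sites$contrast, sep = "\r")
  pr <- prot_ratio[skey]
  normalized <- !is.na(pr)
  sites$normalized_ratio <- ifelse(normalized, sites$raw_ratio / pr,
                                   sites$raw_ratio)
  sites$protein_normalized <- normalized
  n_un <- sum(!normalized)
  if (n_un > 0)
    message(n_un, " site(s) kept unnormalized: parent protein not quantified")
  attr(sites, "n_unnormalized") <- n_un
  sites
}
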