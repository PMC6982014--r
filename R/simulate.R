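#' Configuration for the synthetic TMT experiment generator
#'
#' Defaults emulate a 9-channel experiment (3 conditions x 3 biological
#' replicates) with log-normally distributed reporter intensities,
#' several unique peptides per protein, 10% truly regulated proteins at a
#' 4-fold effect, multiplicative log2-normal channel noise of SD 0.15,
#' and Beta(4, 1) phosphosite localization probabilities (about 68% of
#' sites exceed the 0.75 filter).
#'
#' @param seed integer seed; one seeded generator is threaded through all
#'   draws, so identical seeds give identical output.
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein mean of the (>= 1 truncated) per-protein
#'   peptide count distribution.
#' @param design a [tmt_design()]; the first condition listed is the
#'   unperturbed reference.
#' @param fraction_regulated fraction of proteins with a true effect.
#' @param effect_fold true fold change of regulated entities (> 1;
#'   direction is random per entity).
#' @param intensity_log_mean,intensity_log_sd natural-log mean and SD of
#'   the log-normal peptide base intensity.
#' @param noise_log2_sd SD of the per-channel multiplicative log2-normal
#'   noise (>= 0).
#' @param prob_unique probability a peptide is unique to its protein.
#' @param phospho_fraction fraction of proteins carrying phosphosites.
#' @param loc_prob_alpha,loc_prob_beta Beta parameters of the site
#'   localization probabilities.
#' @param fraction_phospho_independent fraction of sites whose regulation
#'   is independent of their protein's abundance (these stay regulated
#'   after protein normalization; co-regulated sites are driven to 1).
#' @param n_categories number of annotation categories.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 2000,
                       peptides_per_protein = 5,
                       design = default_design(),
                       fraction_regulated = 0.1, effect_fold = 4,
                       intensity_log_mean = log(1e6),
                       intensity_log_sd = 1,
                       noise_log2_sd = 0.15, prob_unique = 0.9,
                       phospho_fraction = 0.3,
                       loc_prob_alpha = 4, loc_prob_beta = 1,
                       fraction_phospho_independent = 0.1,
                       n_categories = 20) {
  frac <- c(fraction_regulated, phospho_fraction,
            fraction_phospho_independent, prob_unique)
  if (any(frac < 0 | frac > 1))
    stop("validation error: fractions must lie in [0, 1]")
  if (effect_fold <= 1)
    stop("validation error: effect_fold must exceed 1")
  if (noise_log2_sd < 0)
    stop("validation error: noise_log2_sd must be >= 0")
  if (n_proteins < 1 || peptides_per_protein < 1)
    stop("validation error: n_proteins and peptides_per_protein must be >= 1")
  if (loc_prob_alpha <= 0 || loc_prob_beta <= 0)
    stop("validation error: Beta parameters must be positive")
  validate_design(design)
  structure(list(seed = as.integer(seed), n_proteins = n_proteins,
                 peptides_per_protein = peptides_per_protein,
                 design = design, fraction_regulated = fraction_regulated,
                 effect_fold = effect_fold,
                 intensity_log_mean = intensity_log_mean,
                 intensity_log_sd = intensity_log_sd,
                 noise_log2_sd = noise_log2_sd, prob_unique = prob_unique,
                 phospho_fraction = phospho_fraction,
                 loc_prob_alpha = loc_prob_alpha,
                 loc_prob_beta = loc_prob_beta,
                 fraction_phospho_independent = fraction_phospho_independent,
                 n_categories = n_categories),
            class = "sim_config")
}

# intensity matrix for a set of peptides: base * condition multiplier *
# multiplicative log2-normal noise, one column per design channel
channel_intensities <- function(base, mult_rows, design, noise_log2_sd) {
  n <- length(base)
  k <- nrow(design)
  cond_idx <- match(design$condition, colnames(mult_rows))
  m <- base * mult_rows[, cond_idx, drop = FALSE]
  noise <- matrix(2^stats::rnorm(n * k, 0, noise_log2_sd), n, k)
  ints <- m * noise
  colnames(ints) <- paste0("intensity_", design$channel)
  as.data.frame(ints)
}

#' Simulate a TMT proteome/phosphoproteome experiment with known truth
#'
#' Generates a PSM table, a phosphopeptide PSM table, an annotation map
#' and the ground truth under a [sim_config()]. Regulated proteins have
#' one randomly chosen treatment condition multiplied by
#' `effect_fold^(+/-1)`; phosphosites either co-vary with their protein
#' or (with probability `fraction_phospho_independent`) carry an
#' additional site-level effect of their own. One annotation category
#' (`CAT01`) is enriched among truly up-regulated proteins so that
#' enrichment power can be tested.
#'
#' @param config a [sim_config()].
#' @return List with elements `psms` (unmodified-peptide `psm_table`),
#'   `phospho_psms` (phosphopeptide `psm_table`), `design`, `annotation`,
#'   `truth` (list: `protein_mult` and `site_mult` condition-multiplier
#'   matrices, `sites` site metadata) and `config`.
#' @export
simulate_tmt_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- config$design
  conds <- unique(design$condition)
  reference <- conds[1]
  np <- config$n_proteins
  accs <- sprintf("P%05d", seq_len(np))

  # per-protein condition multipliers
  mult <- matrix(1, np, length(conds), dimnames = list(accs, conds))
  regulated <- stats::runif(np) < config$fraction_regulated
  if (length(conds) > 1) {
    target <- sample(conds[-1], np, replace = TRUE)
    direction <- sample(c(1, -1), np, replace = TRUE)
    for (i in which(regulated))
      mult[i, target[i]] <- config$effect_fold^direction[i]
  }

  # unmodified peptides
  n_pep <- 1 + stats::rpois(np, max(config$peptides_per_protein - 1, 0))
  prot_of_pep <- rep(seq_len(np), n_pep)
  total <- length(prot_of_pep)
  pep_seq <- sprintf("PEP%07d", seq_len(total))
  base <- exp(stats::rnorm(total, config$intensity_log_mean,
                           config$intensity_log_sd))
  psms <- data.frame(
    peptide_sequence = pep_seq,
    protein_accession = accs[prot_of_pep],
    is_unique = stats::runif(total) < config$prob_unique,
    modifications = "",
    stringsAsFactors = FALSE)
  psms <- cbind(psms, channel_intensities(
    base, mult[prot_of_pep, , drop = FALSE], design, config$noise_log2_sd))
  psms <- as_psm_table(psms, design)

  # phosphosites: 1-3 sites per phosphoprotein, 2-3 supporting peptides
  is_phospho <- stats::runif(np) < config$phospho_fraction
  phos_prot <- which(is_phospho)
  n_sites <- if (length(phos_prot)) sample(1:3, length(phos_prot),
                                           replace = TRUE) else integer()
  site_prot <- rep(phos_prot, n_sites)
  ns_total <- length(site_prot)
  site_mult <- matrix(1, ns_total, length(conds),
                      dimnames = list(NULL, conds))
  independent <- stats::runif(ns_total) < config$fraction_phospho_independent
  if (length(conds) > 1 && ns_total > 0) {
    s_target <- sample(conds[-1], ns_total, replace = TRUE)
    s_dir <- sample(c(1, -1), ns_total, replace = TRUE)
    for (i in which(independent))
      site_mult[i, s_target[i]] <- config$effect_fold^s_dir[i]
  }
  sites <- data.frame(
    protein_accession = accs[site_prot],
    position = sample(1:600, ns_total, replace = TRUE),
    amino_acid = sample(c("S", "T", "Y"), ns_total, replace = TRUE,
                        prob = c(0.8, 0.15, 0.05)),
    localization_prob = if (ns_total)
      stats::rbeta(ns_total, config$loc_prob_alpha, config$loc_prob_beta)
      else numeric(),
    independent = independent,
    stringsAsFactors = FALSE)
  # drop accidental duplicate (accession, position) pairs
  dup <- duplicated(sites[c("protein_accession", "position")])
  sites <- sites[!dup, , drop = FALSE]
  site_mult <- site_mult[!dup, , drop = FALSE]
  ns_total <- nrow(sites)

  n_support <- if (ns_total) sample(2:3, ns_total, replace = TRUE) else
    integer()
  site_of_pep <- rep(seq_len(ns_total), n_support)
  ptotal <- length(site_of_pep)
  if (ptotal > 0) {
    pbase <- exp(stats::rnorm(ptotal, config$intensity_log_mean,
                              config$intensity_log_sd))
    eff_mult <- mult[match(sites$protein_accession[site_of_pep], accs), ,
                     drop = FALSE] *
      site_mult[site_of_pep, , drop = FALSE]
    colnames(eff_mult) <- conds
    phospho_psms <- data.frame(
      peptide_sequence = sprintf("PHO%07d", seq_len(ptotal)),
      protein_accession = sites$protein_accession[site_of_pep],
      is_unique = TRUE,
      modifications = paste(sites$amino_acid[site_of_pep],
                            sites$position[site_of_pep],
                            round(sites$localization_prob[site_of_pep], 6),
                            sep = ":"),
      stringsAsFactors = FALSE)
    phospho_psms <- cbind(phospho_psms, channel_intensities(
      pbase, eff_mult, design, config$noise_log2_sd))
    phospho_psms <- as_psm_table(phospho_psms, design)
  } else {
    phospho_psms <- NULL
  }

  # annotation: random categories; CAT01 enriched among truly-up proteins
  cats <- sprintf("CAT%02d", seq_len(config$n_categories))
  nspaces <- c("biological process", "molecular function",
               "cellular component", "pathway")
  cat_ns <- stats::setNames(rep(nspaces, length.out = length(cats)), cats)
  n_cat_per_prot <- sample(1:3, np, replace = TRUE)
  ann_acc <- rep(accs, n_cat_per_prot)
  ann_cat <- unlist(lapply(n_cat_per_prot, function(k)
    sample(cats, k, replace = FALSE)), use.names = FALSE)
  truly_up <- accs[apply(mult > 1, 1, any)]
  extra <- truly_up[stats::runif(length(truly_up)) < 0.6]
  ann_acc <- c(ann_acc, extra)
  ann_cat <- c(ann_cat, rep("CAT01", length(extra)))
  annotation <- annotation_map(ann_acc, ann_cat, unname(cat_ns[ann_cat]))

  # site loc prob rounded in the packed string; keep truth consistent
  sites$localization_prob <- round(sites$localization_prob, 6)
  list(psms = psms, phospho_psms = phospho_psms, design = design,
       annotation = annotation,
       truth = list(protein_mult = mult, site_mult = site_mult,
                    sites = sites, reference = reference),
       config = config)
}

# true fold change of each entity for a "num/den" contrast label
true_ratio_for <- function(mult, contrast) {
  parts <- strsplit(contrast, "/", fixed = TRUE)[[1]]
  if (!all(parts %in% colnames(mult)))
    stop("input error: contrast names unknown condition(s): ", contrast)
  mult[, parts[1]] / mult[, parts[2]]
}

#' Confusion-matrix summaries of differential calls against ground truth
#'
#' @param calls data frame of protein calls with columns
#'   `protein_accession`, `contrast`, `regulated` (from
#'   [quantify_proteins()]); unquantified entities count as not called.
#' @param truth the `truth` element of [simulate_tmt_experiment()]
#'   output.
#' @return Data frame per contrast: `sensitivity` (regulated truths
#'   called up or down), `specificity` (null truths called ns),
#'   `fdr` (false discoveries among calls), `direction_accuracy`
#'   (correct sign among true positives), and the underlying counts.
#' @export
evaluate_recovery <- function(calls, truth) {
  mult <- truth$protein_mult
  if (!all(calls$protein_accession %in% rownames(mult)))
    stop("input error: calls contain entities absent from the truth")
  out <- lapply(sort(unique(calls$contrast)), function(ct) {
    d <- calls[calls$contrast == ct, , drop = FALSE]
    tr <- true_ratio_for(mult, ct)[d$protein_accession]
    status <- ifelse(tr > 1, "up", ifelse(tr < 1, "down", "null"))
    called <- d$regulated %in% c("up", "down")
    tp <- sum(called & status != "null")
    fp <- sum(called & status == "null")
    fn <- sum(!called & status != "null")
    tn <- sum(!called & status == "null")
    dir_ok <- sum(called & status != "null" & d$regulated == status)
    data.frame(
      contrast = ct,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
      direction_accuracy = if (tp > 0) dir_ok / tp else NA_real_,
      tp = tp, fp = fp, fn = fn, tn = tn,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
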