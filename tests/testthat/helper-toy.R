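# Small in-code fixtures shared across test files.

# two-condition, two-replicate design
toy_design2 <- function() {
  tmt_design(channel = c("c1", "c2", "c3", "c4"),
             condition = c("A", "A", "B", "B"),
             replicate = c(1, 2, 1, 2))
}

# build a plain-dialect PSM table from per-row intensity vectors
toy_psms <- function(design, seqs, accs, unique, intensities,
                     mods = rep("", length(seqs))) {
  ints <- do.call(rbind, intensities)
  colnames(ints) <- paste0("intensity_", design$channel)
  df <- data.frame(peptide_sequence = seqs, protein_accession = accs,
                   is_unique = unique, modifications = mods,
                   stringsAsFactors = FALSE)
  as_psm_table(cbind(df, as.data.frame(ints)), design)
}

# single-channel-per-condition design: intensities are per-condition
toy_design1 <- function(conds = c("A", "B")) {
  tmt_design(channel = paste0("ch", seq_along(conds)),
             condition = conds, replicate = rep(1, length(conds)))
}

# annotation map built from the bundled differential-protein table:
# category = functional section heading of each accession
fixture_annotation <- function() {
  tab <- utils::read.delim(tmtphos_example("poplar_protein_diff.tsv"))
  annotation_map(tab$accession, tab$category)
}

# independent hypergeometric upper-tail oracle: explicit sum of
# binomial-coefficient terms P[X >= k]
hyper_tail_oracle <- function(k, K, N, n) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
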