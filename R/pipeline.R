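#' Run the complete differential workflow
#'
#' Convenience driver: protein quantification for every contrast,
#' phosphosite quantification normalized by the protein results,
#' up/down tallies, and (when an annotation map is given) category
#' enrichment of the up- and down-regulated protein sets per contrast
#' with the z-score matrix. Results are optionally written to `out_dir`
#' via [write_results()].
#'
#' @param psms unmodified-peptide `psm_table`.
#' @param design a [tmt_design()].
#' @param contrasts contrast labels.
#' @param phospho_psms optional phosphopeptide `psm_table`.
#' @param annotation optional `annotation_map`.
#' @param thresholds a [thresholds()] object.
#' @param out_dir optional output directory.
#' @param seed optional integer recorded in the manifest.
#' @return List with `protein_quant`, `site_quant`, `counts`,
#'   `site_counts`, `enrichment`, `enrichment_matrix`.
#' @export
run_tmt_pipeline <- function(psms, design, contrasts = "Cd/CK",
                             phospho_psms = NULL, annotation = NULL,
                             thresholds = tmtphos::thresholds(),
                             out_dir = NULL, seed = NULL) {
  pq <- quantify_proteins(psms, design, contrasts, thresholds)
  sq <- NULL
  if (!is.null(phospho_psms))
    sq <- quantify_phosphosites(phospho_psms, design, contrasts,
                                protein_quant = pq,
                                thresholds = thresholds)
  enr <- NULL
  em <- NULL
  if (!is.null(annotation)) {
    parts <- list()
    for (ct in contrasts) {
      d <- pq[pq$contrast == ct & pq$quantified, , drop = FALSE]
      background <- d$protein_accession
      for (dirn in c("up", "down")) {
        fg <- d$protein_accession[d$regulated == dirn]
        if (length(fg) == 0) next
        r <- enrich_categories(fg, background, annotation)
        if (nrow(r) > 0) {
          r$cluster <- paste(ct, dirn)
          parts[[paste(ct, dirn)]] <- r
        }
      }
    }
    if (length(parts) > 0) {
      enr <- do.call(rbind, c(parts, make.row.names = FALSE))
      em <- enrichment_matrix(enr, alpha = thresholds$alpha)
    }
  }
  if (!is.null(out_dir))
    write_results(out_dir, protein_quant = pq, site_quant = sq,
                  enrichment = enr, thresholds = thresholds, seed = seed)
  list(protein_quant = pq, site_quant = sq,
       counts = count_regulated(pq),
       site_counts = if (!is.null(sq)) count_regulated(sq) else NULL,
       enrichment = enr, enrichment_matrix = em)
}
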