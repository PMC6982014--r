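#' Read a PSM (peptide-spectrum match) table with reporter intensities
#'
#' Two dialects are supported. `"plain"` is the package's canonical layout:
#' columns `peptide_sequence`, `protein_accession`, `is_unique`
#' (TRUE/FALSE), `modifications` (packed string, see Details) and one
#' `intensity_<channel>` column per design channel. `"maxquant-like"`
#' consumes a MaxQuant-style export: `Sequence`, `Proteins`,
#' `Unique (Groups)` (yes/no), `Reporter intensity 1..k` (mapped
#' positionally onto the design's channel order) and, when present,
#' `Amino acid`, `Position` and `Localization prob` describing a single
#' phosphosite per row.
#'
#' Rows whose intensity fields do not parse as numbers are rejected; the
#' count of rejected rows is attached as attribute `n_rejected` and
#' reported via `message()`. Row order is preserved.
#'
#' @details Modifications are packed as semicolon-separated
#'   `residue:position:localization_probability` triples, e.g.
#'   `"S:123:0.98;T:130:0.6"`; the empty string marks an unmodified
#'   peptide. Positions are 1-based protein coordinates.
#'
#' @param path path to a tab-delimited file.
#' @param design a [tmt_design()] describing the channels.
#' @param dialect `"plain"` or `"maxquant-like"`.
#' @return A `psm_table` data frame in the canonical layout, with
#'   attributes `channels` and `n_rejected`.
#' @export
read_psm_table <- function(path, design, dialect = c("plain", "maxquant-like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("format error: file not found: ", path)
  validate_design(design)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (dialect == "maxquant-like") {
    req <- c("Sequence", "Proteins", "Unique (Groups)")
    miss <- setdiff(req, names(raw))
    if (length(miss) > 0)
      stop("format error: missing required column: ",
           paste(miss, collapse = ", "))
    rep_cols <- paste("Reporter intensity", seq_len(nrow(design)))
    miss <- setdiff(rep_cols, names(raw))
    if (length(miss) > 0)
      stop("format error: missing required column: ",
           paste(miss, collapse = ", "))
    mods <- rep("", nrow(raw))
    if (all(c("Amino acid", "Position", "Localization prob") %in% names(raw))) {
      has <- nzchar(raw[["Amino acid"]]) & !is.na(raw[["Amino acid"]])
      mods[has] <- paste(raw[["Amino acid"]][has], raw[["Position"]][has],
                         raw[["Localization prob"]][has], sep = ":")
    }
    out <- data.frame(peptide_sequence = raw$Sequence,
                      protein_accession = raw$Proteins,
                      is_unique = tolower(raw[["Unique (Groups)"]]) %in%
                        c("yes", "true", "+", "1"),
                      modifications = mods,
                      stringsAsFactors = FALSE)
    ints <- raw[rep_cols]
    names(ints) <- paste0("intensity_", design$channel)
  } else {
    req <- c("peptide_sequence", "protein_accession", "is_unique",
             "modifications")
    int_cols <- paste0("intensity_", design$channel)
    miss <- setdiff(c(req, int_cols), names(raw))
    if (length(miss) > 0) {
      if (any(grepl("^intensity_", miss)))
        stop("design error: intensity column(s) absent for design channel(s): ",
             paste(sub("^intensity_", "", grep("^intensity_", miss, value = TRUE)),
                   collapse = ", "))
      stop("format error: missing required column: ",
           paste(miss, collapse = ", "))
    }
    out <- data.frame(peptide_sequence = raw$peptide_sequence,
                      protein_accession = raw$protein_accession,
                      is_unique = tolower(raw$is_unique) %in%
                        c("yes", "true", "+", "1"),
                      modifications = raw$modifications,
                      stringsAsFactors = FALSE)
    ints <- raw[int_cols]
  }
  suppressWarnings(ints[] <- lapply(ints, as.numeric))
  bad <- rowSums(is.na(as.matrix(ints))) > 0
  if (any(bad))
    message(sum(bad), " row(s) rejected: non-numeric reporter intensities")
  out <- cbind(out, stats::setNames(ints, paste0("intensity_", design$channel)))
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  as_psm_table(out, design, n_rejected = sum(bad))
}

#' Coerce a data frame to a validated PSM table
#'
#' @param x data frame in the canonical plain layout (see
#'   [read_psm_table()]).
#' @param design a [tmt_design()].
#' @param n_rejected count of rejected input rows to record.
#' @return A `psm_table` data frame.
#' @export
as_psm_table <- function(x, design, n_rejected = 0L) {
  int_cols <- paste0("intensity_", design$channel)
  miss <- setdiff(int_cols, names(x))
  if (length(miss) > 0)
    stop("design error: intensity column(s) absent for design channel(s): ",
         paste(sub("^intensity_", "", miss), collapse = ", "))
  ints <- as.matrix(x[int_cols])
  if (any(ints < 0, na.rm = TRUE))
    stop("format error: negative reporter intensities")
  structure(x, class = c("psm_table", "data.frame"),
            channels = design$channel, n_rejected = as.integer(n_rejected))
}

#' Write a PSM table in the plain dialect
#'
#' Inverse of [read_psm_table()] for `dialect = "plain"`; a written table
#' re-read against the same design reproduces the records exactly.
#'
#' @param psms a `psm_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Expand the packed modifications column into one row per (PSM, site).
# Returns psm_row, residue, position, localization_prob.
parse_modifications <- function(mods) {
  items <- strsplit(mods, ";", fixed = TRUE)
  n_each <- lengths(items)
  rows <- rep(seq_along(mods), n_each)
  flat <- unlist(items, use.names = FALSE)
  if (length(flat) == 0)
    return(data.frame(psm_row = integer(), residue = character(),
                      position = integer(), localization_prob = numeric(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(flat, ":", fixed = TRUE))
  out <- data.frame(psm_row = rows,
                    residue = parts[, 1],
                    position = as.integer(parts[, 2]),
                    localization_prob = as.numeric(parts[, 3]),
                    stringsAsFactors = FALSE)
  if (any(!out$residue %in% c("S", "T", "Y")))
    stop("format error: modified residue must be one of S/T/Y")
  if (any(out$position < 1))
    stop("format error: site positions are 1-based and must be >= 1")
  if (any(out$localization_prob < 0 | out$localization_prob > 1))
    stop("format error: localization probability must lie in [0, 1]")
  out
}

#' Read a protein-to-category annotation table
#'
#' Expects a tab-delimited file with columns `accession` and `category`
#' (GO/KEGG-style identifiers) and an optional `namespace` column
#' (e.g. biological process / molecular function / cellular component /
#' pathway). Duplicate (accession, category) pairs are collapsed.
#'
#' @param path path to the annotation file.
#' @return An `annotation_map` data frame with columns
#'   `protein_accession`, `category`, `namespace`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (nrow(tab) == 0) {
    warning("empty annotation file: ", path)
    return(annotation_map(character(), character(), character()))
  }
  miss <- setdiff(c("accession", "category"), names(tab))
  if (length(miss) > 0)
    stop("format error: missing required column: ",
         paste(miss, collapse = ", "))
  ns <- if ("namespace" %in% names(tab)) tab$namespace else
    rep(NA_character_, nrow(tab))
  annotation_map(tab$accession, tab$category, ns)
}

#' Construct an annotation map
#'
#' @param accession protein accessions.
#' @param category category identifiers (non-empty strings).
#' @param namespace optional namespace per entry.
#' @return An `annotation_map` data frame.
#' @export
annotation_map <- function(accession, category,
                           namespace = rep(NA_character_, length(accession))) {
  if (any(!nzchar(category)))
    stop("format error: empty category identifier")
  out <- data.frame(protein_accession = as.character(accession),
                    category = as.character(category),
                    namespace = as.character(namespace),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("protein_accession", "category")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_map", "data.frame")
  out
}

#' Look up the categories of one protein
#'
#' @param annotation an `annotation_map`.
#' @param accession a single protein accession.
#' @return Character vector of category identifiers (possibly empty).
#' @export
annotation_lookup <- function(annotation, accession) {
  annotation$category[annotation$protein_accession == accession]
}

#' Read a physiological summary table
#'
#' Tab-delimited, one row per metric x treatment with columns `metric`,
#' `treatment`, `mean`, `sd`, `n` and optional `unit` and `letter`
#' (reported Tukey grouping) columns.
#'
#' @param path path to the table.
#' @return A data frame.
#' @export
read_physiology <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  miss <- setdiff(c("metric", "treatment", "mean", "sd", "n"), names(tab))
  if (length(miss) > 0)
    stop("format error: missing required column: ",
         paste(miss, collapse = ", "))
  if (any(tab$sd < 0)) stop("format error: negative SD")
  tab
}

#' Path to a bundled example data file
#'
#' The package ships transcribed summary tables from a poplar
#' cadmium/nitrogen stress study: `"poplar_physiology.tsv"` (chlorophyll,
#' gas exchange, tissue Cd and redox metrics as mean/SD/n with reported
#' Tukey letters), `"poplar_protein_diff.tsv"` (differentially regulated
#' proteins with fold-change ratios and p-values per contrast) and
#' `"poplar_phosphosite_diff.tsv"` (differentially regulated
#' phosphosites).
#'
#' @param file file name; with no argument, lists available files.
#' @return A file path, or a character vector of file names.
#' @export
tmtphos_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "tmtphos")))
  path <- system.file("extdata", file, package = "tmtphos")
  if (!nzchar(path)) stop("no such example file: ", file)
  path
}

format_ratio <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 3, format = "f"))
}

format_pval <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 4), format = "g", digits = 4))
}

#' Write pipeline result tables
#'
#' Writes tab-delimited outputs, one file per contrast for protein and
#' phosphosite quantification, plus enrichment tables and a run manifest
#' recording the thresholds and seed. Ratios are printed with 3 decimal
#' places and p-values with 4 significant digits; column order is fixed,
#' so identical inputs yield byte-identical files.
#'
#' @param out_dir output directory (created if absent).
#' @param protein_quant optional protein quantification data frame
#'   (from [quantify_proteins()]).
#' @param site_quant optional phosphosite data frame
#'   (from [quantify_phosphosites()]).
#' @param enrichment optional enrichment result data frame
#'   (from [enrich_categories()], with a `cluster` column) .
#' @param thresholds optional [thresholds()] recorded in the manifest.
#' @param seed optional integer seed recorded in the manifest.
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(out_dir, protein_quant = NULL, site_quant = NULL,
                          enrichment = NULL, thresholds = NULL, seed = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok) stop("I/O error: cannot create output directory: ", out_dir)
  paths <- character()
  slug <- function(contrast) gsub("/", "_vs_", contrast, fixed = TRUE)
  write_one <- function(tab, path) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, path)
  }
  if (!is.null(protein_quant)) {
    for (ct in sort(unique(protein_quant$contrast))) {
      tab <- protein_quant[protein_quant$contrast == ct,
                           c("protein_accession", "ratio", "p_value",
                             "n_unique_peptides", "regulated")]
      tab$ratio <- format_ratio(tab$ratio)
      tab$p_value <- format_pval(tab$p_value)
      write_one(tab, file.path(out_dir,
                               paste0("protein_quant_", slug(ct), ".tsv")))
    }
    if (length(unique(protein_quant$contrast)) == 0)
      write_one(protein_quant[0, c("protein_accession", "ratio", "p_value",
                                   "n_unique_peptides", "regulated")],
                file.path(out_dir, "protein_quant_empty.tsv"))
  }
  if (!is.null(site_quant)) {
    for (ct in sort(unique(site_quant$contrast))) {
      tab <- site_quant[site_quant$contrast == ct,
                        c("protein_accession", "position", "amino_acid",
                          "localization_prob", "raw_ratio",
                          "normalized_ratio", "p_value",
                          "protein_normalized", "regulated")]
      tab$raw_ratio <- format_ratio(tab$raw_ratio)
      tab$normalized_ratio <- format_ratio(tab$normalized_ratio)
      tab$localization_prob <- format_ratio(tab$localization_prob)
      tab$p_value <- format_pval(tab$p_value)
      write_one(tab, file.path(out_dir,
                               paste0("phosphosite_quant_", slug(ct), ".tsv")))
    }
  }
  if (!is.null(enrichment)) {
    tab <- enrichment
    tab$p_value <- format_pval(tab$p_value)
    if ("p_adjust" %in% names(tab)) tab$p_adjust <- format_pval(tab$p_adjust)
    write_one(tab, file.path(out_dir, "enrichment.tsv"))
  }
  manifest <- c(
    if (!is.null(thresholds))
      paste0(names(unclass(thresholds)), "\t",
             unlist(unclass(thresholds))),
    if (!is.null(seed)) paste0("seed\t", seed)
  )
  mf <- file.path(out_dir, "manifest.tsv")
  writeLines(c("key\tvalue", manifest), mf)
  paths <- c(paths, mf)
  invisible(paths)
}
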