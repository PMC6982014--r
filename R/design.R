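#' Construct a channel-to-sample design map
#'
#' A design map assigns every reporter channel of the multiplex to one
#' condition and replicate. Channel labels are opaque strings ("126",
#' "127N", ...): quantification needs only channel identity, not reporter
#' masses.
#'
#' @param channel character vector of channel labels, one per multiplex
#'   channel, in acquisition order.
#' @param condition character vector, condition of each channel.
#' @param replicate integer vector, biological replicate index (>= 1)
#'   within each condition.
#' @return A `tmt_design` data frame with columns `channel`, `condition`,
#'   `replicate`.
#' @examples
#' tmt_design(c("126", "127N", "127C", "128N"),
#'            c("CK", "CK", "Cd", "Cd"), c(1, 2, 1, 2))
#' @export
tmt_design <- function(channel, condition, replicate) {
  design <- data.frame(channel = as.character(channel),
                       condition = as.character(condition),
                       replicate = as.integer(replicate),
                       stringsAsFactors = FALSE)
  validate_design(design)
  class(design) <- c("tmt_design", "data.frame")
  design
}

#' Default 3-condition x 3-replicate design
#'
#' Nine channels of a TMT multiplex assigned to control (CK), cadmium
#' stress (Cd) and cadmium plus nitrogen (CdN), three biological
#' replicates each.
#'
#' @return A `tmt_design` data frame with 9 rows.
#' @export
default_design <- function() {
  tmt_design(
    channel = c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                "130N", "130C"),
    condition = rep(c("CK", "Cd", "CdN"), each = 3),
    replicate = rep(1:3, times = 3)
  )
}

validate_design <- function(design) {
  req <- c("channel", "condition", "replicate")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0)
    stop("design error: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$channel))
    stop("design error: duplicated channel label(s): ",
         paste(unique(design$channel[duplicated(design$channel)]),
               collapse = ", "))
  if (any(is.na(design$replicate)) || any(design$replicate < 1))
    stop("design error: replicate indices must be positive integers")
  if (any(!nzchar(design$condition)) || any(is.na(design$condition)))
    stop("design error: empty condition label")
  invisible(design)
}

#' Read a design table
#'
#' Expects a tab-delimited file with columns `channel`, `condition`,
#' `replicate` (one row per channel).
#'
#' @param path path to the tab-delimited design file.
#' @return A `tmt_design` data frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design error: file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = "character")
  req <- c("channel", "condition", "replicate")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("design error: missing column(s): ", paste(miss, collapse = ", "))
  tmt_design(tab$channel, tab$condition, as.integer(tab$replicate))
}

#' Differential-calling thresholds
#'
#' Bundles the cutoffs used throughout the pipeline. Defaults follow the
#' conventional criteria for TMT differential analysis of this design:
#' fold change > 1.3 for proteins, > 1.2 for phosphosites, raw p < 0.05,
#' site localization probability > 0.75, and at least two unique peptides
#' per quantified protein.
#'
#' @param fc_proteome protein fold-change cutoff (> 1).
#' @param fc_phospho phosphosite fold-change cutoff (> 1).
#' @param alpha significance level in (0, 1).
#' @param loc_prob_min minimum phosphosite localization probability
#'   (strict inequality is applied: sites must exceed this value).
#' @param min_unique_peptides minimum number of unique peptides for a
#'   protein to be quantified (>= 1).
#' @return A named list of class `tmt_thresholds`.
#' @export
thresholds <- function(fc_proteome = 1.3, fc_phospho = 1.2, alpha = 0.05,
                       loc_prob_min = 0.75, min_unique_peptides = 2) {
  if (fc_proteome <= 1 || fc_phospho <= 1)
    stop("configuration error: fold-change thresholds must exceed 1")
  if (alpha <= 0 || alpha >= 1)
    stop("configuration error: alpha must lie in (0, 1)")
  if (loc_prob_min < 0 || loc_prob_min > 1)
    stop("configuration error: loc_prob_min must lie in [0, 1]")
  if (min_unique_peptides < 1)
    stop("configuration error: min_unique_peptides must be >= 1")
  structure(list(fc_proteome = fc_proteome, fc_phospho = fc_phospho,
                 alpha = alpha, loc_prob_min = loc_prob_min,
                 min_unique_peptides = as.integer(min_unique_peptides)),
            class = "tmt_thresholds")
}

# Split "Cd/CK" into numerator and denominator condition, validated
# against the design. Numerator is always the first-named condition.
parse_contrast <- function(contrast, design) {
  parts <- strsplit(contrast, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2 || any(!nzchar(parts)))
    stop("design error: contrast must have the form 'treatment/reference': ",
         contrast)
  unknown <- setdiff(parts, design$condition)
  if (length(unknown) > 0)
    stop("design error: contrast names unknown condition(s): ",
         paste(unknown, collapse = ", "))
  list(numerator = parts[1], denominator = parts[2])
}
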