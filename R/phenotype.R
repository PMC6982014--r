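#' Percent change between two treatment means
#'
#' `100 * (treatment - reference) / reference`; the sign gives the
#' direction (negative = decrease relative to the reference).
#'
#' @param treatment_mean treatment mean(s).
#' @param reference_mean reference mean(s); must be non-zero.
#' @return Percent change(s), unrounded.
#' @export
percent_change <- function(treatment_mean, reference_mean) {
  if (any(reference_mean == 0))
    stop("domain error: zero reference mean")
  100 * (treatment_mean - reference_mean) / reference_mean
}

#' One-way ANOVA and Tukey HSD from summary statistics
#'
#' Computes the within-group mean square as the df-weighted average of
#' the group variances (`MSw = sum((n_i - 1) s_i^2) / sum(n_i - 1)`,
#' exact for any design since raw replicate values enter ANOVA only
#' through their group means and variances) and the pairwise Tukey
#' studentized-range p-values
#' `q_ij = |m_i - m_j| / sqrt(MSw/2 * (1/n_i + 1/n_j))`.
#'
#' @param means numeric vector of group means (named or not).
#' @param sds numeric vector of group SDs.
#' @param ns integer vector of group sizes (>= 2).
#' @return List with `p` (symmetric matrix of pairwise Tukey p-values),
#'   `ms_within`, `df_within`, and the omnibus ANOVA `f` and `p_anova`.
#' @export
tukey_hsd_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2) stop("input error: at least two groups required")
  if (length(sds) != k || length(ns) != k)
    stop("input error: means, sds and ns must have equal length")
  if (any(ns < 2)) stop("input error: group sizes must be >= 2")
  if (any(sds < 0)) stop("input error: negative SD")
  df_w <- sum(ns - 1)
  ms_w <- sum((ns - 1) * sds^2) / df_w
  grand <- sum(ns * means) / sum(ns)
  ms_b <- sum(ns * (means - grand)^2) / (k - 1)
  f <- if (ms_w > 0) ms_b / ms_w else ifelse(ms_b > 0, Inf, NaN)
  p_anova <- if (is.nan(f)) NA_real_ else
    stats::pf(f, k - 1, df_w, lower.tail = FALSE)
  p <- matrix(1, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(ms_w / 2 * (1 / ns[i] + 1 / ns[j]))
    p[i, j] <- p[j, i] <- if (se == 0) {
      if (means[i] == means[j]) 1 else 0
    } else
      stats::ptukey(abs(means[i] - means[j]) / se, k, df_w,
                    lower.tail = FALSE)
  }
  nm <- names(means)
  if (!is.null(nm)) dimnames(p) <- list(nm, nm)
  list(p = p, ms_within = ms_w, df_within = df_w, f = f, p_anova = p_anova)
}

#' Compact letter display from summary statistics
#'
#' Assigns grouping letters by a greedy insert-and-absorb pass over the
#' treatments ordered by descending mean: the largest mean receives "A",
#' and each treatment joins every existing letter group whose members it
#' does not differ from significantly (pairwise Tukey HSD at `alpha`),
#' opening a new letter when it joins none. Treatments sharing a letter
#' do not differ significantly.
#'
#' @param means named numeric vector of group means (names are treatment
#'   labels; unnamed vectors get G1, G2, ...).
#' @param sds group SDs.
#' @param ns group sizes.
#' @param alpha significance level; a pair differs when its Tukey p-value
#'   is `<= alpha`.
#' @return Named character vector of letter strings, one per treatment,
#'   in the input order.
#' @export
tukey_letters <- function(means, sds, ns, alpha = 0.05) {
  k <- length(means)
  nm <- names(means)
  if (is.null(nm)) nm <- paste0("G", seq_len(k))
  if (all(sds == 0) && length(unique(means)) == 1) {
    message("degenerate input: all groups identical; single letter assigned")
    return(stats::setNames(rep("A", k), nm))
  }
  hsd <- tukey_hsd_summary(means, sds, ns)
  differs <- hsd$p <= alpha
  ord <- order(means, decreasing = TRUE)
  groups <- list()            # each element: indices sharing one letter
  for (i in ord) {
    joined <- FALSE
    for (g in seq_along(groups)) {
      if (!any(differs[i, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], i)
        joined <- TRUE
      }
    }
    if (!joined) groups[[length(groups) + 1]] <- i
  }
  # absorb letter groups fully contained in another
  keep <- rep(TRUE, length(groups))
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    if (a != b && keep[a] && keep[b] &&
        all(groups[[a]] %in% groups[[b]]))
      keep[a] <- FALSE
  }
  groups <- groups[keep]
  letters_out <- stats::setNames(rep("", k), nm)
  for (g in seq_along(groups))
    for (i in groups[[g]])
      letters_out[i] <- paste0(letters_out[i], LETTERS[g])
  letters_out
}

#' Summarize physiological metrics: letters and percent changes
#'
#' For every metric in a summary table (see [read_physiology()]),
#' computes the Tukey compact letter display from mean/SD/n and the
#' percent change of every ordered treatment pair.
#'
#' @param physiology data frame with columns `metric`, `treatment`,
#'   `mean`, `sd`, `n` (and optionally `letter` with reported
#'   groupings).
#' @param alpha significance level for the letter display.
#' @return List with `letters` (metric, treatment, mean, sd, n, letter,
#'   and `reported_letter` when available) and `changes` (metric,
#'   treatment, reference, percent_change rounded to one decimal).
#' @export
phenotype_summary <- function(physiology, alpha = 0.05) {
  metrics <- unique(physiology$metric)
  letters_rows <- list()
  change_rows <- list()
  for (m in metrics) {
    d <- physiology[physiology$metric == m, , drop = FALSE]
    lt <- tukey_letters(stats::setNames(d$mean, d$treatment), d$sd, d$n,
                        alpha = alpha)
    lrow <- data.frame(metric = m, treatment = d$treatment, mean = d$mean,
                       sd = d$sd, n = d$n, letter = unname(lt),
                       stringsAsFactors = FALSE)
    if ("letter" %in% names(d)) lrow$reported_letter <- d$letter
    letters_rows[[m]] <- lrow
    pairs <- expand.grid(treatment = d$treatment, reference = d$treatment,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$treatment != pairs$reference, , drop = FALSE]
    pairs$metric <- m
    pairs$percent_change <- round(percent_change(
      d$mean[match(pairs$treatment, d$treatment)],
      d$mean[match(pairs$reference, d$treatment)]), 1)
    change_rows[[m]] <- pairs[c("metric", "treatment", "reference",
                                "percent_change")]
  }
  list(letters = do.call(rbind, c(letters_rows, make.row.names = FALSE)),
       changes = do.call(rbind, c(change_rows, make.row.names = FALSE)))
}

#' Compare computed letter displays with reported ones
#'
#' Letter labels are arbitrary up to renaming, so displays are compared
#' by the partition they induce: two treatments share a letter in the
#' computed display iff they share one in the reported display. Rows
#' where the two partitions disagree are returned so that genuine
#' statistical contradictions are reported rather than silently matched.
#'
#' @param letters data frame from [phenotype_summary()]`$letters` with
#'   both `letter` and `reported_letter` columns.
#' @return Data frame of disagreeing metric/treatment-pair rows (zero
#'   rows when the displays agree everywhere).
#' @export
compare_letter_display <- function(letters) {
  if (!"reported_letter" %in% names(letters))
    stop("input error: no reported_letter column to compare against")
  out <- list()
  for (m in unique(letters$metric)) {
    d <- letters[letters$metric == m, , drop = FALSE]
    for (i in seq_len(nrow(d) - 1)) for (j in (i + 1):nrow(d)) {
      share <- function(a, b) any(strsplit(a, "")[[1]] %in%
                                    strsplit(b, "")[[1]])
      comp <- share(d$letter[i], d$letter[j])
      repo <- share(d$reported_letter[i], d$reported_letter[j])
      if (comp != repo)
        out[[length(out) + 1]] <- data.frame(
          metric = m, treatment_a = d$treatment[i],
          treatment_b = d$treatment[j],
          computed_share = comp, reported_share = repo,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(metric = character(), treatment_a = character(),
                      treatment_b = character(), computed_share = logical(),
                      reported_share = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
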