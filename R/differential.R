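#' Classify fold changes as up-, down- or not regulated
#'
#' An entity is called `"up"` when its ratio strictly exceeds `tau` and
#' its p-value is strictly below `alpha`; `"down"` when the ratio is
#' strictly below `1/tau` with p below `alpha`; otherwise `"ns"`.
#' Boundary values (`ratio == tau`, `p == alpha`) are `"ns"`, and an
#' undefined (NA) p-value or ratio yields `"ns"`. The reciprocal
#' down-threshold makes the call symmetric: `classify_regulation(r, p)`
#' is `"up"` exactly when `classify_regulation(1/r, p)` is `"down"`.
#'
#' @param ratio positive fold-change ratio(s).
#' @param p_value p-value(s) in `[0, 1]` (NA allowed).
#' @param tau fold-change threshold, must exceed 1 (1.3 for proteins,
#'   1.2 for phosphosites by convention).
#' @param alpha significance level.
#' @return Character vector of calls in `up/down/ns`.
#' @export
classify_regulation <- function(ratio, p_value, tau, alpha = 0.05) {
  if (tau <= 1) stop("configuration error: tau must exceed 1")
  if (alpha <= 0 || alpha >= 1)
    stop("configuration error: alpha must lie in (0, 1)")
  sig <- !is.na(p_value) & p_value < alpha & !is.na(ratio)
  out <- rep("ns", length(ratio))
  out[sig & ratio > tau] <- "up"
  out[sig & ratio < 1 / tau] <- "down"
  out
}

#' Tally up/down/ns calls per contrast
#'
#' @param calls data frame with columns `contrast` and `regulated`
#'   (or `call`).
#' @return Data frame with one row per contrast: `n_up`, `n_down`,
#'   `n_ns`, `n_quantified`.
#' @export
count_regulated <- function(calls) {
  cc <- if ("regulated" %in% names(calls)) calls$regulated else calls$call
  if (is.null(cc)) stop("input error: no 'regulated' or 'call' column")
  keep <- cc %in% c("up", "down", "ns")
  calls <- calls[keep, , drop = FALSE]
  cc <- cc[keep]
  cts <- if (nrow(calls) > 0) sort(unique(calls$contrast)) else character()
  out <- data.frame(
    contrast = cts,
    n_up = vapply(cts, function(x) sum(cc == "up" & calls$contrast == x),
                  integer(1)),
    n_down = vapply(cts, function(x) sum(cc == "down" & calls$contrast == x),
                    integer(1)),
    n_ns = vapply(cts, function(x) sum(cc == "ns" & calls$contrast == x),
                  integer(1)),
    stringsAsFactors = FALSE)
  out$n_quantified <- out$n_up + out$n_down + out$n_ns
  rownames(out) <- NULL
  out
}
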