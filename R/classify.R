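#' Guideline category rule
#'
#' Copy-number cutoffs for the negative / equivocal / positive calls:
#' counts of at least `positive_low` are positive, counts in
#' `[equivocal_low, positive_low)` are equivocal, the rest negative.
#' Defaults follow the ASCO/CAP convention (4 and 6 copies).
#'
#' @param equivocal_low Lower equivocal cutoff (default 4).
#' @param positive_low Lower positive cutoff (default 6).
#' @return Object of class `category_rule`.
#' @export
category_rule <- function(equivocal_low = 4, positive_low = 6) {
  if (!(0 < equivocal_low && equivocal_low < positive_low)) {
    stop("need 0 < equivocal_low < positive_low", call. = FALSE)
  }
  structure(list(equivocal_low = equivocal_low, positive_low = positive_low,
                 labels = c("negative", "equivocal", "positive")),
            class = "category_rule")
}

#' Category probabilities for a true copy number
#'
#' Probability that a single enumerated nucleus yields a negative,
#' equivocal, or positive count under the binomial observation model.
#' Cutoffs are applied to the integer count: with the default rule,
#' positive is `n >= 6` and equivocal is `n` in `{4, 5}`.
#'
#' @param N True copy number (non-negative integer).
#' @param spec A [section_spec()].
#' @param rule A [category_rule()].
#' @return Named numeric vector `c(P_neg, P_eqv, P_pos)` summing to 1.
#' @examples
#' category_probabilities(8, section_spec(6, 3, 0.8)) # P_pos ~ 0.71
#' @export
category_probabilities <- function(N, spec, rule = category_rule()) {
  stopifnot(inherits(rule, "category_rule"))
  p <- retention_probability(spec)
  pmf <- observed_pmf(N, p)
  pos <- pmf$support >= rule$positive_low
  eqv <- pmf$support >= rule$equivocal_low & pmf$support < rule$positive_low
  P_pos <- sum(pmf$prob[pos])
  P_eqv <- sum(pmf$prob[eqv])
  c(P_neg = 1 - P_eqv - P_pos, P_eqv = P_eqv, P_pos = P_pos)
}

# five-bin shading of a grid cell from its category probabilities
shade_label <- function(probs) {
  if (probs[["P_neg"]] >= 0.9) "blue"
  else if (probs[["P_neg"]] >= 0.5) "green"
  else if (probs[["P_pos"]] >= 0.9) "pink"
  else if (probs[["P_pos"]] >= 0.5) "orange"
  else "yellow"
}

#' Misclassification probability grid
#'
#' Category probabilities for every combination of true copy number and
#' section thickness, with a five-bin shade label per cell: blue
#' (`P_neg >= 0.9`), green (`0.5 <= P_neg < 0.9`), yellow (neither
#' probability reaches 0.5), orange (`0.5 <= P_pos < 0.9`), pink
#' (`P_pos >= 0.9`).
#'
#' @param N_range Integer vector of true copy numbers.
#' @param t_range Numeric vector of section thicknesses, um.
#' @param d Nuclear diameter, um (default 3).
#' @param c Enumeration threshold (default 0.8).
#' @param rule A [category_rule()].
#' @return A data.frame with columns `N`, `t`, `P_neg`, `P_eqv`, `P_pos`,
#'   `shade`.
#' @examples
#' g <- probability_grid(2:12, 2:8)
#' subset(g, N == 8 & t == 6) # orange cell, P_pos ~ 0.71
#' @export
probability_grid <- function(N_range, t_range, d = 3, c = 0.8,
                             rule = category_rule()) {
  if (length(N_range) == 0L || length(t_range) == 0L) {
    stop("N_range and t_range must be non-empty", call. = FALSE)
  }
  cells <- expand.grid(N = N_range, t = t_range, KEEP.OUT.ATTRS = FALSE)
  res <- t(mapply(function(N, t) {
    category_probabilities(N, section_spec(t, d, c), rule)
  }, cells$N, cells$t))
  out <- cbind(cells, as.data.frame(res))
  out$shade <- apply(res, 1L, shade_label)
  out[order(out$N, out$t), , drop = FALSE]
}

#' Classify a slide-level result
#'
#' Deterministic guideline label for an observed slide mean: positive if the
#' target/control ratio is at least 2.0 (when a ratio is supplied) or the
#' mean count is at least `positive_low`; equivocal if the mean count falls
#' in `[equivocal_low, positive_low)`; otherwise negative. Thresholds are
#' inclusive on the left.
#'
#' @param mean_count Observed mean copies per nucleus (>= 0).
#' @param ratio Optional target/control ratio (>= 0).
#' @param rule A [category_rule()].
#' @param ratio_cutoff Ratio at or above which the result is positive
#'   (default 2.0).
#' @return One of "negative", "equivocal", "positive".
#' @examples
#' classify_observed(3.4, ratio = 1.4) # "negative"
#' classify_observed(6.0)              # "positive" (boundary inclusive)
#' @export
classify_observed <- function(mean_count, ratio = NULL, rule = category_rule(),
                              ratio_cutoff = 2.0) {
  stopifnot(inherits(rule, "category_rule"))
  if (mean_count < 0) stop("mean_count must be >= 0", call. = FALSE)
  if (!is.null(ratio) && ratio < 0) stop("ratio must be >= 0", call. = FALSE)
  if ((!is.null(ratio) && ratio >= ratio_cutoff) ||
      mean_count >= rule$positive_low) {
    "positive"
  } else if (mean_count >= rule$equivocal_low) {
    "equivocal"
  } else {
    "negative"
  }
}
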