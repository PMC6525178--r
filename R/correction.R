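#' Thickness correction factor
#'
#' Ratio of signal-retention probabilities between two section thicknesses,
#' `p(t_to) / p(t_from)`. Multiplying an observed mean copy number from a
#' `t_from`-um section by this factor gives its expected value on a
#' `t_to`-um section. The factor is 1 when the thicknesses agree and
#' reciprocal under swapping.
#'
#' @param t_from Thickness the observation was made at, um.
#' @param t_to Thickness to correct to, um.
#' @param d Nuclear diameter, um (default 3).
#' @param c Enumeration threshold (default 0.8).
#' @return Dimensionless correction factor.
#' @examples
#' correction_factor(2, 4) # ~1.3248
#' @export
correction_factor <- function(t_from, t_to, d = 3, c = 0.8) {
  retention_probability(section_spec(t_to, d, c)) /
    retention_probability(section_spec(t_from, d, c))
}

#' Correct an observed copy number to another thickness
#'
#' @param n_obs Observed mean copies per nucleus (>= 0).
#' @inheritParams correction_factor
#' @return Corrected mean copies; linear in `n_obs`.
#' @examples
#' correct_observed(6.0, 2, 6) # ~8.90
#' @export
correct_observed <- function(n_obs, t_from, t_to, d = 3, c = 0.8) {
  if (any(n_obs < 0)) stop("n_obs must be >= 0", call. = FALSE)
  n_obs * correction_factor(t_from, t_to, d, c)
}

#' Back-calculate the true copy number
#'
#' Inverts the thinning model's mean: `N_hat = n_obs / p(spec)`. Correcting
#' an observation from thickness a to b is the same as back-calculating at a
#' and projecting forward at b.
#'
#' @param n_obs Observed mean copies per nucleus (>= 0).
#' @param spec A [section_spec()] describing how the observation was made.
#' @return Estimated true copies `N_hat`.
#' @export
estimate_true_copy_number <- function(n_obs, spec) {
  if (any(n_obs < 0)) stop("n_obs must be >= 0", call. = FALSE)
  n_obs / retention_probability(spec)
}

#' Interval estimate for a corrected copy number
#'
#' Central 95% interval for the m-nucleus mean count at the target
#' thickness, given the true copy number back-calculated from the thin
#' section: normal approximation with mean `N_hat * p(t_to)` and variance
#' `N_hat * p(t_to) * (1 - p(t_to)) / m`, clipped at 0. The width scales as
#' `1/sqrt(m)`.
#'
#' @inheritParams correct_observed
#' @param m Number of nuclei enumerated per slide (default 20).
#' @param level Coverage (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
correction_interval <- function(n_obs, t_from, t_to, d = 3, c = 0.8, m = 20,
                                level = 0.95) {
  stopifnot(m >= 1, level > 0, level < 1)
  if (n_obs < 0) stop("n_obs must be >= 0", call. = FALSE)
  p_to <- retention_probability(section_spec(t_to, d, c))
  N_hat <- estimate_true_copy_number(n_obs, section_spec(t_from, d, c))
  mu <- N_hat * p_to
  sdev <- sqrt(N_hat * p_to * (1 - p_to) / m)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = max(mu - z * sdev, 0), high = mu + z * sdev)
}

#' Thin-to-thick correction table
#'
#' Full correction table: for each source thickness, each observed value and
#' each target thickness, the corrected point value and its interval.
#' Values are exact; rounding to 2 decimals happens only in
#' [format_correction_table()].
#'
#' @param t_from_list Source thicknesses, um (default `c(2, 3)`).
#' @param t_to_list Target thicknesses, um (default `c(4, 5, 6)`).
#' @param observed_grid Observed values (default `seq(2, 6, by = 0.5)`).
#' @param d Nuclear diameter, um. @param c Enumeration threshold.
#' @param m Nuclei per slide for the intervals (default 20).
#' @return A data.frame with columns `observed`, `t_from_um`, `t_to_um`,
#'   `corrected`, `ci_low`, `ci_high`, `d_um`, `c`, `m`.
#' @examples
#' tab <- correction_table()
#' subset(tab, observed == 2 & t_from_um == 2 & t_to_um == 4)
#' @export
correction_table <- function(t_from_list = c(2, 3), t_to_list = c(4, 5, 6),
                             observed_grid = seq(2, 6, by = 0.5),
                             d = 3, c = 0.8, m = 20) {
  if (length(t_from_list) == 0L || length(t_to_list) == 0L ||
      length(observed_grid) == 0L) {
    stop("grids must be non-empty", call. = FALSE)
  }
  cells <- expand.grid(observed = observed_grid, t_to_um = t_to_list,
                       t_from_um = t_from_list, KEEP.OUT.ATTRS = FALSE)
  corrected <- mapply(correct_observed, cells$observed, cells$t_from_um,
                      cells$t_to_um, MoreArgs = list(d = d, c = c))
  ci <- t(mapply(correction_interval, cells$observed, cells$t_from_um,
                 cells$t_to_um, MoreArgs = list(d = d, c = c, m = m)))
  data.frame(observed = cells$observed, t_from_um = cells$t_from_um,
             t_to_um = cells$t_to_um, corrected = corrected,
             ci_low = ci[, "low"], ci_high = ci[, "high"],
             d_um = d, c = c, m = m)
}

#' Format a correction table for display
#'
#' Renders one source-thickness block in the familiar published layout:
#' observed values down the rows, target thicknesses across the columns,
#' "point (low-high)" per cell, rounded to 2 decimals (round-half-to-even,
#' R's default).
#'
#' @param tab Output of [correction_table()].
#' @return Character matrix (one block per source thickness, stacked), with
#'   a header row per block; also printed via `cat` when `print = TRUE`.
#' @param print Print the facsimile to the console (default FALSE).
#' @export
format_correction_table <- function(tab, print = FALSE) {
  fmt <- function(x) formatC(round(x, 2), format = "f", digits = 2)
  blocks <- lapply(split(tab, tab$t_from_um), function(b) {
    t_tos <- sort(unique(b$t_to_um))
    obs <- sort(unique(b$observed))
    body <- sapply(t_tos, function(tt) {
      bb <- b[b$t_to_um == tt, ]
      bb <- bb[order(bb$observed), ]
      sprintf("%s (%s-%s)", fmt(bb$corrected), fmt(bb$ci_low), fmt(bb$ci_high))
    })
    body <- cbind(fmt(obs), body)
    header <- c(sprintf("t = %g um: observed", b$t_from_um[1L]),
                sprintf("%g um", t_tos))
    rbind(header, body)
  })
  out <- do.call(rbind, blocks)
  dimnames(out) <- NULL
  if (print) {
    widths <- apply(nchar(out), 2L, max)
    for (i in seq_len(nrow(out))) {
      padded <- mapply(formatC, out[i, ], width = widths,
                       MoreArgs = list(flag = "-"))
      cat(paste(padded, collapse = "  "), "\n")
    }
  }
  invisible(out)
}
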