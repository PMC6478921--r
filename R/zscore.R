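# Directional activation Z-score: concordance between a reference
# contrast's expected gene directions and an observed differential
# expression contrast.

#' Activation Z-score against a directional reference
#'
#' Matches the reference genes to the observed contrast's significant genes
#' (q below `q_max`, default 0.2) and scores directional concordance:
#' \deqn{Z = \sum_i w_i x_i / \sqrt{\sum_i w_i^2}}
#' where \eqn{x_i = +1} when the observed fold-change sign agrees with the
#' reference direction and \eqn{-1} otherwise, with edge weights
#' \eqn{w_i = 1} by default. Reference genes absent from the observed
#' significant set are dropped, not counted as discordant (set
#' `include_nonsignificant = TRUE` to match against all observed genes).
#'
#' @param ref Data frame with columns gene, direction (+1/-1) and optionally
#'   weight; see [read_directional_reference()].
#' @param observed An `ifn_de` object or data frame with columns gene, lfc, q.
#' @param q_max Observed-significance cutoff (default 0.2).
#' @param include_nonsignificant Match against all observed genes instead of
#'   only the significant ones.
#' @return An `ifn_zscore` one-row tibble: reference, z, n_matched,
#'   n_concordant, n_discordant, significant_95, significant_99.
#' @export
activation_z <- function(ref, observed, q_max = 0.2,
                         include_nonsignificant = FALSE) {
  ref <- validate_directional_reference(ref, attr(ref, "reference") %||%
                                          "reference")
  obs <- as_tibble(observed)[, c("gene", "lfc", "q")]
  if (!include_nonsignificant) obs <- obs[obs$q < q_max, ]
  obs <- obs[obs$lfc != 0, ]
  m <- dplyr::inner_join(ref, obs, by = "gene")
  if (nrow(m) == 0L) {
    abort("no reference gene matches the observed significant genes; Z undefined",
          class = "ifnsig_undefined_score")
  }
  x <- ifelse(sign(m$lfc) == m$direction, 1, -1)
  z <- sum(m$weight * x) / sqrt(sum(m$weight^2))
  out <- tibble(reference = attr(ref, "reference"),
                z = z,
                n_matched = nrow(m),
                n_concordant = sum(x > 0),
                n_discordant = sum(x < 0),
                significant_95 = z_significance(z, 0.95),
                significant_99 = z_significance(z, 0.99))
  structure(out, class = c("ifn_zscore", class(out)))
}

#' Significance flag for an activation Z-score
#'
#' Two-sided thresholds: |Z| > 1.96 at the 95% level and |Z| > 2.54 at the
#' 99% level. These constants are the thresholds used in the field's
#' activation-score convention; set `exact = TRUE` to use the exact normal
#' quantiles instead (2.576 at 99%).
#'
#' @param z Z-score(s).
#' @param level 0.95 or 0.99.
#' @param exact Use `qnorm(1 - (1 - level)/2)` instead of the stored
#'   constants.
#' @return Logical vector.
#' @export
z_significance <- function(z, level = 0.95, exact = FALSE) {
  if (!level %in% c(0.95, 0.99)) stop_validation("level must be 0.95 or 0.99")
  threshold <- if (exact) {
    qnorm(1 - (1 - level) / 2)
  } else if (level == 0.95) 1.96 else 2.54
  abs(z) > threshold
}
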