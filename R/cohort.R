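# Cohort-level inference: IGS positivity calls against control-derived
# thresholds, activity stratification, Welch/Hedges effect sizes, signature
# ranking, time-course gain/loss analysis, score regression, module
# eigengenes and ANOVA with Tukey's multiple comparisons.

#' Classify patients as signature-positive
#'
#' A patient is positive for a signature when their enrichment score is
#' strictly greater than the healthy-control mean plus `sd_multiplier`
#' control standard deviations (sample SD, n-1 denominator), computed per
#' signature from the control samples only.
#'
#' @param scores An `ifn_scores` tibble (or data frame with sample,
#'   signature, score).
#' @param meta Metadata tibble with sample and group columns.
#' @param signatures Optional character vector restricting the signatures
#'   classified.
#' @param sd_multiplier Number of control SDs above the control mean
#'   (default 2).
#' @return An `ifn_positivity` tibble: one row per SLE sample per signature
#'   with score, threshold and call (`"positive"`/`"negative"`).
#' @export
classify_positive <- function(scores, meta, signatures = NULL,
                              sd_multiplier = 2) {
  scores <- as_tibble(scores)
  meta <- validate_metadata(meta)
  if (!is.null(signatures)) {
    missing <- setdiff(signatures, unique(scores$signature))
    if (length(missing) > 0L) {
      stop_validation(paste0("signature(s) absent from scores: ",
                             paste(missing, collapse = ", ")))
    }
    scores <- scores[scores$signature %in% signatures, ]
  }
  joined <- dplyr::inner_join(scores, meta[, c("sample", "group")],
                              by = "sample")
  ctrl <- joined[joined$group == "control", ]
  n_ctrl <- length(unique(ctrl$sample))
  if (n_ctrl < 2L) {
    stop_degenerate("positivity threshold needs at least 2 control samples")
  }
  thresholds <- ctrl %>%
    dplyr::group_by(.data$signature) %>%
    dplyr::summarise(ctrl_mean = mean(.data$score),
                     ctrl_sd = sd(.data$score), .groups = "drop") %>%
    dplyr::mutate(threshold = .data$ctrl_mean + sd_multiplier * .data$ctrl_sd)
  if (any(thresholds$ctrl_sd == 0)) {
    warn("control scores are constant for at least one signature (zero SD)")
  }
  out <- joined[joined$group == "SLE", ] %>%
    dplyr::inner_join(thresholds, by = "signature") %>%
    dplyr::mutate(call = ifelse(.data$score > .data$threshold,
                                "positive", "negative")) %>%
    dplyr::select("sample", "signature", "score", "threshold", "call")
  structure(out, class = c("ifn_positivity", class(out)),
            sd_multiplier = sd_multiplier, n_controls = n_ctrl)
}

#' Fraction of positive patients, optionally by stratum
#'
#' @param calls An `ifn_positivity` tibble.
#' @param strata Optional data frame with sample plus stratum columns (e.g.
#'   the activity column from [split_by_sledai()]).
#' @return A tibble with n, n_positive and fraction_positive per signature
#'   (and stratum).
#' @export
positivity_rate <- function(calls, strata = NULL) {
  calls <- as_tibble(calls)
  if (!is.null(strata)) {
    calls <- dplyr::inner_join(calls, as_tibble(strata), by = "sample")
  }
  grp <- c("signature", setdiff(names(calls),
                                c("sample", "signature", "score",
                                  "threshold", "call")))
  calls %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::summarise(n = dplyr::n(),
                     n_positive = sum(.data$call == "positive"),
                     fraction_positive = .data$n_positive / .data$n,
                     .groups = "drop")
}

#' Split SLE patients by disease activity
#'
#' Active: SLEDAI of at least 6; inactive: below 6. Controls are excluded;
#' SLE samples without a SLEDAI value are listed in a warning and excluded.
#'
#' @param meta Metadata tibble with sample, group and sledai columns.
#' @param threshold Activity cutoff (default 6).
#' @return The SLE rows of `meta` with an added `activity` column
#'   (`"active"`/`"inactive"`).
#' @export
split_by_sledai <- function(meta, threshold = 6) {
  meta <- validate_metadata(meta)
  if (!"sledai" %in% names(meta)) {
    stop_validation("metadata has no sledai column")
  }
  sle <- meta[meta$group == "SLE", ]
  miss <- sle$sample[is.na(sle$sledai)]
  if (length(miss) > 0L) {
    warn(paste0("excluding ", length(miss), " SLE sample(s) without SLEDAI: ",
                paste(head(miss, 5L), collapse = ", ")))
    sle <- sle[!is.na(sle$sledai), ]
  }
  dplyr::mutate(sle, activity = ifelse(.data$sledai >= threshold,
                                       "active", "inactive"))
}

#' Welch's unequal-variance t-test
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @return A one-row tibble with t, df (Welch-Satterthwaite) and two-sided p.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_degenerate("each group needs at least 2 values")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    # t.test errors on constant data; equal constants carry no evidence
    if (mean(a) == mean(b)) return(tibble(t = 0, df = length(a) + length(b) - 2,
                                          p = 1))
    stop_degenerate("both groups are constant with different means")
  }
  fit <- stats::t.test(a, b, var.equal = FALSE)
  tibble(t = unname(fit$statistic), df = unname(fit$parameter),
         p = fit$p.value)
}

#' Hedges' g standardized mean difference
#'
#' \eqn{g = (\bar a - \bar b) / s_p} with the pooled standard deviation
#' \eqn{s_p^2 = ((n_1-1)s_a^2 + (n_2-1)s_b^2)/(n_1+n_2-2)}. The small-sample
#' correction \eqn{J = 1 - 3/(4(n_1+n_2)-9)} is applied when
#' `correction = TRUE` (default off, matching the plain pooled-SD
#' calculator convention).
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @param correction Apply the small-sample correction factor.
#' @return The effect size g (positive when `mean(a) > mean(b)`).
#' @export
hedges_g <- function(a, b, correction = FALSE) {
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop_degenerate("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(0)
    abort("zero pooled SD with unequal means; effect size undefined",
          class = "ifnsig_undefined_effect")
  }
  g <- (mean(a) - mean(b)) / sqrt(sp2)
  if (isTRUE(correction)) g <- g * (1 - 3 / (4 * (n1 + n2) - 9))
  g
}

#' Rank signatures by effect size against controls
#'
#' Per signature, Welch's t and Hedges' g of SLE patient scores versus
#' control scores; signatures whose Welch p is at least `alpha` are flagged
#' `"N.S."`. The table is ordered by g descending, the convention used to
#' name the dominant IFN subtype in a tissue.
#'
#' @param scores An `ifn_scores` tibble.
#' @param meta Metadata with sample and group.
#' @param alpha Significance level for the N.S. flag (default 0.05).
#' @param correction Passed to [hedges_g()].
#' @return An `ifn_effects` tibble: signature, t, df, p, g, n_sle,
#'   n_control, flag.
#' @export
rank_signatures_by_effect <- function(scores, meta, alpha = 0.05,
                                      correction = FALSE) {
  scores <- as_tibble(scores)
  meta <- validate_metadata(meta)
  joined <- dplyr::inner_join(scores, meta[, c("sample", "group")],
                              by = "sample")
  out <- joined %>%
    dplyr::group_by(.data$signature) %>%
    dplyr::group_modify(function(df, key) {
      a <- df$score[df$group == "SLE"]
      b <- df$score[df$group == "control"]
      wt <- welch_t(a, b)
      dplyr::mutate(wt, g = hedges_g(a, b, correction = correction),
                    n_sle = length(a), n_control = length(b))
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(flag = ifelse(.data$p < alpha, "significant", "N.S.")) %>%
    dplyr::arrange(dplyr::desc(.data$g))
  structure(out, class = c("ifn_effects", class(out)), alpha = alpha)
}

#' Time-course gain/loss analysis of signature scores
#'
#' Per patient and signature, the across-time standard deviation of the
#' enrichment score is compared to a significance threshold: either the
#' largest control-score SD across signatures (`"max_control_sd"`, the
#' default rule) or a fixed value (default 0.2). Patients whose trajectory
#' SD exceeds the threshold are categorized by their first and last
#' positivity calls: negative-to-positive is `gain`, positive-to-negative is
#' `loss`, anything else `fluctuating`; sub-threshold trajectories are
#' `stable`. Positivity calls use the control mean + 2 SD rule per
#' signature and timepoint-pooled controls.
#'
#' @param scores An `ifn_scores` tibble covering patients and controls.
#' @param meta Metadata with sample, group, patient and timepoint columns
#'   (controls need no patient/timepoint).
#' @param threshold_rule `"max_control_sd"`, `"per_signature_control_sd"`
#'   or `"fixed"`.
#' @param fixed_threshold Threshold used when `threshold_rule = "fixed"`
#'   (default 0.2).
#' @param sd_multiplier Positivity multiplier passed to
#'   [classify_positive()].
#' @return An `ifn_trajectory` tibble: one row per patient per signature
#'   with n_timepoints, traj_sd, threshold, significant, first_call,
#'   last_call and category.
#' @export
trajectory_analysis <- function(scores, meta,
                                threshold_rule = c("max_control_sd",
                                                   "per_signature_control_sd",
                                                   "fixed"),
                                fixed_threshold = 0.2,
                                sd_multiplier = 2) {
  threshold_rule <- match.arg(threshold_rule)
  scores <- as_tibble(scores)
  meta <- validate_metadata(meta)
  if (!all(c("patient", "timepoint") %in% names(meta))) {
    stop_validation("time-course metadata needs patient and timepoint columns")
  }
  joined <- dplyr::inner_join(scores, meta, by = "sample")
  ctrl <- joined[joined$group == "control", ]
  if (nrow(ctrl) < 2L) stop_degenerate("control scores are required")

  ctrl_sd <- ctrl %>%
    dplyr::group_by(.data$signature) %>%
    dplyr::summarise(ctrl_sd = sd(.data$score), .groups = "drop")
  thresholds <- switch(threshold_rule,
    fixed = dplyr::mutate(ctrl_sd, threshold = fixed_threshold),
    per_signature_control_sd = dplyr::mutate(ctrl_sd,
                                             threshold = .data$ctrl_sd),
    max_control_sd = dplyr::mutate(ctrl_sd,
                                   threshold = max(.data$ctrl_sd)))

  calls <- classify_positive(scores, meta, sd_multiplier = sd_multiplier)
  sle <- joined[joined$group == "SLE", ] %>%
    dplyr::inner_join(as_tibble(calls)[, c("sample", "signature", "call")],
                      by = c("sample", "signature"))

  timepoints <- sort(unique(sle$timepoint))
  if (length(timepoints) < 2L) {
    stop_degenerate("time-course analysis needs at least 2 timepoints")
  }
  complete <- sle %>%
    dplyr::group_by(.data$patient, .data$signature) %>%
    dplyr::filter(dplyr::n_distinct(.data$timepoint) == length(timepoints)) %>%
    dplyr::ungroup()
  dropped <- setdiff(unique(sle$patient), unique(complete$patient))
  if (length(dropped) > 0L) {
    warn(paste0("excluding patient(s) missing timepoints: ",
                paste(head(dropped, 5L), collapse = ", ")))
  }

  out <- complete %>%
    dplyr::arrange(.data$timepoint) %>%
    dplyr::group_by(.data$patient, .data$signature) %>%
    dplyr::summarise(n_timepoints = dplyr::n(),
                     traj_sd = sd(.data$score),
                     first_call = dplyr::first(.data$call),
                     last_call = dplyr::last(.data$call),
                     .groups = "drop") %>%
    dplyr::inner_join(thresholds[, c("signature", "threshold")],
                      by = "signature") %>%
    dplyr::mutate(significant = .data$traj_sd > .data$threshold,
                  category = dplyr::case_when(
                    !significant ~ "stable",
                    first_call == "negative" & last_call == "positive" ~ "gain",
                    first_call == "positive" & last_call == "negative" ~ "loss",
                    TRUE ~ "fluctuating"))
  structure(out, class = c("ifn_trajectory", class(out)),
            threshold_rule = threshold_rule)
}

#' Linear regression between two per-patient quantities
#'
#' Ordinary least squares of `y` on `x` (columns of `data`), reporting the
#' slope, intercept, coefficient of determination and two-sided p-value for
#' a non-zero slope — the workhorse for relating the IGS to cell-type
#' scores or to SLEDAI.
#'
#' @param data A data frame.
#' @param x,y Column names (unquoted) of predictor and response.
#' @return An `ifn_regression` one-row tibble: slope, intercept, r_squared,
#'   p, n; the underlying `lm` fit is attached as attribute `fit`.
#' @export
regress_scores <- function(data, x, y) {
  x <- enquo(x)
  y <- enquo(y)
  df <- tibble(x = dplyr::pull(data, !!x), y = dplyr::pull(data, !!y))
  df <- df[complete.cases(df), ]
  if (nrow(df) < 3L) stop_degenerate("regression needs at least 3 points")
  if (sd(df$x) == 0) stop_degenerate("predictor is constant")
  fit <- lm(y ~ x, data = df)
  sm <- summary(fit)
  out <- tibble(slope = unname(coef(fit)[2L]),
                intercept = unname(coef(fit)[1L]),
                r_squared = sm$r.squared,
                p = sm$coefficients[2L, 4L],
                n = nrow(df))
  structure(out, class = c("ifn_regression", class(out)),
            fit = fit, x_name = as_name(x), y_name = as_name(y))
}

#' @export
tidy.ifn_regression <- function(x, ...) {
  fit <- attr(x, "fit")
  sm <- summary(fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1L], std_error = sm[, 2L],
         statistic = sm[, 3L], p_value = sm[, 4L])
}

#' @export
glance.ifn_regression <- function(x, ...) as_tibble(unclass(x))

#' Scatter plot with the fitted regression line
#'
#' @param object An `ifn_regression` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ifn_regression <- function(object, ...) {
  fit <- attr(object, "fit")
  df <- fit$model
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(x = attr(object, "x_name"), y = attr(object, "y_name"),
                  subtitle = sprintf("r² = %.2f, p = %.3g",
                                     object$r_squared, object$p)) +
    ggplot2::theme_minimal()
}

#' Module eigengene and trait correlation
#'
#' The eigengene is the first principal component of the per-gene
#' standardized module submatrix, sign-oriented so its mean correlation with
#' the module genes is positive. When metadata is supplied, Pearson
#' correlations of the eigengene with the binary disease indicator
#' (SLE vs control) and with SLEDAI are reported.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param module_genes Character vector of module genes (at least 2 present
#'   unless `allow_single = TRUE`).
#' @param meta Optional metadata with sample, group and (optionally) sledai.
#' @param allow_single Permit a single-gene module, whose eigengene is the
#'   standardized gene profile.
#' @return An `ifn_eigengene` tibble: sample, eigengene; trait correlations
#'   (tibble attribute `trait_cor`), variance explained, genes used.
#' @export
module_eigengene <- function(expr, module_genes, meta = NULL,
                             allow_single = FALSE) {
  assert_expression(expr)
  if (ncol(expr) < 3L) stop_degenerate("eigengene needs at least 3 samples")
  present <- intersect(module_genes, rownames(expr))
  min_genes <- if (allow_single) 1L else 2L
  if (length(present) < min_genes) {
    stop_degenerate(paste0("only ", length(present),
                           " module gene(s) present in the matrix"))
  }
  sub <- expr[present, , drop = FALSE]
  keep <- apply(sub, 1L, sd) > 0
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) < min_genes) {
    stop_degenerate("too few non-constant module genes")
  }
  z <- t(scale(t(sub)))
  sv <- svd(z)
  eig <- sv$v[, 1L]
  # orient so the eigengene tracks the module genes positively
  if (mean(cor(eig, t(z))) < 0) eig <- -eig
  var_explained <- sv$d[1L]^2 / sum(sv$d^2)
  out <- tibble(sample = colnames(expr), eigengene = eig)

  trait_cor <- NULL
  if (!is.null(meta)) {
    meta <- validate_metadata(meta, expr)
    m <- dplyr::inner_join(out, meta, by = "sample")
    rows <- list()
    disease <- as.numeric(m$group == "SLE")
    if (sd(disease) > 0) {
      ct <- cor.test(m$eigengene, disease)
      rows$disease <- tibble(trait = "disease", r = unname(ct$estimate),
                             p = ct$p.value, n = nrow(m))
    }
    if ("sledai" %in% names(m) && sum(!is.na(m$sledai)) >= 3L &&
        sd(m$sledai, na.rm = TRUE) > 0) {
      ok <- !is.na(m$sledai)
      ct <- cor.test(m$eigengene[ok], m$sledai[ok])
      rows$sledai <- tibble(trait = "sledai", r = unname(ct$estimate),
                            p = ct$p.value, n = sum(ok))
    }
    trait_cor <- purrr::list_rbind(rows)
  }
  structure(out, class = c("ifn_eigengene", class(out)),
            trait_cor = trait_cor, var_explained = var_explained,
            genes = rownames(sub))
}

#' @export
glance.ifn_eigengene <- function(x, ...) {
  tc <- attr(x, "trait_cor")
  base <- tibble(n_genes = length(attr(x, "genes")),
                 var_explained = attr(x, "var_explained"))
  if (is.null(tc) || nrow(tc) == 0L) return(base)
  wide <- tidyr::pivot_wider(tc, names_from = "trait",
                             values_from = c("r", "p", "n"))
  dplyr::bind_cols(base, wide)
}

#' One-way ANOVA with Tukey's multiple comparisons
#'
#' Compares mean scores across three or more groups; pairwise differences
#' are adjusted with Tukey's honestly-significant-difference procedure
#' (Tukey-Kramer for unequal group sizes).
#'
#' @param data A data frame.
#' @param score,group Column names (unquoted) of the response and the
#'   grouping factor.
#' @return An `ifn_anova` object: list with `f`, `p`, `df_between`,
#'   `df_within` and a `pairwise` tibble (comparison, diff, lwr, upr,
#'   p_adj).
#' @export
anova_tukey <- function(data, score, group) {
  score <- enquo(score)
  group <- enquo(group)
  df <- tibble(score = dplyr::pull(data, !!score),
               group = factor(dplyr::pull(data, !!group)))
  df <- df[complete.cases(df), ]
  lev <- levels(droplevels(df$group))
  if (length(lev) < 3L) {
    stop_validation("fewer than 3 groups: use welch_t() for two-group comparisons")
  }
  sizes <- table(droplevels(df$group))
  if (any(sizes < 2L)) stop_degenerate("every group needs at least 2 samples")
  fit <- aov(score ~ group, data = df)
  an <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$group
  pairwise <- tibble(comparison = rownames(tk), diff = unname(tk[, "diff"]),
                     lwr = unname(tk[, "lwr"]), upr = unname(tk[, "upr"]),
                     p_adj = unname(tk[, "p adj"]))
  structure(list(f = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
                 df_between = an[["Df"]][1L], df_within = an[["Df"]][2L],
                 pairwise = pairwise, fit = fit),
            class = "ifn_anova")
}

#' @export
print.ifn_anova <- function(x, ...) {
  cat("<ifn_anova> F(", x$df_between, ", ", x$df_within, ") = ",
      format(x$f, digits = 4), ", p = ", format(x$p, digits = 3),
      "\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.ifn_anova <- function(x, ...) x$pairwise

#' @export
glance.ifn_anova <- function(x, ...) {
  tibble(f = x$f, p = x$p, df_between = x$df_between,
         df_within = x$df_within)
}

#' Bar plot of positivity rates
#'
#' @param object An `ifn_positivity` tibble.
#' @param strata Optional strata table passed to [positivity_rate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ifn_positivity <- function(object, strata = NULL, ...) {
  rates <- positivity_rate(object, strata)
  extra <- setdiff(names(rates), c("signature", "n", "n_positive",
                                   "fraction_positive"))
  p <- ggplot2::ggplot(rates,
                       ggplot2::aes(.data$signature,
                                    .data$fraction_positive))
  if (length(extra) > 0L) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data[[extra[[1L]]]]),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col(fill = "steelblue")
  }
  p + ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction IGS-positive") +
    ggplot2::theme_minimal()
}

#' Trajectory plot of per-patient scores over time
#'
#' @param object An `ifn_trajectory` tibble.
#' @param scores,meta The score and metadata tables used to build it.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ifn_trajectory <- function(object, scores, meta, ...) {
  joined <- dplyr::inner_join(as_tibble(scores), validate_metadata(meta),
                              by = "sample") %>%
    dplyr::filter(.data$group == "SLE") %>%
    dplyr::inner_join(as_tibble(object)[, c("patient", "signature",
                                            "category")],
                      by = c("patient", "signature"))
  ggplot2::ggplot(joined, ggplot2::aes(.data$timepoint, .data$score,
                                       group = .data$patient,
                                       colour = .data$category)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$signature)) +
    ggplot2::labs(x = "timepoint", y = "enrichment score") +
    ggplot2::theme_minimal()
}

#' @importFrom stats coef
NULL
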