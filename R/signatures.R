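# Construction of IFN reference signatures: moderated differential
# expression, threshold filtering, Venn partitioning, annotation filtering
# and seeded random control signatures.

#' Moderated two-group differential expression
#'
#' Per-gene two-group comparison with empirical-Bayes variance moderation.
#' Ordinary pooled residual variances \eqn{s_g^2} (on \eqn{d = n_1 + n_2 - 2}
#' degrees of freedom) are shrunk towards a prior variance \eqn{s_0^2}
#' estimated, together with its prior degrees of freedom \eqn{d_0}, by
#' matching the moments of the scaled F distribution that the \eqn{s_g^2}
#' follow under the hierarchical model. The posterior variance is
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d s_g^2) / (d_0 + d),}
#' the moderated t is the mean difference over
#' \eqn{\tilde{s}_g \sqrt{1/n_1 + 1/n_2}}, with p-values on \eqn{d_0 + d}
#' degrees of freedom and Benjamini-Hochberg adjusted q-values.
#'
#' @param expr Numeric genes-by-samples log2 expression matrix.
#' @param group1,group2 Character vectors of sample identifiers (each of
#'   length at least 2, disjoint). Log fold change is group1 minus group2.
#' @param d0 Optional override of the prior degrees of freedom: `0` gives the
#'   ordinary pooled t, `Inf` full shrinkage to the prior variance. `NULL`
#'   (default) estimates it from the data.
#' @return An object of class `ifn_de`: a tibble with columns gene, lfc, t,
#'   p, q, s2 and df, carrying the fitted prior (`d0`, `s0_sq`) and design as
#'   attributes. Use [tidy()] / [glance()] to extract them.
#' @export
moderated_de <- function(expr, group1, group2, d0 = NULL) {
  assert_expression(expr)
  group1 <- as.character(group1)
  group2 <- as.character(group2)
  if (length(intersect(group1, group2)) > 0L) {
    stop_validation("groups must be disjoint")
  }
  missing <- setdiff(c(group1, group2), colnames(expr))
  if (length(missing) > 0L) {
    stop_validation(paste0("sample(s) absent from matrix: ",
                           paste(head(missing, 5L), collapse = ", ")))
  }
  n1 <- length(group1)
  n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop_degenerate("each group needs at least 2 samples")

  x1 <- expr[, group1, drop = FALSE]
  x2 <- expr[, group2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, var)
  v2 <- apply(x2, 1L, var)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
  if (all(s2 <= 0)) {
    abort("all genes have zero pooled variance; prior cannot be estimated",
          class = "ifnsig_estimation")
  }

  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, d)
  } else {
    if (d0 < 0) stop_validation("d0 must be non-negative (may be Inf)")
    s0 <- fit_variance_prior(s2, d)$s0_sq
    prior <- list(d0 = d0, s0_sq = s0)
  }

  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s0_sq, length(s2))
  } else {
    (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
  }
  lfc <- m1 - m2
  tstat <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- prior$d0 + d
  p <- 2 * pt(-abs(tstat), df = df_total)
  q <- bh_fdr(p)

  out <- tibble(gene = rownames(expr), lfc = unname(lfc), t = unname(tstat),
                p = unname(p), q = unname(q), s2 = unname(s2),
                s2_post = unname(s2_post))
  structure(out,
            class = c("ifn_de", class(out)),
            d0 = prior$d0, s0_sq = prior$s0_sq, df_residual = d,
            df_total = df_total, n1 = n1, n2 = n2)
}

# Moment estimation of the inverse-chi-square variance prior from the
# log-variance distribution: E[log s^2] and Var[log s^2] determine
# (d0, s0^2) through digamma/trigamma identities of the scaled F.
fit_variance_prior <- function(s2, d) {
  s2 <- s2[s2 > 0]
  if (length(s2) < 2L) {
    abort("prior estimation needs at least 2 genes with positive variance",
          class = "ifnsig_estimation")
  }
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  e_mean <- mean(e)
  e_var <- var(e) - trigamma(d / 2)
  if (is.finite(e_var) && e_var > 0) {
    d0 <- 2 * trigamma_inverse(e_var)
    s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(e_mean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton iteration for y with trigamma(y) = x
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' @export
print.ifn_de <- function(x, ...) {
  cat("<ifn_de> ", nrow(x), " genes, ", attr(x, "n1"), " vs ", attr(x, "n2"),
      " samples; prior d0 = ", format(attr(x, "d0"), digits = 4),
      ", s0^2 = ", format(attr(x, "s0_sq"), digits = 4), "\n", sep = "")
  NextMethod()
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values, capped at 1 and monotone in sorted p order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Derive a signature from a differential-expression table
#'
#' Genes pass with `q < q_max` and linear fold change strictly above
#' `fc_min` in the requested direction (the down set uses `2^(-lfc)`).
#'
#' @param de An `ifn_de` object or data frame with columns gene, lfc, q.
#' @param q_max FDR cutoff in (0, 1\]; strict `<`.
#' @param fc_min Linear fold-change cutoff, at least 1; strict `>`.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @param name Signature name.
#' @param source Provenance label.
#' @return An [ifn_signature()]; with `direction = "up"` and no passing gene
#'   a warning is emitted and an `ifn_signature` cannot be formed, so `NULL`
#'   is returned.
#' @export
derive_signature <- function(de, q_max = 0.01, fc_min = 2,
                             direction = c("up", "down", "both"),
                             name = "signature", source = "derived") {
  direction <- match.arg(direction)
  if (nrow(de) == 0L) stop_validation("empty DE table")
  if (q_max <= 0 || q_max > 1) stop_validation("q_max must lie in (0, 1]")
  if (fc_min < 1) stop_validation("fc_min must be at least 1 (linear scale)")
  sig_q <- de$q < q_max
  up <- de$gene[sig_q & 2^de$lfc > fc_min]
  down <- de$gene[sig_q & 2^(-de$lfc) > fc_min]
  if (direction == "up") down <- character()
  if (direction == "down") {
    up <- down
    down <- character()
  }
  if (length(up) == 0L) {
    warn(paste0("signature '", name, "' is empty at q<", q_max,
                ", FC>", fc_min))
    return(NULL)
  }
  ifn_signature(name, up = up, down = down, source = source)
}

#' Venn partition of IFN signatures
#'
#' Partitions the union of the input up-gene sets into disjoint membership
#' cells and reports the type I core (intersection of the three type I
#' sets) and the type I/II shared subset (core intersected with the type II
#' set). The core count is conventionally reported as
#' `core-only + shared_I_II` (e.g. 146 + 54 = 200).
#'
#' @param sigs Named list of [ifn_signature()] objects.
#' @param type_I_names Names of the three type I signatures.
#' @param type_II_name Name of the type II signature.
#' @return An object of class `ifn_venn`: list with `cells` (tibble of
#'   membership pattern, count, genes), `core`, `shared_I_II`,
#'   `core_only` gene vectors.
#' @export
venn_partition <- function(sigs, type_I_names, type_II_name) {
  needed <- c(type_I_names, type_II_name)
  missing <- setdiff(needed, names(sigs))
  if (length(missing) > 0L) {
    abort(paste0("signature(s) not found: ", paste(missing, collapse = ", ")),
          class = "ifnsig_lookup")
  }
  if (length(type_I_names) != 3L) {
    stop_validation("exactly three type I signature names are required")
  }
  sets <- lapply(sigs, function(s) s$up)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(g) universe %in% g,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  cells <- tibble(pattern = pattern, gene = universe) %>%
    dplyr::group_by(.data$pattern) %>%
    dplyr::summarise(n = dplyr::n(),
                     genes = list(sort(.data$gene)), .groups = "drop")
  core <- Reduce(intersect, sets[type_I_names])
  shared_I_II <- intersect(core, sets[[type_II_name]])
  structure(list(cells = cells,
                 core = sort(core),
                 shared_I_II = sort(shared_I_II),
                 core_only = sort(setdiff(core, shared_I_II)),
                 type_I_names = type_I_names,
                 type_II_name = type_II_name),
            class = "ifn_venn")
}

#' @export
print.ifn_venn <- function(x, ...) {
  cat("<ifn_venn> core ", length(x$core), " (",
      length(x$core_only), " + ", length(x$shared_I_II),
      " shared type I/II)\n", sep = "")
  print(x$cells)
  invisible(x)
}

#' Filter a signature by gene annotation
#'
#' Keeps only genes whose annotation class is in `keep_classes`, e.g. to
#' restrict a signature to interferon-inducible genes per an annotation
#' database export.
#'
#' @param sig An [ifn_signature()].
#' @param annotation Data frame with columns gene and class.
#' @param keep_classes Character vector of classes to retain.
#' @return A filtered [ifn_signature()] with provenance appended, or `NULL`
#'   if no up gene survives (with a warning).
#' @export
filter_by_annotation <- function(sig, annotation, keep_classes) {
  if (nrow(annotation) == 0L) stop_validation("empty annotation table")
  kept <- unique(annotation$gene[annotation$class %in% keep_classes])
  up <- intersect(sig$up, kept)
  down <- intersect(sig$down, kept)
  if (length(up) == 0L) {
    warn(paste0("no up gene of '", sig$name, "' carries a kept class"))
    return(NULL)
  }
  ifn_signature(sig$name, up = up, down = down,
                source = paste0(sig$source, "; filtered to ",
                                paste(keep_classes, collapse = "/")))
}

#' Seeded random control signature
#'
#' Uniform sample of `n` genes without replacement from a DE gene universe,
#' reproducible for a given seed — the negative-control counterpart of the
#' biological signatures.
#'
#' @param universe Character vector of candidate genes.
#' @param n Number of genes (default 100).
#' @param seed Integer seed.
#' @param name Signature name.
#' @return An [ifn_signature()].
#' @export
random_signature <- function(universe, n = 100L, seed = 1L,
                             name = paste0("random_", seed)) {
  universe <- unique(as.character(universe))
  if (n > length(universe)) {
    stop_validation("n exceeds the size of the gene universe")
  }
  genes <- withr::with_seed(seed, sample(universe, n))
  ifn_signature(name, up = genes, source = paste0("random seed ", seed))
}

#' Error rate of a minimal signature overlap
#'
#' Probability that all `k` detected transcripts of a category are false
#' discoveries when each is a false discovery independently with probability
#' `fdr`: simply `fdr^k`. At the FDR 0.2 cutoff this gives 20% for one
#' transcript, 4% for two and 0.8% for three — the rationale for requiring a
#' minimum overlap of three transcripts per gene set.
#'
#' @param k Number of overlapping transcripts (positive integer).
#' @param fdr False discovery rate in (0, 1).
#' @return The probability `fdr^k`.
#' @export
minimal_overlap_error <- function(k, fdr) {
  if (any(k < 1L) || any(k != round(k))) {
    stop_validation("k must be a positive integer")
  }
  if (any(fdr <= 0 | fdr >= 1)) stop_validation("fdr must lie in (0, 1)")
  fdr^k
}

#' Remove overlapping genes from a signature
#'
#' Drops from `sig` any gene present in the other signatures — used before
#' regressing an IFN signature score against a cell-type score so shared
#' transcripts cannot drive the association.
#'
#' @param sig An [ifn_signature()].
#' @param others A list of [ifn_signature()] objects (or one).
#' @return The pruned [ifn_signature()], or `NULL` (with a warning) if no up
#'   gene remains.
#' @export
remove_overlap <- function(sig, others) {
  if (inherits(others, "ifn_signature")) others <- list(others)
  shared <- unique(unlist(lapply(others, function(s) c(s$up, s$down))))
  up <- setdiff(sig$up, shared)
  down <- setdiff(sig$down, shared)
  if (length(up) == 0L) {
    warn(paste0("removing overlaps empties signature '", sig$name, "'"))
    return(NULL)
  }
  ifn_signature(sig$name, up = up, down = down,
                source = paste0(sig$source, "; overlaps removed"))
}

# tidiers ---------------------------------------------------------------------

#' @export
tidy.ifn_de <- function(x, ...) {
  as_tibble(unclass(x)[c("gene", "lfc", "t", "p", "q")])
}

#' @export
glance.ifn_de <- function(x, ...) {
  tibble(d0 = attr(x, "d0"), s0_sq = attr(x, "s0_sq"),
         df_residual = attr(x, "df_residual"), df_total = attr(x, "df_total"),
         n1 = attr(x, "n1"), n2 = attr(x, "n2"), n_genes = nrow(x))
}

#' Volcano plot of a differential-expression fit
#'
#' @param object An `ifn_de` object.
#' @param q_max,fc_min Thresholds highlighted in the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ifn_de <- function(object, q_max = 0.01, fc_min = 2, ...) {
  df <- tidy(object) %>%
    dplyr::mutate(hit = .data$q < q_max & abs(.data$lfc) > log2(fc_min))
  ggplot2::ggplot(df, ggplot2::aes(.data$lfc, -log10(.data$p),
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
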