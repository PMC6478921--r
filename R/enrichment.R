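# Single-sample enrichment engine: Gaussian-kernel cumulative scores per
# gene, symmetric rank statistics per sample, and a Kolmogorov-Smirnov-like
# weighted random walk over the ranked gene list yielding a GSVA-style
# enrichment score in (-1, 1) per sample per signature.

#' Kernel cumulative-density transform of an expression matrix
#'
#' For each gene g and sample j, estimates the cumulative proportion of
#' samples with lower expression using a Gaussian kernel:
#' \deqn{\hat z_{gj} = \frac{1}{n} \sum_k \Phi\!\left(\frac{x_{gj} - x_{gk}}{h_g}\right)}
#' with per-gene bandwidth \eqn{h_g = s_g / 4} (a quarter of the gene's
#' standard deviation). Genes constant across samples get 0.5 everywhere.
#'
#' @param expr Numeric genes-by-samples matrix with at least 3 samples.
#' @return A matrix of the same dimensions with values in (0, 1).
#' @export
kcdf_transform <- function(expr) {
  assert_expression(expr)
  n <- ncol(expr)
  if (n < 3L) stop_degenerate("kernel estimation needs at least 3 samples")
  z <- matrix(0.5, nrow = nrow(expr), ncol = n,
              dimnames = dimnames(expr))
  s <- apply(expr, 1L, sd)
  active <- which(s > 0)
  for (g in active) {
    h <- s[[g]] / 4
    x <- expr[g, ]
    z[g, ] <- rowMeans(pnorm(outer(x, x, "-") / h))
  }
  z
}

# Per-sample symmetric rank statistic: genes ranked by kernel score
# descending (ties broken by gene symbol for determinism), then
# r = |N/2 - rank| so both tails of the ranking carry large weight.
kernel_rank_stats <- function(z) {
  n_genes <- nrow(z)
  genes <- rownames(z)
  rank_mat <- matrix(NA_integer_, n_genes, ncol(z), dimnames = dimnames(z))
  for (j in seq_len(ncol(z))) {
    ord <- order(-z[, j], genes)
    rank_mat[ord, j] <- seq_len(n_genes)
  }
  list(rank = rank_mat, sym = abs(n_genes / 2 - rank_mat))
}

#' Enrichment random walk for one signature
#'
#' Walks down each sample's ranked gene list: signature genes step the walk
#' up by their normalized symmetric rank weight \eqn{r^\tau / \sum_{set}
#' r^\tau}, other genes step it down by \eqn{1/(N - |set|)}. The enrichment
#' score is either the signed sum of the maximum positive and minimum
#' negative deviations (`"difference"`, default) or the single
#' largest-magnitude deviation (`"two_sided"`; exact magnitude ties resolve
#' to the positive deviation). With down-regulated genes
#' present the score is ES(up) - ES(down).
#'
#' @param z Kernel score matrix from [kcdf_transform()].
#' @param sig An [ifn_signature()].
#' @param es_mode `"difference"` or `"two_sided"`.
#' @param tau Walk weight exponent (default 1).
#' @param min_set_size Minimum number of signature genes that must be present
#'   in the matrix (default 3, the smallest overlap with a tolerable
#'   false-discovery error).
#' @return Named numeric vector of per-sample scores in (-1, 1), or `NULL`
#'   (with a warning) when fewer than `min_set_size` genes are present.
#' @export
enrichment_walk <- function(z, sig, es_mode = c("difference", "two_sided"),
                            tau = 1, min_set_size = 3L) {
  es_mode <- match.arg(es_mode)
  stats <- kernel_rank_stats(z)
  up <- walk_scores(stats, sig$up, es_mode, tau, min_set_size, sig$name)
  if (is.null(up)) return(NULL)
  if (length(sig$down) > 0L) {
    down <- walk_scores(stats, sig$down, es_mode, tau, min_set_size,
                        paste0(sig$name, " (down set)"))
    if (!is.null(down)) up <- up - down
  }
  up
}

walk_scores <- function(stats, genes, es_mode, tau, min_set_size, label) {
  present <- intersect(genes, rownames(stats$rank))
  m <- length(present)
  n <- nrow(stats$rank)
  if (m < min_set_size) {
    warn(paste0("signature '", label, "' has ", m, " gene(s) in the matrix ",
                "(minimum ", min_set_size, "); skipped"))
    return(NULL)
  }
  if (m >= n) stop_degenerate("signature covers the whole gene universe")
  in_set <- rownames(stats$rank) %in% present
  dec <- 1 / (n - m)
  vapply(seq_len(ncol(stats$rank)), function(j) {
    ord <- order(stats$rank[, j])
    set_ord <- in_set[ord]
    w <- stats$sym[ord, j]^tau
    steps <- ifelse(set_ord, w / sum(w[set_ord]), -dec)
    walk <- cumsum(steps)
    max_pos <- max(0, max(walk))
    min_neg <- min(0, min(walk))
    if (es_mode == "difference") {
      max_pos + min_neg
    } else {
      # exact magnitude ties resolve to the positive deviation
      d <- max_pos + min_neg
      if (d >= -1e-12) max_pos else min_neg
    }
  }, numeric(1L)) |> setNames(colnames(stats$rank))
}

#' Score signatures across all samples
#'
#' Composes [kcdf_transform()] and [enrichment_walk()] over a signature
#' collection. Signatures with fewer than `min_set_size` genes present in
#' the matrix are dropped with a warning.
#'
#' @param expr Numeric genes-by-samples log2 expression matrix.
#' @param sigs A named list of [ifn_signature()] objects (or a single one).
#' @param es_mode `"difference"` (default) or `"two_sided"`.
#' @param tau Walk weight exponent.
#' @param min_set_size Minimum signature genes present (default 3).
#' @return An `ifn_scores` tibble in long format with columns sample,
#'   signature and score (strictly inside (-1, 1)).
#' @export
score_signatures <- function(expr, sigs,
                             es_mode = c("difference", "two_sided"),
                             tau = 1, min_set_size = 3L) {
  es_mode <- match.arg(es_mode)
  if (inherits(sigs, "ifn_signature")) sigs <- list(sigs)
  if (is.null(names(sigs)) || any(!nzchar(names(sigs)))) {
    names(sigs) <- vapply(sigs, `[[`, character(1L), "name")
  }
  z <- kcdf_transform(expr)
  per_sig <- purrr::map(sigs, function(s) {
    enrichment_walk(z, s, es_mode = es_mode, tau = tau,
                    min_set_size = min_set_size)
  })
  per_sig <- purrr::compact(per_sig)
  if (length(per_sig) == 0L) {
    stop_degenerate("no signature had enough genes in the matrix")
  }
  out <- purrr::imap(per_sig, function(sc, nm) {
    tibble(sample = names(sc), signature = nm, score = unname(sc))
  }) %>%
    purrr::list_rbind()
  structure(out, class = c("ifn_scores", class(out)),
            es_mode = es_mode, min_set_size = min_set_size, tau = tau)
}

#' @export
tidy.ifn_scores <- function(x, ...) as_tibble(unclass(x))

#' Spread an enrichment score table to samples-by-signatures
#'
#' @param scores An `ifn_scores` tibble.
#' @return A wide tibble with one row per sample.
#' @export
scores_wide <- function(scores) {
  tidy(scores) %>%
    tidyr::pivot_wider(names_from = "signature", values_from = "score")
}

#' Heatmap of enrichment scores
#'
#' Red above zero (enriched), blue below — the conventional rendering of
#' GSVA score matrices.
#'
#' @param object An `ifn_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ifn_scores <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$sample, .data$signature,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ES") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
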