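# Independent oracles and small fixtures shared across tests. The oracles
# are written directly from first principles (explicit loops, textbook
# formulas) and never call the package's own code paths.

# small cohort design used wherever a full synthetic cohort is needed
small_design <- function(...) {
  args <- list(n_controls = 10L, n_patients = 10L, n_genes = 300L,
               core_size = 50L, shared_I_II_size = 13L, unique_size = 20L,
               cell_module_size = 15L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_design, args)
}

toy_expr <- function(n_genes = 20L, n_samples = 8L, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, 7, 1), n_genes, n_samples)
  })
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  m
}

# brute-force Benjamini-Hochberg: q_i = min over tail of p * m / rank
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    tail_vals <- vapply(rank_i:m, function(r) p[ord[r]] * m / r, numeric(1))
    q[i] <- min(1, min(tail_vals))
  }
  q
}

# textbook Welch t: explicit formulas, no stats::t.test
oracle_welch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_hedges <- function(a, b, correction = FALSE) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  g <- (mean(a) - mean(b)) / sp
  if (correction) g <- g * (1 - 3 / (4 * (n1 + n2) - 9))
  g
}

# brute-force single-sample enrichment written from the published GSVA
# equations: explicit per-sample kernel sums, ranking and walk loop.
oracle_gsva <- function(X, set_genes, mode = "difference", tau = 1) {
  G <- nrow(X); n <- ncol(X)
  z <- matrix(NA_real_, G, n, dimnames = dimnames(X))
  for (g in seq_len(G)) {
    s <- sd(X[g, ])
    for (j in seq_len(n)) {
      if (s == 0) {
        z[g, j] <- 0.5
      } else {
        acc <- 0
        for (k in seq_len(n)) acc <- acc + pnorm((X[g, j] - X[g, k]) / (s / 4))
        z[g, j] <- acc / n
      }
    }
  }
  in_set <- rownames(X) %in% set_genes
  m <- sum(in_set)
  es <- numeric(n)
  for (j in seq_len(n)) {
    ord <- order(-z[, j], rownames(X))
    rnk <- integer(G)
    rnk[ord] <- seq_len(G)
    w <- abs(G / 2 - rnk)^tau
    denom <- sum(w[in_set])
    walk <- 0; best_pos <- 0; best_neg <- 0
    for (pos in seq_len(G)) {
      g <- ord[pos]
      walk <- walk + if (in_set[g]) w[g] / denom else -1 / (G - m)
      if (walk > best_pos) best_pos <- walk
      if (walk < best_neg) best_neg <- walk
    }
    es[j] <- if (mode == "difference") {
      best_pos + best_neg
    } else if (best_pos + best_neg >= -1e-12) {
      best_pos  # magnitude ties resolve to the positive deviation
    } else {
      best_neg
    }
  }
  setNames(es, colnames(X))
}

# first principal component by explicit eigen-decomposition of the sample
# covariance of the standardized module matrix
oracle_eigengene <- function(expr, genes) {
  z <- t(scale(t(expr[genes, , drop = FALSE])))
  ev <- eigen(crossprod(z))
  v <- ev$vectors[, 1L]
  if (mean(cor(v, t(z))) < 0) v <- -v
  v
}

expect_tbl_equal <- function(x, y, tolerance = 1e-12) {
  expect_equal(as.data.frame(x), as.data.frame(y), tolerance = tolerance)
}
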