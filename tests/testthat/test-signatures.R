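test_that("moderated t collapses to the ordinary pooled t when d0 = 0", {
  m <- toy_expr(30L, 10L, seed = 11L)
  g1 <- colnames(m)[1:5]
  g2 <- colnames(m)[6:10]
  de <- moderated_de(m, g1, g2, d0 = 0)
  for (g in rownames(m)) {
    a <- m[g, g1]; b <- m[g, g2]
    sp2 <- ((4) * var(a) + (4) * var(b)) / 8
    t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
    expect_equal(de$t[de$gene == g], t_ref, tolerance = 1e-10)
  }
})

test_that("identical within-group variances trigger complete shrinkage", {
  # every gene shows the same residual pattern, so s^2 is constant across
  # genes: the prior df is infinite and every posterior variance collapses
  # to the single moment-matched target
  base <- c(-1, 0, 1, -1, 0, 1)
  m <- t(sapply(1:12, function(i) base + i))
  dimnames(m) <- list(paste0("g", 1:12), paste0("s", 1:6))
  de <- moderated_de(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_true(is.infinite(attr(de, "d0")))
  expect_length(unique(round(de$s2_post, 12)), 1L)
  # the target is the bias-corrected log-variance mean of the scaled-F fit
  d <- 4
  target <- exp(mean(log(de$s2)) - digamma(d / 2) + log(d / 2))
  expect_equal(unique(de$s2_post), target, tolerance = 1e-12)
})

test_that("planted differential genes are recovered and match a plain-t oracle", {
  m <- withr::with_seed(7L, {
    mm <- matrix(rnorm(20 * 8, 7, 0.5), 20, 8)
    mm[1:5, 1:4] <- mm[1:5, 1:4] + 2
    mm
  })
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:8))
  de <- moderated_de(m, colnames(m)[1:4], colnames(m)[5:8])
  hits <- de$gene[de$q < 0.05]
  expect_setequal(hits, sprintf("g%02d", 1:5))

  # ordinary-t + BH oracle on the same draw confirms the gene set
  p_ord <- apply(m, 1L, function(x) {
    stats::t.test(x[1:4], x[5:8], var.equal = TRUE)$p.value
  })
  oracle_hits <- rownames(m)[oracle_bh(p_ord) < 0.05]
  expect_setequal(hits, oracle_hits)
})

test_that("moderated fit agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  m <- toy_expr(60L, 12L, seed = 21L)
  m[1:10, 1:6] <- m[1:10, 1:6] + 1.5
  g1 <- colnames(m)[1:6]
  g2 <- colnames(m)[7:12]
  de <- moderated_de(m, g1, g2)
  design <- cbind(1, colnames(m) %in% g1)
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[, 2L]), tolerance = 1e-6)
  expect_equal(de$p, unname(fit$p.value[, 2L]), tolerance = 1e-6)
})

test_that("BH adjustment reproduces hand step-up values", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_error(bh_fdr(c(0.1, 1.2)), class = "ifnsig_validation")
})

test_that("BH adjustment equals the brute-force tail-minimum oracle", {
  withr::with_seed(5L, {
    for (n in 2:6) {
      for (rep in 1:20) {
        p <- runif(n)
        expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
      }
    }
  })
  # all permutations of a fixed 4-vector
  p <- c(0.011, 0.2, 0.049, 0.9)
  perms <- list(1:4, c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2))
  for (idx in perms) {
    expect_equal(bh_fdr(p[idx]), oracle_bh(p[idx]), tolerance = 1e-12)
  }
})

test_that("signature derivation applies strict q and fold-change cuts", {
  de <- tibble::tibble(gene = c("a", "b", "c", "d"),
                       lfc = c(1.1, 2, 0.9, -1.5),
                       q = c(0.009, 0.01, 0.001, 0.001))
  sig <- derive_signature(de, q_max = 0.01, fc_min = 2, name = "s")
  # a: q .009 and fold 2^1.1 = 2.14 > 2 -> in; b excluded (q = .01 exactly);
  # c excluded (fold 1.87); d is down-regulated
  expect_setequal(sig$up, "a")
  both <- derive_signature(de, q_max = 0.01, fc_min = 2, direction = "both",
                           name = "s")
  expect_setequal(both$down, "d")
  expect_warning(
    empty <- derive_signature(dplyr::mutate(de, q = 0.5), name = "s"),
    "empty")
  expect_null(empty)
})

test_that("signature derivation is monotone in its thresholds", {
  withr::with_seed(3L, {
    de <- tibble::tibble(gene = sprintf("g%03d", 1:200),
                         lfc = rnorm(200, 0, 1.5),
                         q = runif(200))
  })
  tight <- derive_signature(de, q_max = 0.05, fc_min = 2, name = "t")
  loose_q <- derive_signature(de, q_max = 0.2, fc_min = 2, name = "l")
  loose_fc <- derive_signature(de, q_max = 0.05, fc_min = 1.5, name = "l2")
  expect_true(all(tight$up %in% loose_q$up))
  expect_true(all(tight$up %in% loose_fc$up))
})

test_that("venn partition computes core and shared sets by set algebra", {
  sigs <- list(A = ifn_signature("A", c("x", "y", "z")),
               B = ifn_signature("B", c("y", "z")),
               C = ifn_signature("C", c("z", "y", "w")),
               W = ifn_signature("W", c("z", "y", "q")))
  vp <- venn_partition(sigs, c("A", "B", "C"), "W")
  expect_setequal(vp$core, c("y", "z"))
  expect_setequal(vp$shared_I_II, c("y", "z"))

  disj <- list(A = ifn_signature("A", "a"), B = ifn_signature("B", "b"),
               C = ifn_signature("C", "c"), W = ifn_signature("W", "w"))
  expect_length(venn_partition(disj, c("A", "B", "C"), "W")$core, 0L)

  expect_error(venn_partition(sigs, c("A", "B", "missing"), "W"),
               class = "ifnsig_lookup")
})

test_that("venn cells are disjoint and cover the union for random sets", {
  withr::with_seed(9L, {
    for (rep in 1:10) {
      universe <- sprintf("g%03d", 1:60)
      sigs <- lapply(setNames(nm = c("A", "B", "C", "W")), function(nm) {
        ifn_signature(nm, sample(universe, sample(5:40, 1)))
      })
      vp <- venn_partition(sigs, c("A", "B", "C"), "W")
      all_genes <- unlist(vp$cells$genes)
      expect_false(anyDuplicated(all_genes) > 0)
      expect_setequal(all_genes, unique(unlist(lapply(sigs, `[[`, "up"))))
    }
  })
})

test_that("annotation filtering keeps only the requested classes", {
  sig <- ifn_signature("s", c("A", "B", "C"))
  ann <- tibble::tibble(gene = c("A", "B"), class = c("type_I", "type_I"))
  kept <- filter_by_annotation(sig, ann, "type_I")
  expect_setequal(kept$up, c("A", "B"))
  expect_match(kept$source, "type_I")

  all_ann <- tibble::tibble(gene = c("A", "B", "C"), class = "type_I")
  expect_setequal(filter_by_annotation(sig, all_ann, "type_I")$up, sig$up)

  expect_error(filter_by_annotation(sig, ann[0, ], "type_I"),
               class = "ifnsig_validation")
})

test_that("random signatures are seed-reproducible uniform draws", {
  universe <- sprintf("g%04d", 1:1000)
  s1 <- random_signature(universe, 100L, seed = 1L)
  s1b <- random_signature(universe, 100L, seed = 1L)
  s2 <- random_signature(universe, 100L, seed = 2L)
  expect_identical(s1$up, s1b$up)
  expect_true(length(setdiff(s1$up, s2$up)) >= 1L)
  expect_setequal(random_signature(universe, 1000L, seed = 3L)$up, universe)
  expect_error(random_signature(universe, 1001L), class = "ifnsig_validation")
})

test_that("minimal overlap error is the false-discovery power law", {
  expect_equal(minimal_overlap_error(1, 0.2), 0.2)
  expect_equal(minimal_overlap_error(2, 0.2), 0.04)
  expect_equal(minimal_overlap_error(3, 0.2), 0.008)
  expect_equal(minimal_overlap_error(2, 0.5), 0.25)
  expect_error(minimal_overlap_error(0, 0.2), class = "ifnsig_validation")
  expect_error(minimal_overlap_error(2, 1), class = "ifnsig_validation")
})

test_that("overlap removal prunes shared transcripts before regression", {
  ifn <- ifn_signature("ifn", c("A", "B", "C", "D"))
  mono <- ifn_signature("mono", c("C", "D", "E"))
  pruned <- remove_overlap(ifn, mono)
  expect_setequal(pruned$up, c("A", "B"))
  expect_warning(expect_null(remove_overlap(mono, ifn_signature("x", c("C", "D", "E")))))
})
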