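score_tbl <- function(samples, scores, signature = "IFN_Core") {
  tibble::tibble(sample = samples, signature = signature, score = scores)
}

meta_tbl <- function(samples, groups, ...) {
  tibble::tibble(sample = samples, group = groups, ...)
}

test_that("positivity threshold is control mean plus two control SDs", {
  sc <- score_tbl(c("c1", "c2", "c3", "p1", "p2", "p3"),
                  c(-0.2, 0, 0.2, 0.5, 0.3, 0.4))
  meta <- meta_tbl(c("c1", "c2", "c3", "p1", "p2", "p3"),
                   c(rep("control", 3), rep("SLE", 3)))
  calls <- classify_positive(sc, meta)
  # controls: mean 0, SD 0.2 -> threshold 0.4
  expect_equal(unique(calls$threshold), 0.4)
  expect_equal(calls$call[calls$sample == "p1"], "positive")
  expect_equal(calls$call[calls$sample == "p2"], "negative")
  # exactly at threshold is negative (strict >)
  expect_equal(calls$call[calls$sample == "p3"], "negative")
})

test_that("constant controls give a zero-SD threshold with a warning", {
  sc <- score_tbl(c("c1", "c2", "p1"), c(0.1, 0.1, 0.2))
  meta <- meta_tbl(c("c1", "c2", "p1"), c("control", "control", "SLE"))
  expect_warning(calls <- classify_positive(sc, meta), "constant")
  expect_equal(calls$call, "positive")
  expect_error(
    classify_positive(score_tbl(c("c1", "p1"), c(0, 1)),
                      meta_tbl(c("c1", "p1"), c("control", "SLE"))),
    class = "ifnsig_degenerate_input")
})

test_that("positivity rates stratify by activity", {
  samples <- c(paste0("c", 1:3), paste0("p", 1:4))
  sc <- score_tbl(samples, c(-0.1, 0, 0.1, 0.5, 0.5, 0.01, 0.5))
  meta <- meta_tbl(samples, c(rep("control", 3), rep("SLE", 4)),
                   sledai = c(NA, NA, NA, 8, 6, 2, 5))
  calls <- classify_positive(sc, meta)
  strata <- split_by_sledai(meta)[, c("sample", "activity")]
  rates <- positivity_rate(calls, strata)
  expect_equal(rates$fraction_positive[rates$activity == "active"], 1)
  expect_equal(rates$fraction_positive[rates$activity == "inactive"], 0.5)
})

test_that("SLEDAI splitting uses the >= 6 boundary and excludes controls", {
  meta <- meta_tbl(c("c1", "p1", "p2", "p3", "p4"),
                   c("control", rep("SLE", 4)),
                   sledai = c(NA, 6, 5, 2, 10))
  split <- split_by_sledai(meta)
  expect_setequal(split$sample[split$activity == "active"], c("p1", "p4"))
  expect_setequal(split$sample[split$activity == "inactive"], c("p2", "p3"))

  meta$sledai[meta$sample == "p2"] <- NA
  expect_warning(split2 <- split_by_sledai(meta), "p2")
  expect_false("p2" %in% split2$sample)
})

test_that("Welch t matches the textbook formula oracle", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  res <- welch_t(c(1, 2, 3), c(3, 4, 5))
  ref <- oracle_welch(c(1, 2, 3), c(3, 4, 5))
  expect_equal(res$t, ref$t, tolerance = 1e-10)
  expect_equal(res$p, ref$p, tolerance = 1e-10)
  withr::with_seed(31L, {
    for (rep in 1:50) {
      a <- rnorm(sample(3:12, 1))
      b <- rnorm(sample(3:12, 1), sd = runif(1, 0.2, 3))
      got <- welch_t(a, b)
      ref <- oracle_welch(a, b)
      expect_equal(got$t, ref$t, tolerance = 1e-10)
      expect_equal(got$df, ref$df, tolerance = 1e-10)
      expect_equal(got$p, ref$p, tolerance = 1e-10)
    }
  })
})

test_that("Welch df falls below the pooled df under variance imbalance", {
  withr::with_seed(37L, {
    a <- rnorm(8, sd = 10)
    b <- rnorm(8, sd = 1)
  })
  expect_lt(welch_t(a, b)$df, length(a) + length(b) - 2)
})

test_that("Hedges g uses the pooled SD with optional small-sample correction", {
  expect_equal(hedges_g(c(1, 2), c(1, 2)), 0)
  expect_equal(hedges_g(c(3, 4, 5), c(1, 2, 3)), 2)
  expect_equal(hedges_g(c(3, 4, 5), c(1, 2, 3), correction = TRUE), 1.6)
  withr::with_seed(41L, {
    for (rep in 1:50) {
      a <- rnorm(sample(3:10, 1), mean = 1)
      b <- rnorm(sample(3:10, 1))
      expect_equal(hedges_g(a, b), oracle_hedges(a, b), tolerance = 1e-10)
      expect_equal(hedges_g(a, b, TRUE), oracle_hedges(a, b, TRUE),
                   tolerance = 1e-10)
    }
  })
  expect_error(hedges_g(c(1, 1), c(2, 2)), class = "ifnsig_undefined_effect")
})

test_that("effect ranking orders signatures by g and flags non-significance", {
  samples <- c(paste0("c", 1:5), paste0("p", 1:5))
  groups <- c(rep("control", 5), rep("SLE", 5))
  withr::with_seed(43L, {
    sc <- dplyr::bind_rows(
      score_tbl(samples, c(rnorm(5, 0, 0.1), rnorm(5, 0.8, 0.1)), "strong"),
      score_tbl(samples, c(rnorm(5, 0, 0.1), rnorm(5, 0.3, 0.1)), "weak"),
      score_tbl(samples, rep(rnorm(5, 0, 0.1), 2L), "null"))
  })
  eff <- rank_signatures_by_effect(sc, meta_tbl(samples, groups))
  expect_equal(eff$signature[1L], "strong")
  expect_true(eff$g[1L] > eff$g[eff$signature == "weak"])
  expect_equal(eff$flag[eff$signature == "null"], "N.S.")
  # duplicated signature scores give identical g
  sc2 <- dplyr::bind_rows(score_tbl(samples, sc$score[sc$signature == "strong"], "dup"),
                          sc[sc$signature == "strong", ])
  eff2 <- rank_signatures_by_effect(sc2, meta_tbl(samples, groups))
  expect_equal(eff2$g[1L], eff2$g[2L])
})

test_that("trajectory categories apply the SD threshold and first/last calls", {
  # controls pin the positivity threshold at 0 + 2*0.05 = 0.1 and the
  # trajectory threshold (max control SD) at 0.05
  ctrl <- score_tbl(paste0("c", 1:3), c(-0.05, 0, 0.05))
  sle <- score_tbl(paste0("p1_t", 1:3), c(-0.3, 0.1, 0.3))
  stable <- score_tbl(paste0("p2_t", 1:3), c(0.2, 0.2, 0.2))
  loss <- score_tbl(paste0("p3_t", 1:3), c(0.3, 0.1, -0.3))
  fluct <- score_tbl(paste0("p4_t", 1:3), c(0.3, -0.3, 0.32))
  sc <- dplyr::bind_rows(ctrl, sle, stable, loss, fluct)
  meta <- dplyr::bind_rows(
    meta_tbl(paste0("c", 1:3), "control",
             patient = NA_character_, timepoint = NA_integer_),
    tibble::tibble(sample = sc$sample[4:15], group = "SLE",
                   patient = rep(paste0("p", 1:4), each = 3),
                   timepoint = rep(1:3, 4)))
  traj <- trajectory_analysis(sc, meta)
  expect_equal(traj$threshold[1L], sd(c(-0.05, 0, 0.05)))
  got <- setNames(traj$category, traj$patient)
  expect_equal(got[["p1"]], "gain")   # SD ~ .306, neg -> pos
  expect_equal(got[["p2"]], "stable")
  expect_equal(got[["p3"]], "loss")
  expect_equal(got[["p4"]], "fluctuating")
  expect_equal(sd(c(-0.3, 0.1, 0.3)), 0.3055, tolerance = 1e-4)
  # every patient lands in exactly one category
  expect_equal(sort(names(got)), paste0("p", 1:4))
})

test_that("the trajectory threshold rule takes the largest control SD", {
  # three signatures with control SDs 0.12, 0.2, 0.15 -> threshold 0.2
  ctrl_scores <- list(sigA = c(-0.12, 0, 0.12), sigB = c(-0.2, 0, 0.2),
                      sigC = c(-0.15, 0, 0.15))
  sc <- dplyr::bind_rows(lapply(names(ctrl_scores), function(s) {
    dplyr::bind_rows(score_tbl(paste0("c", 1:3), ctrl_scores[[s]], s),
                     score_tbl(paste0("p1_t", 1:2), c(0, 0.1), s))
  }))
  meta <- dplyr::bind_rows(
    meta_tbl(paste0("c", 1:3), "control",
             patient = NA_character_, timepoint = NA_integer_),
    tibble::tibble(sample = paste0("p1_t", 1:2), group = "SLE",
                   patient = "p1", timepoint = 1:2))
  traj <- trajectory_analysis(sc, meta)
  expect_equal(unique(traj$threshold), sd(c(-0.2, 0, 0.2)))
  fixed <- trajectory_analysis(sc, meta, threshold_rule = "fixed")
  expect_equal(unique(fixed$threshold), 0.2)
})

test_that("patients missing a timepoint are excluded with a warning", {
  sc <- dplyr::bind_rows(score_tbl(paste0("c", 1:3), c(-0.1, 0, 0.1)),
                         score_tbl(c("p1_t1", "p1_t2", "p2_t1"),
                                   c(0, 0.5, 0.3)))
  meta <- dplyr::bind_rows(
    meta_tbl(paste0("c", 1:3), "control",
             patient = NA_character_, timepoint = NA_integer_),
    tibble::tibble(sample = c("p1_t1", "p1_t2", "p2_t1"), group = "SLE",
                   patient = c("p1", "p1", "p2"), timepoint = c(1, 2, 1)))
  expect_warning(traj <- trajectory_analysis(sc, meta), "p2")
  expect_setequal(traj$patient, "p1")
})

test_that("score regression reports slope, fit quality and slope p-value", {
  df <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  # lm warns about the deliberately perfect fit
  fit <- suppressWarnings(regress_scores(df, x, y))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$p, 0.05)
  expect_error(regress_scores(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               class = "ifnsig_degenerate_input")
  expect_error(regress_scores(df[1:2, ], x, y),
               class = "ifnsig_degenerate_input")
  # tidy/glance expose the lm summary
  expect_equal(nrow(suppressWarnings(tidy(fit))), 2L)
  expect_equal(glance(fit)$n, 10L)
})

test_that("null regression rejects the slope at the nominal rate", {
  runs <- 500L
  rejections <- withr::with_seed(47L, {
    sum(vapply(seq_len(runs), function(i) {
      df <- tibble::tibble(x = rnorm(20), y = rnorm(20))
      regress_scores(df, x, y)$p < 0.05
    }, logical(1L)))
  })
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / runs)
  expect_lt(abs(rejections / runs - 0.05), ci + 1e-9)
})

test_that("module eigengene matches an eigen-decomposition oracle", {
  m <- toy_expr(20L, 10L, seed = 53L)
  genes <- rownames(m)[1:5]
  eg <- module_eigengene(m, genes)
  ref <- oracle_eigengene(m, genes)
  expect_equal(abs(cor(eg$eigengene, ref)), 1, tolerance = 1e-10)
  # orientation: positive mean correlation with module genes
  z <- t(scale(t(m[genes, ])))
  expect_gt(mean(cor(eg$eigengene, t(z))), 0)
})

test_that("degenerate module shapes reduce to the standardized gene", {
  m <- toy_expr(10L, 8L, seed = 59L)
  eg1 <- module_eigengene(m, "g001", allow_single = TRUE)
  expect_equal(abs(cor(eg1$eigengene, m["g001", ])), 1, tolerance = 1e-10)
  # two perfectly correlated genes
  m["g002", ] <- 2 * m["g001", ] + 1
  eg2 <- module_eigengene(m, c("g001", "g002"))
  expect_equal(abs(cor(eg2$eigengene, m["g001", ])), 1, tolerance = 1e-10)
  expect_error(module_eigengene(m, "g001"), class = "ifnsig_degenerate_input")
})

test_that("eigengene trait correlation separates disease from control", {
  d <- small_design(delta = c(IFNB1 = 2), fraction_positive = 1, seed = 61L)
  co <- generate_cohort(d)
  eg <- module_eigengene(co$expr, co$signatures$IFN_Core$up, meta = co$meta)
  gl <- glance(eg)
  expect_gt(gl$r_disease, 0)
  expect_lt(gl$p_disease, 0.05)
})

test_that("ANOVA with Tukey HSD separates only the shifted group", {
  df <- tibble::tibble(score = c(1, 2, 3, 1, 2, 3, 11, 12, 13),
                       grp = rep(c("a", "b", "c"), each = 3))
  res <- anova_tukey(df, score, grp)
  pw <- tidy(res)
  expect_lt(pw$p_adj[pw$comparison == "c-a"], 0.05)
  expect_lt(pw$p_adj[pw$comparison == "c-b"], 0.05)
  expect_gt(pw$p_adj[pw$comparison == "b-a"], 0.05)
  # cross-check the pairwise c-a comparison against the studentized range
  ng <- 3; nper <- 3
  mse <- sum(tapply(df$score, df$grp, function(x) sum((x - mean(x))^2))) /
    (nrow(df) - ng)
  qstat <- abs(mean(df$score[df$grp == "c"]) - mean(df$score[df$grp == "a"])) /
    sqrt(mse / nper)
  p_ref <- 1 - ptukey(qstat, ng, nrow(df) - ng)
  expect_equal(pw$p_adj[pw$comparison == "c-a"], p_ref, tolerance = 1e-10)

  expect_error(anova_tukey(df[df$grp != "c", ], score, grp),
               class = "ifnsig_validation")
})

test_that("equal group means give a small F and no pairwise rejections", {
  withr::with_seed(67L, {
    df <- tibble::tibble(score = rnorm(30, 0, 1),
                         grp = rep(c("a", "b", "c"), each = 10))
    df$score <- df$score - ave(df$score, df$grp)  # force equal (zero) means
  })
  res <- anova_tukey(df, score, grp)
  expect_equal(res$f, 0, tolerance = 1e-20)
  expect_true(all(tidy(res)$p_adj > 0.99))
})
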