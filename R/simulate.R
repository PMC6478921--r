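# Synthetic expression cohorts with planted ground truth. The generator
# emulates the structure the analysis assumes: log2 expression with
# Gaussian noise around gene-level baselines, a healthy control group,
# IGS-positive patients carrying additive subtype-specific induction on
# signature genes, monocyte-weighted induction (monocytes carry the IGS),
# cell-composition effects on cell-type modules, and a SLEDAI-like activity
# covariate tied to plasma-cell/cell-cycle modules but only weakly to the
# IGS.

#' Cohort design
#'
#' Collects the parameters of a simulated cohort. Defaults describe an
#' IFNB1-dominant SLE cohort: type I induction strongest for IFNB1, about
#' 70% of patients IGS-positive, microarray-like log2 noise.
#'
#' @param n_controls,n_patients Group sizes.
#' @param delta Named vector of additive log2 induction effects per subtype
#'   (`IFNA2`, `IFNB1`, `IFNW1`, `IFNG`, `TNF`, `IL12`); all non-negative.
#' @param fraction_positive Fraction of patients carrying the IGS.
#' @param noise_sd Residual (within-subject) log2 noise SD.
#' @param subject_sd Between-subject log2 SD: a per-subject, per-gene random
#'   effect shared across a patient's timepoints, so repeated measures of
#'   one person vary less than measures across people.
#' @param n_genes Total genes (must host the signature universe).
#' @param core_size,shared_I_II_size,unique_size Signature topology: shared
#'   type I core, its type I/II shared subset, and per-subtype unique genes.
#' @param cell_module_size Genes per cell-type/process module.
#' @param monocyte_fraction Optional fixed monocyte fraction for every
#'   sample; `NULL` draws per-sample simplex fractions.
#' @param monocyte_ref Reference monocyte fraction at which induction is at
#'   its nominal strength.
#' @param lymphocyte_mult Induction multiplier for lymphocyte-biased
#'   signature genes (default 0.33, a roughly 3:1 monocyte bias).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `ifn_design`.
#' @export
cohort_design <- function(n_controls = 20L, n_patients = 20L,
                          delta = c(IFNA2 = 0.75, IFNB1 = 1.5, IFNW1 = 0.75,
                                    IFNG = 0.5, TNF = 0, IL12 = 0),
                          fraction_positive = 0.7,
                          noise_sd = 0.5,
                          subject_sd = 0.3,
                          n_genes = 1000L,
                          core_size = 200L,
                          shared_I_II_size = 54L,
                          unique_size = 50L,
                          cell_module_size = 30L,
                          monocyte_fraction = NULL,
                          monocyte_ref = 0.2,
                          lymphocyte_mult = 0.33,
                          seed = 1L) {
  subtypes <- c("IFNA2", "IFNB1", "IFNW1", "IFNG", "TNF", "IL12")
  full <- setNames(rep(0, length(subtypes)), subtypes)
  full[names(delta)] <- delta
  if (any(full < 0)) stop_validation("induction effects must be non-negative")
  if (fraction_positive < 0 || fraction_positive > 1) {
    stop_validation("fraction_positive must lie in [0, 1]")
  }
  if (noise_sd < 0 || subject_sd < 0) {
    stop_validation("noise_sd and subject_sd must be non-negative")
  }
  if (shared_I_II_size > core_size) {
    stop_validation("shared_I_II_size cannot exceed core_size")
  }
  if (!is.null(monocyte_fraction) &&
      (monocyte_fraction <= 0 || monocyte_fraction >= 1)) {
    stop_validation("monocyte_fraction must lie in (0, 1)")
  }
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 delta = full, fraction_positive = fraction_positive,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 n_genes = as.integer(n_genes),
                 core_size = as.integer(core_size),
                 shared_I_II_size = as.integer(shared_I_II_size),
                 unique_size = as.integer(unique_size),
                 cell_module_size = as.integer(cell_module_size),
                 monocyte_fraction = monocyte_fraction,
                 monocyte_ref = monocyte_ref,
                 lymphocyte_mult = lymphocyte_mult,
                 seed = as.integer(seed)),
            class = "ifn_design")
}

#' Build the signature gene universe of a design
#'
#' Lays out disjoint gene blocks with the IFN-subtype topology: a type I
#' core shared by IFNA2/IFNB1/IFNW1 (whose first `shared_I_II_size` genes
#' are also induced by IFNG), unique genes per subtype, cell-type/process
#' modules (monocyte, T cell, B cell, plasma cell, cell cycle) and
#' background genes. Gene naming and block layout are deterministic.
#'
#' @param design An [cohort_design()] object.
#' @return A list with `signatures` (named [ifn_signature()] list),
#'   `modules` (named gene-vector list), `genes` (the universe) and
#'   `cell_bias` (named "monocyte"/"lymphocyte" vector over signature
#'   genes).
#' @export
make_signature_universe <- function(design) {
  needed <- design$core_size + 6L * design$unique_size +
    5L * design$cell_module_size
  if (design$n_genes < needed + 10L) {
    stop_validation(paste0("n_genes too small: need at least ", needed + 10L))
  }
  genes <- sprintf("G%05d", seq_len(design$n_genes))
  cursor <- 0L
  take <- function(k) {
    block <- genes[cursor + seq_len(k)]
    cursor <<- cursor + k
    block
  }
  core <- take(design$core_size)
  shared_I_II <- core[seq_len(design$shared_I_II_size)]
  uniq <- lapply(setNames(nm = c("IFNA2", "IFNB1", "IFNW1", "IFNG", "TNF",
                                 "IL12")),
                 function(s) take(design$unique_size))
  modules <- lapply(setNames(nm = c("monocyte", "t_cell", "b_cell",
                                    "plasma_cell", "cell_cycle")),
                    function(m) take(design$cell_module_size))
  sigs <- list(
    IFNA2 = ifn_signature("IFNA2", c(core, uniq$IFNA2), source = "simulated"),
    IFNB1 = ifn_signature("IFNB1", c(core, uniq$IFNB1), source = "simulated"),
    IFNW1 = ifn_signature("IFNW1", c(core, uniq$IFNW1), source = "simulated"),
    IFNG = ifn_signature("IFNG", c(shared_I_II, uniq$IFNG),
                         source = "simulated"),
    TNF = ifn_signature("TNF", uniq$TNF, source = "simulated"),
    IL12 = ifn_signature("IL12", uniq$IL12, source = "simulated"))
  if (design$core_size > 0L) {
    sigs$IFN_Core <- ifn_signature("IFN_Core", core, source = "simulated")
  }
  sig_genes <- unique(unlist(lapply(sigs, `[[`, "up")))
  # deterministic ~3:1 monocyte bias over signature genes
  bias <- ifelse(seq_along(sig_genes) %% 4L == 0L, "lymphocyte", "monocyte")
  list(signatures = sigs, modules = modules, genes = genes,
       cell_bias = setNames(bias, sig_genes))
}

# simplex cell fractions per sample; monocyte mean ~ monocyte_ref
draw_cell_fractions <- function(n, design) {
  if (!is.null(design$monocyte_fraction)) {
    mono <- rep(design$monocyte_fraction, n)
    rest <- 1 - mono
    t_frac <- rest * 0.55 / 0.8
    b_frac <- rest - t_frac
  } else {
    shapes <- c(design$monocyte_ref, 0.55, 1 - design$monocyte_ref - 0.55) * 20
    g <- matrix(rgamma(3L * n, shape = rep(shapes, each = n)), ncol = 3L)
    g <- g / rowSums(g)
    mono <- g[, 1L]
    t_frac <- g[, 2L]
    b_frac <- g[, 3L]
  }
  tibble(monocyte = mono, t_cell = t_frac, b_cell = b_frac)
}

# shared machinery: one expression column per row of `samples`
# (sample, group, induction_mult, fractions, activity latent)
build_expression <- function(design, universe, samples) {
  n_genes <- design$n_genes
  genes <- universe$genes
  mu <- rnorm(n_genes, mean = 7, sd = 1.5)
  expr <- matrix(rnorm(n_genes * nrow(samples), mean = mu,
                       sd = design$noise_sd),
                 nrow = n_genes, ncol = nrow(samples),
                 dimnames = list(genes, samples$sample))
  # between-subject random effect, shared across a subject's timepoints
  if (design$subject_sd > 0) {
    subjects <- unique(samples$subject)
    b <- matrix(rnorm(n_genes * length(subjects), 0, design$subject_sd),
                nrow = n_genes, dimnames = list(genes, subjects))
    expr <- expr + b[, samples$subject, drop = FALSE]
  }

  bias_mult <- ifelse(universe$cell_bias == "lymphocyte",
                      design$lymphocyte_mult, 1)
  gene_idx <- match(names(universe$cell_bias), genes)

  for (i in seq_len(nrow(samples))) {
    row <- samples[i, ]
    # cell-composition shifts on the cell-type/process modules
    expr[match(universe$modules$monocyte, genes), i] <-
      expr[match(universe$modules$monocyte, genes), i] +
      2 * log2(row$monocyte / design$monocyte_ref)
    expr[match(universe$modules$t_cell, genes), i] <-
      expr[match(universe$modules$t_cell, genes), i] +
      2 * log2(row$t_cell / 0.55)
    expr[match(universe$modules$b_cell, genes), i] <-
      expr[match(universe$modules$b_cell, genes), i] +
      2 * log2(row$b_cell / (1 - design$monocyte_ref - 0.55))
    # activity-linked plasma cell / cell cycle variation (all samples; the
    # SLEDAI-like index is recorded for patients only)
    act <- max(row$activity, 0)
    idx_act <- match(c(universe$modules$plasma_cell,
                       universe$modules$cell_cycle), genes)
    expr[idx_act, i] <- expr[idx_act, i] + 0.5 * act
    if (row$group != "SLE") next
    # IGS induction on the dominant subtype's signature (core + unique),
    # monocyte-weighted
    dom <- names(design$delta)[which.max(design$delta)]
    if (row$induction_mult > 0 && design$delta[[dom]] > 0) {
      eff <- numeric(n_genes)
      eff[match(universe$signatures[[dom]]$up, genes)] <- design$delta[[dom]]
      mono_scale <- rep(1, n_genes)
      mono_scale[gene_idx] <- ifelse(universe$cell_bias == "monocyte",
                                     row$monocyte / design$monocyte_ref, 1)
      full_mult <- rep(1, n_genes)
      full_mult[gene_idx] <- bias_mult
      expr[, i] <- expr[, i] +
        row$induction_mult * eff * full_mult * mono_scale
    }
  }
  expr
}

#' Generate a synthetic cross-sectional cohort
#'
#' Draws a control group and an SLE patient group per the design: baseline
#' expression \eqn{x_{gj} = \mu_g + \varepsilon}, \eqn{\mu_g \sim N(7,
#' 1.5^2)} log2 units, Gaussian noise; IGS-positive patients receive the
#' dominant (largest-delta) subtype's induction on that subtype's signature
#' genes (shared core plus unique genes), scaled up or down by each
#' sample's monocyte fraction for monocyte-biased genes and attenuated for
#' lymphocyte-biased genes. A latent activity value drives plasma-cell and
#' cell-cycle modules in every sample and is recorded as a SLEDAI-like
#' index for patients, so disease activity correlates with those modules
#' but not with the IGS.
#'
#' @param design An [cohort_design()] object.
#' @return A list of class `ifn_cohort`: `expr` (matrix), `meta` (tibble),
#'   `truth` (tibble of planted parameters), `signatures`, `modules`.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "ifn_design"))
  universe <- make_signature_universe(design)
  withr::with_seed(design$seed, {
    n_pos <- round(design$fraction_positive * design$n_patients)
    positive <- seq_len(design$n_patients) <= n_pos
    activity <- rnorm(design$n_patients)
    sledai <- pmax(0L, as.integer(round(5 + 3 * activity)))
    samples <- dplyr::bind_rows(
      tibble(sample = sprintf("ctrl%03d", seq_len(design$n_controls)),
             group = "control", induction_mult = 0,
             activity = rnorm(design$n_controls),
             sledai = NA_integer_, positive = FALSE),
      tibble(sample = sprintf("sle%03d", seq_len(design$n_patients)),
             group = "SLE", induction_mult = as.numeric(positive),
             activity = activity, sledai = sledai, positive = positive))
    samples <- dplyr::bind_cols(samples,
                                draw_cell_fractions(nrow(samples), design))
    samples$subject <- samples$sample
    expr <- build_expression(design, universe, samples)
  })
  dominant <- names(design$delta)[which.max(design$delta)]
  meta <- samples %>%
    dplyr::transmute(.data$sample, .data$group, .data$sledai)
  truth <- samples %>%
    dplyr::filter(.data$group == "SLE") %>%
    dplyr::transmute(.data$sample, igs_positive = .data$positive,
                     dominant_subtype = dominant, .data$sledai,
                     .data$activity, .data$monocyte, .data$t_cell,
                     .data$b_cell)
  structure(list(expr = expr, meta = meta, truth = truth,
                 signatures = universe$signatures,
                 modules = universe$modules, design = design),
            class = "ifn_cohort")
}

#' @export
print.ifn_cohort <- function(x, ...) {
  cat("<ifn_cohort> ", nrow(x$expr), " genes x ", ncol(x$expr), " samples (",
      x$design$n_controls, " control, ", x$design$n_patients, " SLE)\n",
      sep = "")
  invisible(x)
}

#' Generate a longitudinal cohort with planted trajectory profiles
#'
#' Each patient follows a `stable`, `gain` or `loss` profile: the induction
#' multiplier ramps from 0 to 1 over the timepoints (gain), from 1 to 0
#' (loss), or stays flat (stable; at 1 for planted-positive patients, 0
#' otherwise). Controls are sampled once. The truth table records the
#' intended category per patient.
#'
#' @param design An [cohort_design()] object.
#' @param n_timepoints Number of timepoints (at least 2).
#' @param profiles Character vector of profiles, recycled over patients.
#' @return A list of class `ifn_cohort` with longitudinal `meta`
#'   (patient, timepoint) and truth carrying `planted_category`.
#' @export
generate_timecourse <- function(design, n_timepoints = 3L,
                                profiles = c("stable", "gain", "loss")) {
  stopifnot(inherits(design, "ifn_design"))
  if (n_timepoints < 2L) {
    stop_validation("a time course needs at least 2 timepoints")
  }
  bad <- setdiff(profiles, c("stable", "gain", "loss"))
  if (length(bad) > 0L) {
    stop_validation(paste0("unknown profile(s): ", paste(bad, collapse = ", ")))
  }
  universe <- make_signature_universe(design)
  profile <- rep_len(profiles, design$n_patients)
  ramp <- seq(0, 1, length.out = n_timepoints)
  withr::with_seed(design$seed, {
    n_pos <- round(design$fraction_positive * design$n_patients)
    base_positive <- seq_len(design$n_patients) <= n_pos
    activity <- rnorm(design$n_patients)
    sledai <- pmax(0L, as.integer(round(5 + 3 * activity)))
    pat <- tibble(patient = sprintf("sle%03d", seq_len(design$n_patients)),
                  profile = profile, base_positive = base_positive,
                  activity = activity, sledai = sledai)
    pat_frac <- draw_cell_fractions(design$n_patients, design)
    long <- tidyr::crossing(pat, timepoint = seq_len(n_timepoints)) %>%
      dplyr::mutate(
        induction_mult = dplyr::case_when(
          profile == "gain" ~ ramp[.data$timepoint],
          profile == "loss" ~ ramp[n_timepoints + 1L - .data$timepoint],
          TRUE ~ as.numeric(.data$base_positive)),
        sample = sprintf("%s_t%d", .data$patient, .data$timepoint),
        group = "SLE")
    long <- dplyr::bind_cols(long,
                             pat_frac[match(long$patient, pat$patient), ])
    ctrl <- tibble(sample = sprintf("ctrl%03d", seq_len(design$n_controls)),
                   group = "control", induction_mult = 0,
                   activity = rnorm(design$n_controls),
                   sledai = NA_integer_, patient = NA_character_,
                   timepoint = NA_integer_)
    ctrl <- dplyr::bind_cols(ctrl, draw_cell_fractions(design$n_controls,
                                                       design))
    samples <- dplyr::bind_rows(
      ctrl,
      long[, c("sample", "group", "induction_mult", "activity", "sledai",
               "patient", "timepoint", "monocyte", "t_cell", "b_cell")])
    samples$subject <- ifelse(is.na(samples$patient), samples$sample,
                              samples$patient)
    expr <- build_expression(design, universe, samples)
  })
  meta <- samples %>%
    dplyr::transmute(.data$sample, .data$group, .data$sledai, .data$patient,
                     .data$timepoint)
  truth <- long %>%
    dplyr::transmute(.data$patient, .data$sample, .data$timepoint,
                     planted_category = .data$profile,
                     .data$induction_mult, .data$sledai, .data$monocyte)
  structure(list(expr = expr, meta = meta, truth = truth,
                 signatures = universe$signatures,
                 modules = universe$modules, design = design),
            class = "ifn_cohort")
}

#' Write a simulated cohort to plain-text files
#'
#' @param cohort An `ifn_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             signatures = file.path(dir, "signatures.gmt"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(cohort$expr, paths[["expression"]])
  readr::write_tsv(cohort$meta, paths[["metadata"]], progress = FALSE)
  write_gmt(cohort$signatures, paths[["signatures"]])
  readr::write_tsv(cohort$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
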