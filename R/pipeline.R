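# Workflow orchestration: a validated configuration object holding every
# analysis constant, and run_workflow() chaining the stages into the named
# analyses with TSV outputs and a hash manifest.

#' Default pipeline configuration
#'
#' All analysis constants live here with their conventional values: the DE
#' filter (q < 0.2), the reference-signature filter (q < 0.01 with fold
#' change above 2), the SLEDAI activity cutoff (6), the positivity
#' multiplier (2 SD),
#' the trajectory threshold rule, the enrichment mode and minimum set size
#' (3), the Z significance thresholds (1.96 / 2.54) and the random-signature
#' size (100).
#'
#' @param ... Overrides of individual fields.
#' @return A list of class `ifn_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    schema_version = 1L,
    q_max_de = 0.2,
    q_max_signature = 0.01,
    fc_min = 2,
    sledai_cutoff = 6,
    positivity_sd_multiplier = 2,
    trajectory_threshold_rule = "max_control_sd",
    trajectory_fixed_threshold = 0.2,
    es_mode = "difference",
    min_set_size = 3L,
    z_threshold_95 = 1.96,
    z_threshold_99 = 2.54,
    z_exact_quantiles = FALSE,
    random_signature_size = 100L,
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    stop_validation(paste0("unknown config field(s): ",
                           paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  validate_config(structure(cfg, class = "ifn_config"))
}

validate_config <- function(cfg) {
  with(cfg, {
    if (q_max_de <= 0 || q_max_de > 1) stop_validation("q_max_de outside (0, 1]")
    if (q_max_signature <= 0 || q_max_signature > 1) {
      stop_validation("q_max_signature outside (0, 1]")
    }
    if (fc_min < 1) stop_validation("fc_min below 1")
    if (positivity_sd_multiplier <= 0) {
      stop_validation("positivity_sd_multiplier must be positive")
    }
    if (!es_mode %in% c("difference", "two_sided")) {
      stop_validation("es_mode must be 'difference' or 'two_sided'")
    }
    if (min_set_size < 1L) stop_validation("min_set_size below 1")
  })
  cfg
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path YAML file path.
#' @return [read_config()] returns an `ifn_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_config, cfg[setdiff(names(cfg), "schema_version")])
}

#' @rdname read_config
#' @param config An `ifn_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a named analysis workflow
#'
#' Executes the stages of the requested workflow in dependency order on a
#' simulated or loaded cohort, writes every result as TSV under `out_dir`
#' and returns a manifest of outputs with md5 hashes. Workflows: `simulate`
#' (cohort files only), `score`, `classify`, `effects`, `zscore`,
#' `timecourse`, `regress`, or `full` (all of the above on one cohort).
#'
#' @param name Workflow name.
#' @param config An [default_config()] object.
#' @param design Optional [cohort_design()]; defaults to
#'   `cohort_design(seed = config$seed)`.
#' @param out_dir Output directory.
#' @return A manifest tibble (stage, file, md5), invisibly structured as
#'   class `ifn_manifest`.
#' @export
run_workflow <- function(name = c("full", "simulate", "score", "classify",
                                  "effects", "zscore", "timecourse",
                                  "regress"),
                         config = default_config(),
                         design = NULL,
                         out_dir = tempfile("ifnsig_run_")) {
  name <- match.arg(name)
  config <- validate_config(config)
  design <- design %||% cohort_design(seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(stage, path) {
    manifest[[length(manifest) + 1L]] <<-
      tibble(stage = stage, file = basename(path),
             md5 = unname(tools::md5sum(path)))
  }

  if (name == "timecourse") {
    cohort <- generate_timecourse(design)
  } else {
    cohort <- generate_cohort(design)
  }
  for (f in write_cohort(cohort, out_dir)) add("simulate", f)

  if (name != "simulate") {
    scores <- score_signatures(cohort$expr, cohort$signatures,
                               es_mode = config$es_mode,
                               min_set_size = config$min_set_size)
    f <- file.path(out_dir, "scores.tsv")
    readr::write_tsv(tidy(scores), f, progress = FALSE)
    add("score", f)

    if (name %in% c("classify", "full", "timecourse")) {
      calls <- classify_positive(scores, cohort$meta,
                                 sd_multiplier = config$positivity_sd_multiplier)
      f <- file.path(out_dir, "positivity.tsv")
      readr::write_tsv(as_tibble(calls), f, progress = FALSE)
      add("classify", f)
    }
    if (name %in% c("effects", "full")) {
      eff <- rank_signatures_by_effect(scores, cohort$meta)
      f <- file.path(out_dir, "effects.tsv")
      readr::write_tsv(as_tibble(eff), f, progress = FALSE)
      add("effects", f)
    }
    if (name %in% c("zscore", "full")) {
      controls <- cohort$meta$sample[cohort$meta$group == "control"]
      patients <- cohort$meta$sample[cohort$meta$group == "SLE"]
      de <- moderated_de(cohort$expr, patients, controls)
      dominant <- names(design$delta)[which.max(design$delta)]
      ref <- tibble(gene = cohort$signatures[[dominant]]$up,
                    direction = 1, weight = 1)
      attr(ref, "reference") <- dominant
      zr <- activation_z(ref, de, q_max = config$q_max_de)
      f <- file.path(out_dir, "zscore.tsv")
      readr::write_tsv(as_tibble(zr), f, progress = FALSE)
      add("zscore", f)
    }
    if (name == "timecourse") {
      traj <- trajectory_analysis(
        scores, cohort$meta,
        threshold_rule = config$trajectory_threshold_rule,
        fixed_threshold = config$trajectory_fixed_threshold,
        sd_multiplier = config$positivity_sd_multiplier)
      f <- file.path(out_dir, "trajectories.tsv")
      readr::write_tsv(as_tibble(traj), f, progress = FALSE)
      add("timecourse", f)
    }
    if (name %in% c("regress", "full")) {
      ifn_core <- remove_overlap(cohort$signatures$IFN_Core,
                                 list(ifn_signature("mono",
                                                    cohort$modules$monocyte)))
      mono_sig <- ifn_signature("monocyte", cohort$modules$monocyte,
                                source = "simulated module")
      reg_scores <- score_signatures(cohort$expr,
                                     list(IFN_Core = ifn_core,
                                          monocyte = mono_sig),
                                     es_mode = config$es_mode,
                                     min_set_size = config$min_set_size)
      wide <- scores_wide(reg_scores) %>%
        dplyr::inner_join(cohort$meta, by = "sample") %>%
        dplyr::filter(.data$group == "SLE")
      reg <- regress_scores(wide, monocyte, IFN_Core)
      f <- file.path(out_dir, "regression.tsv")
      readr::write_tsv(as_tibble(reg), f, progress = FALSE)
      add("regress", f)
    }
  }
  out <- purrr::list_rbind(manifest)
  f <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(out, f, progress = FALSE)
  structure(out, class = c("ifn_manifest", class(out)), out_dir = out_dir)
}
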