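#' Pipeline run configuration
#'
#' Assembles and validates the options for [run_pipeline()]. Unknown
#' option names are an error (anti-typo). Inputs may be simulated
#' (`sim` config) or loaded from files (`genotype_file` as dosage TSV or
#' VCF, `summary_file`, `cohort_file`).
#'
#' @param out_dir Run directory for reports (created if missing).
#' @param stages Stages to run, a subset of
#'   `c("simulate", "qc", "prs", "predict", "brain", "mr")` in pipeline
#'   order, or `"all"`.
#' @param sim A [sim_config()] used by the simulate stage (`NULL` when
#'   all inputs come from files).
#' @param genotype_file,summary_file,cohort_file Optional input paths
#'   used instead of simulated data.
#' @param qc_preset `"adni"` or `"ukbb"` (see [qc_thresholds()]).
#' @param grid Threshold grid for the sweep.
#' @param n_perm Permutation count for threshold-selection correction
#'   (0 disables the correction stage).
#' @param horizon Follow-up horizon in years (1 or 10); selects the
#'   outcome column `converted_1yr` / `converted_10yr`.
#' @param fdr_family `"joint"` or `"per_measure"` (see [region_scan()]).
#' @param n_pcs Number of genotype principal components.
#' @param seed Integer seed recorded in the manifest; the simulate stage
#'   derives its stage seeds from it.
#' @param resume Reuse stage outputs already present in `out_dir`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            stages = "all",
                            sim = sim_config(seed = 1L),
                            genotype_file = NULL,
                            summary_file = NULL,
                            cohort_file = NULL,
                            qc_preset = "adni",
                            grid = seq(0.001, 1, by = 0.001),
                            n_perm = 0,
                            horizon = 1,
                            fdr_family = "joint",
                            n_pcs = 4,
                            seed = NULL,
                            resume = FALSE) {
  cfg <- as.list(environment())
  all_stages <- c("simulate", "qc", "prs", "predict", "brain", "mr")
  if (identical(cfg$stages, "all")) cfg$stages <- all_stages
  bad <- setdiff(cfg$stages, all_stages)
  if (length(bad)) {
    abort(paste("unknown stage(s):", paste(bad, collapse = ", ")),
          class = "neuroprs_config_error")
  }
  if (!cfg$horizon %in% c(1, 10)) {
    abort("horizon must be 1 or 10", class = "neuroprs_config_error")
  }
  if (!cfg$qc_preset %in% c("adni", "ukbb")) {
    abort("qc_preset must be 'adni' or 'ukbb'",
          class = "neuroprs_config_error")
  }
  if (!cfg$fdr_family %in% c("joint", "per_measure")) {
    abort("fdr_family must be 'joint' or 'per_measure'",
          class = "neuroprs_config_error")
  }
  for (f in c("genotype_file", "summary_file", "cohort_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort(sprintf("%s does not exist: %s", f, cfg[[f]]),
            class = "neuroprs_config_error")
    }
  }
  if (!is.null(cfg$sim)) {
    if (!is.null(cfg$seed)) cfg$sim$seed <- cfg$seed
    validate_sim_config(cfg$sim)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[neuroprs:%s] %s", stage, msg))
}

stage_error <- function(stage, err) {
  abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(err)),
        class = "neuroprs_stage_error", parent = err)
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in order — simulate (optional) ->
#' quality control -> PRS construction (align, clump, sweep, optional
#' permutation correction) -> conversion prediction -> brain-region
#' association scan -> Mendelian-randomization chain — writing each
#' stage's TSV/JSON reports into the run directory plus a `manifest.json`
#' recording the configuration, seed, package version and per-file MD5
#' checksums. With `resume = TRUE`, stages whose outputs already exist
#' are reloaded instead of recomputed. Any stage failure aborts with the
#' stage name.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(cfg$out_dir, paste0(...))
  st <- list()
  outcome <- sprintf("converted_%dyr", cfg$horizon)

  load_inputs <- function() {
    tryCatch({
      if (!is.null(cfg$genotype_file)) {
        st$panel <<- if (grepl("\\.vcf(\\.gz)?$", cfg$genotype_file)) {
          read_vcf_panel(cfg$genotype_file)
        } else read_dosage_tsv(cfg$genotype_file)
      }
      if (!is.null(cfg$summary_file)) {
        st$summary <<- read_gwas_summary(cfg$summary_file)
      }
      if (!is.null(cfg$cohort_file)) {
        st$cohort <<- read_cohort_tsv(cfg$cohort_file)
      }
    }, error = function(e) stage_error("load", e))
  }

  if ("simulate" %in% cfg$stages && is.null(cfg$genotype_file)) {
    tryCatch({
      files <- path(c("genotypes.tsv", "summary.tsv", "cohort.tsv"))
      if (cfg$resume && all(file.exists(files))) {
        pipeline_log("simulate", "reusing existing outputs")
        st$panel <- read_dosage_tsv(files[1])
        st$summary <- read_gwas_summary(files[2])
        st$cohort <- read_cohort_tsv(files[3])
      } else {
        pipeline_log("simulate", sprintf(
          "generating %d samples x %d variants (seed %s)",
          cfg$sim$n_target, cfg$sim$n_variants,
          cfg$sim$seed %||% "unset"))
        study <- simulate_study(cfg$sim)
        st$panel <- study$panel
        st$cohort <- study$cohort
        st$summary <- study$summary
        st$qc_labels <- study$qc_labels
        write_dosage_tsv(st$panel, files[1])
        write_gwas_summary(st$summary, files[2])
        write_cohort_tsv(st$cohort, files[3])
        write_sim_sidecar(cfg$sim, path("sim_config.json"))
      }
    }, error = function(e) stage_error("simulate", e))
  } else {
    load_inputs()
  }

  if ("qc" %in% cfg$stages) {
    tryCatch({
      if (is.null(st$panel)) abort("qc stage needs a genotype panel")
      thr <- qc_thresholds(cfg$qc_preset)
      vq <- filter_variants(st$panel, thr)
      sq <- filter_samples(vq$panel, st$cohort, thr)
      st$panel <- sq$panel
      if (!is.null(sq$cohort)) st$cohort <- sq$cohort
      pcs <- compute_pcs(st$panel, cfg$n_pcs)
      st$cohort <- dplyr::left_join(
        dplyr::select(st$cohort, -dplyr::any_of(names(pcs)[-1])),
        pcs, by = "sample_id")
      readr::write_tsv(vq$report, path("variant_qc.tsv"))
      readr::write_tsv(sq$report, path("sample_qc.tsv"))
      readr::write_tsv(pcs, path("pcs.tsv"))
      pipeline_log("qc", sprintf(
        "%d variants and %d samples retained",
        ncol(st$panel$dosage), nrow(st$panel$dosage)))
    }, error = function(e) stage_error("qc", e))
  }

  if ("prs" %in% cfg$stages) {
    tryCatch({
      if (is.null(st$panel) || is.null(st$summary) || is.null(st$cohort)) {
        abort("prs stage needs panel, summary statistics and cohort")
      }
      aligned <- align_alleles(st$summary, st$panel)
      clumped <- clump(aligned, st$panel)
      pipeline_log("prs", sprintf("%d aligned variants, %d after clumping",
                                  nrow(aligned), nrow(clumped)))
      st$profile <- sweep_and_select(
        st$panel, clumped, st$cohort, grid = cfg$grid, outcome = outcome)
      if (cfg$n_perm > 0) {
        st$profile <- permutation_correct(
          st$profile, n_perm = cfg$n_perm,
          seed = derive_seed(cfg$seed, 99L))
      }
      readr::write_tsv(st$profile$grid, path("prs_thresholds.tsv"))
      sc <- dplyr::mutate(st$profile$scores,
                          n_variants = st$profile$best_n_variants)
      readr::write_tsv(sc, path("prs_scores.tsv"))
      jsonlite::write_json(
        list(best_p_T = st$profile$best_p_T,
             best_r2 = st$profile$best_r2,
             best_n_variants = st$profile$best_n_variants,
             perm_p = st$profile$perm_p,
             n_perm = st$profile$n_perm),
        path("prs_best.json"), auto_unbox = TRUE, digits = NA,
        null = "null")
      pipeline_log("prs", sprintf("best p_T = %g (R2 = %.4f)",
                                  st$profile$best_p_T, st$profile$best_r2))
    }, error = function(e) stage_error("prs", e))
  }

  if ("predict" %in% cfg$stages) {
    tryCatch({
      if (is.null(st$profile)) abort("predict stage needs the prs stage")
      st$prediction <- analyze_conversion(st$profile, st$cohort,
                                          outcome = outcome)
      readr::write_tsv(tidy(st$prediction$logistic),
                       path("logistic_model.tsv"))
      readr::write_tsv(tidy(st$prediction$cox), path("cox_model.tsv"))
      readr::write_tsv(roc_points(st$prediction$logistic$linear_predictors,
                                  st$prediction$logistic$y),
                       path("roc_points.tsv"))
      groups <- dplyr::bind_rows(
        tibble::as_tibble(st$prediction$dichot$table) |>
          dplyr::mutate(split = "dichotomized"),
        tibble::as_tibble(st$prediction$trichot$table) |>
          dplyr::mutate(split = "trichotomized"))
      readr::write_tsv(groups, path("risk_groups.tsv"))
      pipeline_log("predict", sprintf("AUC = %.3f, Nagelkerke R2 = %.4f",
                                      st$prediction$logistic$auc,
                                      st$prediction$logistic$nagelkerke))
    }, error = function(e) stage_error("predict", e))
  }

  if ("brain" %in% cfg$stages) {
    tryCatch({
      if (is.null(st$profile)) abort("brain stage needs the prs stage")
      st$scan <- region_scan(st$cohort, st$profile,
                             fdr_family = cfg$fdr_family)
      readr::write_tsv(tibble::as_tibble(st$scan), path("region_assoc.tsv"))
      pipeline_log("brain", sprintf("%d / %d tests significant at q < 0.05",
                                    sum(st$scan$significant),
                                    nrow(st$scan)))
    }, error = function(e) stage_error("brain", e))
  }

  if ("mr" %in% cfg$stages) {
    tryCatch({
      if (is.null(st$scan)) abort("mr stage needs the brain stage")
      sig <- dplyr::filter(st$scan, .data$significant)
      st$mr <- mr_chain_report(st$profile, st$cohort,
                               sig[c("region", "measure")],
                               outcome = outcome)
      readr::write_tsv(st$mr, path("mr_report.tsv"))
      pipeline_log("mr", sprintf("%d region(s) tested", nrow(st$mr)))
    }, error = function(e) stage_error("mr", e))
  }

  manifest <- list(
    package = "neuroprs",
    version = as.character(utils::packageVersion("neuroprs")),
    seed = cfg$seed,
    stages = cfg$stages,
    config = cfg[c("qc_preset", "n_perm", "horizon", "fdr_family",
                   "n_pcs")],
    grid = list(min = min(cfg$grid), max = max(cfg$grid),
                n = length(cfg$grid)),
    sim = if (!is.null(cfg$sim)) unclass(cfg$sim),
    files = as.list(tools::md5sum(
      sort(list.files(cfg$out_dir, pattern = "\\.(tsv|json)$",
                      full.names = TRUE)))))
  names(manifest$files) <- basename(names(manifest$files))
  manifest$files$manifest.json <- NULL
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  st$out_dir <- cfg$out_dir
  invisible(st)
}
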