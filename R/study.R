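# Full-study orchestration: point process -> spatiotemporal graph ->
# components -> diversity metrics -> permutation / FDR / ANCOVA.

#' Analyse a cohort end to end
#'
#' Runs the full pipeline on an in-memory cohort: thresholds each subject's
#' series into a point process (skipped for binary input), extracts
#' structure-constrained connected components, pools them per group,
#' computes SD and STD at the global and eight system scales, runs the
#' subject-permutation test for every scale x metric (18 tests), applies
#' BH-FDR across the eight system tests separately for SD and STD, and fits
#' the three ANCOVAs (number, mean length, mean height of components on
#' group, age and their interaction).
#'
#' @param cohort An `st_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config A [study_config()] (or list / YAML path of overrides).
#' @return An `st_study` with elements `subject_summaries`, `design`,
#'   `group_metrics`, `tests` (permutation results incl. q-values),
#'   `ancova`, `config`, `config_hash`.
#' @export
analyze_cohort <- function(cohort, config = NULL) {
  stopifnot(inherits(cohort, "st_cohort"))
  cfg <- if (inherits(config, "study_config")) config else study_config(config)
  if (cohort$mode == "raster") cfg$binary_input <- TRUE
  labels <- cohort$labels
  sc <- cohort$sc

  ccsets <- vector("list", length(cohort$subjects))
  summaries <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    raster <- if (cfg$binary_input) {
      r <- s$activity
      storage.mode(r) <- "integer"
      r
    } else {
      zscore_threshold(s$activity, threshold = cfg$threshold,
                       sd_type = cfg$sd_type)
    }
    ccsets[[i]] <- subject_components(
      raster, sc, min_size = cfg$min_cc_size,
      sc_threshold = cfg$sc_threshold, include_self = cfg$include_self,
      subject_id = s$subject_id)
    summaries[[i]] <- cbind(
      data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
                 stringsAsFactors = FALSE),
      cc_summary(ccsets[[i]]))
  }
  summaries <- do.call(rbind, summaries)

  design <- study_design(ccsets, summaries, labels,
                         attribution_frac = cfg$attribution_frac)

  # per-group descriptive metrics at every scale
  grp <- summaries$group
  glev <- sort(unique(grp))
  group_metrics <- do.call(rbind, lapply(glev, function(g) {
    pool_g <- cc_pool(ccsets[grp == g], labels,
                      attribution_frac = cfg$attribution_frac)
    cbind(group = g, scale_metrics(pool_g, sd_variant = cfg$sd_variant,
                                   std_variant = cfg$std_variant))
  }))

  # permutation tests: global + 8 systems, for SD and STD
  scales <- c("global", SYSTEMS)
  tests <- vector("list", 2L * length(scales))
  k <- 0L
  for (metric in c("SD", "STD")) {
    for (scl in scales) {
      k <- k + 1L
      res <- tryCatch(
        permutation_test(design, metric = metric, scale = scl,
                         n_perm = cfg$n_perm, seed = cfg$seed + k,
                         sd_variant = cfg$sd_variant,
                         std_variant = cfg$std_variant),
        error = function(e) NULL)
      tests[[k]] <- if (is.null(res)) {
        data.frame(metric = metric, scale = scl, observed_A = NA_real_,
                   observed_B = NA_real_, observed_diff = NA_real_,
                   p = NA_real_, n_valid_perms = 0L,
                   flag = "insufficient_data", stringsAsFactors = FALSE)
      } else {
        data.frame(metric = metric, scale = scl,
                   observed_A = res$observed_A, observed_B = res$observed_B,
                   observed_diff = res$observed_diff, p = res$p_two_tailed,
                   n_valid_perms = res$n_valid_perms, flag = "",
                   stringsAsFactors = FALSE)
      }
    }
  }
  tests <- do.call(rbind, tests)
  # FDR across the 8 system tests, separately per metric family
  tests$q <- NA_real_
  for (metric in c("SD", "STD")) {
    sel <- tests$metric == metric & tests$scale != "global" &
      !is.na(tests$p)
    if (any(sel)) tests$q[sel] <- fdr_adjust(tests$p[sel])
  }

  ancova <- lapply(c("n_cc", "mean_length", "mean_height"), function(resp)
    tryCatch(cc_ancova(summaries, resp), error = function(e) e$message))
  names(ancova) <- c("n_cc", "mean_length", "mean_height")

  # hash only analysis-relevant parameters, never input/output paths
  cfg_plain <- unclass(cfg)
  cfg_plain$dir <- cfg_plain$out_dir <- NULL
  structure(list(subject_summaries = summaries, design = design,
                 group_metrics = group_metrics, tests = tests,
                 ancova = ancova, config = cfg,
                 config_hash = config_hash(cfg_plain)),
            class = "st_study")
}

#' Run a study from files
#'
#' Reads a cohort directory (manifest, labels, structural matrix, series),
#' analyses it with [analyze_cohort()], and writes the report to
#' `config$out_dir` when set.
#'
#' @param config A [study_config()] list or YAML path; `dir` must point at a
#'   cohort directory.
#' @return The `st_study`, invisibly when writing.
#' @export
run_study <- function(config) {
  cfg <- if (inherits(config, "study_config")) config else study_config(config)
  if (is.null(cfg$dir)) stopf("config$dir (cohort directory) is required")
  cohort <- read_cohort(cfg$dir)
  study <- analyze_cohort(cohort, cfg)
  if (!is.null(cfg$out_dir)) {
    write_study(study, cfg$out_dir)
    return(invisible(study))
  }
  study
}

#' Write a study report
#'
#' Emits `results.csv` (permutation tests with q-values), `ancova.csv`,
#' `group_metrics.csv`, `subjects.csv` and `report.yaml` (a reproducibility
#' block: seed, full configuration, config hash, package version). Outputs
#' are a pure function of inputs + seed, so re-running an unchanged study
#' reproduces them byte for byte.
#'
#' @param study An `st_study`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "st_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(
    cbind(d, config_hash = study$config_hash),
    file.path(out_dir, f), row.names = FALSE)
  wcsv(study$tests, "results.csv")
  anc <- do.call(rbind, lapply(names(study$ancova), function(nm) {
    a <- study$ancova[[nm]]
    if (!inherits(a, "ancova_result"))
      return(data.frame(response = nm, term = NA, F = NA, p = NA,
                        df_num = NA, df_den = NA, note = as.character(a)))
    cbind(response = nm, a$table, note = "")
  }))
  wcsv(anc, "ancova.csv")
  wcsv(study$group_metrics, "group_metrics.csv")
  wcsv(study$subject_summaries, "subjects.csv")
  cfg_rep <- unclass(study$config)
  cfg_rep$dir <- cfg_rep$out_dir <- NULL   # paths are not analysis inputs
  rep <- list(config = cfg_rep,
              config_hash = study$config_hash,
              package_version = as.character(utils::packageVersion("stconnectome")))
  yaml::write_yaml(rep, file.path(out_dir, "report.yaml"))
  invisible(out_dir)
}

#' @export
print.st_study <- function(x, ...) {
  cat(sprintf("Spatiotemporal connectome study: %d subjects, %d components\n",
              nrow(x$subject_summaries), x$design$pool$n_cc))
  glob <- x$tests[x$tests$scale == "global", ]
  for (i in seq_len(nrow(glob)))
    cat(sprintf("  global %s: A = %.4f, B = %.4f, p = %.4g\n",
                glob$metric[i], glob$observed_A[i], glob$observed_B[i],
                glob$p[i]))
  ht <- x$ancova$mean_height
  if (inherits(ht, "ancova_result")) {
    r <- ht$table[ht$table$term == "age", ]
    cat(sprintf("  ANCOVA height ~ age: F(%d, %d) = %.3f, p = %.4g\n",
                r$df_num, r$df_den, r$F, r$p))
  }
  invisible(x)
}
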