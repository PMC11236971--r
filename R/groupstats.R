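# Group inference: subject-level permutation tests on pooled SD/STD,
# BH-FDR across the eight functional systems, and ANCOVA of per-subject
# component characteristics on group and age.

#' Assemble a two-group study design
#'
#' Binds per-subject component sets to the subject manifest and builds the
#' master component pool used for observed and permuted group metrics. The
#' unit of exchangeability is the subject: whole component sets move between
#' groups together (components within a subject are dependent).
#'
#' @param ccsets List of `cc_set`, one per subject, in manifest order.
#' @param subjects data.frame with `subject_id`, `group` (two levels, "A"
#'   treated as first), `age`.
#' @param labels Parcellation.
#' @param attribution_frac 20% rule threshold for the system scales.
#' @return A `study_design`.
#' @export
study_design <- function(ccsets, subjects, labels, attribution_frac = 0.20) {
  stopifnot(is.list(ccsets), length(ccsets) == nrow(subjects))
  if (length(unique(subjects$group)) != 2L)
    stopf("exactly two groups required, got: %s",
          paste(unique(subjects$group), collapse = ", "))
  if (any(!is.finite(subjects$age) | subjects$age <= 0))
    stopf("ages must be finite and positive")
  pool <- cc_pool(ccsets, labels, attribution_frac = attribution_frac)
  cc_by_subject <- split(seq_len(pool$n_cc),
                         factor(pool$subject, levels = subjects$subject_id))
  structure(list(pool = pool, subjects = subjects,
                 cc_by_subject = cc_by_subject, ccsets = ccsets,
                 labels = labels),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("Study design: %d subjects (%s), %d pooled components\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$pool$n_cc))
  invisible(x)
}

metric_on_idx <- function(pool, idx, metric, sd_variant, std_variant) {
  if (metric == "SD") pool_sd_value(pool, idx, sd_variant)
  else pool_std_value(pool, idx, std_variant)
}

#' Subject-permutation test for a pooled group metric
#'
#' Computes the observed SD or STD difference between the two groups' pooled
#' components at the requested scale, then builds the null distribution by
#' reassigning whole subjects to groups (preserving group sizes) and
#' re-pooling. The two-tailed p-value uses add-one smoothing:
#' `p = (1 + #\{|diff_perm| >= |diff_obs|\}) / (n_valid + 1)`. Permutations
#' in which a pooled metric is undefined (e.g. an empty sub-pool) are
#' dropped and counted in `n_valid_perms`.
#'
#' @param design A [study_design()].
#' @param metric `"SD"` or `"STD"`.
#' @param scale `"global"` or a functional system name.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the permutation stream.
#' @param sd_variant,std_variant Metric variants (see [system_diversity()],
#'   [spatiotemporal_diversity()]).
#' @param method `"permutation"` (default, label permutation without
#'   replacement) or `"bootstrap"` (groups resampled with replacement).
#' @return A `permutation_result`.
#' @export
permutation_test <- function(design, metric = c("SD", "STD"),
                             scale = "global", n_perm = 1000L, seed = 1L,
                             sd_variant = "mean_cc",
                             std_variant = "region_pairs",
                             method = c("permutation", "bootstrap")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  stopifnot(inherits(design, "study_design"))
  if (!scale %in% c("global", SYSTEMS))
    stopf("unknown scale '%s'", scale)
  pool <- design$pool
  scale_idx <- if (scale == "global") seq_len(pool$n_cc) else
    which(pool$attrib[, scale])
  per_subj <- lapply(design$cc_by_subject, intersect, x = scale_idx)

  groups <- design$subjects$group
  is_a <- groups == sort(unique(groups))[1L]
  idx_of <- function(subj_sel) unlist(per_subj[subj_sel], use.names = FALSE)
  obs_a <- metric_on_idx(pool, idx_of(is_a), metric, sd_variant, std_variant)
  obs_b <- metric_on_idx(pool, idx_of(!is_a), metric, sd_variant, std_variant)
  if (is.na(obs_a) || is.na(obs_b))
    stopf("insufficient data: %s undefined on an observed pool (scale %s)",
          metric, scale)
  obs_diff <- obs_a - obs_b
  n_subj <- length(is_a)
  n_a <- sum(is_a)

  diffs <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    if (method == "permutation") {
      sel <- logical(n_subj)
      sel[sample.int(n_subj, n_a)] <- TRUE
    } else {
      sel <- logical(n_subj)
      # bootstrap: resample subject indices with replacement per group
      a_ids <- sample.int(n_subj, n_a, replace = TRUE)
      b_ids <- sample.int(n_subj, n_subj - n_a, replace = TRUE)
      va <- metric_on_idx(pool, unlist(per_subj[a_ids], use.names = FALSE),
                          metric, sd_variant, std_variant)
      vb <- metric_on_idx(pool, unlist(per_subj[b_ids], use.names = FALSE),
                          metric, sd_variant, std_variant)
      return(va - vb)
    }
    va <- metric_on_idx(pool, idx_of(sel), metric, sd_variant, std_variant)
    vb <- metric_on_idx(pool, idx_of(!sel), metric, sd_variant, std_variant)
    va - vb
  }, numeric(1)))

  valid <- diffs[!is.na(diffs)]
  n_valid <- length(valid)
  if (!n_valid) stopf("no valid permutation produced a defined metric")
  p <- (1 + sum(abs(valid) >= abs(obs_diff))) / (n_valid + 1)
  structure(list(scale = scale, metric = metric,
                 observed_A = obs_a, observed_B = obs_b,
                 observed_diff = obs_diff, p_two_tailed = p,
                 n_perm = n_perm, n_valid_perms = n_valid,
                 n_dropped = n_perm - n_valid, seed = seed,
                 method = method), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "%s [%s]: A = %.4f, B = %.4f, diff = %+.4f, p = %.4g (%d/%d valid perms)\n",
    x$metric, x$scale, x$observed_A, x$observed_B, x$observed_diff,
    x$p_two_tailed, x$n_valid_perms, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values for a family of p-values (typically the eight
#' per-system tests of one metric). Monotone, each q >= its raw p, capped
#' at 1.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order.
#' @export
fdr_adjust <- function(pvals) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' ANCOVA of a per-subject component characteristic on group and age
#'
#' Ordinary least squares of `response ~ group + age + group:age` with
#' effect-coded group (+1/-1) and mean-centered age, tested with Type-III
#' marginal F tests, so the degrees-of-freedom structure is
#' `F(1, n - 4)` for every term regardless of group imbalance. Subjects with
#' an undefined response (e.g. no retained component, so mean length is
#' undefined) are excluded and counted.
#'
#' @param data data.frame with columns `subject_id`, `group` (two levels),
#'   `age`, and the response column.
#' @param response Name of the response column (`"n_cc"`, `"mean_length"`,
#'   `"mean_height"` in the standard pipeline).
#' @return An `ancova_result` with a `table` of F, p, df per term.
#' @export
cc_ancova <- function(data, response) {
  if (!response %in% names(data))
    stopf("response column '%s' not found", response)
  y <- data[[response]]
  keep <- is.finite(y)
  n_excluded <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  if (length(unique(d$group)) != 2L || min(table(d$group)) < 2L)
    stopf("need >= 2 subjects per group with a defined response")
  g <- ifelse(d$group == sort(unique(d$group))[1L], 1, -1)
  a <- d$age - mean(d$age)
  yv <- d[[response]]
  fit <- stats::lm(yv ~ g + a + g:a)
  if (any(is.na(stats::coef(fit))))
    stopf("rank-deficient design (collinear group/age)")
  if (stats::var(yv) == 0) {
    # degenerate: a constant response carries no effect of any term
    tab <- data.frame(term = c("group", "age", "group:age"),
                      F = 0, p = 1, df_num = 1L,
                      df_den = fit$df.residual, row.names = NULL)
  } else {
    # drop1 warns on near-zero residual variance; the F/p values are still
    # the correct limits, so silence that specific nuisance warning
    dr <- withCallingHandlers(
      stats::drop1(fit, ~ g + a + g:a, test = "F"),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    terms <- c("g", "a", "g:a")
    tab <- data.frame(
      term = c("group", "age", "group:age"),
      F = dr[terms, "F value"],
      p = dr[terms, "Pr(>F)"],
      df_num = dr[terms, "Df"],
      df_den = fit$df.residual,
      row.names = NULL)
  }
  structure(list(response = response, table = tab,
                 n_subjects = nrow(d), n_excluded = n_excluded,
                 fit = fit), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA: %s ~ group + age + group:age (n = %d, %d excluded)\n",
              x$response, x$n_subjects, x$n_excluded))
  with(x$table, for (i in seq_along(term))
    cat(sprintf("  %-10s F(%d, %d) = %8.4f, p = %.4g\n",
                term[i], df_num[i], df_den[i], F[i], p[i])))
  invisible(x)
}
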