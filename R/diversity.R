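# System Diversity (SD) and Spatiotemporal Diversity (STD) on pools of
# connected components. Both are group-level measures: single subjects
# rarely provide enough components for stable estimates.

#' Functional-system embedding of a component
#'
#' Sums the component's spatial activation counts within each of the eight
#' functional systems, giving the 8-long activation-mass vector that SD and
#' STD operate on. Mass is conserved: the entries sum to the component size.
#'
#' @param cc A `cc` component.
#' @param labels Parcellation covering every involved region.
#' @param sysidx Precomputed integer system index (internal fast path; overrides
#'   `labels`).
#' @return Named numeric vector of length 8 (order of
#'   [functional_systems()]).
#' @export
embed_systems <- function(cc, labels = NULL, sysidx = NULL) {
  if (is.null(sysidx)) {
    if (is.null(labels)) stopf("either 'labels' or 'sysidx' is required")
    sysidx <- system_index(labels)
  }
  if (max(cc$regions) > length(sysidx))
    stopf("component involves region %d beyond the %d labelled regions",
          max(cc$regions), length(sysidx))
  mass <- numeric(8L)
  s <- sysidx[cc$regions]
  for (k in seq_along(s)) mass[s[k]] <- mass[s[k]] + cc$x_counts[k]
  names(mass) <- SYSTEMS
  mass
}

#' Attribute a component to functional systems (20% rule)
#'
#' A component is attributed to every system containing at least `frac` of
#' its involved regions (distinct regions with positive activation count).
#' The maximal-share system is always included, so no component is orphaned
#' at the system scale even when every share falls below `frac`.
#'
#' @param cc A `cc` component.
#' @param labels Parcellation.
#' @param frac Attribution threshold on the share of involved regions
#'   (default 0.20).
#' @param sysidx Precomputed system index (overrides `labels`).
#' @return Character vector of system names (possibly several).
#' @export
attribute_systems <- function(cc, labels = NULL, frac = 0.20, sysidx = NULL) {
  if (is.null(sysidx)) sysidx <- system_index(labels)
  share <- tabulate(sysidx[cc$regions], 8L) / length(cc$regions)
  hit <- share >= frac
  hit[which.max(share)] <- TRUE
  SYSTEMS[hit]
}

#' Pool components across subjects
#'
#' Concatenates the retained components of one or more subjects into a
#' `cc_pool`, precomputing the per-component system embeddings, their unit
#' (L2) normalizations, normalized entropies, the region-component
#' incidence used by STD, and the 20%-rule attribution matrix. All SD/STD
#' evaluation and permutation re-pooling work off these caches.
#'
#' @param ccsets A `cc_set` or list of `cc_set` (one per subject).
#' @param labels Parcellation shared by all subjects.
#' @param attribution_frac Threshold for [attribute_systems()].
#' @return A `cc_pool`.
#' @export
cc_pool <- function(ccsets, labels, attribution_frac = 0.20) {
  if (inherits(ccsets, "cc_set")) ccsets <- list(ccsets)
  validate_parcellation(labels)
  sysidx <- system_index(labels)
  comps <- unlist(lapply(ccsets, `[[`, "components"), recursive = FALSE)
  n_cc <- length(comps)
  subject <- vapply(comps, `[[`, character(1), "subject_id")

  mass <- matrix(0, n_cc, 8L, dimnames = list(NULL, SYSTEMS))
  attrib <- matrix(FALSE, n_cc, 8L, dimnames = list(NULL, SYSTEMS))
  ent <- numeric(n_cc)
  inc_region <- vector("list", n_cc)
  for (ci in seq_len(n_cc)) {
    cc <- comps[[ci]]
    m <- embed_systems(cc, sysidx = sysidx)
    mass[ci, ] <- m
    p <- m[m > 0] / sum(m)
    ent[ci] <- -sum(p * log(p)) / log(8)
    share <- tabulate(sysidx[cc$regions], 8L) / length(cc$regions)
    a <- share >= attribution_frac
    a[which.max(share)] <- TRUE
    attrib[ci, ] <- a
    inc_region[[ci]] <- cc$regions
  }
  norms <- sqrt(rowSums(mass^2))
  unit <- mass / ifelse(norms > 0, norms, 1)
  structure(list(
    components = comps, subject = subject, n_cc = n_cc,
    n_regions = if (length(ccsets)) ccsets[[1L]]$n_regions else nrow(labels),
    mass = mass, unit = unit, entropy = ent, attrib = attrib,
    region = unlist(inc_region, use.names = FALSE),
    region_cc = rep.int(seq_len(n_cc), lengths(inc_region)),
    attribution_frac = attribution_frac,
    labels = labels), class = "cc_pool")
}

#' @export
print.cc_pool <- function(x, ...) {
  cat(sprintf(
    "Component pool: %d components from %d subjects, %d regions\n",
    x$n_cc, length(unique(x$subject)), x$n_regions))
  invisible(x)
}

# --- fast metric kernels on a pool restricted to component indices --------

pool_sd_value <- function(pool, idx, variant = "mean_cc") {
  if (!length(idx)) return(NA_real_)
  if (variant == "pooled_hist") {
    m <- colSums(pool$mass[idx, , drop = FALSE])
    p <- m[m > 0] / sum(m)
    return(-sum(p * log(p)) / log(8))
  }
  mean(pool$entropy[idx])
}

pool_std_value <- function(pool, idx, variant = "region_pairs") {
  if (length(idx) < 2L) return(NA_real_)
  u <- pool$unit[idx, , drop = FALSE]
  if (variant == "all_pairs") {
    k <- nrow(u)
    s <- colSums(u)
    mean_cos <- (sum(s^2) - k) / (k * (k - 1))
    return(min(max(1 - mean_cos, 0), 1))
  }
  sel <- pool$region_cc %in% idx
  if (!any(sel)) return(NA_real_)
  reg <- pool$region[sel]
  rows <- match(pool$region_cc[sel], idx)
  s <- rowsum(u[rows, , drop = FALSE], reg)
  k <- as.vector(rowsum(rep(1, length(reg)), reg))
  qual <- k >= 2L
  if (!any(qual)) return(NA_real_)
  sumsq <- rowSums(s[qual, , drop = FALSE]^2)
  kk <- k[qual]
  mean_cos <- (sumsq - kk) / (kk * (kk - 1))
  mean(pmin(pmax(1 - mean_cos, 0), 1))
}

pool_std_n_regions <- function(pool, idx) {
  sel <- pool$region_cc %in% idx
  if (!any(sel)) return(0L)
  k <- as.vector(rowsum(rep(1, sum(sel)), pool$region[sel]))
  sum(k >= 2L)
}

diversity_value <- function(scale, metric, value, n_cc_used,
                            n_regions_used = NA_integer_) {
  structure(list(scale = scale, metric = metric, value = value,
                 n_cc_used = n_cc_used, n_regions_used = n_regions_used),
            class = "diversity_value")
}

#' @export
print.diversity_value <- function(x, ...) {
  cat(sprintf("%s [%s] = %.4f (n_cc = %d%s)\n", x$metric, x$scale, x$value,
              x$n_cc_used,
              if (is.na(x$n_regions_used)) ""
              else sprintf(", n_regions = %d", x$n_regions_used)))
  invisible(x)
}

#' System Diversity of a component pool
#'
#' Per component, the activation mass across the eight functional systems is
#' normalized to a distribution and its Shannon entropy taken (natural log,
#' normalized by `log(8)` to \[0, 1\]); SD is the unweighted mean of these
#' per-component entropies over the pool. SD = 0 iff every component is
#' confined to a single system; SD = 1 requires every component to spread
#' its mass evenly over all eight. Higher SD means more cross-system
#' integration.
#'
#' @param pool A `cc_pool` (optionally pre-restricted; see [scale_metrics()]
#'   for the per-system scales).
#' @param variant `"mean_cc"` (default: mean of per-component entropies) or
#'   `"pooled_hist"` (entropy of the pooled system histogram).
#' @param scale Label stored in the result (default `"global"`).
#' @return A `diversity_value`.
#' @export
system_diversity <- function(pool, variant = c("mean_cc", "pooled_hist"),
                             scale = "global") {
  variant <- match.arg(variant)
  stopifnot(inherits(pool, "cc_pool"))
  if (pool$n_cc == 0L)
    stopf("insufficient data: empty component pool")
  diversity_value(scale, "SD",
                  pool_sd_value(pool, seq_len(pool$n_cc), variant),
                  n_cc_used = pool$n_cc)
}

#' Spatiotemporal Diversity of a component pool
#'
#' For each region participating in at least two components of the pool, the
#' mean pairwise cosine similarity between the unit system embeddings of its
#' components is computed (via the closed form
#' `(||sum u||^2 - n) / (n (n - 1))`), and subtracted from 1; STD is the
#' mean of this dissimilarity over qualifying regions. STD = 0 when every
#' region's components share one embedding direction (perfectly stable
#' system composition over time); values near 1 indicate that regions keep
#' re-appearing in components of very different system composition. Lower
#' STD therefore means higher neural stability.
#'
#' @param pool A `cc_pool`.
#' @param variant `"region_pairs"` (default, region-anchored) or
#'   `"all_pairs"` (all component pairs in the pool, ignoring region
#'   sharing).
#' @param scale Label stored in the result.
#' @return A `diversity_value`.
#' @export
spatiotemporal_diversity <- function(pool,
                                     variant = c("region_pairs", "all_pairs"),
                                     scale = "global") {
  variant <- match.arg(variant)
  stopifnot(inherits(pool, "cc_pool"))
  idx <- seq_len(pool$n_cc)
  val <- pool_std_value(pool, idx, variant)
  if (is.na(val))
    stopf("insufficient data: no region participates in >= 2 components")
  diversity_value(scale, "STD", val, n_cc_used = pool$n_cc,
                  n_regions_used = pool_std_n_regions(pool, idx))
}

#' SD and STD at the global and functional-system scales
#'
#' Computes SD and STD on the whole pool (global scale) and on the
#' eight per-system sub-pools defined by the 20% attribution rule. Sub-pools
#' too small for a metric yield `NA` with `flag = "insufficient_data"`
#' rather than an error.
#'
#' @param pool A `cc_pool`.
#' @param sd_variant,std_variant Passed to [system_diversity()] and
#'   [spatiotemporal_diversity()].
#' @return data.frame with columns `scale`, `metric`, `value`, `n_cc_used`,
#'   `n_regions_used`, `flag`.
#' @export
scale_metrics <- function(pool, sd_variant = "mean_cc",
                          std_variant = "region_pairs") {
  stopifnot(inherits(pool, "cc_pool"))
  scales <- c("global", SYSTEMS)
  out <- vector("list", 2L * length(scales))
  k <- 0L
  for (sc in scales) {
    idx <- if (sc == "global") seq_len(pool$n_cc) else
      which(pool$attrib[, sc])
    for (metric in c("SD", "STD")) {
      k <- k + 1L
      val <- if (metric == "SD") pool_sd_value(pool, idx, sd_variant)
             else pool_std_value(pool, idx, std_variant)
      out[[k]] <- data.frame(
        scale = sc, metric = metric, value = val,
        n_cc_used = length(idx),
        n_regions_used = if (metric == "STD" && length(idx))
          pool_std_n_regions(pool, idx) else NA_integer_,
        flag = if (is.na(val)) "insufficient_data" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
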