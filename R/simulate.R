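#' Simulation parameters for a synthetic two-group study
#'
#' Collects every knob of the synthetic cohort generator. Defaults dimension
#' the study like the target application: 506 regions split over the eight
#' functional systems, 720 frames per subject, and two groups of 42 and 45
#' subjects aged 4.6-18 years. Cascade dynamics (rate, spread, persistence)
#' are set to yield sparse transient events involving a few percent of
#' regions per frame.
#'
#' The planted group contrasts work through three parameters:
#' * `cross_system_coupling` (eta): multiplier in \[0,1\] on `spread_prob`
#'   for between-system structural edges. Higher eta produces more
#'   cross-system components and hence higher System Diversity.
#' * `drift_prob` (rho): per-cascade per-frame probability that the cascade
#'   re-seeds onto a structurally adjacent region of a different system.
#'   Higher rho makes the system composition of events less reproducible,
#'   raising Spatiotemporal Diversity.
#' * `age_map$age_effect`: log-linear coefficient shrinking each cascade's
#'   maximum spatial extent with age (extent cap =
#'   `max_extent * exp(age_effect * (age - age_ref))`), so a negative value
#'   plants an age effect on component height.
#'
#' @param n_regions Number of regions N.
#' @param regions_per_system Length-8 integer vector summing to `n_regions`.
#' @param p_in,p_out Within-/between-system structural edge probabilities.
#' @param n_subjects_A,n_subjects_B Group sizes.
#' @param n_frames Frames per subject T.
#' @param event_rate Expected number of new cascade seeds per frame
#'   (Poisson). Default `0.002 * n_regions`: a constant per-region seeding
#'   rate, so reduced-size studies keep the same activation sparsity as the
#'   full 506-region default (a few percent of cells active, matching the
#'   tail mass selected by the 2 SD point-process threshold).
#' @param spread_prob Per-edge per-frame propagation probability.
#' @param cross_system_coupling Multiplier on `spread_prob` across systems.
#' @param persist_prob Per-active-region per-frame survival probability.
#' @param drift_prob Per-cascade per-frame re-seeding probability.
#'   `spread_prob`, `cross_system_coupling`, `persist_prob` and `drift_prob`
#'   may each be length 2 (group A, group B) to plant a group contrast; a
#'   single value applies to both groups.
#' @param max_extent Baseline cap on the number of distinct regions a single
#'   cascade may involve.
#' @param age_map List with `ages` (optional explicit ages, length
#'   `n_subjects_A + n_subjects_B`, group A first), `age_effect` (default 0),
#'   `age_ref` (centering age, default 10), and `age_range` used to draw ages
#'   uniformly when `ages` is NULL (default c(4.6, 18)).
#' @param noise_sd Gaussian noise SD for BOLD mode, in units of the
#'   (unit-peak) haemodynamic kernel.
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   parameter set including this seed.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_regions = 506L,
                       regions_per_system = c(66L, 66L, 60L, 60L, 50L, 70L,
                                              90L, 44L),
                       p_in = 0.35, p_out = 0.05,
                       n_subjects_A = 42L, n_subjects_B = 45L,
                       n_frames = 720L,
                       event_rate = NULL,
                       spread_prob = 0.25,
                       cross_system_coupling = 0.1,
                       persist_prob = 0.5,
                       drift_prob = 0.05,
                       max_extent = NULL,
                       age_map = list(),
                       noise_sd = 0.1,
                       seed = 1L) {
  p <- list(
    n_regions = check_count(n_regions, "n_regions"),
    regions_per_system = as.integer(regions_per_system),
    p_in = check_prob(p_in, "p_in"),
    p_out = check_prob(p_out, "p_out"),
    n_subjects_A = check_count(n_subjects_A, "n_subjects_A"),
    n_subjects_B = check_count(n_subjects_B, "n_subjects_B"),
    n_frames = check_count(n_frames, "n_frames", min = 2L),
    event_rate = event_rate %||% (0.002 * n_regions),
    spread_prob = check_prob2(spread_prob, "spread_prob"),
    cross_system_coupling = check_prob2(cross_system_coupling,
                                        "cross_system_coupling"),
    persist_prob = check_prob2(persist_prob, "persist_prob"),
    drift_prob = check_prob2(drift_prob, "drift_prob"),
    max_extent = max_extent %||% max(3L, round(0.12 * n_regions)),
    age_map = utils::modifyList(
      list(ages = NULL, age_effect = 0, age_ref = 10,
           age_range = c(4.6, 18)), age_map),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (length(p$regions_per_system) != 8L ||
      sum(p$regions_per_system) != p$n_regions)
    stopf("regions_per_system must have 8 entries summing to n_regions")
  if (!is.numeric(p$event_rate) || p$event_rate < 0)
    stopf("'event_rate' must be >= 0")
  if (!is.null(p$age_map$ages) &&
      length(p$age_map$ages) != p$n_subjects_A + p$n_subjects_B)
    stopf("age_map$ages must have one age per subject (group A first)")
  class(p) <- "sim_params"
  p
}

#' Haemodynamic impulse response used in BOLD mode
#'
#' Difference of two gamma densities sampled at the frame rate, normalized
#' to unit peak: rises to its peak one frame after the event and undershoots
#' afterwards. A fixed configuration constant; only its peak-recovery
#' behaviour under the z >= 2 point process matters downstream.
#'
#' @param len Kernel length in frames.
#' @return Numeric vector of length `len` with `max(.) == 1`.
#' @export
bold_kernel <- function(len = 15L) {
  k <- seq_len(len) - 1L
  h <- stats::dgamma(k, shape = 2, rate = 2) -
    0.25 * stats::dgamma(k, shape = 6, rate = 2)
  h / max(h)
}

# Per-group view of possibly length-2 (A, B) cascade parameters.
group_view <- function(params, grp) {
  gi <- if (identical(grp, "B")) 2L else 1L
  for (f in c("spread_prob", "cross_system_coupling", "persist_prob",
              "drift_prob"))
    params[[f]] <- params[[f]][min(gi, length(params[[f]]))]
  params
}

# One subject's binary raster. Cascades spread only along binarized
# structural edges, so every same-cascade co-activation is backed by a
# structural path (ground truth for component extraction).
simulate_raster <- function(nbrs, sysidx, params, extent_cap) {
  n <- length(sysidx)
  t_total <- params$n_frames
  raster <- matrix(0L, n, t_total)
  cascades <- list()   # each: list(active, involved)
  sp <- params$spread_prob
  eta <- params$cross_system_coupling

  for (t in seq_len(t_total)) {
    nxt <- list()
    for (cs in cascades) {
      if (cs$dormant > 0L) {
        # silent gap frame after a drift re-seed: breaks temporal adjacency,
        # so the drifted continuation forms a new component
        cs$dormant <- cs$dormant - 1L
        if (cs$dormant == 0L) {
          cs$active <- cs$pending
          cs$involved <- unique(c(cs$involved, cs$pending))
        }
        nxt[[length(nxt) + 1L]] <- cs
        next
      }
      act <- cs$active
      surv <- act[stats::runif(length(act)) < params$persist_prob]
      # propagation along structural edges; recruitment outside the
      # cascade's home system is damped by the cross-system coupling
      dst <- unlist(nbrs[act], use.names = FALSE)
      newact <- integer(0)
      if (length(dst)) {
        p_edge <- ifelse(sysidx[dst] == cs$home, sp, sp * eta)
        newact <- unique(dst[stats::runif(length(dst)) < p_edge])
      }
      # only never-involved regions can be recruited: the cascade is a
      # growing front that stalls at the extent cap (or when its home
      # neighbourhood is exhausted) and then decays at the persistence rate,
      # so every event has finite duration and bounded spatial extent
      involved <- cs$involved
      fresh <- setdiff(newact, involved)
      room <- extent_cap - length(involved)
      if (length(fresh) > room)
        fresh <- if (room > 0L) fresh[sample.int(length(fresh), room)]
                 else integer(0)
      active <- unique(c(surv, fresh))
      # drift: the cascade re-homes to the system of a structurally adjacent
      # region and goes silent for one frame (breaking temporal adjacency);
      # the continuation keeps one old active region, so the same regions
      # recur in a component whose composition is dominated by the new home
      if (length(act) && stats::runif(1) < params$drift_prob) {
        cand <- if (length(dst)) unique(dst[sysidx[dst] != cs$home])
                else integer(0)
        if (length(cand)) {
          jump <- cand[sample.int(length(cand), 1L)]
          pend <- unique(c(jump, act[sample.int(length(act), 1L)]))
          nxt[[length(nxt) + 1L]] <- list(active = integer(0),
                                          involved = pend, home = sysidx[jump],
                                          dormant = 1L, pending = pend)
          next
        }
      }
      if (length(active))
        nxt[[length(nxt) + 1L]] <- list(active = active, involved =
                                          unique(c(involved, active)),
                                        home = cs$home,
                                        dormant = 0L, pending = integer(0))
    }
    # new seeds this frame
    n_new <- stats::rpois(1L, params$event_rate)
    if (n_new > 0L) {
      seeds <- sample.int(n, min(n_new, n))
      for (s in seeds)
        nxt[[length(nxt) + 1L]] <- list(active = s, involved = s,
                                        home = sysidx[s],
                                        dormant = 0L, pending = integer(0))
    }
    cascades <- nxt
    if (length(cascades)) {
      on_now <- unique(unlist(lapply(cascades, `[[`, "active"),
                              use.names = FALSE))
      if (length(on_now)) raster[on_now, t] <- 1L
    }
  }
  raster
}

#' Generate a synthetic two-group cohort
#'
#' Simulates per-subject regional activity as structure-constrained cascades:
#' events seed at random regions, spread along binarized structural edges
#' (damped by `cross_system_coupling` across systems), persist, occasionally
#' drift into another system, and die out. In `"raster"` mode the binary
#' point process itself is returned; in `"bold"` mode the raster is convolved
#' with a fixed haemodynamic kernel ([bold_kernel()]) and Gaussian noise of
#' SD `noise_sd` is added, emulating the continuous signal the point-process
#' stage consumes.
#'
#' @param params A [sim_params()] object.
#' @param labels Parcellation (defaults to a fresh one drawn from `params`).
#' @param sc Structural connectome (defaults likewise).
#' @param mode `"raster"` or `"bold"`.
#' @return An `st_cohort` list: `subjects` (each with `subject_id`, `group`,
#'   `age`, `activity` matrix N x T), `labels`, `sc`, `params`, `mode`.
#' @export
generate_cohort <- function(params, labels = NULL, sc = NULL,
                            mode = c("raster", "bold")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "sim_params"))
  if (is.null(labels))
    labels <- generate_parcellation(params$n_regions,
                                    params$regions_per_system,
                                    seed = params$seed)
  validate_parcellation(labels)
  if (is.null(sc))
    sc <- generate_structural_connectome(labels, params$p_in, params$p_out,
                                         seed = params$seed + 1L)
  if (is.matrix(sc)) sc <- structural_connectome(sc)
  if (nrow(sc$adjacency) != nrow(labels))
    stopf("structural connectome (%d) and labels (%d) disagree on N",
          nrow(sc$adjacency), nrow(labels))
  if (nrow(labels) != params$n_regions)
    stopf("labels (%d regions) inconsistent with params n_regions = %d",
          nrow(labels), params$n_regions)

  b <- binarize_sc(sc)
  nbrs <- apply(b, 1L, which, simplify = FALSE)
  sysidx <- system_index(labels)
  n_tot <- params$n_subjects_A + params$n_subjects_B
  groups <- rep(c("A", "B"), c(params$n_subjects_A, params$n_subjects_B))
  am <- params$age_map
  kern <- bold_kernel()

  draws <- with_seed(params$seed, list(
    ages = am$ages %||% stats::runif(n_tot, am$age_range[1],
                                     am$age_range[2]),
    # one sub-stream per subject, so a subject's raster is identical in
    # raster and bold modes and independent of the other subjects
    subj_seeds = sample.int(2147483000L, n_tot)))
  ages <- draws$ages
  subjects <- lapply(seq_len(n_tot), function(i) {
    with_seed(draws$subj_seeds[i], {
      cap <- max(1L, as.integer(round(
        params$max_extent * exp(am$age_effect * (ages[i] - am$age_ref)))))
      ras <- simulate_raster(nbrs, sysidx, group_view(params, groups[i]), cap)
      act <- if (mode == "bold") {
        sig <- matrix(0, nrow(ras), ncol(ras))
        for (k in seq_along(kern)) {
          idx <- k:ncol(ras)
          sig[, idx] <- sig[, idx] +
            kern[k] * ras[, seq_len(ncol(ras) - k + 1L), drop = FALSE]
        }
        sig + matrix(stats::rnorm(length(sig), 0, params$noise_sd),
                     nrow(sig), ncol(sig))
      } else ras
      list(subject_id = sprintf("sub-%s%03d", groups[i], i),
           group = groups[i], age = ages[i], activity = act)
    })
  })
  structure(list(subjects = subjects, labels = labels, sc = sc,
                 params = params, mode = mode),
            class = "st_cohort")
}

#' @export
print.st_cohort <- function(x, ...) {
  ga <- sum(vapply(x$subjects, function(s) s$group == "A", logical(1)))
  cat(sprintf(
    "Synthetic cohort: %d subjects (A=%d, B=%d), %d regions x %d frames, mode '%s'\n",
    length(x$subjects), ga, length(x$subjects) - ga,
    x$params$n_regions, x$params$n_frames, x$mode))
  invisible(x)
}

#' Write a cohort to an output directory
#'
#' Writes the study as plain text: per-subject activity TSV (rows = regions
#' in region_id order, columns = frames), `labels.tsv`, `structural.tsv`, a
#' `manifest.csv` (subject_id, group, age, path) and a `config.yaml` snapshot
#' of every simulation parameter including the seed and a config hash.
#'
#' @param cohort An `st_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "st_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_labels(cohort$labels, file.path(dir, "labels.tsv"))
  write_matrix_tsv(cohort$sc$adjacency, file.path(dir, "structural.tsv"))
  paths <- vapply(cohort$subjects, function(s) {
    p <- file.path("timeseries", paste0(s$subject_id, ".tsv"))
    dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
    write_matrix_tsv(s$activity, file.path(dir, p))
    p
  }, character(1))
  manifest <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    group = vapply(cohort$subjects, `[[`, character(1), "group"),
    age = vapply(cohort$subjects, `[[`, numeric(1), "age"),
    path = paths, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- unclass(cohort$params)
  cfg$mode <- cohort$mode
  cfg$config_hash <- config_hash(cfg)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv`, `labels.tsv`,
#'   `structural.tsv` and the per-subject series.
#' @return An `st_cohort` (with `params` restored from `config.yaml` when
#'   present).
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  labels <- read_labels(file.path(dir, "labels.tsv"))
  sc <- structural_connectome(
    read_matrix_tsv(file.path(dir, "structural.tsv"), expect_square = TRUE))
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    act <- read_matrix_tsv(file.path(dir, manifest$path[i]))
    if (nrow(act) != nrow(labels))
      stopf("subject %s: %d rows but %d labelled regions",
            manifest$subject_id[i], nrow(act), nrow(labels))
    list(subject_id = manifest$subject_id[i], group = manifest$group[i],
         age = manifest$age[i], activity = act)
  })
  params <- NULL
  mode <- "bold"
  cfgp <- file.path(dir, "config.yaml")
  if (file.exists(cfgp)) {
    cfg <- yaml::read_yaml(cfgp)
    mode <- cfg$mode %||% "bold"
  }
  structure(list(subjects = subjects, labels = labels, sc = sc,
                 params = params, mode = mode),
            class = "st_cohort")
}
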