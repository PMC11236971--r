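test_that("parcellation generation satisfies its invariants", {
  p8 <- generate_parcellation(8, rep(1L, 8), seed = 1)
  expect_equal(nrow(p8), 8L)
  expect_setequal(p8$system, functional_systems())

  a <- generate_parcellation(80, rep(10L, 8), seed = 1)
  b <- generate_parcellation(80, rep(10L, 8), seed = 1)
  expect_identical(a, b)
  c2 <- generate_parcellation(80, rep(10L, 8), seed = 2)
  expect_false(identical(a$system, c2$system))

  full <- generate_parcellation(506, c(66L, 66L, 60L, 60L, 50L, 70L, 90L,
                                       44L), seed = 3)
  expect_equal(nrow(full), 506L)
  expect_true(all(full$system %in% functional_systems()))
  expect_equal(full$region_id, 0:505)

  expect_error(generate_parcellation(10, rep(1L, 8)), "does not match")
  expect_error(generate_parcellation(9, c(2L, 2L, rep(1L, 5), 0L)),
               "nonempty")
})

test_that("stochastic block model extremes are deterministic", {
  labels <- generate_parcellation(16, rep(2L, 8), seed = 1)
  sysidx <- match(labels$system, functional_systems())
  sc1 <- generate_structural_connectome(labels, p_in = 1, p_out = 0, seed = 1)
  b <- binarize_sc(sc1)
  same <- outer(sysidx, sysidx, "==")
  diag(same) <- FALSE
  expect_true(all(b[same]))
  expect_true(!any(b[!same]))

  sc0 <- generate_structural_connectome(labels, 0, 0, seed = 1)
  expect_true(all(sc0$adjacency == 0))

  expect_error(generate_structural_connectome(labels, 0.1, 0.5), "exceed")
})

test_that("block model densities match their binomial targets over replicates", {
  labels <- generate_parcellation(80, rep(10L, 8), seed = 4)
  sysidx <- match(labels$system, functional_systems())
  same <- outer(sysidx, sysidx, "==") & upper.tri(matrix(0, 80, 80))
  diff <- (!outer(sysidx, sysidx, "==")) & upper.tri(matrix(0, 80, 80))
  n_seeds <- 200
  hit_in <- hit_out <- 0
  for (s in seq_len(n_seeds)) {
    b <- binarize_sc(generate_structural_connectome(labels, 0.5, 0.05,
                                                    seed = s))
    hit_in <- hit_in + sum(b[same])
    hit_out <- hit_out + sum(b[diff])
  }
  n_in <- sum(same) * n_seeds
  n_out <- sum(diff) * n_seeds
  expect_lt(abs(hit_in / n_in - 0.5), 3 * sqrt(0.5 * 0.5 / n_in))
  expect_lt(abs(hit_out / n_out - 0.05), 3 * sqrt(0.05 * 0.95 / n_out))
})

test_that("cohorts are deterministic and degenerate parameters behave", {
  base <- list(n_regions = 24, regions_per_system = rep(3L, 8),
               n_subjects_A = 2, n_subjects_B = 2, n_frames = 30, seed = 5)
  p <- do.call(sim_params, base)
  co1 <- generate_cohort(p, mode = "raster")
  co2 <- generate_cohort(p, mode = "raster")
  expect_identical(co1, co2)

  p0 <- do.call(sim_params, c(base, list(event_rate = 0)))
  co0 <- generate_cohort(p0, mode = "raster")
  expect_true(all(vapply(co0$subjects, function(s) all(s$activity == 0L),
                         logical(1))))
})

test_that("without propagation or persistence every active cell is isolated", {
  p <- sim_params(n_regions = 40, regions_per_system = rep(5L, 8),
                  n_subjects_A = 1, n_subjects_B = 1, n_frames = 100,
                  event_rate = 0.1, spread_prob = 0, persist_prob = 0,
                  drift_prob = 0, seed = 6)
  co <- generate_cohort(p, mode = "raster")
  for (s in co$subjects) {
    expect_gt(sum(s$activity), 0)
    cs <- subject_components(s$activity, co$sc, min_size = 1L)
    expect_true(all(vapply(cs$components, `[[`, numeric(1), "size") == 1))
  }
})

test_that("raster cascades only co-activate structurally connected regions", {
  # with a block-diagonal SC (p_out = 0) and no cross-system mechanism a
  # component can never span systems: there is no structural path between
  # blocks, so this checks spreading respects the binarized edges
  p <- sim_params(n_regions = 32, regions_per_system = rep(4L, 8),
                  p_in = 0.9, p_out = 0,
                  n_subjects_A = 3, n_subjects_B = 1, n_frames = 60,
                  cross_system_coupling = 1, drift_prob = 0.3, seed = 7)
  co <- generate_cohort(p, mode = "raster")
  sysidx <- match(co$labels$system[order(co$labels$region_id)],
                  functional_systems())
  for (s in co$subjects[1:3]) {
    cs <- subject_components(s$activity, co$sc, min_size = 2L)
    for (cc in cs$components)
      expect_equal(length(unique(sysidx[cc$regions])), 1L)
  }
})

test_that("higher cross-system coupling yields more multi-system components", {
  n_rep <- 10
  frac_multi <- function(eta, seed) {
    p <- sim_params(n_regions = 48, regions_per_system = rep(6L, 8),
                    n_subjects_A = 4, n_subjects_B = 1, n_frames = 100,
                    cross_system_coupling = eta, seed = seed)
    co <- generate_cohort(p, mode = "raster")
    pool <- cc_pool(lapply(co$subjects[1:4], function(s)
      subject_components(s$activity, co$sc, subject_id = s$subject_id)),
      co$labels)
    share <- pool$mass / rowSums(pool$mass)
    mean(rowSums(share >= 0.2) >= 2)
  }
  wins <- sum(vapply(seq_len(n_rep), function(r)
    frac_multi(0.9, 1000 + r) > frac_multi(0.1, 1000 + r), logical(1)))
  expect_gte(wins, 8)
})

test_that("bold mode recovers the planted point process at moderate noise", {
  kern <- bold_kernel()
  expect_equal(max(kern), 1)
  lag <- which.max(kern) - 1L
  p <- sim_params(n_regions = 64, regions_per_system = rep(8L, 8),
                  n_subjects_A = 2, n_subjects_B = 1, n_frames = 200,
                  noise_sd = 0.2, seed = 8)   # noise at 0.2 x kernel peak
  ras_co <- generate_cohort(p, mode = "raster")
  bold_co <- generate_cohort(p, mode = "bold")
  recalls <- fp <- c()
  for (i in 1:2) {
    ras <- ras_co$subjects[[i]]$activity
    det <- unclass(zscore_threshold(bold_co$subjects[[i]]$activity, 2))
    tt <- ncol(ras)
    planted <- matrix(0L, nrow(ras), tt)
    planted[, (1 + lag):tt] <- ras[, 1:(tt - lag)]
    recalls <- c(recalls, sum(det & planted) / sum(planted))
    fp <- c(fp, sum(det & !planted) / length(planted))
  }
  expect_gt(mean(recalls), 0.80)
  expect_lt(mean(fp), 0.05)
})

test_that("planted knobs move their metrics in the documented direction", {
  # 5-point grids, rank correlation > 0 across 10 seeds per point
  grid_stat <- function(param, vals, fn) {
    out <- NULL
    for (v in vals) for (s in 1:10) {
      args <- list(n_regions = 40, regions_per_system = rep(5L, 8),
                   n_subjects_A = 3, n_subjects_B = 1, n_frames = 80,
                   seed = 9000 + s)
      args[[param]] <- v
      p <- do.call(sim_params, args)
      co <- generate_cohort(p, mode = "raster")
      cs <- lapply(co$subjects[1:3], function(su)
        subject_components(su$activity, co$sc, subject_id = su$subject_id))
      out <- rbind(out, c(v, fn(cs, co$labels)))
    }
    out
  }
  sd_fn <- function(cs, labels)
    tryCatch(system_diversity(cc_pool(cs, labels))$value,
             error = function(e) NA)
  std_fn <- function(cs, labels)
    tryCatch(spatiotemporal_diversity(cc_pool(cs, labels))$value,
             error = function(e) NA)
  h_fn <- function(cs, labels)
    mean(unlist(lapply(cs, function(x)
      vapply(x$components, `[[`, numeric(1), "height"))), na.rm = TRUE)

  g1 <- grid_stat("cross_system_coupling", c(.1, .3, .5, .7, .9), sd_fn)
  expect_gt(cor(g1[, 1], g1[, 2], method = "spearman",
                use = "complete.obs"), 0)
  g2 <- grid_stat("drift_prob", c(0, .15, .3, .45, .6), std_fn)
  expect_gt(cor(g2[, 1], g2[, 2], method = "spearman",
                use = "complete.obs"), 0)
  g3 <- grid_stat("spread_prob", c(.1, .2, .3, .4, .5), h_fn)
  expect_gt(cor(g3[, 1], g3[, 2], method = "spearman",
                use = "complete.obs"), 0)
})

test_that("per-group parameters produce the planted asymmetry only in the targeted group", {
  p <- sim_params(n_regions = 40, regions_per_system = rep(5L, 8),
                  n_subjects_A = 4, n_subjects_B = 4, n_frames = 100,
                  cross_system_coupling = c(0.9, 0.05), seed = 10)
  co <- generate_cohort(p, mode = "raster")
  pools <- lapply(c("A", "B"), function(g) {
    subj <- Filter(function(s) s$group == g, co$subjects)
    cc_pool(lapply(subj, function(s)
      subject_components(s$activity, co$sc, subject_id = s$subject_id)),
      co$labels)
  })
  expect_gt(system_diversity(pools[[1]])$value,
            system_diversity(pools[[2]])$value)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(n_regions = 10, regions_per_system = rep(1L, 8)),
               "summing")
  expect_error(sim_params(n_regions = 16, regions_per_system = rep(2L, 8),
                          spread_prob = 1.5), "probabilit")
  expect_error(sim_params(n_regions = 16, regions_per_system = rep(2L, 8),
                          age_map = list(ages = c(5, 6))), "one age")
  p <- sim_params(n_regions = 16, regions_per_system = rep(2L, 8),
                  n_subjects_A = 1, n_subjects_B = 1, n_frames = 10)
  labels_bad <- generate_parcellation(24, rep(3L, 8))
  expect_error(generate_cohort(p, labels = labels_bad), "inconsistent|disagree")
})
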