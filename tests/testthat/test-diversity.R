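test_that("system embedding sums the activation counts per system", {
  labels <- labels_for(c("VIS", "VIS", "SM"))
  cc <- make_cc(1:3, c(1, 2, 1), n_regions = 3)
  m <- embed_systems(cc, labels)
  expect_equal(unname(m[c("VIS", "SM")]), c(3, 1))
  expect_equal(sum(m), cc$size)   # mass conservation

  pure <- make_cc(1:2, c(2, 5), n_regions = 3)
  expect_equal(sum(embed_systems(pure, labels) > 0), 1L)
})

test_that("proportional activation vectors share one unit embedding", {
  labels <- labels_for(c("VIS", "SM", "DM", "DM"))
  a <- make_cc(c(1, 3), c(1, 2), n_regions = 4)
  b <- make_cc(c(1, 3), c(2, 4), n_regions = 4)
  ua <- embed_systems(a, labels); ua <- ua / sqrt(sum(ua^2))
  ub <- embed_systems(b, labels); ub <- ub / sqrt(sum(ub^2))
  expect_equal(ua, ub)
})

test_that("the 20% attribution rule returns all qualifying systems plus the argmax", {
  labels <- labels_for(rep(c("VIS", "SM"), each = 10))
  pure <- make_cc(1:4, rep(1, 4), n_regions = 20)
  expect_equal(attribute_systems(pure, labels), "VIS")

  half <- make_cc(c(1:3, 11:13), rep(1, 6), n_regions = 20)
  expect_setequal(attribute_systems(half, labels), c("VIS", "SM"))

  skew <- make_cc(c(1:9, 11), rep(1, 10), n_regions = 20)  # 90/10
  expect_equal(attribute_systems(skew, labels), "VIS")

  # argmax kept even when every share is below the threshold
  labels8 <- labels_for(functional_systems())
  spread <- make_cc(1:8, c(2, rep(1, 7)), n_regions = 8)
  expect_true("VIS" %in% attribute_systems(spread, labels8, frac = 0.99))
})

test_that("SD is zero on single-system pools and one at uniform mass", {
  labels <- labels_for(rep(functional_systems(), each = 2))
  pure_pool <- cc_pool(make_ccset(list(
    make_cc(1:2, c(1, 1), 16), make_cc(1, 3, 16)), 16), labels)
  expect_equal(system_diversity(pure_pool)$value, 0)

  uni <- make_cc(seq(1, 15, by = 2), rep(2, 8), 16)
  uni_pool <- cc_pool(make_ccset(list(uni), 16), labels)
  expect_equal(system_diversity(uni_pool)$value, 1)
})

test_that("SD matches the closed-form entropy on the 3:1 example", {
  labels <- labels_for(c("VIS", "VIS", "SM"))
  cc <- make_cc(1:3, c(1, 2, 1), n_regions = 3)
  pool <- cc_pool(make_ccset(list(cc), 3), labels)
  h <- -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(8)
  expect_equal(system_diversity(pool)$value, h)
  expect_equal(round(h, 4), 0.2704)
})

test_that("STD is zero for collinear embeddings and one for orthogonal pairs", {
  labels <- labels_for(rep(c("VIS", "SM"), each = 4))
  col <- cc_pool(make_ccset(list(
    make_cc(1:2, c(1, 1), 8), make_cc(c(1, 3), c(2, 2), 8),
    make_cc(1:3, c(4, 2, 2), 8)), 8), labels)
  # all three CCs are pure VIS -> embeddings collinear
  expect_equal(spatiotemporal_diversity(col)$value, 0)

  # orthogonal pair: region 4 relabeled so its own mass sits in one system
  # while its partner component is pure in the other
  labels2 <- labels_for(c("VIS", "VIS", "VIS", "SM", "SM", "SM", "SM", "SM"))
  orth <- cc_pool(make_ccset(list(
    make_cc(c(1, 2), c(1, 1), 8),            # pure VIS
    make_cc(c(4, 5), c(1, 1), 8)), 8), labels2)
  # no shared region -> STD undefined
  expect_error(spatiotemporal_diversity(orth), "insufficient")

  mixed <- cc_pool(make_ccset(list(
    make_cc(c(1, 2), c(1, 1), 8),            # pure VIS
    make_cc(c(1, 5, 6), c(1, 2, 2), 8)), 8), labels)
  # region 1 shared; cos between (VIS) and (VIS:1, SM:4) in (0,1)
  v <- spatiotemporal_diversity(mixed)$value
  expect_gt(v, 0)
  expect_lt(v, 1)
})

test_that("fast STD equals the brute-force all-pairs oracle on random pools", {
  set.seed(5)
  labels <- labels_for(functional_systems())
  for (rep in 1:30) {
    n_cc <- sample(2:10, 1)
    comps <- lapply(seq_len(n_cc), function(i) {
      k <- sample(1:8, 1)
      regions <- sort(sample(1:8, k))
      make_cc(regions, sample(1:4, k, replace = TRUE), 8)
    })
    pool <- cc_pool(make_ccset(comps, 8), labels)
    want <- oracle_std(pool$mass, lapply(comps, `[[`, "regions"), 8)
    if (is.na(want)) {
      expect_error(spatiotemporal_diversity(pool), "insufficient")
    } else {
      expect_equal(spatiotemporal_diversity(pool)$value, want,
                   tolerance = 1e-10)
    }
  }
})

test_that("relabeling systems permutes per-system scales but leaves global values unchanged", {
  sim <- small_cohort_design(n_subj_per_group = 3, seed = 9)
  labels <- sim$cohort$labels
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)   # permutation of the 8 systems
  labels2 <- labels
  labels2$system <- functional_systems()[perm][match(labels$system,
                                                     functional_systems())]
  pool1 <- cc_pool(sim$ccsets, labels)
  pool2 <- cc_pool(sim$ccsets, labels2)
  expect_equal(system_diversity(pool1)$value, system_diversity(pool2)$value)
  expect_equal(spatiotemporal_diversity(pool1)$value,
               spatiotemporal_diversity(pool2)$value)
  m1 <- scale_metrics(pool1)
  m2 <- scale_metrics(pool2)
  for (s in seq_along(functional_systems())) {
    from <- functional_systems()[s]
    to <- functional_systems()[perm[s]]
    expect_equal(m2$value[m2$scale == to & m2$metric == "SD"],
                 m1$value[m1$scale == from & m1$metric == "SD"])
  }
})

test_that("SD of a merged pool is the count-weighted mean of sub-pool SDs", {
  sim1 <- small_cohort_design(n_subj_per_group = 2, seed = 13)
  labels <- sim1$cohort$labels
  poolA <- cc_pool(sim1$ccsets[1:2], labels)
  poolB <- cc_pool(sim1$ccsets[3:4], labels)
  merged <- cc_pool(sim1$ccsets, labels)
  want <- (poolA$n_cc * system_diversity(poolA)$value +
           poolB$n_cc * system_diversity(poolB)$value) /
    (poolA$n_cc + poolB$n_cc)
  expect_equal(system_diversity(merged)$value, want)
})

test_that("scale_metrics flags empty sub-pools instead of failing", {
  labels <- labels_for(rep(c("VIS", "SM"), each = 4))
  labels$system <- rep(c("VIS", "SM"), each = 4)
  pool <- cc_pool(make_ccset(list(
    make_cc(1:2, c(1, 1), 8), make_cc(c(1, 2), c(2, 1), 8)), 8),
    labels_for(rep(c("VIS", "SM"), each = 4)))
  m <- scale_metrics(pool)
  expect_equal(nrow(m), 18L)
  expect_true(all(m$value[!is.na(m$value)] >= 0 &
                  m$value[!is.na(m$value)] <= 1))
  expect_true(all(m$flag[m$scale == "CBL"] == "insufficient_data"))
  expect_equal(m$value[m$scale == "VIS" & m$metric == "SD"], 0)
})

test_that("metrics stay within [0, 1] on simulated pools", {
  sim <- small_cohort_design(n_subj_per_group = 4, seed = 17,
                             cross_system_coupling = 0.5, drift_prob = 0.3)
  m <- scale_metrics(cc_pool(sim$ccsets, sim$cohort$labels))
  ok <- !is.na(m$value)
  expect_true(any(ok))
  expect_true(all(m$value[ok] >= 0 & m$value[ok] <= 1))
})

test_that("unlabeled regions are rejected at embedding", {
  labels <- labels_for(c("VIS", "SM"))
  cc <- make_cc(c(1, 3), c(1, 1), n_regions = 3)
  expect_error(embed_systems(cc, labels), "beyond")
})
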