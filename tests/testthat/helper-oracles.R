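# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths.

# Weakly connected components by explicit node/edge enumeration + BFS.
# Returns a list of components, each a sorted vector of cell keys
# "region.frame" (1-based), including singletons.
oracle_components <- function(raster, b, include_self = TRUE) {
  n <- nrow(raster)
  nodes <- list()
  for (t in seq_len(ncol(raster)))
    for (i in seq_len(n))
      if (raster[i, t] == 1) nodes[[length(nodes) + 1L]] <- c(i, t)
  m <- length(nodes)
  if (!m) return(list())
  adj <- vector("list", m)
  for (a in seq_len(m)) {
    for (bb in seq_len(m)) {
      if (a >= bb) next
      ia <- nodes[[a]][1]; ta <- nodes[[a]][2]
      ib <- nodes[[bb]][1]; tb <- nodes[[bb]][2]
      ok <- abs(ta - tb) <= 1 &&
        ((ia != ib && b[ia, ib]) || (ia == ib && include_self))
      if (ok) {
        adj[[a]] <- c(adj[[a]], bb)
        adj[[bb]] <- c(adj[[bb]], a)
      }
    }
  }
  comp <- integer(m)
  nc <- 0L
  for (s in seq_len(m)) {
    if (comp[s]) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!comp[w]) { comp[w] <- nc; queue <- c(queue, w) }
    }
  }
  out <- lapply(split(seq_len(m), comp), function(ix)
    sort(vapply(nodes[ix], function(nd) (nd[2] - 1L) * n + nd[1], numeric(1))))
  unname(out)
}

# Canonical form of a partition (list of cell-id sets) for comparison.
canon_partition <- function(sets, min_size = 1L) {
  sets <- Filter(function(s) length(s) >= min_size, sets)
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, numeric(1), 1L))]
}

# All-pairs mean cosine STD, straight from definitions.
oracle_std <- function(mass, region_lists, n_regions) {
  norms <- sqrt(rowSums(mass^2))
  unit <- mass / norms
  vals <- c()
  for (i in seq_len(n_regions)) {
    p_i <- which(vapply(region_lists, function(r) i %in% r, logical(1)))
    if (length(p_i) < 2) next
    cs <- c()
    for (a in seq_along(p_i)) for (b in seq_along(p_i))
      if (a < b) cs <- c(cs, sum(unit[p_i[a], ] * unit[p_i[b], ]))
    vals <- c(vals, 1 - mean(cs))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# Literal BH step-up: q_(i) = min_{j >= i} p_(j) * n / j, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) ps[j] * n / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Type-III F statistics via explicit projection matrices.
oracle_ancova_f <- function(y, g, a) {
  x <- cbind(1, g, a, g * a)
  n <- length(y)
  pf <- x %*% solve(crossprod(x)) %*% t(x)
  sse_f <- sum((y - pf %*% y)^2)
  vapply(2:4, function(j) {
    xr <- x[, -j, drop = FALSE]
    pr <- xr %*% solve(crossprod(xr)) %*% t(xr)
    sse_r <- sum((y - pr %*% y)^2)
    ((sse_r - sse_f) / 1) / (sse_f / (n - 4))
  }, numeric(1))
}

# Tiny fixtures ------------------------------------------------------------

# The 3-region worked example: SC chain 1-2-3, systems VIS,VIS,SM,
# active cells (1,1),(2,1),(2,2),(3,2).
toy_fixture <- function() {
  labels <- data.frame(region_id = 0:2,
                       region_name = c("r0", "r1", "r2"),
                       system = c("VIS", "VIS", "SM"),
                       stringsAsFactors = FALSE)
  class(labels) <- c("parcellation", "data.frame")
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1
  raster <- matrix(0L, 3, 3)
  raster[1, 1] <- raster[2, 1] <- raster[2, 2] <- raster[3, 2] <- 1L
  list(labels = labels, sc = structural_connectome(adj), raster = raster)
}

random_instance <- function(n_max = 12, t_max = 15, p_act = 0.3,
                            p_sc = 0.3) {
  n <- sample(2:n_max, 1)
  tt <- sample(2:t_max, 1)
  raster <- matrix(rbinom(n * tt, 1, p_act), n, tt)
  adj <- matrix(0, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- rbinom(sum(ut), 1, p_sc)
  adj <- adj + t(adj)
  list(raster = raster, sc = structural_connectome(adj), n = n, t = tt)
}

# Small synthetic pool built directly from hand-made components.
make_cc <- function(regions, x_counts, n_regions, t_min = 1,
                    subject_id = "s1") {
  structure(list(regions = as.integer(regions),
                 x_counts = as.integer(x_counts),
                 size = sum(x_counts), t_min = t_min,
                 t_max = t_min + max(x_counts) - 1,
                 length = max(x_counts),
                 height = length(regions) / n_regions,
                 subject_id = subject_id), class = "cc")
}

make_ccset <- function(comps, n_regions, n_frames = 20,
                       subject_id = "s1") {
  structure(list(components = comps, n_regions = n_regions,
                 n_frames = n_frames, n_discarded = 0L,
                 n_discarded_cells = 0L, min_size = 2L,
                 subject_id = subject_id), class = "cc_set")
}

labels_for <- function(systems) {
  labels <- data.frame(region_id = seq_along(systems) - 1L,
                       region_name = paste0("r", seq_along(systems)),
                       system = systems, stringsAsFactors = FALSE)
  class(labels) <- c("parcellation", "data.frame")
  labels
}

small_cohort_design <- function(n_subj_per_group = 6, n_regions = 40,
                                n_frames = 100, seed = 1, ...) {
  p <- sim_params(n_regions = n_regions,
                  regions_per_system = rep(n_regions / 8, 8),
                  n_subjects_A = n_subj_per_group,
                  n_subjects_B = n_subj_per_group,
                  n_frames = n_frames, seed = seed, ...)
  co <- generate_cohort(p, mode = "raster")
  cs <- lapply(co$subjects, function(s)
    subject_components(s$activity, co$sc, subject_id = s$subject_id))
  subs <- data.frame(
    subject_id = vapply(co$subjects, `[[`, character(1), "subject_id"),
    group = vapply(co$subjects, `[[`, character(1), "group"),
    age = vapply(co$subjects, `[[`, numeric(1), "age"),
    stringsAsFactors = FALSE)
  list(cohort = co, ccsets = cs, subjects = subs,
       design = study_design(cs, subs, co$labels))
}
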