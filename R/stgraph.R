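# Multilayer spatiotemporal graph: nodes are active (region, frame) cells,
# edges require structural support within the same or consecutive frames.
# Cells are encoded as a single integer id = (frame - 1) * N + region.

cell_id <- function(region, frame, n_regions) (frame - 1L) * n_regions + region
cell_region <- function(id, n_regions) ((id - 1L) %% n_regions) + 1L
cell_frame <- function(id, n_regions) ((id - 1L) %/% n_regions) + 1L

#' Build the multilayer spatiotemporal graph
#'
#' Nodes are the active cells of the raster. An undirected edge joins
#' `(i, t)` and `(j, t')` iff `|t - t'| <= 1` and either `i = j` (temporal
#' self-continuity, optional) or regions i and j share a binarized
#' structural edge. Same-frame pairs thus capture structurally backed
#' co-activation, consecutive-frame pairs capture propagation along white
#' matter.
#'
#' @param raster An [zscore_threshold()] raster or any binary N x T matrix.
#' @param sc A `structural_connectome` or plain symmetric matrix.
#' @param sc_threshold Optional binarization threshold override
#'   (edge iff weight > threshold).
#' @param include_self Keep temporal edges `(i,t)-(i,t+1)` for persistently
#'   active regions (default TRUE; without them a continuously active region
#'   would fragment into per-frame pieces).
#' @return An `st_graph`: `nodes` (sorted cell ids), `edges` (m x 2 matrix of
#'   cell ids), `n_regions`, `n_frames`.
#' @export
build_stgraph <- function(raster, sc, sc_threshold = NULL,
                          include_self = TRUE) {
  raster <- unclass(raster)
  if (!all(raster %in% c(0L, 1L)))
    stopf("raster must be binary")
  b <- binarize_sc(sc, sc_threshold)
  n <- nrow(raster)
  t_total <- ncol(raster)
  if (nrow(b) != n)
    stopf("raster has %d regions but structural connectome has %d",
          n, nrow(b))

  act <- lapply(seq_len(t_total), function(t) which(raster[, t] == 1L))
  edges <- vector("list", 2L * t_total)
  k <- 0L
  for (t in seq_len(t_total)) {
    at <- act[[t]]
    if (length(at) > 1L) {
      sub <- b[at, at, drop = FALSE]
      sub[lower.tri(sub, diag = TRUE)] <- FALSE
      idx <- which(sub, arr.ind = TRUE, useNames = FALSE)
      if (nrow(idx)) {
        k <- k + 1L
        edges[[k]] <- cbind(cell_id(at[idx[, 1L]], t, n),
                            cell_id(at[idx[, 2L]], t, n))
      }
    }
    if (t < t_total && length(at) && length(act[[t + 1L]])) {
      at1 <- act[[t + 1L]]
      cross <- b[at, at1, drop = FALSE]
      if (include_self) {
        common <- match(intersect(at, at1), at)
        if (length(common))
          cross[cbind(common, match(at[common], at1))] <- TRUE
      }
      idx <- which(cross, arr.ind = TRUE, useNames = FALSE)
      if (nrow(idx)) {
        k <- k + 1L
        edges[[k]] <- cbind(cell_id(at[idx[, 1L]], t, n),
                            cell_id(at1[idx[, 2L]], t + 1L, n))
      }
    }
  }
  edges <- if (k) do.call(rbind, edges[seq_len(k)]) else
    matrix(integer(0), 0L, 2L)
  structure(list(nodes = which(raster == 1L), edges = edges,
                 n_regions = n, n_frames = t_total,
                 include_self = include_self),
            class = "st_graph")
}

#' @export
print.st_graph <- function(x, ...) {
  cat(sprintf(
    "Spatiotemporal graph: %d nodes (active cells), %d edges, %d regions x %d frames\n",
    length(x$nodes), nrow(x$edges), x$n_regions, x$n_frames))
  invisible(x)
}

#' Extract weakly connected components
#'
#' Partitions the spatiotemporal graph's nodes into weakly connected
#' components — each a transient cluster of structurally backed
#' co-activation — and computes per-component descriptors: the spatial
#' activation counts (how many frames each region is active within the
#' component), frame span, `length` (t_max - t_min + 1 frames), `size`
#' (node count) and `height` (fraction of all N regions involved).
#' Components smaller than `min_size` are discarded but counted.
#'
#' @param graph An `st_graph`.
#' @param min_size Minimum node count for a component to be retained
#'   (default 2: singletons carry no connectivity).
#' @param subject_id Optional owner id attached to each component.
#' @return A `cc_set`: list with `components` (each a `cc` with fields
#'   `cells` (sorted cell ids `(frame-1)*N + region`), `regions`,
#'   `x_counts`, `size`, `t_min`, `t_max`, `length`, `height`,
#'   `subject_id`), `n_regions`, `n_frames`, `n_discarded`,
#'   `n_discarded_cells`, `min_size`.
#' @export
extract_components <- function(graph, min_size = 2L, subject_id = NA_character_) {
  stopifnot(inherits(graph, "st_graph"))
  nodes <- graph$nodes
  n <- graph$n_regions
  if (!length(nodes)) {
    return(structure(list(components = list(), n_regions = n,
                          n_frames = graph$n_frames, n_discarded = 0L,
                          n_discarded_cells = 0L, min_size = min_size,
                          subject_id = subject_id),
                     class = "cc_set"))
  }
  v <- match(graph$edges, nodes)
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  if (length(v))
    g <- igraph::add_edges(g, t(matrix(v, ncol = 2L)))
  memb <- igraph::components(g, mode = "weak")$membership

  ord <- order(memb, nodes)
  ids <- nodes[ord]
  mm <- memb[ord]
  starts <- c(1L, which(diff(mm) != 0L) + 1L)
  ends <- c(starts[-1L] - 1L, length(mm))
  comps <- vector("list", length(starts))
  keep <- logical(length(starts))
  n_disc_cells <- 0L
  for (ci in seq_along(starts)) {
    idc <- ids[starts[ci]:ends[ci]]
    if (length(idc) < min_size) {
      n_disc_cells <- n_disc_cells + length(idc)
      next
    }
    keep[ci] <- TRUE
    reg <- cell_region(idc, n)
    frm <- cell_frame(idc, n)
    tab <- table(reg)
    regions <- as.integer(names(tab))
    comps[[ci]] <- structure(list(
      cells = idc,
      regions = regions,
      x_counts = as.integer(tab),
      size = length(idc),
      t_min = min(frm), t_max = max(frm),
      length = max(frm) - min(frm) + 1L,
      height = length(regions) / n,
      subject_id = subject_id), class = "cc")
  }
  structure(list(components = comps[keep], n_regions = n,
                 n_frames = graph$n_frames,
                 n_discarded = sum(!keep), n_discarded_cells = n_disc_cells,
                 min_size = min_size, subject_id = subject_id),
            class = "cc_set")
}

#' Spatial activation vector of a component
#'
#' @param cc A `cc` component.
#' @param n_regions Total region count N.
#' @return Length-N integer vector whose i-th entry is the number of frames
#'   within the component in which region i is active.
#' @export
cc_activation_vector <- function(cc, n_regions) {
  x <- integer(n_regions)
  x[cc$regions] <- cc$x_counts
  x
}

#' Per-subject component summary
#'
#' @param ccset A `cc_set`.
#' @return One-row data.frame with `n_cc`, `mean_length`, `mean_height`
#'   (means are `NA` when no component was retained).
#' @export
cc_summary <- function(ccset) {
  stopifnot(inherits(ccset, "cc_set"))
  comps <- ccset$components
  if (!length(comps))
    return(data.frame(n_cc = 0L, mean_length = NA_real_,
                      mean_height = NA_real_))
  data.frame(
    n_cc = length(comps),
    mean_length = mean(vapply(comps, `[[`, numeric(1), "length")),
    mean_height = mean(vapply(comps, `[[`, numeric(1), "height")))
}

#' One-call component extraction from a raster
#'
#' Convenience wrapper: [build_stgraph()] followed by
#' [extract_components()].
#'
#' @inheritParams build_stgraph
#' @inheritParams extract_components
#' @return A `cc_set`.
#' @export
subject_components <- function(raster, sc, min_size = 2L, sc_threshold = NULL,
                               include_self = TRUE,
                               subject_id = NA_character_) {
  extract_components(
    build_stgraph(raster, sc, sc_threshold = sc_threshold,
                  include_self = include_self),
    min_size = min_size, subject_id = subject_id)
}

#' @export
print.cc_set <- function(x, ...) {
  s <- cc_summary(x)
  cat(sprintf(
    "Component set: %d retained (min_size %d), %d discarded (%d cells); mean length %.2f frames, mean height %.3f\n",
    s$n_cc, x$min_size, x$n_discarded, x$n_discarded_cells,
    s$mean_length, s$mean_height))
  invisible(x)
}

#' Tabulate a component set
#'
#' @param ccset A `cc_set`.
#' @param labels Optional parcellation; when given, one extra column per
#'   functional system holds that system's activation mass.
#' @return data.frame, one row per retained component.
#' @export
cc_table <- function(ccset, labels = NULL) {
  comps <- ccset$components
  base <- data.frame(
    subject_id = vapply(comps, `[[`, character(1), "subject_id"),
    cc_id = seq_along(comps),
    size = vapply(comps, `[[`, numeric(1), "size"),
    length = vapply(comps, `[[`, numeric(1), "length"),
    height = vapply(comps, `[[`, numeric(1), "height"),
    t_min = vapply(comps, `[[`, numeric(1), "t_min"),
    t_max = vapply(comps, `[[`, numeric(1), "t_max"),
    n_regions_involved = vapply(comps, function(cc) length(cc$regions),
                                numeric(1)))
  if (!is.null(labels)) {
    sysidx <- system_index(labels)
    m <- t(vapply(comps, function(cc) embed_systems(cc, sysidx = sysidx),
                  numeric(8)))
    colnames(m) <- SYSTEMS
    base <- cbind(base, as.data.frame(m))
  }
  base
}
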