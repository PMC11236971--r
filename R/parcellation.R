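#' Generate a synthetic parcellation label table
#'
#' Builds a label table assigning each of `n_regions` grey-matter regions to
#' one of the eight functional systems (see [functional_systems()]). System
#' membership is laid out in blocks whose sizes are given by
#' `regions_per_system`; the region order is then shuffled deterministically
#' so that system membership is not trivially contiguous (as in a real atlas,
#' where region index carries no system information).
#'
#' @param n_regions Total number of regions (N).
#' @param regions_per_system Integer vector of length 8 (order of
#'   [functional_systems()]) summing to `n_regions`.
#' @param seed RNG seed controlling the deterministic shuffle.
#' @return A `parcellation` data.frame with columns `region_id` (0-based,
#'   contiguous), `region_name`, `system`.
#' @examples
#' generate_parcellation(8, rep(1L, 8), seed = 1)
#' @export
generate_parcellation <- function(n_regions, regions_per_system, seed = 1L) {
  n_regions <- check_count(n_regions, "n_regions")
  if (length(regions_per_system) != 8L)
    stopf("'regions_per_system' must have 8 entries, got %d",
          length(regions_per_system))
  regions_per_system <- vapply(seq_along(regions_per_system), function(i)
    check_count(regions_per_system[i], sprintf("regions_per_system[%d]", i),
                min = 0L), integer(1))
  if (sum(regions_per_system) != n_regions)
    stopf("sum(regions_per_system) = %d does not match n_regions = %d",
          sum(regions_per_system), n_regions)
  if (n_regions >= 8L && any(regions_per_system == 0L))
    stopf("all 8 systems must be nonempty when n_regions >= 8")

  systems <- rep(SYSTEMS, times = regions_per_system)
  systems <- with_seed(seed, sample(systems))
  labels <- data.frame(
    region_id = seq_len(n_regions) - 1L,
    region_name = sprintf("R%04d_%s", seq_len(n_regions) - 1L, systems),
    system = systems,
    stringsAsFactors = FALSE
  )
  class(labels) <- c("parcellation", "data.frame")
  labels
}

validate_parcellation <- function(labels) {
  req <- c("region_id", "region_name", "system")
  if (!all(req %in% names(labels)))
    stopf("label table must have columns %s", paste(req, collapse = ", "))
  bad <- setdiff(unique(labels$system), SYSTEMS)
  if (length(bad))
    stopf("unknown functional system(s): %s (valid: %s)",
          paste(bad, collapse = ", "), paste(SYSTEMS, collapse = ", "))
  n <- nrow(labels)
  if (anyDuplicated(labels$region_id))
    stopf("duplicate region_id in label table")
  if (!identical(sort(as.integer(labels$region_id)), seq_len(n) - 1L))
    stopf("region_id must be contiguous 0..N-1")
  invisible(labels)
}

# Integer system index (1..8) per region, in region_id order.
system_index <- function(labels) {
  labels <- labels[order(labels$region_id), , drop = FALSE]
  match(labels$system, SYSTEMS)
}

#' Read a parcellation label table
#'
#' Reads a tab-separated table with columns `region_id` (0-based),
#' `region_name` and `system`, validating the system vocabulary and the
#' contiguity of region ids. Rows are returned sorted by `region_id` so they
#' align with matrix rows.
#'
#' @param path Path to the TSV file.
#' @return A `parcellation` data.frame.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("label file not found: %s", path)
  labels <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_parcellation(labels)
  labels <- labels[order(labels$region_id), , drop = FALSE]
  rownames(labels) <- NULL
  class(labels) <- c("parcellation", "data.frame")
  labels
}

#' Write a parcellation label table to TSV
#'
#' @param labels A `parcellation` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  validate_parcellation(labels)
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation: %d regions, systems: %s\n", nrow(x),
              paste(sprintf("%s=%d", SYSTEMS,
                            tabulate(match(x$system, SYSTEMS), 8L)),
                    collapse = " ")))
  invisible(x)
}
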