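# Plain-text readers/writers. All matrices travel as headerless TSV with
# rows in region_id order (0-based ids live only in label tables and
# manifests); frames are columns. Inspectability beats compactness at this
# scale (N ~ 500, T ~ 700).

#' Read a numeric matrix from TSV
#'
#' Accepts a headerless numeric body, or a header row; a leading
#' `region_id` column is recognised and used to order rows. Ragged rows and
#' non-numeric cells raise errors naming the offending line.
#'
#' @param path File path.
#' @param expect_square Validate the matrix as square and symmetric.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path, expect_square = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty matrix file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  offset <- 0L
  ids <- NULL
  first <- suppressWarnings(as.numeric(parts[[1L]]))
  if (anyNA(first)) {            # header row
    hdr <- parts[[1L]]
    parts <- parts[-1L]
    offset <- 1L
    if (identical(hdr[1L], "region_id")) ids <- TRUE
  }
  lens <- lengths(parts)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stopf("ragged TSV %s: line %d has %d fields, expected %d",
          path, bad + offset, lens[bad], lens[1L])
  }
  rows <- lapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]]))
    if (anyNA(v))
      stopf("non-numeric cell in %s at line %d", path, i + offset)
    v
  })
  m <- do.call(rbind, rows)
  if (isTRUE(ids)) {
    ord <- order(m[, 1L])
    m <- m[ord, -1L, drop = FALSE]
  }
  if (expect_square) {
    if (nrow(m) != ncol(m))
      stopf("%s: expected square matrix, got %d x %d", path, nrow(m), ncol(m))
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      stopf("%s: square matrix is not symmetric", path)
  }
  m
}

#' Write a numeric matrix as headerless TSV
#'
#' @param m Matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a subject manifest
#'
#' CSV with columns `subject_id`, `group`, `age`, `path` (per-subject
#' activity TSV, relative to the manifest's directory).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "age", "path")
  if (!all(req %in% names(m)))
    stopf("manifest must have columns %s", paste(req, collapse = ", "))
  if (anyDuplicated(m$subject_id)) stopf("duplicate subject_id in manifest")
  m
}

#' Default study configuration
#'
#' Single source of pipeline parameters; a YAML file (or list) overrides the
#' defaults. Defaults: activation threshold 2 SD, minimum component size 2,
#' structural binarization threshold 0, 20% system attribution, 1000
#' permutations, alpha 0.05.
#'
#' @param config Optional path to a YAML file or a named list of overrides.
#' @return Named list with class `study_config`.
#' @export
study_config <- function(config = NULL) {
  defaults <- list(
    dir = NULL,                 # cohort directory (manifest.csv etc.)
    out_dir = NULL,
    threshold = 2.0,
    sd_type = "sample",
    min_cc_size = 2L,
    sc_threshold = 0,
    include_self = TRUE,
    attribution_frac = 0.20,
    sd_variant = "mean_cc",
    std_variant = "region_pairs",
    n_perm = 1000L,
    alpha = 0.05,
    seed = 1L,
    binary_input = FALSE)
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(defaults, config %||% list())
  check_prob(cfg$attribution_frac, "attribution_frac")
  check_prob(cfg$alpha, "alpha")
  check_count(cfg$min_cc_size, "min_cc_size")
  check_count(cfg$n_perm, "n_perm")
  class(cfg) <- "study_config"
  cfg
}
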