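#' @keywords internal
"_PACKAGE"

# Canonical functional-system vocabulary: the seven cortical resting-state
# systems plus the cerebellum. Order is fixed; all per-system vectors use it.
SYSTEMS <- c("VIS", "SM", "DA", "VA", "LIM", "FP", "DM", "CBL")

#' Functional system names
#'
#' The eight large-scale functional systems used throughout the package:
#' visual (VIS), somatomotor (SM), dorsal attention (DA), ventral attention
#' (VA), limbic (LIM), frontoparietal (FP), default mode (DM) and cerebellar
#' (CBL). All per-system vectors (embeddings, per-scale metrics) follow this
#' order.
#'
#' @return Character vector of length 8.
#' @export
functional_systems <- function() SYSTEMS

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stopf("'%s' must be a single probability in [0, 1], got %s", name,
          paste(format(x), collapse = ","))
  invisible(x)
}

# probability that may carry one value per group (length 1 or 2)
check_prob2 <- function(x, name) {
  if (!is.numeric(x) || !length(x) %in% 1:2 || any(!is.finite(x)) ||
      any(x < 0) || any(x > 1))
    stopf("'%s' must be 1 or 2 (per-group) probabilities in [0, 1]", name)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stopf("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

# Stable hash of a configuration list, used to stamp outputs so that any
# report can be traced back to the exact parameter set that produced it.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  # 31-bit polynomial rolling hash over the serialized config;
  # dependency-free and stable across platforms.
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# All randomness goes through local RNG state so that callers' RNG streams
# are never disturbed and every function is deterministic given `seed`.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}
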