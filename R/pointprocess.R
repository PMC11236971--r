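#' Reduce regional time series to a binary point process
#'
#' Each region's time series is z-scored with its own mean and sample
#' (n - 1) standard deviation across frames; a cell is active when its
#' z-score is at or above `threshold` (one-sided: only positive deflections
#' count). Regions with zero variance are everywhere inactive.
#'
#' @param ts N x T numeric matrix of regional time series (rows = regions in
#'   region_id order).
#' @param threshold Activation threshold in SD units (default 2).
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return An `activation_raster`: integer 0/1 matrix of the same shape with
#'   attributes `threshold_used` and `sd_type`.
#' @examples
#' ts <- matrix(rnorm(50), 5, 10)
#' r <- zscore_threshold(ts)
#' mean(r)  # ~ 1 - pnorm(2)
#' @export
zscore_threshold <- function(ts, threshold = 2.0,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ts <- as.matrix(ts)
  if (ncol(ts) < 2L)
    stopf("time series must have at least 2 frames, got %d", ncol(ts))
  if (any(!is.finite(ts)))
    stopf("time series contain non-finite values")
  mu <- rowMeans(ts)
  cen <- ts - mu
  ss <- rowSums(cen^2)
  denom <- if (sd_type == "sample") ncol(ts) - 1L else ncol(ts)
  sd_r <- sqrt(ss / denom)
  z <- cen / ifelse(sd_r > 0, sd_r, Inf)   # zero-variance rows -> z = 0
  raster <- matrix(0L, nrow(ts), ncol(ts))
  raster[z >= threshold & sd_r > 0] <- 1L
  structure(raster, threshold_used = threshold, sd_type = sd_type,
            class = c("activation_raster", class(raster)))
}

#' @export
print.activation_raster <- function(x, ...) {
  cat(sprintf(
    "Activation raster: %d regions x %d frames, %d active cells (%.2f%%), threshold %g SD\n",
    nrow(x), ncol(x), sum(x), 100 * mean(x), attr(x, "threshold_used")))
  invisible(x)
}
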