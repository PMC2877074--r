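#' Filtering parameters
#'
#' Bundles every threshold of the screening procedure.  The defaults are the
#' published settings: probes are selected when their genotype fold change
#' exceeds 1.5 (or, in the stringent variant, 3) in at least two consecutive
#' time-points, while never varying more than 1.5-fold outside that window;
#' raw intensities below 10 are floored to 10 before ratios are formed, and
#' probes whose raw intensity stays under 100 are tagged as low expressors.
#'
#' @param fold_threshold Ratio (> 1) a probe must exceed, up
#'   (`r > fold_threshold`) or down (`r < 1/fold_threshold`), inside the
#'   selected window.  Published values: 1.5 and 3.
#' @param escape_threshold Ratio (> 1) bounding the allowed variation outside
#'   the window: all out-of-window ratios must lie strictly within
#'   `(1/escape_threshold, escape_threshold)`.  Published value: 1.5.
#' @param min_run Minimum number of consecutive exceeding time-points
#'   (integer >= 2).
#' @param intensity_floor Raw-intensity floor applied before division;
#'   intensities below it are replaced by it.  Published value: 10.
#' @param low_expressor_cutoff Raw intensity below which a probe is classed
#'   as a low expressor (strict `<`).  Published value: 100.
#' @param min_present_run Minimum number of consecutive "present" detection
#'   calls a probe needs, in at least one genotype's series, to survive the
#'   detection filter (integer >= 2).
#' @param require_uniform_direction If `TRUE` (default), an exceedance run
#'   must be direction-uniform; a contiguous block mixing up- and
#'   down-exceedances is split into separate runs (and hence rejected as
#'   multiple runs).  If `FALSE`, any contiguous exceedance block counts as
#'   one run of direction `"mixed"` when signs differ.
#'
#' @return An object of class `"filter_params"`.
#' @examples
#' filter_params()                    # published 1.5-fold setting
#' filter_params(fold_threshold = 3)  # stringent 3-fold setting
#' @export
filter_params <- function(fold_threshold = 1.5,
                          escape_threshold = 1.5,
                          min_run = 2L,
                          intensity_floor = 10,
                          low_expressor_cutoff = 100,
                          min_present_run = 2L,
                          require_uniform_direction = TRUE) {
  p <- list(fold_threshold = as.numeric(fold_threshold),
            escape_threshold = as.numeric(escape_threshold),
            min_run = as.integer(min_run),
            intensity_floor = as.numeric(intensity_floor),
            low_expressor_cutoff = as.numeric(low_expressor_cutoff),
            min_present_run = as.integer(min_present_run),
            require_uniform_direction = isTRUE(require_uniform_direction))
  if (!is.finite(p$escape_threshold) || p$escape_threshold <= 1)
    stop("escape_threshold must be > 1")
  if (!is.finite(p$fold_threshold) || p$fold_threshold < p$escape_threshold)
    stop("fold_threshold must be >= escape_threshold")
  if (is.na(p$min_run) || p$min_run < 2L)
    stop("min_run must be an integer >= 2")
  if (is.na(p$min_present_run) || p$min_present_run < 2L)
    stop("min_present_run must be an integer >= 2")
  if (p$intensity_floor < 0)
    stop("intensity_floor must be non-negative")
  if (p$intensity_floor >= p$low_expressor_cutoff)
    stop("intensity_floor must be below low_expressor_cutoff")
  structure(p, class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat("Filter parameters:\n")
  cat(sprintf("  fold threshold        %g (window: r > %g or r < %.4g)\n",
              x$fold_threshold, x$fold_threshold, 1 / x$fold_threshold))
  cat(sprintf("  escape threshold      %g (outside band: %.4g .. %g)\n",
              x$escape_threshold, 1 / x$escape_threshold, x$escape_threshold))
  cat(sprintf("  min run               %d consecutive time-points\n", x$min_run))
  cat(sprintf("  intensity floor       %g\n", x$intensity_floor))
  cat(sprintf("  low-expressor cutoff  %g\n", x$low_expressor_cutoff))
  cat(sprintf("  min present run       %d\n", x$min_present_run))
  cat(sprintf("  uniform direction     %s\n", x$require_uniform_direction))
  invisible(x)
}
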