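#' Floor raw intensities
#'
#' Replaces every intensity below the floor with the floor (raw values below
#' 10 correspond to "absent" signal and are set to 10 before ratios are
#' formed, so all fold changes are finite and positive).
#'
#' @param raw Non-negative numeric matrix or vector.
#' @param intensity_floor Floor in raw units (default 10).
#' @return Same shape as `raw`, with no value below the floor.
#' @examples
#' floor_intensities(c(5, 10, 40000))   # 10 10 40000
#' @export
floor_intensities <- function(raw, intensity_floor = 10) {
  if (intensity_floor < 0) stop("intensity_floor must be non-negative")
  if (any(raw < 0, na.rm = TRUE)) stop("negative intensities")
  pmax(raw, intensity_floor)
}

#' Compute genotype fold-change series per probe
#'
#' For one tissue, forms the per-time-point ratio of floored Akita intensity
#' to floored WT intensity for every probe.  Time-points where either
#' genotype's chip is missing (e.g. excluded by QC) are masked: the ratio is
#' `NA` and the mask is `TRUE` there.
#'
#' @param dataset An [expression_dataset()]; QC-excluded chips should already
#'   have been dropped with [exclude_chips()].
#' @param tissue Tissue to analyse.
#' @param params A [filter_params()] (supplies the intensity floor).
#' @param probes Optional subset of probe ids; default all probes.
#'
#' @return An object of class `"FoldChangeSeries"`: a list with
#'   `ratios` (probe x time-point matrix, `NA` at masked points),
#'   `mask` (logical per time-point, `TRUE` = no ratio available),
#'   `days` (ordered integer days), and `tissue`.
#' @examples
#' ds <- simulate_dataset(sim_params(n_probes = 20, noise_cv = 0, seed = 1))$dataset
#' fc <- compute_fold_changes(ds, "DRG", filter_params())
#' dim(fc$ratios)
#' @export
compute_fold_changes <- function(dataset, tissue, params = filter_params(),
                                 probes = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  man <- dataset$manifest
  if (!tissue %in% man$tissue) stop("tissue not in manifest: ", tissue)
  man <- man[man$tissue == tissue, , drop = FALSE]
  days <- sort(unique(man$day))
  if (is.null(probes)) probes <- rownames(dataset$raw)
  floored <- floor_intensities(
    dataset$raw[probes, , drop = FALSE], params$intensity_floor)

  ratios <- matrix(NA_real_, length(probes), length(days),
                   dimnames = list(probes, day_labels(days)))
  mask <- rep(TRUE, length(days))
  for (j in seq_along(days)) {
    ak <- man$chip_id[man$genotype == "Akita" & man$day == days[j]]
    wt <- man$chip_id[man$genotype == "WT" & man$day == days[j]]
    if (length(ak) == 1L && length(wt) == 1L) {
      ratios[, j] <- floored[, ak] / floored[, wt]
      mask[j] <- FALSE
    }
  }
  structure(list(ratios = ratios, mask = mask, days = days, tissue = tissue),
            class = "FoldChangeSeries")
}

#' @export
print.FoldChangeSeries <- function(x, ...) {
  cat(sprintf("FoldChangeSeries (%s): %d probes x %d time-points, %d masked\n",
              x$tissue, nrow(x$ratios), length(x$days), sum(x$mask)))
  invisible(x)
}

# Per-time-point exceedance state: +1 up, -1 down, 0 in-band, NA masked.
exceedance_state <- function(ratios, fold_threshold, mask = NULL) {
  s <- ifelse(ratios > fold_threshold, 1L,
              ifelse(ratios < 1 / fold_threshold, -1L, 0L))
  if (!is.null(mask)) s[mask] <- NA_integer_
  s
}

#' Find maximal exceedance runs in a fold-change series
#'
#' A run is a maximal block of consecutive unmasked time-points whose ratio
#' exceeds the fold threshold in one direction (`r > fold_threshold` up,
#' `r < 1/fold_threshold` down, both strict).  A masked time-point
#' terminates a run.
#'
#' @param ratios Numeric vector of per-time-point ratios for one probe.
#' @param params A [filter_params()].
#' @param mask Logical vector, `TRUE` where no ratio is available (default
#'   none; `NA` ratios are also treated as masked).
#' @return Data frame with columns `direction` ("up"/"down"), `start`,
#'   `end` (1-based inclusive indices) and `length`; zero rows if no run.
#' @examples
#' find_exceedance_runs(c(1, 1, 1.8, 1.8, 1, 1, 1, 1), filter_params())
#' @export
find_exceedance_runs <- function(ratios, params = filter_params(), mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(ratios))
  mask <- mask | is.na(ratios)
  s <- exceedance_state(ratios, params$fold_threshold, mask)
  # rle over the state with NA encoded as a separator that never matches
  code <- ifelse(is.na(s), 9L, s)
  if (!params$require_uniform_direction) {
    # merge contiguous nonzero blocks irrespective of sign
    grp <- ifelse(code %in% c(1L, -1L), 5L, code)
  } else grp <- code
  r <- rle(grp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c(1L, -1L, 5L)
  if (!any(keep))
    return(data.frame(direction = character(), start = integer(),
                      end = integer(), length = integer()))
  starts <- starts[keep]; ends <- ends[keep]; vals <- r$values[keep]
  dir <- vapply(seq_along(starts), function(i) {
    block <- s[starts[i]:ends[i]]
    if (all(block == 1L)) "up" else if (all(block == -1L)) "down" else "mixed"
  }, character(1))
  data.frame(direction = dir, start = starts, end = ends,
             length = ends - starts + 1L)
}

#' Classify one probe's fold-change series
#'
#' The core selection rule: a probe is accepted iff its series contains
#' exactly one exceedance run at the fold threshold, that run spans at least
#' `min_run` consecutive time-points, and every unmasked ratio outside the
#' run lies strictly within the escape band
#' `(1/escape_threshold, escape_threshold)`.  With the published setting
#' (fold = escape = 1.5) this reduces to: the exceedance set is a single
#' direction-uniform contiguous block of length >= 2.  Masked time-points
#' break runs and are exempt from the escape constraint.
#'
#' @inheritParams find_exceedance_runs
#' @return A list of class `"window_call"`: `accepted` (logical),
#'   `direction`, `start`, `end`, `run_length`, `max_magnitude` (largest
#'   `max(r, 1/r)` inside the window), and `reason` — `"accepted"` or which
#'   clause failed (`"no_exceedance_run"`, `"multiple_runs"`,
#'   `"run_too_short"`, `"escape_violation"`).
#' @examples
#' classify_probe(c(1, 1, 1.8, 1.8, 1, 1, 1, 1), filter_params())$accepted  # TRUE
#' classify_probe(c(1, 1, 1.8, 1.8, 1, 1, 1.9, 1), filter_params())$reason
#' @export
classify_probe <- function(ratios, params = filter_params(), mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(ratios))
  mask <- mask | is.na(ratios)
  runs <- find_exceedance_runs(ratios, params, mask)

  reject <- function(reason)
    structure(list(accepted = FALSE, direction = NA_character_,
                   start = NA_integer_, end = NA_integer_,
                   run_length = NA_integer_, max_magnitude = NA_real_,
                   reason = reason),
              class = "window_call")

  if (nrow(runs) == 0L) return(reject("no_exceedance_run"))
  if (nrow(runs) > 1L) return(reject("multiple_runs"))
  if (runs$length < params$min_run) return(reject("run_too_short"))

  idx <- runs$start:runs$end
  out <- setdiff(which(!mask), idx)
  r_out <- ratios[out]
  if (length(r_out) &&
      any(r_out >= params$escape_threshold | r_out <= 1 / params$escape_threshold))
    return(reject("escape_violation"))

  r_in <- ratios[idx]
  structure(list(accepted = TRUE, direction = runs$direction,
                 start = runs$start, end = runs$end,
                 run_length = runs$length,
                 max_magnitude = max(pmax(r_in, 1 / r_in)),
                 reason = "accepted"),
            class = "window_call")
}

#' @export
print.window_call <- function(x, ...) {
  if (x$accepted)
    cat(sprintf("ACCEPT: %s, time-points %d-%d (run %d), max magnitude %.3g\n",
                x$direction, x$start, x$end, x$run_length, x$max_magnitude))
  else
    cat(sprintf("REJECT: %s\n", x$reason))
  invisible(x)
}

#' Brute-force window-enumeration oracle
#'
#' Independent re-derivation of [classify_probe()] used for verification:
#' enumerates every contiguous window of unmasked time-points and literally
#' checks the three clauses (all in-window ratios exceed the fold threshold
#' in one direction; window length >= `min_run`; all unmasked out-of-window
#' ratios strictly inside the escape band).  Accepts iff some window passes.
#' Intended for short series only.
#'
#' @inheritParams find_exceedance_runs
#' @return Same contract as [classify_probe()], except `reason` is either
#'   `"accepted"` or `"no_qualifying_window"`.
#' @export
classify_probe_oracle <- function(ratios, params = filter_params(), mask = NULL) {
  n <- length(ratios)
  if (n > 16L) stop("oracle enumeration limited to series of length <= 16")
  if (is.null(mask)) mask <- rep(FALSE, n)
  mask <- mask | is.na(ratios)
  ft <- params$fold_threshold; et <- params$escape_threshold
  best <- NULL
  for (s in seq_len(n)) {
    for (e in s:n) {
      if ((e - s + 1L) < params$min_run) next
      idx <- s:e
      if (any(mask[idx])) next
      r_in <- ratios[idx]
      up <- all(r_in > ft); down <- all(r_in < 1 / ft)
      if (!up && !down) next
      out <- setdiff(which(!mask), idx)
      r_out <- ratios[out]
      if (length(r_out) && any(r_out >= et | r_out <= 1 / et)) next
      best <- list(start = s, end = e, direction = if (up) "up" else "down",
                   r_in = r_in)
    }
  }
  if (is.null(best))
    return(structure(list(accepted = FALSE, direction = NA_character_,
                          start = NA_integer_, end = NA_integer_,
                          run_length = NA_integer_, max_magnitude = NA_real_,
                          reason = "no_qualifying_window"),
                     class = "window_call"))
  structure(list(accepted = TRUE, direction = best$direction,
                 start = best$start, end = best$end,
                 run_length = best$end - best$start + 1L,
                 max_magnitude = max(pmax(best$r_in, 1 / best$r_in)),
                 reason = "accepted"),
            class = "window_call")
}

#' Classify every probe of a fold-change series object
#'
#' @param fc A `"FoldChangeSeries"` from [compute_fold_changes()].
#' @param params A [filter_params()].
#' @return A list with `calls`, a data frame of accepted probes (columns
#'   `probe_id`, `direction`, `start`, `end`, `start_day`, `end_day`,
#'   `run_length`, `max_magnitude`, `low_expressor` initialised `NA`), and
#'   `rejections`, a named table of rejection reasons.
#' @export
classify_all_probes <- function(fc, params = filter_params()) {
  stopifnot(inherits(fc, "FoldChangeSeries"))
  probes <- rownames(fc$ratios)
  rows <- vector("list", length(probes))
  reasons <- character(length(probes))
  for (i in seq_along(probes)) {
    wc <- classify_probe(fc$ratios[i, ], params, fc$mask)
    reasons[i] <- wc$reason
    if (wc$accepted)
      rows[[i]] <- data.frame(
        probe_id = probes[i], direction = wc$direction,
        start = wc$start, end = wc$end,
        start_day = fc$days[wc$start], end_day = fc$days[wc$end],
        run_length = wc$run_length, max_magnitude = wc$max_magnitude,
        low_expressor = NA)
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(calls))
    calls <- data.frame(probe_id = character(), direction = character(),
                        start = integer(), end = integer(),
                        start_day = integer(), end_day = integer(),
                        run_length = integer(), max_magnitude = numeric(),
                        low_expressor = logical())
  list(calls = calls, rejections = table(reasons[reasons != "accepted"]))
}

#' Flag low-expressor probes among accepted calls
#'
#' A probe counts as a low expressor when its summary raw intensity — the
#' median raw value across the tissue's retained chips by default — is
#' strictly below the cutoff (published cutoff: 100 raw units).
#'
#' @param calls Data frame of accepted calls from [classify_all_probes()].
#' @param dataset The (tissue-restricted, QC-applied) dataset the calls came
#'   from.
#' @param cutoff Raw-intensity cutoff (strict `<`), default from
#'   [filter_params()].
#' @param summary_fun Summary statistic across chips; `stats::median`
#'   (default) or `mean`.
#' @return `calls` with the `low_expressor` column filled in.
#' @export
flag_low_expressors <- function(calls, dataset, cutoff = 100,
                                summary_fun = stats::median) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (nrow(calls) == 0L) return(calls)
  summ <- apply(dataset$raw[calls$probe_id, , drop = FALSE], 1L, summary_fun)
  calls$low_expressor <- unname(summ < cutoff)
  calls
}
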