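#' Simulation parameters for synthetic bead-array datasets
#'
#' Describes a two-genotype (Akita vs WT), multi-time-point bead-array-like
#' experiment with known ground truth.  Probes fall into five classes:
#' `stable` (equal expression in both genotypes), `developmental_trend`
#' (a shared age trend, still equal between genotypes), `planted_window`
#' (a genuine differential window of known direction, length and fold),
#' `zigzag_low` (low-intensity probes whose genotype ratio alternates
#' direction from one time-point to the next — the noisy profiles the
#' escape constraint is designed to eliminate), and `absent` (background
#' probes carrying "absent" calls at all but at most one time-point).
#'
#' @param n_probes Number of probes (positive).
#' @param time_points Ordered integer postnatal days; default
#'   `c(20, 24, 28, 32, 36, 40, 48, 56)` (P20..P56).
#' @param class_fractions Named proportions over the five classes; must sum
#'   to 1.
#' @param planted_spec Data frame with columns `direction` (`"up"`/`"down"`),
#'   `run_length` (>= 2) and `fold` (> 1), recycled across planted probes.
#'   Default: folds of 2.0 with run lengths 2-6 in both directions.
#' @param tissues Tissue labels; one dataset spans all of them (each tissue
#'   gets its own baseline expression program, so chips cluster by tissue).
#' @param intensity_range `(low, high)` raw-intensity bounds for probes
#'   carrying real signal; default `c(10, 40000)`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise; default 0.1.
#' @param chip_scale_spread Standard deviation (log scale) of per-chip
#'   scale factors; default 0.05.
#' @param outlier_chip Optional list `list(tissue=, genotype=, day=)` naming
#'   one chip whose probe profile is replaced by an independent draw from
#'   another tissue's expression program (emulating a tissue swap), the
#'   scenario behind clustering-based chip elimination.
#' @param call_thresholds Named vector `c(absent=, marginal=)`: a probe's
#'   true signal below `absent` yields an "A" call, below `marginal` an
#'   "M", otherwise "P".  Defaults `c(absent = 10, marginal = 20)`.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(n_probes = 2000,
                       time_points = c(20L, 24L, 28L, 32L, 36L, 40L, 48L, 56L),
                       class_fractions = c(stable = 0.55,
                                           developmental_trend = 0.15,
                                           planted_window = 0.05,
                                           zigzag_low = 0.15,
                                           absent = 0.10),
                       planted_spec = NULL,
                       tissues = "DRG",
                       intensity_range = c(10, 40000),
                       noise_cv = 0.1,
                       chip_scale_spread = 0.05,
                       outlier_chip = NULL,
                       call_thresholds = c(absent = 10, marginal = 20),
                       seed = NULL) {
  n_probes <- as.integer(n_probes)
  if (is.na(n_probes) || n_probes <= 0L) stop("n_probes must be positive")
  time_points <- as.integer(time_points)
  if (any(diff(time_points) <= 0L)) stop("time_points must be increasing")
  classes <- c("stable", "developmental_trend", "planted_window",
               "zigzag_low", "absent")
  cf <- rep(0, length(classes)); names(cf) <- classes
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% classes))
    stop("class_fractions must be named with classes among: ",
         paste(classes, collapse = ", "))
  cf[names(class_fractions)] <- class_fractions
  if (abs(sum(cf) - 1) > 1e-8) stop("class_fractions must sum to 1")
  if (is.null(planted_spec))
    planted_spec <- data.frame(
      direction = rep(c("up", "down"), 4L),
      run_length = c(2L, 2L, 2L, 3L, 3L, 4L, 5L, 6L),
      fold = 2.0)
  if (!all(c("direction", "run_length", "fold") %in% names(planted_spec)))
    stop("planted_spec needs columns direction, run_length, fold")
  if (!all(planted_spec$direction %in% c("up", "down")))
    stop("planted direction must be 'up' or 'down'")
  if (any(planted_spec$run_length < 2L))
    stop("planted run_length must be >= 2")
  if (any(planted_spec$run_length > length(time_points)))
    stop("planted run_length exceeds the number of time-points")
  if (any(planted_spec$fold <= 1)) stop("planted fold must be > 1")
  if (length(intensity_range) != 2L || any(intensity_range <= 0) ||
      intensity_range[1L] >= intensity_range[2L])
    stop("intensity_range must be positive with low < high")
  if (noise_cv < 0 || chip_scale_spread < 0)
    stop("noise_cv and chip_scale_spread must be non-negative")
  if (!is.null(outlier_chip)) {
    if (!all(c("genotype", "day") %in% names(outlier_chip)))
      stop("outlier_chip needs at least genotype and day")
    if (is.null(outlier_chip$tissue)) outlier_chip$tissue <- tissues[1L]
    if (!outlier_chip$tissue %in% tissues ||
        !outlier_chip$genotype %in% c("Akita", "WT") ||
        !as.integer(outlier_chip$day) %in% time_points)
      stop("outlier_chip does not name a chip of this design")
  }
  structure(list(n_probes = n_probes, time_points = time_points,
                 class_fractions = cf, planted_spec = planted_spec,
                 tissues = as.character(tissues),
                 intensity_range = as.numeric(intensity_range),
                 noise_cv = as.numeric(noise_cv),
                 chip_scale_spread = as.numeric(chip_scale_spread),
                 outlier_chip = outlier_chip,
                 call_thresholds = call_thresholds,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_params")
}

#' Simulate a synthetic bead-array dataset with ground truth
#'
#' Generates the full chip set (`|time_points|` x 2 genotypes per tissue;
#' the optional outlier chip is emitted too — it is the QC stage's job to
#' remove it).  Intensities follow a log-uniform per-probe baseline spanning
#' the intensity range with multiplicative log-normal noise and per-chip
#' scale factors; detection calls derive from the true (noise-free) signal.
#' At `noise_cv = 0` and `chip_scale_spread = 0`, planted probes have
#' genotype-ratio exceedance exactly over their true window and ratio
#' exactly 1 elsewhere.
#'
#' @param params A [sim_params()].
#' @return A list with `dataset` (an [expression_dataset()]) and `truth`,
#'   a data frame with one row per probe: `probe_id`, `class`, `direction`,
#'   `window_start`, `window_end` (1-based time-point indices), `fold`, and
#'   `low_expressor` (baseline below 100 in the first tissue).
#' @examples
#' sim <- simulate_dataset(sim_params(n_probes = 100, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(params$seed)
  }
  n <- params$n_probes
  days <- params$time_points
  Tn <- length(days)
  lo <- params$intensity_range[1L]; hi <- params$intensity_range[2L]
  # headroom so noisy present-class intensities stay inside the range
  # (residual excursions are clamped, emulating scanner saturation)
  head_f <- 1 + 6 * params$noise_cv + 6 * params$chip_scale_spread

  # class sizes: rounded fractions, remainder absorbed by the largest class
  sizes <- floor(params$class_fractions * n)
  sizes[which.max(sizes)] <- sizes[which.max(sizes)] + (n - sum(sizes))
  class <- rep(names(sizes), times = sizes)
  probe_ids <- sprintf("probe_%05d", seq_len(n))

  is_planted <- class == "planted_window"
  npl <- sum(is_planted)
  spec <- params$planted_spec[
    ((seq_len(npl) - 1L) %% nrow(params$planted_spec)) + 1L, , drop = FALSE]
  max_fold <- if (npl) max(spec$fold) else 1

  truth <- data.frame(probe_id = probe_ids, class = class,
                      direction = NA_character_,
                      window_start = NA_integer_, window_end = NA_integer_,
                      fold = NA_real_, low_expressor = NA)
  if (npl) {
    truth$direction[is_planted] <- spec$direction
    truth$fold[is_planted] <- spec$fold
    ws <- vapply(spec$run_length, function(L)
      sample.int(Tn - L + 1L, 1L), integer(1))
    truth$window_start[is_planted] <- ws
    truth$window_end[is_planted] <- ws + spec$run_length - 1L
  }

  # per-tissue log-uniform baselines; floors keep each class in its regime
  runif_log <- function(m, a, b) exp(stats::runif(m, log(a), log(b)))
  base_for_class <- function(cl) {
    m <- sum(class == cl)
    switch(cl,
      stable = ,
      developmental_trend = runif_log(m, 30, hi / (head_f * 1.5)),
      planted_window = runif_log(m, 300, hi / (head_f * max_fold)),
      zigzag_low = stats::runif(m, 25, 95),
      absent = stats::runif(m, 1, 9))
  }
  baseline <- matrix(NA_real_, n, length(params$tissues),
                     dimnames = list(probe_ids, params$tissues))
  for (k in seq_along(params$tissues))
    for (cl in names(sizes))
      baseline[class == cl, k] <- base_for_class(cl)
  truth$low_expressor <- baseline[, 1L] < 100

  # shared developmental trend (identical in both genotypes, ratio stays 1)
  z <- (seq_len(Tn) - (Tn + 1) / 2) / (Tn - 1)      # centred, range 1
  trend <- matrix(1, n, Tn)
  is_trend <- class == "developmental_trend"
  if (any(is_trend)) {
    slope <- stats::runif(sum(is_trend), -1, 1)      # |log2 drift| <= 0.5
    trend[is_trend, ] <- 2^(outer(slope, z))
  }

  # true Akita/WT ratio per probe x time-point
  ratio <- matrix(1, n, Tn)
  if (npl) {
    wpl <- which(is_planted)
    for (i in seq_along(wpl)) {
      idx <- truth$window_start[wpl[i]]:truth$window_end[wpl[i]]
      f <- if (spec$direction[i] == "up") spec$fold[i] else 1 / spec$fold[i]
      ratio[wpl[i], idx] <- f
    }
  }
  is_zig <- class == "zigzag_low"
  if (any(is_zig)) {
    wz <- which(is_zig)
    amp <- stats::runif(length(wz), 1.6, 2.5)
    phase <- sample(c(0L, 1L), length(wz), replace = TRUE)
    jit <- matrix(stats::runif(length(wz) * Tn, 0.9, 1.1), length(wz), Tn)
    sgn <- outer(phase, seq_len(Tn), function(p, t) (-1)^(p + t))
    ratio[wz, ] <- (amp^sgn) * jit
  }

  # flicker: roughly half the absent probes show one spurious present call
  flick <- data.frame(probe = integer(), tissue = character(),
                      genotype = character(), t = integer())
  wa <- which(class == "absent")
  if (length(wa)) {
    do_fl <- stats::runif(length(wa)) < 0.5
    for (i in wa[do_fl])
      flick <- rbind(flick, data.frame(
        probe = i, tissue = sample(params$tissues, 1L),
        genotype = sample(c("Akita", "WT"), 1L),
        t = sample.int(Tn, 1L)))
  }

  chips <- expand.grid(day = days, genotype = c("Akita", "WT"),
                       tissue = params$tissues, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  chips$chip_id <- sprintf("%s_%s_P%d", chips$tissue, chips$genotype, chips$day)

  sdlog <- sqrt(log(1 + params$noise_cv^2))
  raw <- matrix(NA_real_, n, nrow(chips),
                dimnames = list(probe_ids, chips$chip_id))
  calls <- matrix("P", n, nrow(chips), dimnames = dimnames(raw))
  ct <- params$call_thresholds

  for (j in seq_len(nrow(chips))) {
    tis <- chips$tissue[j]; g <- chips$genotype[j]
    t_idx <- match(chips$day[j], days)
    signal <- baseline[, tis] * trend[, t_idx]
    if (g == "Akita") signal <- signal * ratio[, t_idx]

    oc <- params$outlier_chip
    if (!is.null(oc) && oc$tissue == tis && oc$genotype == g &&
        as.integer(oc$day) == chips$day[j]) {
      # tissue swap: an independent draw from another expression program
      if (length(params$tissues) > 1L) {
        other <- setdiff(params$tissues, tis)[1L]
        signal <- baseline[, other] * trend[, t_idx]
      } else {
        signal <- sample(signal)
      }
    }

    calls[, j] <- ifelse(signal < ct[["absent"]], "A",
                         ifelse(signal < ct[["marginal"]], "M", "P"))
    scale_c <- exp(stats::rnorm(1L, 0, params$chip_scale_spread))
    noise <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    raw[, j] <- signal * scale_c * noise
  }

  if (nrow(flick))
    for (i in seq_len(nrow(flick))) {
      cid <- sprintf("%s_%s_P%d", flick$tissue[i], flick$genotype[i],
                     days[flick$t[i]])
      calls[flick$probe[i], cid] <- "P"
    }

  # saturation / background clamp keeps signal-bearing probes in range
  raw <- pmin(raw, hi)
  present_rows <- class != "absent"
  raw[present_rows, ] <- pmax(raw[present_rows, , drop = FALSE], lo)

  manifest <- chips[, c("chip_id", "tissue", "genotype", "day")]
  list(dataset = expression_dataset(raw, calls, manifest), truth = truth)
}

#' Canonical filtering-rule example profiles
#'
#' Four per-probe fold-change patterns illustrating the selection rule at
#' the 1.5-fold setting over the eight standard time-points:
#' \describe{
#'   \item{A}{up-regulation in 2 consecutive time-points — selected}
#'   \item{B}{down-regulation in 3 consecutive time-points — selected}
#'   \item{C}{up-regulation in 2 consecutive time-points plus an isolated
#'     later up-excursion — eliminated by the escape constraint}
#'   \item{D}{down-regulation in 3 consecutive time-points followed by a
#'     later up-excursion — eliminated}
#' }
#'
#' @return Named list of panels, each a list with `ratios` (length 8),
#'   `days`, `decision` (`"selected"`/`"eliminated"`) and, for selected
#'   panels, `direction` and `run_length`.
#' @export
example_profiles <- function() {
  days <- c(20L, 24L, 28L, 32L, 36L, 40L, 48L, 56L)
  list(
    A = list(ratios = c(1, 1, 1.8, 1.8, 1, 1, 1, 1), days = days,
             decision = "selected", direction = "up", run_length = 2L),
    B = list(ratios = c(1, 1, 0.5, 0.5, 0.5, 1, 1, 1), days = days,
             decision = "selected", direction = "down", run_length = 3L),
    C = list(ratios = c(1, 1, 1.8, 1.8, 1, 1, 1.9, 1), days = days,
             decision = "eliminated"),
    D = list(ratios = c(1, 1, 0.5, 0.5, 0.5, 1, 1, 1.7), days = days,
             decision = "eliminated"))
}

#' Write the canonical example fixtures to disk
#'
#' Emits the four [example_profiles()] fold-change series and their expected
#' decisions as tab-delimited files, for use as golden test fixtures.
#'
#' @param out_dir Writable directory (created if needed).
#' @return Named character vector of the files written
#'   (`profiles`, `expected`).
#' @export
write_fixture_suite <- function(out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
    stop("cannot write to directory: ", out_dir)
  pan <- example_profiles()
  prof <- do.call(rbind, lapply(names(pan), function(p)
    data.frame(panel = p, day = pan[[p]]$days, ratio = pan[[p]]$ratios)))
  exp <- do.call(rbind, lapply(names(pan), function(p)
    data.frame(panel = p, decision = pan[[p]]$decision,
               direction = if (is.null(pan[[p]]$direction)) NA_character_
                           else pan[[p]]$direction,
               run_length = if (is.null(pan[[p]]$run_length)) NA_integer_
                            else pan[[p]]$run_length)))
  files <- c(profiles = file.path(out_dir, "example_fold_changes.tsv"),
             expected = file.path(out_dir, "example_expected.tsv"))
  utils::write.table(prof, files[["profiles"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(exp, files[["expected"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files
}
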