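#' Run-length summary of accepted probes
#'
#' The headline summary table: for each minimum run length k in 2..6, the
#' number of accepted probes whose differential window spans at least k
#' consecutive time-points, with the low-expressor sub-count, alongside the
#' platform size and the number of probes eliminated by the detection
#' filter.  Counts are cumulative in k (the row at k = 2 includes every
#' longer run), so they are non-increasing; an exact-length mode is
#' available via `cumulative = FALSE`.
#'
#' @param calls Accepted-call data frame ([classify_all_probes()], with
#'   low-expressor flags filled by [flag_low_expressors()]).
#' @param platform_size Total number of probes on the platform.
#' @param eliminated Number of probes removed by the detection filter.
#' @param tissue Tissue label carried into the table.
#' @param k Run lengths to tabulate; default `2:6`.
#' @param cumulative Count runs of length `>= k` (default) or exactly `k`.
#' @return An object of class `"run_length_summary"`; its
#'   `as.data.frame()` has columns `tissue`, `min_run`, `n_probes`,
#'   `n_low_expressor`, `platform_size`, `eliminated`.
#' @examples
#' calls <- data.frame(probe_id = letters[1:4], run_length = c(2, 2, 3, 5),
#'                     low_expressor = c(TRUE, FALSE, TRUE, FALSE))
#' run_length_summary(calls, platform_size = 100, eliminated = 60)
#' @export
run_length_summary <- function(calls, platform_size, eliminated,
                               tissue = NA_character_, k = 2:6,
                               cumulative = TRUE) {
  n <- vapply(k, function(kk) {
    sel <- if (cumulative) calls$run_length >= kk else calls$run_length == kk
    sum(sel)
  }, integer(1))
  nle <- vapply(k, function(kk) {
    sel <- if (cumulative) calls$run_length >= kk else calls$run_length == kk
    sum(sel & calls$low_expressor %in% TRUE)
  }, integer(1))
  structure(list(table = data.frame(
    tissue = tissue, min_run = as.integer(k), n_probes = n,
    n_low_expressor = nle, platform_size = as.integer(platform_size),
    eliminated = as.integer(eliminated)),
    cumulative = cumulative),
    class = "run_length_summary")
}

#' @export
as.data.frame.run_length_summary <- function(x, ...) x$table

#' @export
print.run_length_summary <- function(x, ...) {
  t <- x$table
  cat(sprintf("Run-length summary%s (%s runs), platform %d probes, %d eliminated by detection filter:\n",
              if (is.na(t$tissue[1L])) "" else paste0(" [", t$tissue[1L], "]"),
              if (x$cumulative) ">= k" else "exactly k",
              t$platform_size[1L], t$eliminated[1L]))
  for (i in seq_len(nrow(t)))
    cat(sprintf("  k = %d: %4d probes (%d low expressors)\n",
                t$min_run[i], t$n_probes[i], t$n_low_expressor[i]))
  invisible(x)
}

#' Candidate gene panels
#'
#' The three profile panels examined for candidate genes: sensory-neuron
#' development and sodium channels (DRG), Schwann-cell myelination
#' (endoneurium), and cholesterol metabolism (endoneurium).  Shipped as a
#' packaged table; probe mappings are platform-annotation data and are
#' supplied separately (see [panel_profiles()]).
#'
#' @param panel Optional panel name to subset to.
#' @return Data frame with columns `panel` and `gene`.
#' @export
gene_panels <- function(panel = NULL) {
  path <- system.file("extdata", "gene_panels.tsv", package = "tcscreen",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, colClasses = "character")
  if (!is.null(panel)) {
    if (!panel %in% tab$panel)
      stop("unknown panel: ", panel, " (available: ",
           paste(unique(tab$panel), collapse = ", "), ")")
    tab <- tab[tab$panel == panel, , drop = FALSE]
  }
  tab
}

#' Median-normalized profiles for a gene panel
#'
#' Maps panel gene symbols to probes through a user-supplied mapping table,
#' extracts median-normalized per-genotype time profiles via
#' [median_profile()], and flags whether each mapped gene would trigger the
#' consecutive-window filter at the given parameters (the coherence check
#' that none of the candidate genes met the 1.5-fold criterion).
#'
#' @param dataset A QC-applied [expression_dataset()].
#' @param panel Data frame with a `gene` column (e.g. from
#'   [gene_panels()]), or a panel name.
#' @param mapping Data frame with columns `gene`, `probe_id` linking symbols
#'   to platform probes.
#' @param tissue Tissue to profile (default the single tissue present).
#' @param params A [filter_params()] used for the filter flag.
#' @return A list with `profiles` (tidy data frame: `gene`, `probe_id`,
#'   `day`, `genotype`, `value`), `filter_flags` (per mapped gene, `TRUE`
#'   iff any of its probes is accepted by [classify_probe()]), and
#'   `unmapped` (symbols without a probe).
#' @export
panel_profiles <- function(dataset, panel, mapping, tissue = NULL,
                           params = filter_params()) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.character(panel) && length(panel) == 1L) panel <- gene_panels(panel)
  if (!all(c("gene", "probe_id") %in% names(mapping)))
    stop("mapping needs columns gene, probe_id")
  genes <- unique(panel$gene)
  map <- mapping[mapping$gene %in% genes &
                   mapping$probe_id %in% rownames(dataset$raw), , drop = FALSE]
  unmapped <- setdiff(genes, map$gene)
  if (nrow(map) == 0L)
    return(list(profiles = data.frame(gene = character(),
                                      probe_id = character(), day = integer(),
                                      genotype = character(), value = numeric()),
                filter_flags = logical(), unmapped = unmapped))
  if (is.null(tissue)) {
    tissue <- unique(dataset$manifest$tissue)
    if (length(tissue) > 1L)
      stop("dataset has multiple tissues; specify 'tissue'")
  }
  prof <- median_profile(dataset, unique(map$probe_id), tissue)
  prof$gene <- map$gene[match(prof$probe_id, map$probe_id)]
  prof <- prof[, c("gene", "probe_id", "day", "genotype", "value")]

  fc <- compute_fold_changes(dataset, tissue, params,
                             probes = unique(map$probe_id))
  acc <- vapply(rownames(fc$ratios), function(p)
    classify_probe(fc$ratios[p, ], params, fc$mask)$accepted, logical(1))
  flags <- vapply(unique(map$gene), function(g)
    any(acc[map$probe_id[map$gene == g]]), logical(1))
  list(profiles = prof, filter_flags = flags, unmapped = unmapped)
}

#' Plot panel profiles
#'
#' Line plot of median-normalized expression against postnatal day, one
#' facet per gene, coloured by genotype.  Requires ggplot2.
#'
#' @param profiles The `profiles` element of [panel_profiles()].
#' @return A ggplot object.
#' @export
plot_panel_profiles <- function(profiles) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = day, y = value, colour = genotype)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~gene) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "postnatal day", y = "median-normalized intensity")
}

#' Run the full screening pipeline
#'
#' QC (chip summaries, optional correlation-clustering outlier detection)
#' -> chip exclusion -> per-tissue normalization -> detection filter ->
#' floored fold-change windows -> low-expressor flagging -> run-length
#' summary, writing all tables plus a log of every parameter, every
#' excluded chip with its reason, and every elimination count.  Re-running
#' with identical inputs and config is bit-identical.
#'
#' @param config Named list (or path to a YAML file read by
#'   [read_config()]) with keys: `matrix`, `calls`, `manifest` (input
#'   paths; alternatively pass `dataset`), `tissues` (default: all in the
#'   manifest), `normalization` (`"quantile"`/`"none"`, default quantile),
#'   `qc_cluster` (logical, default `TRUE` when >= 2 tissues),
#'   `manual_exclusions`, `genotype_rule`, `mask_rule`, the
#'   [filter_params()] fields, and `out_dir`.
#' @param dataset Optionally, an in-memory [expression_dataset()] instead
#'   of input paths.
#' @return Invisibly, a list with per-tissue `calls` and `summary`, the
#'   `qc` report, `excluded` chip ids, and `files`, the manifest of files
#'   written.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  stopifnot(is.list(config))
  get_cfg <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  if (is.null(dataset)) {
    for (key in c("matrix", "calls", "manifest"))
      if (is.null(config[[key]]))
        stop("config key '", key, "' is required when no dataset is given")
    dataset <- read_dataset(config$matrix, config$calls, config$manifest)
  }
  params <- filter_params(
    fold_threshold = get_cfg("fold_threshold", 1.5),
    escape_threshold = get_cfg("escape_threshold", 1.5),
    min_run = get_cfg("min_run", 2L),
    intensity_floor = get_cfg("intensity_floor", 10),
    low_expressor_cutoff = get_cfg("low_expressor_cutoff", 100),
    min_present_run = get_cfg("min_present_run", 2L),
    require_uniform_direction = get_cfg("require_uniform_direction", TRUE))
  out_dir <- get_cfg("out_dir", stop("config key 'out_dir' is required"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tissues <- get_cfg("tissues", unique(dataset$manifest$tissue))
  manual <- get_cfg("manual_exclusions", character())
  bad <- setdiff(manual, dataset$manifest$chip_id)
  if (length(bad)) stop("manual exclusion of unknown chip(s): ",
                        paste(bad, collapse = ", "))
  do_cluster <- get_cfg("qc_cluster",
                        length(unique(dataset$manifest$tissue)) >= 2L)
  genotype_rule <- get_cfg("genotype_rule", "either")
  mask_rule <- get_cfg("mask_rule", "break")
  normalization <- get_cfg("normalization", "quantile")

  log_path <- file.path(out_dir, "pipeline_log.txt")
  logf <- file(log_path, "w")
  on.exit(close(logf), add = TRUE)
  logline <- function(...) writeLines(sprintf(...), logf)
  logline("tcscreen pipeline log")
  logline("fold_threshold=%g escape_threshold=%g min_run=%d intensity_floor=%g",
          params$fold_threshold, params$escape_threshold, params$min_run,
          params$intensity_floor)
  logline("low_expressor_cutoff=%g min_present_run=%d uniform_direction=%s",
          params$low_expressor_cutoff, params$min_present_run,
          params$require_uniform_direction)
  logline("normalization=%s genotype_rule=%s mask_rule=%s qc_cluster=%s",
          normalization, genotype_rule, mask_rule, do_cluster)

  qc <- if (do_cluster) chip_qc_report(dataset, manual)
        else {
          rep <- chip_summary(dataset)
          rep$outlier <- rep$chip_id %in% manual
          rep$reason <- ifelse(rep$outlier, "manual", "")
          rep
        }
  excluded <- qc$chip_id[qc$outlier]
  for (i in which(qc$outlier))
    logline("excluded chip %s: %s", qc$chip_id[i], qc$reason[i])
  files <- c(log = log_path, qc = file.path(out_dir, "chip_qc.tsv"))
  utils::write.table(qc, files[["qc"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  retained <- exclude_chips(dataset, excluded)
  retained <- normalize_per_tissue(retained, normalization)

  results <- list()
  for (tis in tissues) {
    sub <- subset_tissue(retained, tis)
    det <- consecutive_present_filter(sub, tis, params,
                                      genotype_rule = genotype_rule,
                                      mask_rule = mask_rule)
    logline("[%s] detection filter eliminated %d of %d probes",
            tis, det$eliminated, det$n_total)
    fc <- compute_fold_changes(sub, tis, params, probes = det$retained)
    cls <- classify_all_probes(fc, params)
    calls <- flag_low_expressors(cls$calls, sub,
                                 cutoff = params$low_expressor_cutoff)
    for (r in names(cls$rejections))
      logline("[%s] rejection %s: %d", tis, r, cls$rejections[[r]])
    summ <- run_length_summary(calls, platform_size = det$n_total,
                               eliminated = det$eliminated, tissue = tis)
    f <- write_results(calls, summ, out_dir, prefix = tis)
    logline("[%s] accepted %d probes (%d low expressors)",
            tis, nrow(calls), sum(calls$low_expressor %in% TRUE))
    files <- c(files, f)
    results[[tis]] <- list(calls = calls, summary = summ,
                           detection = det)
  }
  invisible(list(tissues = results, qc = qc, excluded = excluded,
                 files = files))
}
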