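#' Write an expression dataset as tab-delimited files
#'
#' Three files: the intensity matrix (probes as rows, chip ids as header),
#' the call matrix with tokens "A"/"M"/"P" in the same layout, and the
#' manifest (`chip_id`, `tissue`, `genotype`, `day`).
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,calls_path,manifest_path Output file paths.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_dataset <- function(dataset, matrix_path, calls_path, manifest_path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  write_mat <- function(m, path) {
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(dataset$raw, matrix_path)
  write_mat(dataset$calls, calls_path)
  utils::write.table(dataset$manifest, manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix = matrix_path, calls = calls_path,
              manifest = manifest_path))
}

#' Read an expression dataset from tab-delimited files
#'
#' Counterpart of [write_dataset()].  The matrix and call files must share
#' identical probe and chip axes; unknown call tokens and negative
#' intensities are rejected with the offending cell named; the manifest is
#' validated against the matrix columns (duplicate (tissue, genotype, day)
#' combinations are errors).
#'
#' @param matrix_path,calls_path,manifest_path Paths written by
#'   [write_dataset()] (or any files in the same layout).
#' @return A validated [expression_dataset()].
#' @export
read_dataset <- function(matrix_path, calls_path, manifest_path) {
  read_mat <- function(path, what) {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = c(probe_id = "character"))
    if (names(df)[1L] != "probe_id")
      stop("first column of ", what, " file must be 'probe_id'")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$probe_id
    m
  }
  raw <- read_mat(matrix_path, "matrix")
  storage.mode(raw) <- "double"
  calls_df <- utils::read.delim(calls_path, check.names = FALSE,
                                colClasses = "character")
  if (names(calls_df)[1L] != "probe_id")
    stop("first column of calls file must be 'probe_id'")
  calls <- as.matrix(calls_df[, -1L, drop = FALSE])
  rownames(calls) <- calls_df$probe_id
  if (!identical(dim(calls), dim(raw)))
    stop(sprintf("shape mismatch: matrix is %d x %d but calls is %d x %d",
                 nrow(raw), ncol(raw), nrow(calls), ncol(calls)))
  manifest <- utils::read.delim(manifest_path,
                                colClasses = c(chip_id = "character"))
  expression_dataset(raw, calls, manifest)
}

#' Write probe-level results and the run-length summary
#'
#' The probe-level table has one row per accepted probe (probe id,
#' direction, window start/end days, run length, low-expressor flag, max
#' in-window magnitude) in a deterministic order: run length descending,
#' then probe id.  An empty call set yields a header-only file and a
#' summary of zeros.
#'
#' @param calls Accepted-call data frame from [classify_all_probes()] /
#'   [flag_low_expressors()].
#' @param summary A [run_length_summary()].
#' @param out_dir Writable output directory (created if needed).
#' @param prefix File-name prefix, e.g. the tissue label.
#' @return Named character vector of files written (`results`, `summary`).
#' @export
write_results <- function(calls, summary, out_dir, prefix = "results") {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
    stop("cannot write to directory: ", out_dir)
  cols <- c("probe_id", "direction", "start_day", "end_day", "run_length",
            "low_expressor", "max_magnitude")
  out <- calls[order(-calls$run_length, calls$probe_id), cols, drop = FALSE]
  files <- c(
    results = file.path(out_dir, paste0(prefix, "_probes.tsv")),
    summary = file.path(out_dir, paste0(prefix, "_summary.tsv")))
  utils::write.table(out, files[["results"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(summary), files[["summary"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files
}

#' Read an analysis configuration file
#'
#' YAML configuration mirroring the arguments of [run_pipeline()].  Unknown
#' keys are errors, so a typo cannot silently fall back to a default.
#'
#' @param path Path to a YAML file.
#' @return A named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("matrix", "calls", "manifest", "tissues", "normalization",
             "qc_cluster", "manual_exclusions", "genotype_rule", "mask_rule",
             "fold_threshold", "escape_threshold", "min_run",
             "intensity_floor", "low_expressor_cutoff", "min_present_run",
             "require_uniform_direction", "out_dir", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  cfg
}
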