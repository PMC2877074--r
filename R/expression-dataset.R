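#' Construct an expression dataset
#'
#' The universal substrate of the pipeline: a probe x chip raw-intensity
#' matrix, a matching matrix of detection calls, and a sample manifest.
#' Each chip is one hybridized array identified by tissue, genotype and
#' postnatal day.
#'
#' @param raw Numeric probe x chip matrix of non-negative raw intensities,
#'   with probe ids as rownames and chip ids as colnames.
#' @param calls Character matrix of the same shape and dimnames as `raw`,
#'   with detection-call tokens `"A"` (absent), `"M"` (marginal) or
#'   `"P"` (present).
#' @param manifest Data frame with one row per chip and columns
#'   `chip_id`, `tissue`, `genotype` (one of `"Akita"`, `"WT"`) and
#'   `day` (positive integer postnatal day, e.g. 20 for P20).
#'
#' @return An object of class `"ExpressionDataset"`: a list with elements
#'   `raw`, `calls` and `manifest`.
#'
#' @details Within a tissue each (genotype, day) pair may map to at most one
#'   chip; the design has no chip replicates.  Days are stored as integers so
#'   that ordering and gap handling are arithmetic; display labels "P20",
#'   "P24", ... are derived.
#'
#' @examples
#' raw <- matrix(100, 2, 2, dimnames = list(c("p1", "p2"), c("c1", "c2")))
#' calls <- matrix("P", 2, 2, dimnames = dimnames(raw))
#' man <- data.frame(chip_id = c("c1", "c2"), tissue = "DRG",
#'                   genotype = c("Akita", "WT"), day = 20L)
#' expression_dataset(raw, calls, man)
#' @export
expression_dataset <- function(raw, calls, manifest) {
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("'raw' must be a numeric matrix")
  if (is.null(rownames(raw)) || is.null(colnames(raw)))
    stop("'raw' must have probe rownames and chip colnames")
  if (anyDuplicated(rownames(raw)))
    stop("duplicate probe ids in 'raw'")
  if (anyDuplicated(colnames(raw)))
    stop("duplicate chip ids in 'raw'")
  if (any(raw < 0))
    stop("negative intensities in 'raw'")
  if (!is.matrix(calls) || !identical(dim(calls), dim(raw)))
    stop("'calls' must be a matrix with the same shape as 'raw'")
  if (!identical(dimnames(calls), dimnames(raw)))
    stop("'calls' dimnames differ from 'raw'")
  bad <- which(!calls %in% c("A", "M", "P"))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(calls))
    stop(sprintf(
      "unknown call token %s at probe '%s', chip '%s'",
      dQuote(calls[bad[1L]]), rownames(calls)[i[1L]], colnames(calls)[i[2L]]))
  }
  manifest <- validate_manifest(manifest, colnames(raw))
  structure(list(raw = raw, calls = calls, manifest = manifest),
            class = "ExpressionDataset")
}

validate_manifest <- function(manifest, chip_ids) {
  need <- c("chip_id", "tissue", "genotype", "day")
  if (!is.data.frame(manifest) || !all(need %in% names(manifest)))
    stop("manifest must be a data frame with columns ",
         paste(need, collapse = ", "))
  manifest <- as.data.frame(manifest)[, need]
  manifest$chip_id <- as.character(manifest$chip_id)
  manifest$tissue <- as.character(manifest$tissue)
  manifest$genotype <- as.character(manifest$genotype)
  manifest$day <- as.integer(manifest$day)
  if (!setequal(manifest$chip_id, chip_ids) ||
      anyDuplicated(manifest$chip_id))
    stop("manifest chip_ids must match matrix columns exactly, once each")
  if (!all(manifest$genotype %in% c("Akita", "WT")))
    stop("genotype must be 'Akita' or 'WT'")
  if (any(is.na(manifest$day)) || any(manifest$day <= 0))
    stop("day must be a positive integer")
  key <- paste(manifest$tissue, manifest$genotype, manifest$day)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate chip for (tissue, genotype, day): ", d)
  }
  # manifest rows in matrix column order
  manifest[match(chip_ids, manifest$chip_id), , drop = FALSE]
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d probes x %d chips\n",
              nrow(x$raw), ncol(x$raw)))
  for (tis in unique(x$manifest$tissue)) {
    m <- x$manifest[x$manifest$tissue == tis, ]
    cat(sprintf("  %s: %d chips, days %s\n", tis, nrow(m),
                paste(day_labels(sort(unique(m$day))), collapse = " ")))
  }
  invisible(x)
}

#' Postnatal-day labels
#'
#' @param day Integer vector of postnatal days.
#' @return Character vector like `"P20"`.
#' @export
day_labels <- function(day) paste0("P", as.integer(day))

#' Restrict a dataset to a subset of chips
#'
#' @param dataset An [expression_dataset()].
#' @param chip_ids Chips to keep (in the dataset's column order).
#' @return A new `ExpressionDataset` with only those chips.
#' @export
keep_chips <- function(dataset, chip_ids) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!all(chip_ids %in% colnames(dataset$raw)))
    stop("unknown chip id(s): ",
         paste(setdiff(chip_ids, colnames(dataset$raw)), collapse = ", "))
  keep <- colnames(dataset$raw) %in% chip_ids
  expression_dataset(
    dataset$raw[, keep, drop = FALSE],
    dataset$calls[, keep, drop = FALSE],
    dataset$manifest[keep, , drop = FALSE])
}

#' Drop chips from a dataset
#'
#' Typically used to apply QC exclusions before downstream filtering.
#'
#' @inheritParams keep_chips
#' @param chip_ids Chips to remove.
#' @return A new `ExpressionDataset` without those chips.
#' @export
exclude_chips <- function(dataset, chip_ids) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (length(chip_ids) == 0L) return(dataset)
  if (!all(chip_ids %in% colnames(dataset$raw)))
    stop("unknown chip id(s): ",
         paste(setdiff(chip_ids, colnames(dataset$raw)), collapse = ", "))
  keep_chips(dataset, setdiff(colnames(dataset$raw), chip_ids))
}

#' Restrict a dataset to one tissue
#'
#' @inheritParams keep_chips
#' @param tissue Tissue label present in the manifest.
#' @export
subset_tissue <- function(dataset, tissue) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!tissue %in% dataset$manifest$tissue)
    stop("tissue not in manifest: ", tissue)
  keep_chips(dataset, dataset$manifest$chip_id[dataset$manifest$tissue == tissue])
}
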