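#' Per-chip summary statistics
#'
#' Mean raw intensity and fraction of probes called "present" for each chip,
#' the first-line QC numbers inspected before filtering.
#'
#' @param dataset An [expression_dataset()].
#' @return Data frame with columns `chip_id`, `tissue`, `genotype`, `day`,
#'   `mean_intensity`, `fraction_present`, one row per chip.
#' @export
chip_summary <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (nrow(dataset$raw) == 0L) stop("empty dataset")
  man <- dataset$manifest
  data.frame(
    chip_id = man$chip_id, tissue = man$tissue, genotype = man$genotype,
    day = man$day,
    mean_intensity = unname(colMeans(dataset$raw[, man$chip_id, drop = FALSE])),
    fraction_present =
      unname(colMeans(dataset$calls[, man$chip_id, drop = FALSE] == "P")))
}

#' Flag misclustering chips by correlation clustering
#'
#' Chips are clustered hierarchically (average linkage by default) on
#' 1 - Pearson correlation of log2(raw + 1) intensities, the tree is cut
#' into as many clusters as there are tissues, and a chip is flagged when
#' the majority tissue of its cluster differs from its manifest tissue —
#' the rule that reproduces eliminating an endoneurium chip that clusters
#' with the DRG arrays.  When a cluster's tissue vote is tied, every chip in
#' that cluster is flagged with reason `"cluster_tissue_tie"` rather than
#' silently passed.  A constant chip (undefined correlation) is flagged as
#' degenerate.
#'
#' @param dataset An [expression_dataset()] with at least 3 chips spanning
#'   at least 2 tissues.
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"average"`.
#' @return Data frame with columns `chip_id`, `tissue`, `cluster`,
#'   `cluster_majority_tissue`, `outlier` (logical) and `reason` (empty
#'   string for clean chips).
#' @export
cluster_outliers <- function(dataset, linkage = "average") {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  man <- dataset$manifest
  if (nrow(man) < 3L) stop("need at least 3 chips to cluster")
  tissues <- unique(man$tissue)
  if (length(tissues) < 2L)
    stop("need chips from at least 2 tissues to define expected groups")

  lg <- log2(dataset$raw[, man$chip_id, drop = FALSE] + 1)
  sds <- apply(lg, 2L, stats::sd)
  degenerate <- !is.finite(sds) | sds == 0
  out <- data.frame(chip_id = man$chip_id, tissue = man$tissue,
                    cluster = NA_integer_,
                    cluster_majority_tissue = NA_character_,
                    outlier = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  out$outlier[degenerate] <- TRUE
  out$reason[degenerate] <- "degenerate_constant_chip"

  ok <- !degenerate
  if (sum(ok) >= 3L) {
    cm <- stats::cor(lg[, ok, drop = FALSE])
    hc <- stats::hclust(stats::as.dist(1 - cm), method = linkage)
    k <- min(length(unique(man$tissue[ok])), sum(ok))
    cl <- stats::cutree(hc, k = k)
    out$cluster[ok] <- unname(cl[out$chip_id[ok]])
    for (c in unique(cl)) {
      members <- out$chip_id[ok][cl == c]
      votes <- table(out$tissue[out$chip_id %in% members])
      top <- names(votes)[votes == max(votes)]
      if (length(top) > 1L) {
        sel <- out$chip_id %in% members
        out$outlier[sel] <- TRUE
        out$reason[sel] <- "cluster_tissue_tie"
        out$cluster_majority_tissue[sel] <- NA_character_
      } else {
        sel <- out$chip_id %in% members
        out$cluster_majority_tissue[sel] <- top
        mis <- sel & out$tissue != top
        out$outlier[mis] <- TRUE
        out$reason[mis] <- sprintf("clusters_with_%s", top)
      }
    }
    # effectively identical chips in different tissues indicate a swap or
    # copy; the tree cut can place such a pair arbitrarily, so flag both
    # explicitly rather than rely on the cluster vote
    ids_ok <- out$chip_id[ok]
    for (i in seq_len(ncol(cm) - 1L)) {
      for (j in (i + 1L):ncol(cm)) {
        ti <- out$tissue[out$chip_id == ids_ok[i]]
        tj <- out$tissue[out$chip_id == ids_ok[j]]
        if (ti != tj && cm[i, j] > 1 - 1e-10) {
          sel <- out$chip_id %in% ids_ok[c(i, j)]
          out$outlier[sel] <- TRUE
          out$reason[sel] <- ifelse(
            grepl("identical_cross_tissue", out$reason[sel]),
            out$reason[sel], "identical_cross_tissue_pair")
        }
      }
    }
  }
  out
}

#' Normalize intensities within each tissue
#'
#' Each tissue is normalized independently; chips are never mixed across
#' tissues.  Quantile normalization equalizes the within-tissue intensity
#' distributions (a rank-based distribution-matching surrogate for the
#' vendor's cubic-spline option, whose algorithm is unpublished).  Detection
#' calls are untouched.  A tissue with a single chip is passed through with
#' a warning (quantile normalization is undefined there).
#'
#' @param dataset An [expression_dataset()].
#' @param method `"quantile"` (via [limma::normalizeQuantiles()]) or
#'   `"none"` (identity).
#' @return A new `ExpressionDataset` with normalized `raw`.
#' @export
normalize_per_tissue <- function(dataset, method = c("quantile", "none")) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  method <- match.arg(method)
  if (method == "none") return(dataset)
  raw <- dataset$raw
  for (tis in unique(dataset$manifest$tissue)) {
    ids <- dataset$manifest$chip_id[dataset$manifest$tissue == tis]
    if (length(ids) < 2L) {
      warning("tissue '", tis, "' has a single chip; passed through unnormalized")
      next
    }
    raw[, ids] <- limma::normalizeQuantiles(raw[, ids, drop = FALSE])
  }
  expression_dataset(raw, dataset$calls, dataset$manifest)
}

#' Median-normalized expression profiles
#'
#' For profile figures, each probe's intensities are divided by that probe's
#' median across all retained chips of the tissue, yielding comparable
#' per-genotype time profiles centred on 1.  A probe whose median is 0 has
#' no defined profile and is reported with `NA` values.
#'
#' @param dataset An [expression_dataset()] already restricted to retained
#'   chips.
#' @param probe_ids Probes to profile.
#' @param tissue Tissue whose chips define the median; default the single
#'   tissue present.
#' @return A tidy data frame (`probe_id`, `chip_id`, `day`, `genotype`,
#'   `value`) ordered by probe, day, genotype; zero rows for an empty probe
#'   list.
#' @examples
#' raw <- matrix(c(100, 200, 300, 400), 1, 4,
#'               dimnames = list("p1", paste0("c", 1:4)))
#' calls <- matrix("P", 1, 4, dimnames = dimnames(raw))
#' man <- data.frame(chip_id = paste0("c", 1:4), tissue = "DRG",
#'                   genotype = rep(c("Akita", "WT"), 2),
#'                   day = rep(c(20L, 24L), each = 2))
#' median_profile(expression_dataset(raw, calls, man), "p1")$value
#' @export
median_profile <- function(dataset, probe_ids, tissue = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  man <- dataset$manifest
  if (is.null(tissue)) {
    tissue <- unique(man$tissue)
    if (length(tissue) > 1L)
      stop("dataset has multiple tissues; specify 'tissue'")
  }
  man <- man[man$tissue == tissue, , drop = FALSE]
  if (length(probe_ids) == 0L)
    return(data.frame(probe_id = character(), chip_id = character(),
                      day = integer(), genotype = character(),
                      value = numeric()))
  missing <- setdiff(probe_ids, rownames(dataset$raw))
  if (length(missing))
    stop("unknown probe id(s): ", paste(missing, collapse = ", "))
  x <- dataset$raw[probe_ids, man$chip_id, drop = FALSE]
  med <- apply(x, 1L, stats::median)
  zero <- med == 0
  if (any(zero))
    warning("probe(s) with zero median reported as NA: ",
            paste(probe_ids[zero], collapse = ", "))
  med[zero] <- NA_real_
  norm <- sweep(x, 1L, med, "/")
  out <- data.frame(
    probe_id = rep(probe_ids, times = nrow(man)),
    chip_id = rep(man$chip_id, each = length(probe_ids)),
    day = rep(man$day, each = length(probe_ids)),
    genotype = rep(man$genotype, each = length(probe_ids)),
    value = as.vector(norm))
  out[order(out$probe_id, out$day, out$genotype), , drop = FALSE]
}

#' Full chip QC report
#'
#' Combines [chip_summary()] with, when the dataset spans several tissues,
#' the correlation-clustering outlier flags of [cluster_outliers()], and
#' merges in any manual exclusions.
#'
#' @param dataset An [expression_dataset()].
#' @param manual_exclusions Chip ids to flag regardless of clustering.
#' @param linkage Passed to [cluster_outliers()].
#' @return Data frame: one row per chip with summary columns, cluster
#'   columns (NA when clustering is not applicable), `outlier` and `reason`.
#' @export
chip_qc_report <- function(dataset, manual_exclusions = character(),
                           linkage = "average") {
  rep <- chip_summary(dataset)
  if (length(unique(dataset$manifest$tissue)) >= 2L &&
      nrow(dataset$manifest) >= 3L) {
    cl <- cluster_outliers(dataset, linkage = linkage)
    rep <- merge(rep, cl[, c("chip_id", "cluster", "cluster_majority_tissue",
                             "outlier", "reason")],
                 by = "chip_id", sort = FALSE)
  } else {
    rep$cluster <- NA_integer_
    rep$cluster_majority_tissue <- NA_character_
    rep$outlier <- FALSE
    rep$reason <- ""
  }
  man <- rep$chip_id %in% manual_exclusions
  rep$outlier[man] <- TRUE
  rep$reason[man] <- ifelse(nzchar(rep$reason[man]),
                            paste0(rep$reason[man], ";manual"), "manual")
  rep[match(dataset$manifest$chip_id, rep$chip_id), , drop = FALSE]
}
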