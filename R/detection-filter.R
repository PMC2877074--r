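#' Consecutive-presence detection filter
#'
#' First filtering step: with closely spaced time-points, a probe called
#' "present" at only one developmental stage is treated as an artifact.  A
#' probe is retained iff, in at least one genotype's series (or both, see
#' `genotype_rule`), there exist at least `min_present_run` consecutive
#' time-points all called "present".  "Marginal" counts as not present.
#' Time-points whose chip is missing (QC-excluded) carry no call; by default
#' they break a consecutive run (`mask_rule = "break"`); with
#' `mask_rule = "bridge"` the masked point is dropped and its neighbours
#' become adjacent.
#'
#' @param dataset An [expression_dataset()] restricted to chips that passed
#'   QC (missing chips are inferred from the manifest).
#' @param tissue Tissue to filter.
#' @param params A [filter_params()] (supplies `min_present_run`).
#' @param genotype_rule `"either"` (default): a qualifying present-run in one
#'   genotype retains the probe; `"both"`: both genotypes must qualify.
#' @param mask_rule `"break"` (default) or `"bridge"` for time-points with a
#'   missing chip.
#' @return A list with `retained` (character vector of probe ids, in input
#'   order), `eliminated` (count of probes removed) and `n_total`.
#' @examples
#' ds <- simulate_dataset(sim_params(n_probes = 50, seed = 1))$dataset
#' df <- consecutive_present_filter(ds, "DRG", filter_params())
#' df$eliminated
#' @export
consecutive_present_filter <- function(dataset, tissue,
                                       params = filter_params(),
                                       genotype_rule = c("either", "both"),
                                       mask_rule = c("break", "bridge")) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  genotype_rule <- match.arg(genotype_rule)
  mask_rule <- match.arg(mask_rule)
  man <- dataset$manifest
  if (!tissue %in% man$tissue) stop("tissue not in manifest: ", tissue)
  man <- man[man$tissue == tissue, , drop = FALSE]
  days <- sort(unique(man$day))
  if (params$min_present_run > length(days))
    stop("min_present_run exceeds the number of time-points")

  qualifies <- matrix(FALSE, nrow(dataset$calls), 2L,
                      dimnames = list(rownames(dataset$calls), c("Akita", "WT")))
  for (g in c("Akita", "WT")) {
    # present-call matrix over ordered days; NA where the chip is missing
    pres <- matrix(NA, nrow(dataset$calls), length(days))
    for (j in seq_along(days)) {
      id <- man$chip_id[man$genotype == g & man$day == days[j]]
      if (length(id) == 1L) pres[, j] <- dataset$calls[, id] == "P"
    }
    qualifies[, g] <- apply(pres, 1L, has_consecutive_run,
                            k = params$min_present_run, mask_rule = mask_rule)
  }
  keep <- if (genotype_rule == "either") qualifies[, 1L] | qualifies[, 2L]
          else qualifies[, 1L] & qualifies[, 2L]
  list(retained = rownames(dataset$calls)[keep],
       eliminated = sum(!keep),
       n_total = nrow(dataset$calls))
}

# TRUE iff x (logical with NA = no call) contains a run of >= k TRUEs.
# mask_rule "break": NA interrupts a run; "bridge": NAs are dropped first.
has_consecutive_run <- function(x, k, mask_rule = "break") {
  if (mask_rule == "bridge") x <- x[!is.na(x)]
  x <- !is.na(x) & x
  if (!any(x)) return(FALSE)
  r <- rle(x)
  any(r$values & r$lengths >= k)
}
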