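# Builders for small in-code fixtures.

# A tiny one-tissue dataset with explicit values.  `days` gives the
# time-points; each (genotype, day) pair gets one chip.  `akita` and `wt`
# are probe x day matrices of raw intensities; calls default to "P".
tiny_dataset <- function(akita, wt, days = seq_len(ncol(akita)) * 4L + 16L,
                         tissue = "DRG", calls_akita = NULL, calls_wt = NULL) {
  stopifnot(identical(dim(akita), dim(wt)))
  np <- nrow(akita)
  probes <- sprintf("p%02d", seq_len(np))
  ids_a <- sprintf("%s_Akita_P%d", tissue, days)
  ids_w <- sprintf("%s_WT_P%d", tissue, days)
  raw <- cbind(akita, wt)
  colnames(raw) <- c(ids_a, ids_w)
  rownames(raw) <- probes
  if (is.null(calls_akita)) calls_akita <- matrix("P", np, length(days))
  if (is.null(calls_wt)) calls_wt <- matrix("P", np, length(days))
  calls <- cbind(calls_akita, calls_wt)
  dimnames(calls) <- dimnames(raw)
  man <- data.frame(chip_id = c(ids_a, ids_w), tissue = tissue,
                    genotype = rep(c("Akita", "WT"), each = length(days)),
                    day = rep(days, 2L))
  expression_dataset(raw, calls, man)
}

# A dataset whose Akita/WT ratio series is exactly `ratios` for one probe
# (WT held at `base`), with in-band filler probes alongside.
ratio_dataset <- function(ratios, base = 1000,
                          days = c(20L, 24L, 28L, 32L, 36L, 40L, 48L, 56L)) {
  tiny_dataset(matrix(base * ratios, 1L), matrix(base, 1L, length(ratios)),
               days = days)
}

# Random fold-change series exercising in-band, near-threshold and strong
# exceedance regimes, with optional masked time-points.
random_series <- function(n_t, p_mask = 0.15) {
  kind <- sample.int(5L, n_t, replace = TRUE,
                     prob = c(0.45, 0.15, 0.15, 0.15, 0.10))
  r <- numeric(n_t)
  r[kind == 1L] <- runif(sum(kind == 1L), 0.75, 1.35)   # comfortably in band
  r[kind == 2L] <- runif(sum(kind == 2L), 1.55, 4.0)    # up exceedance
  r[kind == 3L] <- 1 / runif(sum(kind == 3L), 1.55, 4.0) # down exceedance
  r[kind == 4L] <- runif(sum(kind == 4L), 1.35, 1.55)   # near up threshold
  r[kind == 5L] <- 1 / runif(sum(kind == 5L), 1.35, 1.55) # near down threshold
  mask <- runif(n_t) < p_mask
  list(ratios = r, mask = mask)
}

# Two-tissue dataset with distinct per-tissue expression programs so that
# chips cluster by tissue.
rbind2tissue_dataset <- function(np = 30L, days = c(20L, 24L, 28L, 32L),
                                 seed = 11L) {
  set.seed(seed)
  b1 <- exp(runif(np, log(50), log(5000)))
  b2 <- exp(runif(np, log(50), log(5000)))
  mk <- function(b, tissue) {
    n_t <- length(days)
    noisy <- function() matrix(b, np, n_t) *
      matrix(exp(rnorm(np * n_t, 0, 0.05)), np, n_t)
    tiny_dataset(noisy(), noisy(), days = days, tissue = tissue)
  }
  d1 <- mk(b1, "DRG"); d2 <- mk(b2, "endoneurium")
  expression_dataset(cbind(d1$raw, d2$raw), cbind(d1$calls, d2$calls),
                     rbind(d1$manifest, d2$manifest))
}

# Independent brute-force check of the consecutive-presence rule for one
# genotype series (logical with NA for masked): enumerate every window.
presence_oracle <- function(x, k, mask_rule = "break") {
  if (mask_rule == "bridge") x <- x[!is.na(x)]
  n <- length(x)
  if (n < k) return(FALSE)
  for (s in seq_len(n - k + 1L)) {
    w <- x[s:(s + k - 1L)]
    if (all(!is.na(w)) && all(w)) return(TRUE)
  }
  FALSE
}
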