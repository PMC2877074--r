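test_that("chip summaries report mean intensity and present fraction", {
  ds <- tiny_dataset(matrix(100, 3, 2), matrix(100, 3, 2))
  s <- chip_summary(ds)
  expect_equal(nrow(s), 4L)
  expect_true(all(s$mean_intensity == 100))
  expect_true(all(s$fraction_present == 1))

  # one chip all-absent
  calls_a <- matrix("P", 3, 2); calls_a[, 1] <- "A"
  ds2 <- tiny_dataset(matrix(100, 3, 2), matrix(100, 3, 2),
                      calls_akita = calls_a)
  s2 <- chip_summary(ds2)
  expect_equal(s2$fraction_present[s2$chip_id == ds2$manifest$chip_id[1]], 0)

  # present fraction tracks the generator's signal-bearing fraction
  sim <- simulate_dataset(sim_params(n_probes = 500, seed = 21))
  s3 <- chip_summary(sim$dataset)
  wt <- s3[s3$genotype == "WT", ]
  expect_true(all(abs(wt$fraction_present -
                        mean(sim$truth$class != "absent")) < 0.03))
})

test_that("misclustering chips are flagged; clean datasets are not", {
  p <- sim_params(n_probes = 300, tissues = c("DRG", "endoneurium"),
                  outlier_chip = list(tissue = "endoneurium",
                                      genotype = "Akita", day = 36),
                  seed = 3)
  qc <- cluster_outliers(simulate_dataset(p)$dataset)
  expect_identical(qc$chip_id[qc$outlier], "endoneurium_Akita_P36")
  expect_match(qc$reason[qc$outlier], "clusters_with_DRG")

  p2 <- sim_params(n_probes = 300, tissues = c("DRG", "endoneurium"),
                   seed = 3)
  qc2 <- cluster_outliers(simulate_dataset(p2)$dataset)
  expect_equal(sum(qc2$outlier), 0L)
})

test_that("outlier clustering is invariant under chip-order permutation", {
  p <- sim_params(n_probes = 200, tissues = c("DRG", "endoneurium"),
                  outlier_chip = list(tissue = "endoneurium",
                                      genotype = "WT", day = 24),
                  seed = 13)
  ds <- simulate_dataset(p)$dataset
  set.seed(99)
  perm <- sample(ncol(ds$raw))
  ds_p <- expression_dataset(ds$raw[, perm], ds$calls[, perm],
                             ds$manifest[perm, ])
  q1 <- cluster_outliers(ds)
  q2 <- cluster_outliers(ds_p)
  expect_setequal(q1$chip_id[q1$outlier], q2$chip_id[q2$outlier])
})

test_that("degenerate and tied clusters are surfaced, never silently passed", {
  ds <- rbind2tissue_dataset()
  # make one chip constant: undefined correlation
  raw <- ds$raw; raw[, 3] <- 500
  dsc <- expression_dataset(raw, ds$calls, ds$manifest)
  qc <- cluster_outliers(dsc)
  expect_true(qc$outlier[3])
  expect_match(qc$reason[3], "degenerate")
  expect_true(all(nzchar(qc$reason[qc$outlier])))

  # identical profiles duplicated across both tissues: tissue vote ties
  np <- 20L
  base <- exp(seq(log(50), log(5000), length.out = np))
  same <- matrix(rep(base, 4), np, 4)
  d1 <- tiny_dataset(same[, 1:2], same[, 3:4], days = c(20L, 24L),
                     tissue = "DRG")
  d2 <- tiny_dataset(same[, 1:2], same[, 3:4], days = c(20L, 24L),
                     tissue = "endoneurium")
  both <- expression_dataset(cbind(d1$raw, d2$raw),
                             cbind(d1$calls, d2$calls),
                             rbind(d1$manifest, d2$manifest))
  qt <- cluster_outliers(both)
  # the duplicated cross-tissue chips are flagged, never silently passed
  expect_true(any(qt$outlier))
  expect_true(any(grepl("identical_cross_tissue|tie", qt$reason[qt$outlier])))
  expect_true(all(nzchar(qt$reason[qt$outlier])))

  expect_error(cluster_outliers(tiny_dataset(matrix(1, 1, 1),
                                             matrix(1, 1, 1))),
               "at least 3 chips")
})

test_that("normalization acts within tissues only and 'none' is identity", {
  ds <- rbind2tissue_dataset(np = 40L)
  expect_identical(normalize_per_tissue(ds, "none"), ds)

  norm <- normalize_per_tissue(ds, "quantile")
  expect_identical(norm$calls, ds$calls)  # calls untouched

  # two chips that are permutations of the same values become identical
  # after sorting
  np <- 30L
  set.seed(4)
  v <- exp(runif(np, log(10), log(1000)))
  ak <- cbind(v, sample(v))
  ds2 <- tiny_dataset(ak, ak[, 2:1], days = c(20L, 24L))
  n2 <- normalize_per_tissue(ds2, "quantile")
  sorted <- apply(n2$raw, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-9))

  # chip-scale factors are removed: per-chip means equalize within tissue
  # (stable probes only, so chips are pure scalings of one another)
  sim <- simulate_dataset(sim_params(n_probes = 300,
                                     class_fractions = c(stable = 1),
                                     noise_cv = 0,
                                     chip_scale_spread = 0.2, seed = 8))
  n3 <- normalize_per_tissue(sim$dataset, "quantile")
  m <- colMeans(n3$raw)
  expect_true(max(abs(m / mean(m) - 1)) < 1e-6)

  # perturbing one tissue leaves the other bit-unchanged
  two <- rbind2tissue_dataset(np = 40L)
  pert <- two$raw
  endo <- two$manifest$chip_id[two$manifest$tissue == "endoneurium"]
  pert[, endo[1]] <- pert[, endo[1]] * 3
  two_p <- expression_dataset(pert, two$calls, two$manifest)
  drg <- two$manifest$chip_id[two$manifest$tissue == "DRG"]
  a <- normalize_per_tissue(two, "quantile")
  b <- normalize_per_tissue(two_p, "quantile")
  expect_identical(a$raw[, drg], b$raw[, drg])

  # single-chip tissue passes through with a warning
  one <- keep_chips(two, c(drg, endo[1]))
  expect_warning(normalize_per_tissue(one, "quantile"), "single chip")
})

test_that("median-normalized profiles centre on 1 and match hand arithmetic", {
  # constant probe -> flat profile at 1
  ds <- tiny_dataset(matrix(500, 1, 2), matrix(500, 1, 2))
  expect_true(all(median_profile(ds, "p01")$value == 1))

  # {100,200,300,400} over 4 chips: median 250 -> 0.4 0.8 1.2 1.6
  ds2 <- tiny_dataset(matrix(c(100, 300), 1, 2), matrix(c(200, 400), 1, 2))
  prof <- median_profile(ds2, "p01")
  expect_setequal(prof$value, c(100, 200, 300, 400) / 250)

  # per-probe median of the profile is 1 by construction
  sim <- simulate_dataset(sim_params(n_probes = 30, seed = 6))
  ids <- rownames(sim$dataset$raw)[1:5]
  p <- median_profile(sim$dataset, ids)
  med <- tapply(p$value, p$probe_id, median)
  expect_equal(as.numeric(med), rep(1, 5))

  # empty probe list and zero-median probe
  expect_equal(nrow(median_profile(ds, character())), 0L)
  dz <- tiny_dataset(matrix(0, 1, 2), matrix(0, 1, 2))
  expect_warning(pz <- median_profile(dz, "p01"), "zero median")
  expect_true(all(is.na(pz$value)))
  expect_error(median_profile(ds, "nope"), "unknown probe")
})
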