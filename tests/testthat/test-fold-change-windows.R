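test_that("intensity flooring fixes low values and nothing else", {
  expect_equal(floor_intensities(c(5, 10, 40000)), c(10, 10, 40000))
  m <- matrix(c(0, 9.99, 10.01, 250), 2)
  expect_equal(floor_intensities(m), matrix(c(10, 10, 10.01, 250), 2))
  expect_error(floor_intensities(m, -1), "non-negative")
  expect_error(floor_intensities(matrix(-3)), "negative")
})

test_that("fold-change series divide floored Akita by floored WT", {
  ds <- tiny_dataset(matrix(c(300, 5), 1, 2), matrix(c(150, 5), 1, 2))
  fc <- compute_fold_changes(ds, "DRG", filter_params())
  expect_equal(unname(fc$ratios[1, ]), c(2.0, 1.0))  # 300/150, 10/10
  expect_false(any(fc$mask))
  expect_error(compute_fold_changes(ds, "liver", filter_params()),
               "not in manifest")
})

test_that("a QC-excluded chip masks its time-point, leaving 7 usable ratios", {
  ak <- matrix(1000, 2, 8); wt <- matrix(500, 2, 8)
  ds <- tiny_dataset(ak, wt, days = c(20L, 24L, 28L, 32L, 36L, 40L, 48L, 56L),
                     tissue = "endoneurium")
  ds <- exclude_chips(ds, "endoneurium_Akita_P36")
  fc <- compute_fold_changes(ds, "endoneurium", filter_params())
  expect_equal(sum(fc$mask), 1L)
  expect_true(fc$mask[match(36L, fc$days)])
  expect_equal(sum(!is.na(fc$ratios[1, ])), 7L)
})

test_that("maximal exceedance runs are found with their directions", {
  p <- filter_params()
  r1 <- find_exceedance_runs(c(1, 1, 1.8, 1.8, 1, 1, 1, 1), p)
  expect_equal(r1, data.frame(direction = "up", start = 3L, end = 4L,
                              length = 2L))
  expect_equal(nrow(find_exceedance_runs(rep(1, 8), p)), 0L)
  r3 <- find_exceedance_runs(c(0.5, 0.5, 0.5, 1, 1, 1, 1, 1.6), p)
  expect_equal(r3$direction, c("down", "up"))
  expect_equal(r3$start, c(1L, 8L))
  expect_equal(r3$length, c(3L, 1L))
  # a masked time-point terminates a run
  r4 <- find_exceedance_runs(c(2, 2, 2, 1, 1, 1, 1, 1), p,
                             mask = c(FALSE, TRUE, rep(FALSE, 6)))
  expect_equal(r4$length, c(1L, 1L))
})

test_that("the classifier reproduces the canonical panel decisions", {
  p <- filter_params()
  pan <- example_profiles()
  a <- classify_probe(pan$A$ratios, p)
  expect_true(a$accepted)
  expect_equal(a$direction, "up"); expect_equal(a$run_length, 2L)
  b <- classify_probe(pan$B$ratios, p)
  expect_true(b$accepted)
  expect_equal(b$direction, "down"); expect_equal(b$run_length, 3L)
  expect_false(classify_probe(pan$C$ratios, p)$accepted)
  expect_false(classify_probe(pan$D$ratios, p)$accepted)
  expect_equal(classify_probe(rep(1, 8), p)$reason, "no_exceedance_run")
  expect_equal(classify_probe(c(1.8, 1, 1, 1, 1, 1, 1, 1), p)$reason,
               "run_too_short")
})

test_that("escape clause matters when fold and escape thresholds differ", {
  p <- filter_params(fold_threshold = 3, escape_threshold = 1.5)
  # clean 3-fold window
  expect_true(classify_probe(c(1, 3.5, 3.5, 1, 1, 1, 1, 1), p)$accepted)
  # out-of-window 2.0 is below the 3-fold run threshold but outside the
  # 1.5-fold escape band
  wc <- classify_probe(c(1, 3.5, 3.5, 1, 2.0, 1, 1, 1), p)
  expect_false(wc$accepted)
  expect_equal(wc$reason, "escape_violation")
})

test_that("masked time-points break runs and are exempt from escape", {
  p <- filter_params()
  mask <- c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  # exceedance adjacent across the mask does not merge
  r <- c(1, 1, 1, 1.8, NA, 1.8, 1, 1)
  expect_false(classify_probe(r, p, mask)$accepted)
  # a wild masked value is ignored by the escape clause
  r2 <- c(1, 1.8, 1.8, 1, 99, 1, 1, 1)
  expect_true(classify_probe(r2, p, mask)$accepted)
})

test_that("low-expressor flag uses the strict raw-intensity cutoff", {
  mk <- function(v) tiny_dataset(matrix(v, 1, 2), matrix(v, 1, 2))
  calls <- data.frame(probe_id = "p01", run_length = 2L,
                      low_expressor = NA)
  expect_true(flag_low_expressors(calls, mk(50))$low_expressor)
  expect_false(flag_low_expressors(calls, mk(100))$low_expressor)  # strict <
  expect_false(flag_low_expressors(calls, mk(40000))$low_expressor)
  expect_equal(nrow(flag_low_expressors(calls[0, ], mk(50))), 0L)
})

test_that("classifier and enumeration oracle agree on random series", {
  set.seed(123)
  params_grid <- list(filter_params(1.5, 1.5), filter_params(3, 1.5),
                      filter_params(min_run = 3L))
  for (i in 1:500) {
    s <- random_series(sample(4:12, 1))
    p <- params_grid[[sample.int(3L, 1L)]]
    a <- classify_probe(s$ratios, p, s$mask)
    b <- classify_probe_oracle(s$ratios, p, s$mask)
    expect_equal(a$accepted, b$accepted,
                 info = paste(round(s$ratios, 3), collapse = ","))
    if (a$accepted) {
      expect_equal(a$start, b$start)
      expect_equal(a$end, b$end)
      expect_equal(a$direction, b$direction)
    }
  }
})

test_that("acceptance is monotone, nested and reciprocal-symmetric", {
  set.seed(321)
  accepts <- function(r, m, p) classify_probe(r, p, m)$accepted
  for (i in 1:300) {
    s <- random_series(8)
    # raising fold_threshold (escape fixed) never turns REJECT into ACCEPT
    lo <- classify_probe(s$ratios, filter_params(1.5, 1.5), s$mask)
    hi <- classify_probe(s$ratios, filter_params(3, 1.5), s$mask)
    if (hi$accepted) expect_true(lo$accepted)
    # accepted set shrinks as min_run grows
    for (k in 2:4) {
      ak <- accepts(s$ratios, s$mask, filter_params(min_run = k))
      ak1 <- accepts(s$ratios, s$mask, filter_params(min_run = k + 1L))
      if (ak1) expect_true(ak)
    }
    # replacing r by 1/r flips direction, preserves acceptance
    a <- classify_probe(s$ratios, filter_params(), s$mask)
    b <- classify_probe(1 / s$ratios, filter_params(), s$mask)
    expect_equal(a$accepted, b$accepted)
    if (a$accepted)
      expect_equal(b$direction, c(up = "down", down = "up")[[a$direction]])
  }
})

test_that("direction-uniformity switch merges mixed blocks when disabled", {
  # adjacent up and down exceedances: two runs when uniform, one mixed run
  # (of length 2) when not
  r <- c(1, 1, 2, 0.4, 1, 1, 1, 1)
  p_uni <- filter_params()
  expect_equal(classify_probe(r, p_uni)$reason, "multiple_runs")
  p_mix <- filter_params(require_uniform_direction = FALSE)
  wc <- classify_probe(r, p_mix)
  expect_true(wc$accepted)
  expect_equal(wc$direction, "mixed")
})
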