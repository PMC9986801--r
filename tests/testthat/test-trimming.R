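test_that("top_half_cutoff follows the stated convention", {
  # all equal -> sd 0 -> cutoff equals the value
  expect_equal(top_half_cutoff(rep(0.7, 9), 3), 0.7)
  expect_equal(top_half_cutoff(rep(0.7, 9), 100), 0.7)
  # {0.2, 0.4, 0.6, 0.8}, k = 3: top half {0.8, 0.6}, mean 0.7, sd 0.1414
  expect_equal(top_half_cutoff(c(0.2, 0.4, 0.6, 0.8), 3),
               0.7 - 3 * sd(c(0.8, 0.6)), tolerance = 1e-12)
  expect_equal(top_half_cutoff(c(0.2, 0.4, 0.6, 0.8), 3), 0.2757,
               tolerance = 1e-3)
  expect_equal(top_half_cutoff(0.5, 2), 0.5)    # single value, sd 0
  expect_error(top_half_cutoff(numeric(0), 3), "at least one")
})

test_that("shipped defaults reproduce the printed constants", {
  p <- trim_params()
  expect_identical(p$cc_sd_ratio, 3)
  expect_identical(p$cc_sd_ratio_end, 2)
  expect_identical(p$minimum_domain_length, 10L)
  expect_equal(p$reasonable_cc_ratio^2, 0.64)
  expect_equal(2 * p$reasonable_cc_diff, 0.3)
})

test_that("step 1 removes the smoothed low-cc dip and honors the pLDDT conjunction", {
  p <- trim_params()
  # constant track: nothing strictly below the cutoff
  keep <- step1_remove_low(rep(0.8, 40), params = p)
  expect_true(all(keep))
  # 50 residues at 0.9 with a dip at 20-26
  cc <- rep(0.9, 50); cc[20:26] <- 0.1
  sm <- smooth_track(cc, 10)
  keep <- step1_remove_low(sm, params = trim_params(use_plddt = FALSE))
  expect_true(all(!keep[21:25]))
  expect_true(all(keep[c(1:15, 31:50)]))
  # brute-force check of the rule itself
  cut <- top_half_cutoff(sm, 3)
  expect_equal(keep, !(sm < cut - 1e-9))
  # conjunction: low cc but high pLDDT is retained when use_plddt
  plddt <- rep(90, 50)
  keep2 <- step1_remove_low(sm, smooth_track(plddt, 10),
                            trim_params(use_plddt = TRUE))
  expect_true(all(keep2))
  # both low -> removed
  plddt[18:28] <- 30
  keep3 <- step1_remove_low(sm, smooth_track(plddt, 10),
                            trim_params(use_plddt = TRUE))
  expect_true(any(!keep3[20:26]))
})

test_that("raising cc_sd_ratio never removes more residues", {
  set.seed(3)
  for (rep_ in 1:5) {
    cc <- smooth_track(runif(60, 0.2, 0.95), 10)
    removed <- sapply(c(1, 2, 3, 4), function(k) {
      sum(!step1_remove_low(cc, params = trim_params(cc_sd_ratio = k,
                                                     use_plddt = FALSE)))
    })
    expect_true(all(diff(removed) <= 0))
  }
})

test_that("step 2 strips weak ends and drops short segments", {
  p <- trim_params()
  n <- 60
  starts <- c(TRUE, rep(FALSE, n - 1))
  # strong interior, weak 2-residue tails on a single segment
  cc <- c(0.2, 0.25, rep(0.9, 40), 0.2, 0.25, rep(0.9, 16))
  cc[43:44] <- c(0.2, 0.25)
  sm <- cc                                  # treat raw == smoothed
  keep1 <- rep(TRUE, n)
  keep1[43:44] <- FALSE                     # two segments: 1-42, 45-60
  out <- step2_trim_ends(keep1, cc, sm, starts, p)
  expect_equal(which(out), c(3:42, 45:60))
  # all above the end cutoff: unchanged
  cc2 <- rep(0.9, n)
  out2 <- step2_trim_ends(rep(TRUE, n), cc2, cc2, starts, p)
  expect_true(all(out2))
  # a 6-residue segment dies under a 10-residue window
  keep3 <- rep(FALSE, n); keep3[1:6] <- TRUE; keep3[11:50] <- TRUE
  out3 <- step2_trim_ends(keep3, cc2, cc2, starts, p)
  expect_true(all(!out3[1:6]))
  expect_true(all(out3[11:50]))
})

test_that("step 3 arithmetic matches the printed constants", {
  p <- trim_params()
  # m = 0.8 -> cutoff = max(0.64*0.8, 0.8-0.3) = 0.512
  segs <- c(0.8, 0.8, 0.5, 0.52)
  # top half = {0.8, 0.8}, m = 0.8
  expect_equal(step3_drop_weak_segments(segs, p), c(TRUE, TRUE, FALSE, TRUE))
  # single segment always kept
  expect_true(step3_drop_weak_segments(0.35, p))
  # m = 0.9: subtractive branch wins (0.6 > 0.576)
  segs2 <- c(0.9, 0.9, 0.59, 0.61)
  expect_equal(step3_drop_weak_segments(segs2, p), c(TRUE, TRUE, FALSE, TRUE))
  expect_error(step3_drop_weak_segments(numeric(0), p), "segments")
})

test_that("a model matching its own map loses nothing", {
  m <- helix_model(40)
  map <- make_map(m, resolution = 2.5)
  out <- trim_to_map(m, map, trim_params(resolution = 2.5))
  expect_equal(n_residues(out$model), 40L)
  expect_equal(out$report$removed_step1, 0L)
  expect_equal(out$report$removed_step2, 0L)
  expect_equal(out$report$removed_step3, 0L)
})

test_that("a displaced region is trimmed away, the rest retained", {
  m <- helix_model(60)
  map <- make_map(m, resolution = 2.5)
  bad <- m
  rows <- bad$atoms$resno %in% 21:40
  bad$atoms$x[rows] <- bad$atoms$x[rows] + 6
  out <- trim_to_map(bad, map, trim_params(resolution = 2.5))
  kept <- residue_table(out$model)$resno
  expect_true(all(!(23:38 %in% kept)))      # displaced core gone
  # accurate regions kept, up to smoothing spillover at the boundaries
  expect_true(all(c(1:12, 48:60) %in% kept))
})

test_that("trim_to_map equals the straight-line oracle on seeded fixtures", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(30:60, 1)
    m <- helix_model(n, seed = i)
    map <- make_map(m, resolution = 3)
    bad <- m
    w <- sample(8:20, 1)
    start <- sample(1:(n - w), 1)
    rows <- bad$atoms$resno %in% start:(start + w - 1)
    bad$atoms$x[rows] <- bad$atoms$x[rows] + runif(1, 0, 7)
    p <- trim_params(resolution = 3, use_plddt = FALSE)
    prof <- local_cc(bad, map, resolution = 3)
    expected <- oracle_trim(prof$local_cc,
                            starts = segment_starts(bad))
    got <- tryCatch(trim_to_map(bad, map, p),
                    itermodel_all_trimmed = function(e) NULL)
    if (is.null(got)) {
      expect_true(all(!expected))
    } else {
      expect_equal(trim_keep_mask(bad, got$model), expected)
    }
  }
})

test_that("all-trimmed input raises a structured error with a report", {
  # a model whose only segment is shorter than the smoothing window is
  # wiped out by step 2
  m <- helix_model(8)
  map <- make_map(m, resolution = 2.5)
  err <- tryCatch(trim_to_map(m, map, trim_params(resolution = 2.5)),
                  itermodel_all_trimmed = function(e) e)
  expect_s3_class(err, "itermodel_all_trimmed")
  expect_true(!is.null(err$report))
  expect_equal(err$report$removed_step2, 8L)
})

test_that("trimming is stable under chain relabeling", {
  fx <- two_domain_fixture()
  m <- fx$prediction
  map <- fx$map
  out1 <- trim_to_map(m, map, trim_params(resolution = 2.5))
  m2 <- m
  m2$atoms$chain <- "Q"
  out2 <- trim_to_map(m2, map, trim_params(resolution = 2.5))
  expect_equal(residue_table(out1$model)$resno,
               residue_table(out2$model)$resno)
})
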