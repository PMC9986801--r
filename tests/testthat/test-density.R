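one_atom_model <- function(b = 0) {
  atomic_model(data.frame(chain = "A", resno = 1L, icode = "",
                          resname = "ALA", atom = "CA", element = "C",
                          x = 0, y = 0, z = 0, b = b, occ = 1))
}

test_that("model_to_map places Gaussian density at atom positions", {
  m <- one_atom_model(b = 0)
  map <- model_to_map(m, spacing = 0.5, resolution = 2)
  peak <- arrayInd(which.max(map$values), dim(map$values))
  pos <- map$origin + (as.numeric(peak) - 1) * map$spacing
  expect_true(all(abs(pos - 0) <= map$spacing / 2 + 1e-9))
  # doubling b lowers and widens the peak
  m2 <- one_atom_model(b = 40)
  m3 <- one_atom_model(b = 80)
  map2 <- model_to_map(m2, spacing = 0.5, resolution = 2)
  map3 <- model_to_map(m3, spacing = 0.5, resolution = 2, grid = map2)
  expect_gt(max(map2$values), max(map3$values))
  frac_above <- function(v) mean(v > 0.05 * max(v))
  expect_gt(frac_above(map3$values), frac_above(map2$values))
  # total density (integral) is conserved regardless of blur
  expect_equal(sum(map2$values), sum(map3$values), tolerance = 1e-3)
})

test_that("atom Gaussians follow the stated variance and weight", {
  # numeric oracle: integrate a 1-atom map; compare the profile with the
  # closed-form Gaussian sigma^2 = (b + 79 (res/3)^2) / (8 pi^2)
  b <- 30; res <- 2.5
  m <- one_atom_model(b = b)
  map <- model_to_map(m, spacing = 0.4, resolution = res)
  expect_equal(sum(map$values) * prod(map$spacing), 6, tolerance = 1e-3)
  sigma2 <- (b + 79 * (res / 3)^2) / (8 * pi^2)
  ax <- map$origin[1] + (seq_len(dim(map$values)[1]) - 1) * map$spacing[1]
  ay <- map$origin[2] + (seq_len(dim(map$values)[2]) - 1) * map$spacing[2]
  az <- map$origin[3] + (seq_len(dim(map$values)[3]) - 1) * map$spacing[3]
  iy <- which.min(abs(ay)); iz <- which.min(abs(az))
  profile <- map$values[, iy, iz]
  r2 <- ax^2 + ay[iy]^2 + az[iz]^2
  expected <- 6 / (2 * pi * sigma2)^1.5 * exp(-r2 / (2 * sigma2))
  sel <- abs(ax) <= 3 * sqrt(sigma2)   # inside the 4-sigma render cutoff
  expect_equal(profile[sel], expected[sel], tolerance = 1e-9)
})

test_that("a two-atom map is the sum of the one-atom maps", {
  a1 <- one_atom_model(b = 20)
  a2 <- one_atom_model(b = 20)
  a2$atoms$x <- 3; a2$atoms$resno <- 2L
  both <- atomic_model(rbind(a1$atoms, a2$atoms))
  map_both <- model_to_map(both, spacing = 0.5, resolution = 2)
  m1 <- model_to_map(a1, resolution = 2, grid = map_both)
  m2 <- model_to_map(a2, resolution = 2, grid = map_both)
  expect_equal(map_both$values, m1$values + m2$values, tolerance = 1e-12)
})

test_that("undersampled grids are refused", {
  expect_error(model_to_map(one_atom_model(), spacing = 1.5, resolution = 2),
               "undersampled")
})

test_that("every residue of a model scores >= 0.99 against its own map", {
  m <- helix_model(30)
  map <- make_map(m, resolution = 2.5)
  prof <- local_cc(m, map, resolution = 2.5)
  expect_true(all(prof$local_cc >= 0.99))
  expect_false(any(prof$flagged))
})

test_that("local_cc against pure noise is near zero", {
  m <- helix_model(60)
  map <- make_map(m, resolution = 2.5)
  set.seed(42)
  noise <- map
  noise$values <- array(rnorm(length(map$values)), dim(map$values))
  prof <- local_cc(m, noise, resolution = 2.5)
  expect_gte(nrow(prof), 50)
  expect_lt(mean(abs(prof$local_cc)), 0.2)
})

test_that("displacing one residue drops only that residue's cc", {
  m <- helix_model(30)
  map <- make_map(m, resolution = 2.5)
  shifted <- m
  rows <- shifted$atoms$resno == 15
  shifted$atoms$x[rows] <- shifted$atoms$x[rows] + 5
  prof <- local_cc(shifted, map, resolution = 2.5)
  med <- median(prof$local_cc)
  expect_lt(prof$local_cc[prof$resno == 15], med)
  others <- prof$local_cc[!prof$resno %in% 14:16]
  expect_true(all(others > 0.9))
})

test_that("local_cc validates coverage", {
  m <- helix_model(20)
  map <- make_map(m, resolution = 2.5)
  far <- transform_model(m, trans = c(500, 0, 0))
  expect_error(local_cc(far, map), "cover")
})

test_that("global_cc self-consistency and optimization dominance", {
  m <- helix_model(25)
  map <- make_map(m, resolution = 2.5)
  plain <- global_cc(m, map, optimize = FALSE, resolution = 2.5)
  expect_gte(plain$cc, 0.99)
  opt <- global_cc(m, map, optimize = TRUE, resolution = 2.5)
  expect_gte(opt$cc, plain$cc)
  expect_true(opt$radius %in% c(1.5, 2.0, 2.5, 3.0))
  expect_true(opt$side_chain_b_increment %in% c(0, 10, 20, 40))
})

test_that("displaced side chains benefit from a positive B increment", {
  m <- helix_model(25)
  map <- make_map(m, resolution = 2.5)
  bad <- m
  cb <- bad$atoms$atom == "CB"
  bad$atoms$x[cb] <- bad$atoms$x[cb] + 1.5
  raw <- global_cc(bad, map, optimize = FALSE, resolution = 2.5)
  opt <- global_cc(bad, map, optimize = TRUE, resolution = 2.5)
  expect_gt(opt$cc, raw$cc)
  expect_gt(opt$side_chain_b_increment, 0)
})

test_that("correlations are invariant to map offset/scale and joint shifts", {
  m <- helix_model(20)
  map <- make_map(m, resolution = 2.5)
  prof <- local_cc(m, map, resolution = 2.5)
  map2 <- map
  map2$values <- 3.7 * map$values + 11
  prof2 <- local_cc(m, map2, resolution = 2.5)
  expect_equal(prof2$local_cc, prof$local_cc, tolerance = 1e-9)
  # joint rigid translation of model and grid origin
  shift <- c(7.3, -2.1, 4.4)
  m3 <- transform_model(m, trans = shift)
  map3 <- map
  map3$origin <- map$origin + shift
  prof3 <- local_cc(m3, map3, resolution = 2.5)
  expect_equal(prof3$local_cc, prof$local_cc, tolerance = 1e-9)
  g <- global_cc(m, map, resolution = 2.5)
  g3 <- global_cc(m3, map3, resolution = 2.5)
  expect_equal(g3$cc, g$cc, tolerance = 1e-9)
})

test_that("per-residue correlation agrees with a brute-force oracle", {
  m <- helix_model(8)
  map <- make_map(m, resolution = 3)
  prof <- local_cc(m, map, mask_radius = 2.5, resolution = 3)
  model_map <- model_to_map(m, resolution = 3, grid = map)
  dims <- dim(map$values)
  grid_pts <- as.matrix(expand.grid(
    x = map$origin[1] + (seq_len(dims[1]) - 1) * map$spacing[1],
    y = map$origin[2] + (seq_len(dims[2]) - 1) * map$spacing[2],
    z = map$origin[3] + (seq_len(dims[3]) - 1) * map$spacing[3]))
  rt <- residue_table(m)
  for (i in c(1, 4, 8)) {
    at <- m$atoms[rt$atom_rows[[i]], ]
    inside <- rep(FALSE, nrow(grid_pts))
    for (j in seq_len(nrow(at))) {
      d2 <- (grid_pts[, 1] - at$x[j])^2 + (grid_pts[, 2] - at$y[j])^2 +
        (grid_pts[, 3] - at$z[j])^2
      inside <- inside | d2 <= 2.5^2
    }
    cc_oracle <- cor(as.numeric(map$values)[inside],
                     as.numeric(model_map$values)[inside])
    expect_equal(prof$local_cc[i], cc_oracle, tolerance = 1e-9)
  }
})

test_that("smooth_track obeys its contract", {
  expect_equal(smooth_track(rep(2.5, 9), 5), rep(2.5, 9))
  x <- rnorm(20)
  expect_equal(smooth_track(x, 1), x)
  # window 3 running means, hand computed
  v <- c(1, 0, 0, 0, 1)
  expect_equal(smooth_track(v, 3), c(1, 1 / 3, 0, 1 / 3, 1))
  # never crosses the segment break
  starts <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(smooth_track(v, 3, starts), c(1, 1 / 3, 0, 0, 1))
  # linear ramps are preserved by centered windows
  ramp <- seq(0, 10, length.out = 21)
  expect_equal(smooth_track(ramp, 7), ramp, tolerance = 1e-12)
  expect_error(smooth_track(v, 0), "window")
})

test_that("maps round-trip through CCP4/MRC and axis permutation is handled", {
  fx <- two_domain_fixture()
  path <- withr::local_tempfile(fileext = ".mrc")
  write_map(fx$map, path)
  back <- read_map(path)
  expect_equal(back$values, fx$map$values, tolerance = 1e-6)
  expect_equal(back$origin, fx$map$origin, tolerance = 1e-5)
  expect_equal(back$spacing, fx$map$spacing, tolerance = 1e-6)
  # a Z,Y,X-ordered file reads back into X,Y,Z order
  con <- file(path, "r+b")
  n <- dim(fx$map$values)
  writeBin(as.integer(n[c(3, 2, 1)]), con, size = 4, endian = "little")
  seek(con, 64, rw = "write")
  writeBin(c(3L, 2L, 1L), con, size = 4, endian = "little")
  seek(con, 1024, rw = "write")
  writeBin(as.numeric(aperm(fx$map$values, c(3, 2, 1))), con, size = 4,
           endian = "little")
  close(con)
  perm <- read_map(path)
  expect_equal(perm$values, fx$map$values, tolerance = 1e-6)
  expect_equal(perm$spacing, fx$map$spacing, tolerance = 1e-6)
})
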