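test_that("kabsch handles identity, rigid motion and degeneracy", {
  set.seed(8)
  A <- matrix(rnorm(30), 10, 3)
  fit <- kabsch(A, A)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  rot <- rotation_z(40)
  B <- sweep(A %*% t(rot), 2, c(1, -2, 3), "+")
  fit2 <- kabsch(A, B)
  expect_lt(fit2$rmsd, 1e-9)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch(A[1:2, ], B[1:2, ]), "3 point")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line + 1), "degenerate|collinear")
})

test_that("kabsch attains the numerically minimized rmsd", {
  # oracle: minimize rmsd over rotations (Euler angles) with optim
  A <- cbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  A <- t(A)                                  # unit right triangle
  B <- A; B[1, 1] <- B[1, 1] + 1             # one vertex moved 1 unit
  fit <- kabsch(A, B)
  euler <- function(p) {
    rotation_z(p[1] * 180 / pi) %*%
      matrix(c(1, 0, 0, 0, cos(p[2]), -sin(p[2]), 0, sin(p[2]), cos(p[2])),
             3, 3, byrow = TRUE) %*%
      rotation_z(p[3] * 180 / pi)
  }
  obj <- function(p) {
    R <- euler(p)
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2)))
  }
  best <- Inf
  for (s in 1:20) {
    set.seed(s)
    r <- optim(runif(3, -pi, pi), obj)$value
    best <- min(best, r)
  }
  expect_equal(fit$rmsd, best, tolerance = 1e-4)
  expect_lte(fit$rmsd, best + 1e-6)
})

test_that("rmsd is invariant under joint pre-rotation", {
  set.seed(2)
  A <- matrix(rnorm(36), 12, 3)
  B <- A + matrix(rnorm(36, sd = 0.5), 12, 3)
  r0 <- kabsch(A, B)$rmsd
  rot <- rotation_z(70)
  r1 <- kabsch(A %*% t(rot), B %*% t(rot))$rmsd
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("compare_models on identical input is perfect", {
  m <- helix_model(30)
  cmp <- compare_models(m, m)
  expect_equal(cmp$rmsd, 0)
  expect_equal(cmp$completeness, 100)
  expect_equal(cmp$coverage, 100)
  expect_equal(cmp$n_matched, 30L)
})

test_that("completeness counts CA atoms within 2 A and is 50% on the half-displaced fixture", {
  m <- helix_model(40)
  half <- m
  rows <- half$atoms$resno <= 20
  # displace along the helix axis: 3 A from the own CA and > 2 A from
  # every other CA, so exactly the displaced half stops matching
  half$atoms$z[rows] <- half$atoms$z[rows] + 3
  cmp <- compare_models(m, half)
  expect_equal(cmp$completeness, 50)
  # a 1.9 A displacement still counts as matched
  near <- m
  near$atoms$x <- near$atoms$x + 1.9
  expect_equal(compare_models(m, near)$completeness, 100)
})

test_that("superposition and nearest-CA fallback pairing work", {
  m <- helix_model(30)
  moved <- transform_model(m, rotation_z(30), c(5, 5, 5))
  cmp <- compare_models(m, moved, superpose = TRUE)
  expect_lt(cmp$rmsd, 1e-9)
  expect_equal(cmp$completeness, 100)
  # renumber: identity pairing fails, nearest-CA fallback recovers
  ren <- m
  ren$atoms$resno <- ren$atoms$resno + 500L
  expect_error(compare_models(m, ren), "no residue pairs")
  cmp2 <- compare_models(m, ren, nearest_fallback = TRUE)
  expect_equal(cmp2$rmsd, 0)
  expect_equal(cmp2$coverage, 100)
})

test_that("symmetry operators parse, validate and apply", {
  op <- parse_symop("-X,Y+1/2,-Z")
  expect_equal(op$rotation, diag(c(-1, 1, -1)))
  expect_equal(op$translation, c(0, 0.5, 0))
  expect_true(op$fractional)
  expect_error(symmetry_operator(matrix(2 * diag(3), 3, 3)), "orthogonal")
  id <- parse_symop("x,y,z")
  expect_equal(id$rotation, diag(3))
})

test_that("symmetry_expand_best recovers the generating operator", {
  m <- helix_model(25)
  cell <- c(60, 60, 80, 90, 90, 90)
  ops <- list(parse_symop("x,y,z"), parse_symop("-x,y+1/2,-z"))
  # build the mobile copy by applying operator #2 to the reference
  mobile <- m
  mobile$atoms[, c("x", "y", "z")] <-
    itermodel:::.apply_symop(as.matrix(m$atoms[, c("x", "y", "z")]),
                             ops[[2]], cell)
  # mobile is far from reference under identity...
  expect_lt(compare_models(m, mobile)$completeness, 50)
  best <- symmetry_expand_best(mobile, m, ops, cell = cell)
  expect_equal(best$completeness, 100)
  expect_equal(best$operator$index, 2L)
  expect_equal(best$rmsd, 0, tolerance = 1e-9)
  # identity operator only equals plain compare_models
  one <- symmetry_expand_best(m, mobile, ops[1], cell = cell)
  expect_equal(one$completeness, compare_models(m, mobile)$completeness)
  # no operators: identity with a warning
  expect_warning(symmetry_expand_best(m, m), "identity")
})

test_that("origin shifts on the half-step grid are searched", {
  m <- helix_model(25)
  cell <- c(50, 50, 70, 90, 90, 90)
  op_shift <- symmetry_operator(diag(3), c(0, 0, 0), fractional = TRUE,
                                allowed_origin_shift = c(1, 0, 0))
  mobile <- transform_model(m, trans = c(25, 0, 0))   # half a cell along x
  best <- symmetry_expand_best(mobile, m, list(op_shift), cell = cell)
  expect_equal(best$completeness, 100)
  expect_equal(best$operator$origin_shift, c(0.5, 0, 0))
})

test_that("tie-breaking prefers lower rmsd and never a worse operator", {
  m <- helix_model(20)
  ops <- list(parse_symop("x,y,z"), parse_symop("-x,-y,z"))
  best <- symmetry_expand_best(m, m, ops, cell = c(40, 40, 40, 90, 90, 90))
  expect_equal(best$operator$index, 1L)
  expect_equal(best$rmsd, 0)
})

test_that("assess_prediction applies the pLDDT-then-smoothed-rmsd filters", {
  n <- 60
  dep <- helix_model(n)
  pred <- dep
  pred$provenance <- "predicted"
  pred$atoms$b <- 95
  # perfect prediction: coverage 100, rmsd 0
  out <- assess_prediction(pred, dep)
  expect_equal(out$coverage, 100)
  expect_equal(out$rmsd, 0, tolerance = 1e-9)
  # a 15-residue region at 5 A error is excluded by the 3 A smoothed cap
  bad <- pred
  rows <- bad$atoms$resno %in% 23:37
  bad$atoms$x[rows] <- bad$atoms$x[rows] + 5
  out2 <- assess_prediction(bad, dep)
  # the 15-residue region is excluded up to smoothing spillover at its edges
  expect_lte(out2$coverage, 100 * (n - 9) / n)
  expect_gte(out2$coverage, 100 * (n - 19) / n)
  expect_lt(out2$rmsd, 3)
  # low-confidence residues are removed first
  lowc <- pred
  lowc$atoms$b[lowc$atoms$resno <= 30] <- 50
  out3 <- assess_prediction(lowc, dep)
  expect_equal(out3$coverage, 50)
})

test_that("the rmsd cap applies to smoothed, not raw, distances", {
  dep <- helix_model(40)
  pred <- dep
  pred$provenance <- "predicted"
  pred$atoms$b <- 95
  rows <- pred$atoms$resno == 20
  pred$atoms$x[rows] <- pred$atoms$x[rows] + 4   # single 4 A spike
  out <- assess_prediction(pred, dep)
  expect_equal(out$coverage, 100)                # window mean stays <= 3
})
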