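#' Least-squares (Kabsch) superposition
#'
#' Returns the proper rotation and translation minimizing the r.m.s.d.
#' of `coordsA` onto `coordsB` (rows are paired points), via SVD of the
#' covariance with the usual determinant sign correction.
#'
#' @param coordsA n x 3 matrix of moving points.
#' @param coordsB n x 3 matrix of target points (paired rows).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3)
#'   and `rmsd` after superposition; apply as `x %*% t(rotation) +
#'   translation`.
#' @export
kabsch <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  .assert(nrow(coordsA) == nrow(coordsB), "point sets must be paired")
  .assert(nrow(coordsA) >= 3, "need at least 3 point pairs")
  ca <- colMeans(coordsA); cb <- colMeans(coordsB)
  A <- sweep(coordsA, 2, ca); B <- sweep(coordsB, 2, cb)
  .assert(sum(A^2) > 1e-12, "degenerate (coincident) points")
  sv <- svd(t(A) %*% B)
  .assert(sv$d[2] > 1e-10 * max(sv$d[1], 1), "degenerate (collinear) geometry")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)
  trans <- unname(cb - as.numeric(rot %*% ca))
  moved <- .apply_rt(coordsA, rot, trans)
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((moved - coordsB)^2))))
}

# Pair residues of two models: identical (chain, resno, icode) first;
# optional nearest-CA fallback within `fallback_dist` for unpaired rows.
.pair_ca <- function(caA, caB, nearest_fallback = FALSE, fallback_dist = 5) {
  keyA <- paste(caA$chain, caA$resno, caA$icode, sep = "\r")
  keyB <- paste(caB$chain, caB$resno, caB$icode, sep = "\r")
  j <- match(keyA, keyB)
  if (nearest_fallback && anyNA(j)) {
    xyzB <- as.matrix(caB[, c("x", "y", "z")])
    for (i in which(is.na(j))) {
      d2 <- colSums((t(xyzB) - unlist(caA[i, c("x", "y", "z")]))^2)
      d2[stats::na.omit(j)] <- Inf     # already claimed
      k <- which.min(d2)
      if (d2[k] <= fallback_dist^2) j[i] <- k
    }
  }
  cbind(A = which(!is.na(j)), B = j[!is.na(j)])
}

#' Compare two models: r.m.s.d., completeness, coverage
#'
#' Residues are paired by identical (chain, residue number, insertion
#' code), optionally with a nearest-CA fallback. With `superpose`, model
#' B is first superposed onto A by Kabsch on the paired CA atoms.
#' Completeness is the percentage of A's CA atoms within 2 Angstrom of
#' any CA atom of B; coverage is the percentage of A's residues with a
#' paired counterpart in B.
#'
#' @param modelA reference [atomic_model()].
#' @param modelB comparison [atomic_model()].
#' @param superpose superpose B onto A before measuring.
#' @param nearest_fallback pair leftover residues with the nearest CA
#'   within 5 A (for renumbered models).
#' @param completeness_dist match distance for completeness (default 2).
#' @return list of class `comparison_result`: rmsd, n_matched,
#'   completeness, coverage (percent), per_residue (paired distances),
#'   transform (when superposed).
#' @export
compare_models <- function(modelA, modelB, superpose = FALSE,
                           nearest_fallback = FALSE,
                           completeness_dist = 2.0) {
  caA <- extract_ca(modelA); caB <- extract_ca(modelB)
  pairs <- .pair_ca(caA, caB, nearest_fallback)
  .assert(nrow(pairs) > 0, "no residue pairs between the two models")
  xyzA <- as.matrix(caA[, c("x", "y", "z")])
  xyzB <- as.matrix(caB[, c("x", "y", "z")])
  transform <- NULL
  if (superpose && nrow(pairs) >= 3) {
    transform <- kabsch(xyzB[pairs[, "B"], , drop = FALSE],
                        xyzA[pairs[, "A"], , drop = FALSE])
    xyzB <- .apply_rt(xyzB, transform$rotation, transform$translation)
  }
  dists <- sqrt(rowSums((xyzA[pairs[, "A"], , drop = FALSE] -
                         xyzB[pairs[, "B"], , drop = FALSE])^2))
  # completeness: nearest B CA (any residue) within the threshold
  near <- vapply(seq_len(nrow(xyzA)), function(i) {
    min(sqrt(colSums((t(xyzB) - xyzA[i, ])^2)))
  }, numeric(1))
  res <- list(
    rmsd = sqrt(mean(dists^2)),
    n_matched = nrow(pairs),
    completeness = 100 * mean(near <= completeness_dist),
    coverage = 100 * nrow(pairs) / nrow(caA),
    per_residue = data.frame(chain = caA$chain[pairs[, "A"]],
                             resno = caA$resno[pairs[, "A"]],
                             dist = dists, stringsAsFactors = FALSE),
    transform = transform,
    operator = NULL
  )
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison: rmsd %.3f A over %d pairs, completeness %.1f%%, coverage %.1f%%>\n",
    x$rmsd, x$n_matched, x$completeness, x$coverage))
  invisible(x)
}

#' Crystallographic symmetry operator
#'
#' @param rotation 3x3 matrix, orthogonal with determinant +-1.
#' @param translation length-3 vector.
#' @param fractional are rotation/translation expressed on fractional
#'   coordinates (requires a cell downstream)?
#' @param allowed_origin_shift length-3 0/1 flags: axes along which an
#'   origin shift of 1/2 may be applied.
#' @return list of class `symmetry_operator`.
#' @export
symmetry_operator <- function(rotation, translation = c(0, 0, 0),
                              fractional = TRUE,
                              allowed_origin_shift = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  .assert(max(abs(t(rotation) %*% rotation - diag(3))) < 1e-6,
          "rotation must be orthogonal")
  .assert(abs(abs(det(rotation)) - 1) < 1e-6, "rotation must have det +-1")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 fractional = fractional,
                 allowed_origin_shift = as.numeric(allowed_origin_shift)),
            class = "symmetry_operator")
}

#' Parse a symmetry operator string such as "-X,Y+1/2,-Z"
#'
#' @param text triplet string on fractional coordinates.
#' @param allowed_origin_shift passed through to [symmetry_operator()].
#' @return a fractional [symmetry_operator()].
#' @export
parse_symop <- function(text, allowed_origin_shift = c(0, 0, 0)) {
  parts <- strsplit(gsub("\\s", "", tolower(text)), ",")[[1]]
  .assert(length(parts) == 3, "operator must have three comma-separated terms")
  rot <- matrix(0, 3, 3); trans <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    for (j in 1:3) {
      v <- c("x", "y", "z")[j]
      if (grepl(paste0("-", v), expr, fixed = TRUE)) rot[i, j] <- -1
      else if (grepl(v, expr, fixed = TRUE)) rot[i, j] <- 1
      expr <- gsub(paste0("[+-]?", v), "", expr)
    }
    if (nchar(expr)) {
      frac <- strsplit(expr, "/")[[1]]
      trans[i] <- if (length(frac) == 2)
        as.numeric(frac[1]) / as.numeric(frac[2]) else as.numeric(expr)
    }
  }
  symmetry_operator(rot, trans, fractional = TRUE,
                    allowed_origin_shift = allowed_origin_shift)
}

# Apply an operator (plus an extra fractional origin shift) to Cartesian
# coordinates; orthogonal cells only.
.apply_symop <- function(xyz, op, cell, origin_shift = c(0, 0, 0)) {
  if (op$fractional) {
    .assert(!is.null(cell), "fractional operator needs cell dimensions")
    abc <- cell[1:3]
    fr <- sweep(xyz, 2, abc, "/")
    fr <- .apply_rt(fr, op$rotation, op$translation + origin_shift)
    sweep(fr, 2, abc, "*")
  } else {
    .apply_rt(xyz, op$rotation, op$translation + origin_shift)
  }
}

#' Best symmetry image of a model for comparison
#'
#' Evaluates [compare_models()] between the reference and every
#' operator-image of the mobile model, trying for each operator all
#' origin shifts on the 1/2-step grid along its allowed axes, and
#' returns the best result (maximum completeness; ties broken by lower
#' r.m.s.d.). With no operators the identity is used with a warning.
#'
#' @param reference reference [atomic_model()].
#' @param mobile mobile [atomic_model()].
#' @param operators list of [symmetry_operator()].
#' @param cell unit cell (a, b, c, alpha, beta, gamma) for fractional
#'   operators.
#' @return the best `comparison_result`, with `operator` recording which
#'   operator and shift produced it.
#' @export
symmetry_expand_best <- function(reference, mobile, operators = list(),
                                 cell = NULL) {
  if (!length(operators)) {
    warning("no symmetry operators supplied; falling back to identity")
    operators <- list(symmetry_operator(diag(3), fractional = FALSE))
  }
  best <- NULL
  for (k in seq_along(operators)) {
    op <- operators[[k]]
    shifts <- expand.grid(
      x = if (op$allowed_origin_shift[1]) c(0, 0.5) else 0,
      y = if (op$allowed_origin_shift[2]) c(0, 0.5) else 0,
      z = if (op$allowed_origin_shift[3]) c(0, 0.5) else 0)
    for (s in seq_len(nrow(shifts))) {
      img <- mobile
      img$atoms[, c("x", "y", "z")] <-
        .apply_symop(.xyz(mobile$atoms), op, cell,
                     origin_shift = as.numeric(shifts[s, ]))
      cmp <- tryCatch(compare_models(reference, img), error = function(e) NULL)
      if (is.null(cmp)) next
      cmp$operator <- list(index = k, origin_shift = as.numeric(shifts[s, ]))
      if (is.null(best) ||
          cmp$completeness > best$completeness ||
          (cmp$completeness == best$completeness && cmp$rmsd < best$rmsd)) {
        best <- cmp
      }
    }
  }
  .assert(!is.null(best), "no operator image could be compared")
  best
}

#' Assess a prediction against a deposited model
#'
#' Superposes the prediction onto the deposited model, removes residues
#' with pLDDT below `plddt_cutoff`, then removes residues whose paired
#' CA distance, smoothed over `rmsd_window` residues, exceeds
#' `rmsd_cap`. Reports the r.m.s.d. over the survivors and the coverage
#' (percent of deposited residues matched by surviving prediction
#' residues).
#'
#' @param predicted predicted [atomic_model()] (pLDDT in B column).
#' @param deposited deposited [atomic_model()].
#' @param plddt_cutoff confidence filter (default 70).
#' @param rmsd_window smoothing window in residues (default 10).
#' @param rmsd_cap smoothed-distance cap in Angstrom (default 3).
#' @return list with `rmsd` (NA with `rmsd_defined = FALSE` when all
#'   residues are filtered), `coverage` (percent), `n_used`.
#' @export
assess_prediction <- function(predicted, deposited, plddt_cutoff = 70,
                              rmsd_window = 10, rmsd_cap = 3.0) {
  caP <- extract_ca(predicted); caD <- extract_ca(deposited)
  pairs <- .pair_ca(caP, caD)
  .assert(nrow(pairs) > 0, "no residue pairs")
  xyzP <- as.matrix(caP[, c("x", "y", "z")])[pairs[, "A"], , drop = FALSE]
  xyzD <- as.matrix(caD[, c("x", "y", "z")])[pairs[, "B"], , drop = FALSE]
  fit <- kabsch(xyzP, xyzD)
  xyzP <- .apply_rt(xyzP, fit$rotation, fit$translation)
  plddt <- predicted$atoms$b[residue_table(predicted)$ca_row][pairs[, "A"]]
  if (max(predicted$atoms$b) <= 1.0) plddt <- plddt * 100
  keep <- plddt >= plddt_cutoff
  dist <- sqrt(rowSums((xyzP - xyzD)^2))
  sm <- smooth_track(dist[keep], rmsd_window)
  keep[keep] <- sm <= rmsd_cap
  n_dep <- nrow(caD)
  if (!any(keep)) {
    return(list(rmsd = NA_real_, rmsd_defined = FALSE, coverage = 0,
                n_used = 0L))
  }
  list(rmsd = sqrt(mean(dist[keep]^2)), rmsd_defined = TRUE,
       coverage = 100 * sum(keep) / n_dep, n_used = sum(keep))
}
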