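#' Specification for a synthetic fixture
#'
#' Describes a toy "true" structure, the inaccuracies of its simulated
#' prediction, and the map computed from it. The stated world: an
#' accurate core around the 1.2 Angstrom r.m.s.d. regime typical of
#' usable predictions, plus an optional displaced/rotated region whose
#' simulated pLDDT is anti-correlated with the local error.
#'
#' @param fold "helix", "two_domain" or "three_domain".
#' @param n_res residues per domain (default 30).
#' @param core_rmsd requested coordinate error of unperturbed regions in
#'   Angstrom (default 1.2).
#' @param region_rmsd extra coordinate error of the perturbed region
#'   (default 4).
#' @param region_rot rotation of the perturbed region in degrees
#'   (default 20); the perturbed region is the last domain.
#' @param resolution map resolution in Angstrom (default 2.5).
#' @param noise_sd map noise standard deviation as a fraction of the
#'   peak density (default 0).
#' @param seed integer seed (mandatory).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(fold = c("helix", "two_domain", "three_domain"),
                         n_res = 30, core_rmsd = 1.2, region_rmsd = 4,
                         region_rot = 20, resolution = 2.5, noise_sd = 0,
                         seed) {
  fold <- match.arg(fold)
  .assert(!missing(seed), "seed is mandatory")
  .assert(n_res >= 5, "need at least 5 residues per domain")
  .assert(all(c(core_rmsd, region_rmsd, region_rot, noise_sd) >= 0),
          "magnitudes must be >= 0")
  structure(list(fold = fold, n_res = as.integer(n_res),
                 core_rmsd = core_rmsd, region_rmsd = region_rmsd,
                 region_rot = region_rot, resolution = resolution,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Ideal poly-alanine helix CA trace plus approximate N, C, O, CB.
.helix_residues <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  ang <- (seq_len(n) - 1) * twist * pi / 180
  ca <- cbind(radius * cos(ang), radius * sin(ang), (seq_len(n) - 1) * rise)
  .build_backbone(ca)
}

# Approximate backbone/CB geometry from a CA trace: bonded neighbors are
# placed along the local chain directions, CB radially outward. Adequate
# for density and correlation fixtures; not stereochemically exact.
.build_backbone <- function(ca) {
  n <- nrow(ca)
  unit <- function(v) v / sqrt(sum(v^2))
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    prev <- if (i > 1) unit(ca[i - 1, ] - ca[i, ]) else -unit(ca[min(i + 1, n), ] - ca[i, ])
    nxt <- if (i < n) unit(ca[i + 1, ] - ca[i, ]) else -prev
    out <- ca[i, ] - c(0, 0, ca[i, 3])
    if (sum(out^2) < 1e-8) out <- c(1, 0, 0)
    out <- unit(out)
    perp <- unit(pracma_cross(nxt, out))
    pos <- rbind(
      N = ca[i, ] + 1.46 * prev,
      CA = ca[i, ],
      C = ca[i, ] + 1.52 * nxt,
      O = ca[i, ] + 1.52 * nxt + 1.23 * perp,
      CB = ca[i, ] + 1.53 * unit(out + c(0, 0, 0.4)))
    atoms[[i]] <- data.frame(
      resno = i, atom = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, atoms)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.rotation_about <- function(axis, degrees) {
  u <- axis / sqrt(sum(axis^2))
  th <- degrees * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(u)
}

#' Generate a toy "true" structure
#'
#' Ideal poly-alanine backbone (+CB) geometry: a single alpha-helix
#' (rise 1.5 A, 100 degrees per residue) or two/three helical domains
#' stacked end to end with 24 A gaps, each rotated 60 degrees relative
#' to the previous and joined by 4-residue stretched linkers, so that
#' the domains form spatially separate compact clusters. Deterministic given
#' the seed. Per-residue region labels (domain / linker ids) are
#' attached as attribute `region`.
#'
#' @param spec a [fixture_spec()].
#' @return an [atomic_model()] with provenance "deposited".
#' @export
make_true_model <- function(spec) {
  n_dom <- switch(spec$fold, helix = 1L, two_domain = 2L, three_domain = 3L)
  linker_len <- 4L
  doms <- list()
  region <- integer(0)
  resno_offset <- 0L
  prev_end_ca <- NULL
  for (k in seq_len(n_dom)) {
    at <- .helix_residues(spec$n_res)
    xyz <- as.matrix(at[, c("x", "y", "z")])
    if (k > 1) {
      # domains stacked end to end with a 24 A gap so the stretched
      # linker cannot bridge them in an 8 A contact graph
      rot <- .rotation_about(c(0, 0, 1), 60 * (k - 1))
      xyz <- xyz %*% t(rot)
      xyz <- sweep(xyz, 2, c(3 * (k - 1), 0,
                             (k - 1) * (1.5 * spec$n_res + 24)), "+")
    }
    at[, c("x", "y", "z")] <- xyz
    if (k > 1) {
      # stretched linker bridging the previous domain end to this start
      start_ca <- xyz[at$atom == "CA", , drop = FALSE][1, ]
      steps <- seq_len(linker_len) / (linker_len + 1)
      lxyz <- t(sapply(steps, function(f) prev_end_ca + f * (start_ca - prev_end_ca)))
      lat <- .build_backbone(lxyz)
      lat$resno <- lat$resno + resno_offset
      doms[[length(doms) + 1L]] <- lat
      region <- c(region, rep(-(k - 1), linker_len))
      resno_offset <- resno_offset + linker_len
    }
    ca_rows <- at$atom == "CA"
    prev_end_ca <- as.matrix(at[ca_rows, c("x", "y", "z")])[spec$n_res, ]
    at$resno <- at$resno + resno_offset
    resno_offset <- resno_offset + spec$n_res
    doms[[length(doms) + 1L]] <- at
    region <- c(region, rep(k, spec$n_res))
  }
  at <- do.call(rbind, doms)
  atoms <- data.frame(chain = "A", resno = at$resno, icode = "",
                      resname = "ALA", atom = at$atom, element = at$element,
                      x = at$x, y = at$y, z = at$z, b = 20, occ = 1,
                      stringsAsFactors = FALSE)
  m <- atomic_model(atoms, provenance = "deposited")
  attr(m, "region") <- region
  m
}

#' Simulate an inaccurate prediction of a true structure
#'
#' Adds seeded sequence-smoothed residue-level coordinate noise
#' normalized to `core_rmsd` everywhere (smooth errors keep the bonded
#' geometry intact, as in real predictions),
#' then displaces the last domain rigidly: a `region_rot` degree
#' rotation about its centroid plus a `region_rmsd` Angstrom
#' translation along a seeded random direction, emulating a prediction
#' whose region is locally accurate but wrongly placed. Simulated pLDDT is
#' written into the B column as 90 - 15 * (smoothed local CA error in
#' Angstrom), clipped to [20, 98], i.e. anti-correlated with the true
#' local error.
#'
#' @param true_model output of [make_true_model()] (with its `region`
#'   attribute).
#' @param spec the same [fixture_spec()].
#' @return an [atomic_model()] with provenance "predicted".
#' @export
make_prediction <- function(true_model, spec) {
  set.seed(spec$seed)
  region <- attr(true_model, "region")
  .assert(!is.null(region), "true_model lacks region labels")
  atoms <- true_model$atoms
  idx <- .residue_index(true_model)
  xyz <- .xyz(atoms)
  n_res <- max(idx)
  # sequence-correlated residue-level noise: prediction errors are
  # smooth along the chain (spline through knots every ~8 residues), so
  # bonded geometry stays intact
  noise_res <- function(target_rmsd) {
    if (target_rmsd <= 0) return(matrix(0, n_res, 3))
    k <- max(4, ceiling(n_res / 8))
    xs <- seq(1, n_res, length.out = k)
    e <- vapply(1:3, function(j)
      stats::spline(xs, stats::rnorm(k), xout = seq_len(n_res),
                    method = "natural")$y,
      numeric(n_res))
    e * target_rmsd / sqrt(mean(rowSums(e^2)))
  }
  xyz <- xyz + noise_res(spec$core_rmsd)[idx, , drop = FALSE]
  last_dom <- max(region)
  if (last_dom > 1 && (spec$region_rot > 0 || spec$region_rmsd > 0)) {
    res_sel <- region == last_dom
    sel <- res_sel[idx]
    sub <- xyz[sel, , drop = FALSE]
    ctr <- colMeans(sub)
    axis <- stats::rnorm(3)
    rot <- .rotation_about(axis, spec$region_rot)
    sub <- sweep(sweep(sub, 2, ctr) %*% t(rot), 2, ctr, "+")
    shift <- stats::rnorm(3)
    sub <- sweep(sub, 2, shift / sqrt(sum(shift^2)) * spec$region_rmsd, "+")
    xyz[sel, ] <- sub
  }
  atoms[, c("x", "y", "z")] <- xyz
  # per-residue true CA error -> simulated pLDDT
  rt <- residue_table(true_model)
  err <- sqrt(rowSums((xyz[rt$ca_row, , drop = FALSE] -
                       .xyz(true_model$atoms)[rt$ca_row, , drop = FALSE])^2))
  sm_err <- smooth_track(err, 5, segment_starts(true_model))
  plddt <- pmin(98, pmax(20, 90 - 15 * sm_err))
  atoms$b <- plddt[idx]
  m <- atomic_model(atoms, provenance = "predicted")
  attr(m, "region") <- region
  attr(m, "true_ca_error") <- err
  m
}

#' Compute a (optionally noisy) map from a model
#'
#' [model_to_map()] at grid spacing `resolution / 3`, plus seeded
#' Gaussian grid noise with standard deviation `noise_sd` times the peak
#' density.
#'
#' @param model an [atomic_model()] (typically the true structure).
#' @param resolution map resolution in Angstrom.
#' @param noise_sd noise level as a fraction of the peak density.
#' @param seed integer seed for the noise.
#' @return a [density_map()].
#' @export
make_map <- function(model, resolution = 2.5, noise_sd = 0, seed = 0) {
  map <- model_to_map(model, spacing = resolution / 3, resolution = resolution)
  if (noise_sd > 0) {
    set.seed(seed)
    map$values <- map$values +
      stats::rnorm(length(map$values), sd = noise_sd * max(map$values))
  }
  map
}

#' Generate the full fixture set for a specification
#'
#' @param spec a [fixture_spec()].
#' @return list with `truth`, `prediction`, `map`.
#' @export
make_fixture <- function(spec) {
  truth <- make_true_model(spec)
  prediction <- make_prediction(truth, spec)
  map <- make_map(truth, resolution = spec$resolution,
                  noise_sd = spec$noise_sd, seed = spec$seed + 1L)
  list(truth = truth, prediction = prediction, map = map)
}
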