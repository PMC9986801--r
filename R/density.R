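#' Real-space density map container
#'
#' A `density_map` is a 3-D grid of density values on an orthogonal
#' lattice: `values[i, j, k]` sits at
#' `origin + (c(i, j, k) - 1) * spacing` (Angstrom, Cartesian).
#'
#' @param values 3-D numeric array.
#' @param spacing grid step in Angstrom (length 1 or 3).
#' @param origin Cartesian position of grid point (1,1,1) in Angstrom.
#' @param cell unit-cell a, b, c, alpha, beta, gamma; defaults to the grid
#'   extent with right angles.
#' @return object of class `density_map`.
#' @export
density_map <- function(values, spacing, origin = c(0, 0, 0), cell = NULL) {
  .assert(length(dim(values)) == 3, "values must be a 3-D array")
  .assert(all(dim(values) >= 2), "grid must have >= 2 points per axis")
  spacing <- rep_len(as.numeric(spacing), 3)
  .assert(all(spacing > 0), "spacing must be positive")
  if (is.null(cell)) cell <- c(dim(values) * spacing, 90, 90, 90)
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), cell = as.numeric(cell)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map: %s grid, spacing %s A, origin (%s) A>\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "/"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

# Grid point coordinates along one axis.
.axis_coords <- function(map, axis) {
  map$origin[axis] + (seq_len(dim(map$values)[axis]) - 1) * map$spacing[axis]
}

# --- CCP4/MRC input/output -------------------------------------------------

#' Read a CCP4/MRC density map
#'
#' Supports mode-2 (float) maps with orthogonal cells. Axis order is
#' normalized to X, Y, Z on read using the MAPC/MAPR/MAPS header fields;
#' the origin is taken from the ORIGIN header words when set, otherwise
#' from NXSTART/NYSTART/NZSTART times the grid spacing.
#'
#' @param path file path.
#' @return a [density_map()].
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nxyz <- h_int[1:3]; mode <- h_int[4]; nstart <- h_int[5:7]; mxyz <- h_int[8:10]
  .assert(mode == 2, "only mode-2 (float32) MRC maps are supported")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # dmin/dmax/dmean
  readBin(con, "integer", n = 2, size = 4, endian = "little")  # ispg, nsymbt
  readBin(con, "integer", n = 25, size = 4, endian = "little") # extra
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readChar(con, 4, useBytes = TRUE)                            # "MAP "
  readBin(con, "integer", n = 1, size = 4, endian = "little")  # machine stamp
  readBin(con, "numeric", n = 1, size = 4, endian = "little")  # rms
  readBin(con, "integer", n = 1, size = 4, endian = "little")  # nlabl
  readChar(con, 800, useBytes = TRUE)
  vals <- readBin(con, "numeric", n = prod(nxyz), size = 4, endian = "little")
  arr <- array(vals, dim = nxyz)
  # nxyz/nstart are in file (column, row, section) order; permute to X,Y,Z
  perm <- order(mapcrs)          # position of axis X, Y, Z among C,R,S
  arr <- aperm(arr, perm)
  spacing <- cella / mxyz            # MX,MY,MZ and CELLA are in X,Y,Z order
  nstart_xyz <- nstart[perm]
  origin <- if (any(orig != 0)) orig else nstart_xyz * spacing
  density_map(arr, spacing = spacing, origin = origin,
              cell = c(cella, cellb))
}

#' Write a CCP4/MRC density map
#'
#' Mode-2 little-endian output with axis order X, Y, Z and the Cartesian
#' origin stored in the ORIGIN header words.
#'
#' @param map a [density_map()].
#' @param path output path.
#' @export
write_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- dim(map$values)
  w_int <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_flt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.numeric(map$values)
  w_int(c(n, 2, c(0, 0, 0), n))
  w_flt(n * map$spacing)                       # cell lengths
  w_flt(map$cell[4:6])                         # cell angles
  w_int(c(1, 2, 3))                            # mapc, mapr, maps
  w_flt(c(min(v), max(v), mean(v)))
  w_int(c(1, 0))                               # ispg, nsymbt
  w_int(rep(0L, 25))
  w_flt(map$origin)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  w_int(16708L)                                # little-endian machine stamp
  w_flt(stats::sd(v))
  w_int(0L)
  writeChar(strrep(" ", 800), con, nchars = 800, eos = NULL)
  w_flt(v)
  invisible(path)
}

# --- Model-derived density -------------------------------------------------

# Render Gaussian-atom density on an explicit grid. Each atom is a single
# Gaussian of integrated weight equal to its electron count and variance
# sigma^2 = (b + B_res) / (8 pi^2) with B_res = 79 * (resolution / 3)^2,
# a resolution-dependent blur.
.render_density <- function(atoms, ngrid, spacing, origin, resolution,
                            sidechain_b_add = 0) {
  vals <- array(0, dim = ngrid)
  b_res <- 79 * (resolution / 3)^2
  ax <- origin[1] + (seq_len(ngrid[1]) - 1) * spacing[1]
  ay <- origin[2] + (seq_len(ngrid[2]) - 1) * spacing[2]
  az <- origin[3] + (seq_len(ngrid[3]) - 1) * spacing[3]
  backbone <- c("N", "CA", "C", "O", "OXT")
  z <- .atom_electrons(atoms$element)
  for (i in seq_len(nrow(atoms))) {
    b <- atoms$b[i]
    if (sidechain_b_add > 0 && !(atoms$atom[i] %in% backbone))
      b <- b + sidechain_b_add
    sigma2 <- (b + b_res) / (8 * pi^2)
    cut <- 4 * sqrt(sigma2)
    ix <- which(abs(ax - atoms$x[i]) <= cut)
    iy <- which(abs(ay - atoms$y[i]) <= cut)
    iz <- which(abs(az - atoms$z[i]) <= cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    amp <- atoms$occ[i] * z[i] / (2 * pi * sigma2)^1.5
    gx <- exp(-(ax[ix] - atoms$x[i])^2 / (2 * sigma2))
    gy <- exp(-(ay[iy] - atoms$y[i])^2 / (2 * sigma2))
    gz <- exp(-(az[iz] - atoms$z[i])^2 / (2 * sigma2))
    gxy <- outer(gx, gy)
    for (k in seq_along(iz)) {
      vals[ix, iy, iz[k]] <- vals[ix, iy, iz[k]] + amp * gz[k] * gxy
    }
  }
  vals
}

#' Compute a model-derived density map
#'
#' Each atom contributes a single Gaussian whose integrated weight is
#' proportional to its element's electron count and whose variance
#' combines the atomic B factor with a resolution-dependent blur,
#' sigma^2 = (b_iso + B_res) / (8 pi^2), B_res = 79 (resolution/3)^2 A^2.
#' The grid covers the model extent plus a 5 A pad, unless an explicit
#' grid (another map) is supplied.
#'
#' @param model an [atomic_model()].
#' @param spacing grid step in Angstrom; must be < resolution / 2.
#' @param resolution nominal resolution in Angstrom controlling the blur.
#' @param grid optional [density_map()] whose grid geometry to reuse.
#' @param sidechain_b_add B increment (A^2) added to every atom beyond the
#'   backbone (used by the correlation optimizer).
#' @return a [density_map()].
#' @export
model_to_map <- function(model, spacing = 1.0, resolution = 3.0, grid = NULL,
                         sidechain_b_add = 0) {
  .assert(nrow(model$atoms) > 0, "empty model")
  if (is.null(grid)) {
    .assert(all(spacing < resolution / 2),
            "spacing must be finer than resolution / 2 (undersampled grid)")
    spacing <- rep_len(spacing, 3)
    lo <- c(min(model$atoms$x), min(model$atoms$y), min(model$atoms$z)) - 5
    hi <- c(max(model$atoms$x), max(model$atoms$y), max(model$atoms$z)) + 5
    ngrid <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
    origin <- lo
  } else {
    ngrid <- dim(grid$values); spacing <- grid$spacing; origin <- grid$origin
  }
  vals <- .render_density(model$atoms, ngrid, spacing, origin, resolution,
                          sidechain_b_add)
  density_map(vals, spacing = spacing, origin = origin,
              cell = if (is.null(grid)) NULL else grid$cell)
}

# Linear grid indices within `radius` of any of the given atom positions.
.mask_indices <- function(map, xyz, radius) {
  ngrid <- dim(map$values)
  ax <- .axis_coords(map, 1); ay <- .axis_coords(map, 2); az <- .axis_coords(map, 3)
  idx <- integer(0)
  for (i in seq_len(nrow(xyz))) {
    ix <- which(abs(ax - xyz[i, 1]) <= radius)
    iy <- which(abs(ay - xyz[i, 2]) <= radius)
    iz <- which(abs(az - xyz[i, 3]) <= radius)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[ix] - xyz[i, 1])^2
    dy2 <- (ay[iy] - xyz[i, 2])^2
    dz2 <- (az[iz] - xyz[i, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    sel <- which(d2 <= radius^2)
    if (!length(sel)) next
    a <- arrayInd(sel, .dim = c(length(ix), length(iy), length(iz)))
    lin <- ix[a[, 1]] + (iy[a[, 2]] - 1L) * ngrid[1] +
      (iz[a[, 3]] - 1L) * prod(ngrid[1:2])
    idx <- c(idx, lin)
  }
  unique(idx)
}

.fraction_inside <- function(map, atoms) {
  ngrid <- dim(map$values)
  hi <- map$origin + (ngrid - 1) * map$spacing
  inside <- atoms$x >= map$origin[1] & atoms$x <= hi[1] &
    atoms$y >= map$origin[2] & atoms$y <= hi[2] &
    atoms$z >= map$origin[3] & atoms$z <= hi[3]
  mean(inside)
}

#' Per-residue local map-model correlation
#'
#' For each residue, the Pearson correlation between the experimental map
#' and a map calculated from the model, over grid points within
#' `mask_radius` of any atom of that residue. Residues whose mask holds
#' fewer than `min_points` grid points get cc = 0 and are flagged.
#'
#' @param model an [atomic_model()].
#' @param map a [density_map()] covering the model (>= 80 percent of
#'   atoms inside the grid).
#' @param mask_radius masking radius in Angstrom (default 2.5).
#' @param resolution resolution used for the model map (default 3).
#' @param min_points minimum masked grid points per residue (default 10).
#' @return a `residue_profile` data.frame with columns chain, resno,
#'   icode, local_cc, n_points, flagged.
#' @export
local_cc <- function(model, map, mask_radius = 2.5, resolution = 3.0,
                     min_points = 10) {
  .assert(.fraction_inside(map, model$atoms) >= 0.8,
          "map does not cover the model (less than 80 percent of atoms inside)")
  model_map <- model_to_map(model, resolution = resolution, grid = map)
  rt <- residue_table(model)
  xyz_all <- .xyz(model$atoms)
  cc <- numeric(nrow(rt)); npts <- integer(nrow(rt)); flagged <- logical(nrow(rt))
  for (i in seq_len(nrow(rt))) {
    idx <- .mask_indices(map, xyz_all[rt$atom_rows[[i]], , drop = FALSE],
                         mask_radius)
    npts[i] <- length(idx)
    if (length(idx) < min_points) { cc[i] <- 0; flagged[i] <- TRUE; next }
    a <- map$values[idx]; b <- model_map$values[idx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) { cc[i] <- 0; flagged[i] <- TRUE; next }
    cc[i] <- stats::cor(a, b)
  }
  out <- data.frame(chain = rt$chain, resno = rt$resno, icode = rt$icode,
                    local_cc = cc, n_points = npts, flagged = flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("residue_profile", class(out))
  out
}

#' Global masked map-model correlation with optional optimization
#'
#' Pearson correlation between the map and the model-derived map over the
#' union of spheres of radius `mask_radius` around all atoms. With
#' `optimize = TRUE` the mask radius is grid-searched over
#' {1.5, 2, 2.5, 3} A and a per-atom-beyond-CA B increment over
#' {0, 10, 20, 40} A^2, returning the maximized correlation and the
#' argmax, the mask-radius / side-chain-B optimization used when scoring
#' rebuilt models against maps.
#'
#' @inheritParams local_cc
#' @param optimize grid-search the mask radius and side-chain B increment.
#' @return list with `cc`, `radius`, `side_chain_b_increment`.
#' @export
global_cc <- function(model, map, optimize = FALSE, mask_radius = 2.5,
                      resolution = 3.0) {
  .assert(.fraction_inside(map, model$atoms) >= 0.8,
          "map does not cover the model (less than 80 percent of atoms inside)")
  radii <- if (optimize) c(1.5, 2.0, 2.5, 3.0) else mask_radius
  incrs <- if (optimize) c(0, 10, 20, 40) else 0
  xyz <- .xyz(model$atoms)
  best <- list(cc = -Inf, radius = radii[1], side_chain_b_increment = incrs[1])
  for (r in radii) {
    idx <- .mask_indices(map, xyz, r)
    if (length(idx) < 10) next
    a <- map$values[idx]
    for (inc in incrs) {
      mm <- model_to_map(model, resolution = resolution, grid = map,
                         sidechain_b_add = inc)
      b <- mm$values[idx]
      cc <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
      if (cc > best$cc) best <- list(cc = cc, radius = r,
                                     side_chain_b_increment = inc)
    }
  }
  .assert(is.finite(best$cc), "empty mask: model does not overlap the map grid")
  best
}

#' Smooth a per-residue track within contiguous segments
#'
#' Centered moving average. Near segment ends the window shrinks
#' symmetrically, and smoothing never crosses a segment boundary (chain
#' break). Output length equals input length; `window = 1` is the
#' identity.
#'
#' @param values per-residue numeric track.
#' @param window window width in residues (default 10).
#' @param starts logical vector flagging the first residue of each
#'   contiguous segment; default: one segment.
#' @return smoothed numeric track.
#' @export
smooth_track <- function(values, window = 10, starts = NULL) {
  .assert(window >= 1, "window must be >= 1")
  n <- length(values)
  if (n == 0) return(values)
  if (is.null(starts)) starts <- c(TRUE, rep(FALSE, n - 1))
  .assert(length(starts) == n, "starts must align with values")
  seg <- .segment_ids(starts)
  out <- numeric(n)
  half <- floor((window - 1) / 2)
  for (s in unique(seg)) {
    pos <- which(seg == s)
    v <- values[pos]
    m <- length(v)
    for (j in seq_len(m)) {
      h <- min(half, j - 1, m - j)
      out[pos[j]] <- mean(v[(j - h):(j + h)])
    }
  }
  out
}
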