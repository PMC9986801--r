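# Shared fixtures (cached per test run) and independent oracles.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fx_cache)) assign(key, force(expr), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

helix_model <- function(n = 50, seed = 1) {
  make_true_model(fixture_spec("helix", n_res = n, seed = seed))
}

two_domain_fixture <- function(seed = 11, noise_sd = 0) {
  cached(sprintf("td_%d_%g", seed, noise_sd),
         make_fixture(fixture_spec("two_domain", n_res = 30, seed = seed,
                                   noise_sd = noise_sd)))
}

# A minimal hand-written one-residue PDB file.
write_min_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.000  12.000  13.000  1.00 20.00           C",
    "END"), path)
  path
}

# Rigidly transform every atom of a model.
transform_model <- function(model, rot = diag(3), trans = c(0, 0, 0)) {
  m <- model
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  m$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(rot), 2, trans, "+")
  m
}

rotation_z <- function(degrees) {
  th <- degrees * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# Straight-line re-implementation of the three-step trimming procedure,
# written independently of the package internals: plain loops over the
# raw correlation (and optional pLDDT) track.
oracle_trim <- function(raw_cc, plddt = NULL, starts = NULL,
                        window = 10, k1 = 3, k2 = 2,
                        ratio = 0.8, diff = 0.15) {
  eps <- 1e-9
  n <- length(raw_cc)
  if (is.null(starts)) starts <- c(TRUE, rep(FALSE, n - 1))
  seg_id <- cumsum(starts)
  smooth1 <- function(v, ids) {
    out <- numeric(length(v))
    h <- floor((window - 1) / 2)
    for (i in seq_along(v)) {
      lo <- i; hi <- i
      for (s in seq_len(h)) {
        if (i - s >= 1 && i + s <= length(v) &&
            ids[i - s] == ids[i] && ids[i + s] == ids[i]) {
          lo <- i - s; hi <- i + s
        } else break
      }
      out[i] <- mean(v[lo:hi])
    }
    out
  }
  tophalf <- function(v, k) {
    sv <- rev(sort(v))[1:ceiling(length(v) / 2)]
    m <- mean(sv)
    s <- if (length(sv) >= 2) sd(sv) else 0
    m - k * s
  }
  sm <- smooth1(raw_cc, seg_id)
  # step 1
  cut1 <- tophalf(sm, k1)
  rm1 <- sm < cut1 - eps
  if (!is.null(plddt)) {
    smp <- smooth1(plddt, seg_id)
    cutp <- tophalf(smp, k1)
    rm1 <- rm1 & (smp < cutp - eps)
  }
  keep <- !rm1
  # step 2: segments = maximal kept runs not crossing starts
  if (!any(keep)) return(rep(FALSE, n))
  cut2 <- tophalf(raw_cc[keep], k2) - eps
  segs <- list(); cur <- c()
  for (i in 1:n) {
    if (!keep[i] || (length(cur) && starts[i])) {
      if (length(cur)) segs[[length(segs) + 1]] <- cur
      cur <- c()
    }
    if (keep[i]) cur <- c(cur, i)
  }
  if (length(cur)) segs[[length(segs) + 1]] <- cur
  keep2 <- rep(FALSE, n)
  final_segs <- list()
  for (sg in segs) {
    while (length(sg) && raw_cc[sg[1]] < cut2 && sm[sg[1]] < cut2)
      sg <- sg[-1]
    while (length(sg) && raw_cc[sg[length(sg)]] < cut2 && sm[sg[length(sg)]] < cut2)
      sg <- sg[-length(sg)]
    if (length(sg) >= window) {
      keep2[sg] <- TRUE
      final_segs[[length(final_segs) + 1]] <- sg
    }
  }
  if (!length(final_segs)) return(rep(FALSE, n))
  # step 3
  mcc <- sapply(final_segs, function(sg) mean(raw_cc[sg]))
  top <- rev(sort(mcc))[1:ceiling(length(mcc) / 2)]
  m <- mean(top)
  cut3 <- max(ratio^2 * m, m - 2 * diff)
  out <- rep(FALSE, n)
  for (j in seq_along(final_segs)) if (mcc[j] >= cut3) out[final_segs[[j]]] <- TRUE
  out
}

# Keep-mask realized by trim_to_map: which input residues survived.
trim_keep_mask <- function(model, trimmed) {
  rt_in <- residue_table(model)
  rt_out <- residue_table(trimmed)
  paste(rt_in$chain, rt_in$resno) %in% paste(rt_out$chain, rt_out$resno)
}
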