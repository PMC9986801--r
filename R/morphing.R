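#' Find rigid anchors between a moving and a target model
#'
#' Identifies the parts of the moving model that match the target after
#' a part-local rigid superposition: each paired residue is scored by
#' its CA distance under a least-squares fit of its local sequence
#' window (so a whole domain that matches the target after its own
#' rigid motion is detected even when no single global superposition
#' fits both domains). Residues closer than `match_distance` are grown
#' into maximal consecutive runs; each run of at least `min_anchor`
#' residues is refit with its own transform (from the original moving
#' coordinates directly onto the target), and residues that still
#' exceed the match distance under the run-local fit are shaved from
#' the run ends.
#'
#' @param moving moving [atomic_model()] (typically a full-length
#'   prediction).
#' @param target target [atomic_model()] sharing chain ids and residue
#'   numbers with `moving`.
#' @param min_anchor minimum run length in residues (default 5).
#' @param match_distance paired-CA distance threshold in Angstrom
#'   (default 3).
#' @return list of class `anchor_set`; each element has `chain`,
#'   `resno` (member residue numbers), `rows` (residue indices in
#'   moving), `rotation`, `translation`.
#' @export
find_anchors <- function(moving, target, min_anchor = 5,
                         match_distance = 3.0) {
  caM <- extract_ca(moving); caT <- extract_ca(target)
  pairs <- .pair_ca(caM, caT)
  .assert(nrow(pairs) >= 3, "too few paired residues between models")
  xyzM <- as.matrix(caM[, c("x", "y", "z")])
  xyzT <- as.matrix(caT[, c("x", "y", "z")])
  pM <- xyzM[pairs[, "A"], , drop = FALSE]
  pT <- xyzT[pairs[, "B"], , drop = FALSE]
  n <- nrow(pairs)
  # consecutive = same chain and residue numbers increasing by 1
  chain <- caM$chain[pairs[, "A"]]; resno <- caM$resno[pairs[, "A"]]
  consec <- c(FALSE, chain[-1] == chain[-length(chain)] &
                diff(resno) == 1)
  block <- cumsum(!consec)            # maximal consecutive stretches
  # window-local fit distance per residue
  half <- max(5L, as.integer(min_anchor))
  d <- rep(Inf, n)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    w <- which(block == block[i] & abs(seq_len(n) - i) <= half)
    if (length(w) < 3) next
    fit <- tryCatch(kabsch(pM[w, , drop = FALSE], pT[w, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    fits[[i]] <- fit
    mv <- .apply_rt(pM[i, , drop = FALSE], fit$rotation, fit$translation)
    d[i] <- sqrt(sum((mv - pT[i, ])^2))
  }
  close_ <- d < match_distance
  # grow maximal runs outward from the best-fitting seeds; a neighbor
  # joins only while it fits the rigid transform of the whole run so
  # far, so runs cannot creep across a displaced-domain boundary
  anchors <- list()
  used <- !close_
  run_fit <- function(run) kabsch(pM[run, , drop = FALSE],
                                  pT[run, , drop = FALSE])
  for (seed in order(d)) {
    if (used[seed] || is.null(fits[[seed]])) next
    run <- seed
    fit <- fits[[seed]]
    repeat {
      grew <- FALSE
      for (dir in c(-1L, 1L)) {
        j <- (if (dir < 0) min(run) else max(run)) + dir
        while (j >= 1 && j <= n && !used[j] && !(j %in% run) &&
               block[j] == block[seed]) {
          mv <- .apply_rt(pM[j, , drop = FALSE], fit$rotation,
                          fit$translation)
          if (sqrt(sum((mv - pT[j, ])^2)) >= match_distance) break
          run <- if (dir < 0) c(j, run) else c(run, j)
          grew <- TRUE
          j <- j + dir
        }
      }
      if (!grew) break
      if (length(run) >= 3) fit <- run_fit(run)
    }
    if (length(run) < max(min_anchor, 3)) { used[seed] <- TRUE; next }
    fit <- run_fit(run)
    dl <- sqrt(rowSums((.apply_rt(pM[run, , drop = FALSE], fit$rotation,
                                  fit$translation) - pT[run, , drop = FALSE])^2))
    lo <- 1L; hi <- length(run)
    while (lo <= hi && dl[lo] >= match_distance) lo <- lo + 1L
    while (hi >= lo && dl[hi] >= match_distance) hi <- hi - 1L
    used[seed] <- TRUE
    if (hi - lo + 1L < max(min_anchor, 3)) next
    run <- run[lo:hi]
    used[run] <- TRUE       # shaved residues stay available to later seeds
    fit <- run_fit(run)
    anchors[[length(anchors) + 1L]] <- list(
      chain = chain[run][1],
      resno = resno[run],
      rows = pairs[run, "A"],
      rotation = fit$rotation,
      translation = fit$translation)
  }
  anchors <- anchors[order(vapply(anchors, function(a) min(a$rows), numeric(1)))]
  .assert(length(anchors) > 0, "no anchor runs found between the models")
  structure(anchors, class = "anchor_set")
}

#' Morph a model through a set of rigid anchors
#'
#' Residues inside an anchor move by that anchor's rigid transform.
#' Residues between two anchors of the same chain move by a smooth
#' positional blend of the flanking anchors' actions,
#' x' = (1 - s) T_L(x) + s T_R(x) with s the smoothstep
#' (3t^2 - 2t^3) of the fractional sequence position t across the gap,
#' so the deformation field is continuous (and has zero slope) at the
#' anchor borders. Residues before the first or after the last anchor
#' of a chain follow the nearest anchor rigidly; residues in chains
#' without anchors fall back to an exponential sequence-distance blend
#' over all anchors (decay `tau` residues). All atoms of a residue
#' share the residue-level blend.
#'
#' @param moving [atomic_model()] to deform.
#' @param anchors an `anchor_set` from [find_anchors()].
#' @param tau decay length of the cross-chain fallback blend (default
#'   10 residues).
#' @return morphed [atomic_model()] with identical residue/atom content.
#' @export
direct_morph <- function(moving, anchors, tau = 10) {
  .assert(length(anchors) >= 1, "need at least one anchor")
  rt <- residue_table(moving)
  n <- nrow(rt)
  idx <- .residue_index(moving)
  # anchor$rows index CA-bearing residues; map to residue-table indices
  ca_pos <- which(!is.na(rt$ca_row))
  anchor_rows <- lapply(anchors, function(a) ca_pos[a$rows])
  in_anchor <- rep(NA_integer_, n)
  for (a in seq_along(anchors)) in_anchor[anchor_rows[[a]]] <- a
  anchor_chain <- vapply(anchors, `[[`, character(1), "chain")
  xyz <- .xyz(moving$atoms)
  new_xyz <- xyz
  t_imgs <- lapply(anchors, function(a) .apply_rt(xyz, a$rotation, a$translation))
  blend2 <- function(rows, aL, aR, s) {
    (1 - s) * t_imgs[[aL]][rows, , drop = FALSE] +
      s * t_imgs[[aR]][rows, , drop = FALSE]
  }
  for (r in seq_len(n)) {
    rows <- which(idx == r)
    a0 <- in_anchor[r]
    if (!is.na(a0)) {
      new_xyz[rows, ] <- t_imgs[[a0]][rows, , drop = FALSE]
      next
    }
    same <- which(anchor_chain == rt$chain[r])
    if (length(same)) {
      lefts <- same[vapply(same, function(a) max(anchor_rows[[a]]) < r, logical(1))]
      rights <- same[vapply(same, function(a) min(anchor_rows[[a]]) > r, logical(1))]
      if (length(lefts) && length(rights)) {
        aL <- lefts[which.max(vapply(lefts, function(a) max(anchor_rows[[a]]), numeric(1)))]
        aR <- rights[which.min(vapply(rights, function(a) min(anchor_rows[[a]]), numeric(1)))]
        dL <- r - max(anchor_rows[[aL]])
        dR <- min(anchor_rows[[aR]]) - r
        t <- dL / (dL + dR)
        s <- 3 * t^2 - 2 * t^3
        new_xyz[rows, ] <- blend2(rows, aL, aR, s)
      } else {
        a_near <- same[which.min(vapply(same, function(a)
          min(abs(anchor_rows[[a]] - r)), numeric(1)))]
        new_xyz[rows, ] <- t_imgs[[a_near]][rows, , drop = FALSE]
      }
    } else {
      dseq <- vapply(seq_along(anchors), function(a)
        min(abs(anchor_rows[[a]] - r)), numeric(1))
      w <- exp(-dseq / tau)
      w <- w / sum(w)
      blended <- 0
      for (q in seq_along(anchors)) {
        blended <- blended + w[q] * t_imgs[[q]][rows, , drop = FALSE]
      }
      new_xyz[rows, ] <- blended
    }
  }
  out <- moving
  out$atoms[, c("x", "y", "z")] <- new_xyz
  out
}

#' Superpose-and-morph a prediction onto a target model
#'
#' Finds rigid anchors ([find_anchors()]) and deforms the moving model
#' through them ([direct_morph()]). The returned model carries a
#' `max_local_distortion` attribute: the largest difference between the
#' displacement vectors of neighboring residues, a warning signal
#' because large distortions produce implausible geometry.
#'
#' @inheritParams find_anchors
#' @param tau blend decay length in residues.
#' @return morphed [atomic_model()] with attribute
#'   `max_local_distortion` (Angstrom).
#' @export
superpose_and_morph <- function(moving, target, min_anchor = 5,
                                match_distance = 3.0, tau = 10) {
  anchors <- find_anchors(moving, target, min_anchor, match_distance)
  morphed <- direct_morph(moving, anchors, tau)
  ca0 <- extract_ca(moving); ca1 <- extract_ca(morphed)
  shift <- as.matrix(ca1[, c("x", "y", "z")]) - as.matrix(ca0[, c("x", "y", "z")])
  distortion <- 0
  if (nrow(shift) > 1) {
    same_chain <- ca0$chain[-1] == ca0$chain[-nrow(ca0)]
    dd <- sqrt(rowSums((shift[-1, , drop = FALSE] -
                        shift[-nrow(shift), , drop = FALSE])^2))
    distortion <- if (any(same_chain)) max(dd[same_chain]) else 0
  }
  attr(morphed, "max_local_distortion") <- distortion
  morphed
}
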