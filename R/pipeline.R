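#' Configuration of the iterative model-building cycle
#'
#' @param resolution high-resolution limit of the data in Angstrom.
#' @param cycle_rmsd_to_resolution_ratio convergence ratio: iteration
#'   stops when the r.m.s.d. between successive rebuilt models is less
#'   than this ratio times the resolution (default 0.25).
#' @param min_cycles at least this many cycles are carried out
#'   (default 3).
#' @param max_cycles hard cycle cap (default 10).
#' @param trim a [trim_params()].
#' @param confidence a [confidence_params()].
#' @param seed integer seed driving every stochastic engine.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(resolution = 2.5,
                            cycle_rmsd_to_resolution_ratio = 0.25,
                            min_cycles = 3, max_cycles = 10,
                            trim = trim_params(),
                            confidence = confidence_params(),
                            seed = 1L) {
  .assert(resolution > 0, "resolution must be positive")
  .assert(cycle_rmsd_to_resolution_ratio > 0, "ratio must be positive")
  .assert(min_cycles >= 1, "min_cycles must be >= 1")
  structure(list(resolution = resolution,
                 cycle_rmsd_to_resolution_ratio = cycle_rmsd_to_resolution_ratio,
                 min_cycles = as.integer(min_cycles),
                 max_cycles = as.integer(max_cycles),
                 trim = trim, confidence = confidence,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Convergence test for the iterative cycle
#'
#' TRUE when at least `min_cycles` cycles have run and the overall CA
#' r.m.s.d. between the current and previous rebuilt models is strictly
#' less than `cycle_rmsd_to_resolution_ratio` times the resolution.
#'
#' @param current current rebuilt [atomic_model()].
#' @param previous previous rebuilt [atomic_model()].
#' @param cycle 1-based index of the cycle just completed.
#' @param config a [pipeline_config()].
#' @return logical.
#' @export
converged <- function(current, previous, cycle, config) {
  if (cycle < config$min_cycles) return(FALSE)
  rmsd <- tryCatch(compare_models(current, previous)$rmsd,
                   error = function(e) Inf)
  rmsd < config$cycle_rmsd_to_resolution_ratio * config$resolution
}

#' Keep a candidate model only if its proxy free R decreases
#'
#' Rebuilding does not necessarily improve a model, so a candidate
#' replaces the incumbent only when its (proxy) free R is strictly
#' lower; ties keep the incumbent.
#'
#' @param candidate list(model, free_r).
#' @param incumbent list(model, free_r).
#' @return list(model, free_r, kept) where `kept` says whether the
#'   candidate was accepted.
#' @export
keep_if_better <- function(candidate, incumbent) {
  if (is.null(incumbent) || candidate$free_r < incumbent$free_r) {
    list(model = candidate$model, free_r = candidate$free_r, kept = TRUE)
  } else {
    list(model = incumbent$model, free_r = incumbent$free_r, kept = FALSE)
  }
}

#' Construct a docked prediction guided by a rebuilt model
#'
#' Each full-length prediction is rigidly superposed (Kabsch on shared
#' CA atoms) onto the corresponding chain of the rebuilt model and the
#' placed predictions are concatenated, without morphing: each chain of
#' the result is identical to a prediction up to a rigid motion. Clashes
#' between placed chains (any inter-chain CA pair closer than 3 A) are
#' reported via a warning, since docked predictions are not always
#' geometrically plausible.
#'
#' @param predictions named list of predicted [atomic_model()]s, one per
#'   rebuilt chain id.
#' @param rebuilt rebuilt [atomic_model()] guiding the placement.
#' @return docked [atomic_model()] (provenance "predicted").
#' @export
construct_docked <- function(predictions, rebuilt) {
  ca_reb <- extract_ca(rebuilt)
  chains <- unique(ca_reb$chain)
  missing <- setdiff(chains, names(predictions))
  .assert(length(missing) == 0,
          paste("no prediction supplied for chain(s):",
                paste(missing, collapse = ", ")))
  placed <- list()
  for (ch in chains) {
    pred <- predictions[[ch]]
    caP <- extract_ca(pred)
    sub <- ca_reb[ca_reb$chain == ch, , drop = FALSE]
    j <- match(sub$resno, caP$resno)
    ok <- !is.na(j)
    .assert(sum(ok) >= 3, paste("chain", ch, "shares too few residues"))
    fit <- kabsch(as.matrix(caP[j[ok], c("x", "y", "z")]),
                  as.matrix(sub[ok, c("x", "y", "z")]))
    out <- pred
    out$atoms$chain <- ch
    out$atoms[, c("x", "y", "z")] <-
      .apply_rt(.xyz(pred$atoms), fit$rotation, fit$translation)
    placed[[ch]] <- out
  }
  atoms <- do.call(rbind, lapply(placed, `[[`, "atoms"))
  docked <- atomic_model(atoms, provenance = "predicted")
  # clash scan between placed chains
  ca <- extract_ca(docked)
  if (length(chains) > 1) {
    xyz <- as.matrix(ca[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    inter <- outer(ca$chain, ca$chain, "!=")
    clash <- d < 3 & inter
    if (any(clash)) {
      prs <- which(clash, arr.ind = TRUE)
      prs <- prs[prs[, 1] < prs[, 2], , drop = FALSE]
      bad <- unique(t(apply(prs, 1, function(p) sort(c(ca$chain[p[1]], ca$chain[p[2]])))))
      warning(sprintf("docked prediction has clashing chain pairs: %s",
                      paste(apply(bad, 1, paste, collapse = "-"), collapse = ", ")))
    }
  }
  docked
}

# --- Mock engine suite -----------------------------------------------------

#' Deterministic mock engine suite for the orchestrator
#'
#' Stand-ins for the external prediction, molecular replacement,
#' refinement and rebuilding engines, built around a known truth so the
#' cycle logic can be exercised end to end. The predictor returns
#' alpha * template + (1 - alpha) * truth plus seeded noise with a pLDDT
#' track anti-correlated with the local error; MR superposes onto the
#' truth frame; the refiner scores a proxy free R from the global
#' map-model correlation (1 - cc rescaled into [0.2, 0.6]); the
#' rebuilder nudges each atom a bounded step toward the local density
#' centroid.
#'
#' @param truth the true [atomic_model()].
#' @param truth_map the map computed from it.
#' @param initial_prediction full-length starting prediction used when no
#'   template is available (cycle 1).
#' @param alpha template retention weight in the mock predictor
#'   (default 0.5).
#' @param noise_sd coordinate noise per prediction in Angstrom
#'   (default 0.05).
#' @param rebuild_step maximum atom displacement per rebuild in Angstrom
#'   (default 0.2).
#' @param resolution resolution used for proxy scoring.
#' @return list of engine closures: `predict(template, seed)`,
#'   `mr(model, seed)`, `refine(model, map, seed)`,
#'   `rebuild(model, map, seed)`.
#' @export
mock_engines <- function(truth, truth_map, initial_prediction,
                         alpha = 0.5, noise_sd = 0.05, rebuild_step = 0.2,
                         resolution = 2.5) {
  true_xyz <- .xyz(truth$atoms)
  true_key <- .res_key(truth$atoms)
  pred0 <- initial_prediction

  predict_fn <- function(template = NULL, seed = 0L) {
    set.seed(seed)
    out <- pred0
    xyz <- .xyz(out$atoms)
    key <- .res_key(out$atoms)
    tgt <- true_xyz[match(paste(key, out$atoms$atom),
                          paste(true_key, truth$atoms$atom)), , drop = FALSE]
    if (is.null(template)) {
      new_xyz <- xyz
    } else {
      tkey <- paste(.res_key(template$atoms), template$atoms$atom)
      j <- match(paste(key, out$atoms$atom), tkey)
      tmpl_xyz <- .xyz(template$atoms)[j, , drop = FALSE]
      has <- !is.na(j)
      new_xyz <- xyz
      new_xyz[has, ] <- alpha * tmpl_xyz[has, , drop = FALSE] +
        (1 - alpha) * tgt[has, , drop = FALSE]
      new_xyz[!has, ] <- alpha * xyz[!has, , drop = FALSE] +
        (1 - alpha) * tgt[!has, , drop = FALSE]
    }
    new_xyz <- new_xyz + matrix(stats::rnorm(length(new_xyz), sd = noise_sd),
                                ncol = 3)
    out$atoms[, c("x", "y", "z")] <- new_xyz
    rt <- residue_table(out)
    err <- sqrt(rowSums((new_xyz[rt$ca_row, , drop = FALSE] -
                         true_xyz[match(paste(.res_key(out$atoms)[rt$ca_row], "CA"),
                                        paste(true_key, truth$atoms$atom)), ,
                                  drop = FALSE])^2))
    plddt <- pmin(98, pmax(20, 90 - 15 * smooth_track(err, 5)))
    out$atoms$b <- plddt[.residue_index(out)]
    out$provenance <- "predicted"
    out <- structure(out, class = "atomic_model")
    pred0 <<- out
    out
  }

  mr_fn <- function(model, seed = 0L) {
    caM <- extract_ca(model); caT <- extract_ca(truth)
    pairs <- .pair_ca(caM, caT)
    fit <- kabsch(as.matrix(caM[pairs[, "A"], c("x", "y", "z")]),
                  as.matrix(caT[pairs[, "B"], c("x", "y", "z")]))
    out <- model
    out$atoms[, c("x", "y", "z")] <- .apply_rt(.xyz(model$atoms),
                                               fit$rotation, fit$translation)
    out
  }

  refine_fn <- function(model, map, seed = 0L) {
    cc <- global_cc(model, map, optimize = FALSE,
                    resolution = resolution)$cc
    free_r <- min(0.6, max(0.2, 0.2 + 0.4 * (1 - cc)))
    list(model = model, free_r = free_r)
  }

  rebuild_fn <- function(model, map, seed = 0L) {
    out <- model
    xyz <- .xyz(model$atoms)
    for (i in seq_len(nrow(xyz))) {
      ctr <- .density_centroid(map, xyz[i, ], radius = 1.5)
      if (is.null(ctr)) next
      step <- ctr - xyz[i, ]
      len <- sqrt(sum(step^2))
      if (len > rebuild_step) step <- step * rebuild_step / len
      xyz[i, ] <- xyz[i, ] + step
    }
    out$atoms[, c("x", "y", "z")] <- xyz
    out$provenance <- "rebuilt"
    list(model = out, map = map)
  }

  list(predict = predict_fn, mr = mr_fn, refine = refine_fn,
       rebuild = rebuild_fn)
}

# Density-weighted centroid of grid points within `radius` of a point.
.density_centroid <- function(map, pos, radius = 1.5) {
  idx <- .mask_indices(map, matrix(pos, 1, 3), radius)
  if (length(idx) < 4) return(NULL)
  a <- arrayInd(idx, dim(map$values))
  pts <- cbind(.axis_coords(map, 1)[a[, 1]],
               .axis_coords(map, 2)[a[, 2]],
               .axis_coords(map, 3)[a[, 3]])
  w <- map$values[idx]
  w <- w - min(w)
  if (sum(w) <= 0) return(NULL)
  colSums(pts * w) / sum(w)
}

#' Run the iterative predict/rebuild/trim cycles
#'
#' Cycle 1: predict (no template), process the prediction (confidence
#' trim + pLDDT-to-ADP), molecular-replacement placement, morph the
#' full-length prediction onto the placed model, refine, rebuild, trim
#' to the map. Later cycles use the previous kept model as the
#' prediction template and skip MR. After each cycle the rebuilt model
#' is kept only if its proxy free R decreases. Iteration ends when the
#' r.m.s.d. between successive kept models drops below
#' `cycle_rmsd_to_resolution_ratio * resolution` (after at least
#' `min_cycles` cycles) or at `max_cycles`.
#'
#' @param config a [pipeline_config()].
#' @param engines an engine suite (see [mock_engines()]).
#' @param map the working density map.
#' @return list of per-cycle records (class `cycle_record`): cycle,
#'   predicted, rebuilt, trimmed, free_r, rmsd_to_previous, kept,
#'   converged.
#' @export
run_cycles <- function(config, engines, map) {
  records <- list()
  incumbent <- NULL
  prev_trimmed <- NULL
  template <- NULL
  for (cycle in seq_len(config$max_cycles)) {
    seed <- config$seed + cycle
    predicted <- engines$predict(template, seed)
    proc <- process_predicted_model(predicted, config$confidence)$processed
    working <- if (cycle == 1) engines$mr(proc, seed) else proc
    target <- if (cycle == 1) working else prev_trimmed
    morphed <- tryCatch(
      superpose_and_morph(predicted, target),
      error = function(e) working)
    refined <- engines$refine(morphed, map, seed)
    rebuilt <- engines$rebuild(refined$model, map, seed)
    scored <- engines$refine(rebuilt$model, map, seed)
    sel <- keep_if_better(list(model = scored$model, free_r = scored$free_r),
                          incumbent)
    incumbent <- sel[c("model", "free_r")]
    trimmed <- trim_to_map(incumbent$model, map, config$trim)
    rmsd_prev <- if (is.null(prev_trimmed)) NA_real_ else
      tryCatch(compare_models(trimmed$model, prev_trimmed)$rmsd,
               error = function(e) Inf)
    conv <- if (is.null(prev_trimmed)) FALSE else
      converged(trimmed$model, prev_trimmed, cycle, config)
    records[[cycle]] <- structure(
      list(cycle = cycle, predicted = predicted, rebuilt = sel$model,
           trimmed = trimmed$model, free_r = sel$free_r,
           rmsd_to_previous = rmsd_prev, kept = sel$kept,
           converged = conv, trim_report = trimmed$report),
      class = "cycle_record")
    prev_trimmed <- trimmed$model
    template <- trimmed$model
    if (conv) break
  }
  records
}

#' @export
print.cycle_record <- function(x, ...) {
  cat(sprintf(
    "<cycle %d: free R %.3f, rmsd to previous %s, kept %s, converged %s>\n",
    x$cycle, x$free_r,
    ifelse(is.na(x$rmsd_to_previous), "NA",
           sprintf("%.3f A", x$rmsd_to_previous)),
    x$kept, x$converged))
  invisible(x)
}
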