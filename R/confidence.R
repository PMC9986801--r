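#' Parameters for predicted-model processing
#'
#' @param plddt_cutoff residues with pLDDT strictly below this score are
#'   trimmed (percent scale; default 70, the "moderate confidence"
#'   boundary).
#' @param plddt_scale "percent", "fraction" or "auto" (detect from the
#'   model; fraction-scale scores are normalized to percent).
#' @param min_domain_residues smallest domain emitted by
#'   [split_into_domains()]; smaller groups are merged into the nearest
#'   group (default 10).
#' @param contact_distance CA-CA contact threshold in Angstrom for the
#'   domain contact graph (default 8).
#' @return list of class `confidence_params`.
#' @export
confidence_params <- function(plddt_cutoff = 70,
                              plddt_scale = c("auto", "percent", "fraction"),
                              min_domain_residues = 10,
                              contact_distance = 8.0) {
  plddt_scale <- match.arg(plddt_scale)
  .assert(plddt_cutoff > 0 && plddt_cutoff <= 100, "plddt_cutoff must be in (0, 100]")
  .assert(min_domain_residues >= 1, "min_domain_residues must be >= 1")
  structure(list(plddt_cutoff = plddt_cutoff, plddt_scale = plddt_scale,
                 min_domain_residues = as.integer(min_domain_residues),
                 contact_distance = contact_distance),
            class = "confidence_params")
}

#' Detect the scale of pLDDT values stored in the B column
#'
#' Predictors emit pLDDT either as 0-100 or 0-1. The rule is: fraction if
#' the maximum stored value is <= 1, percent otherwise.
#'
#' @param model predicted [atomic_model()] carrying pLDDT in `b`.
#' @return "fraction" or "percent".
#' @export
detect_plddt_scale <- function(model) {
  if (max(model$atoms$b) <= 1.0) "fraction" else "percent"
}

# Per-residue pLDDT on the percent scale, taken from the CA atom.
.residue_plddt <- function(model, params) {
  rt <- residue_table(model)
  .assert(all(!is.na(rt$ca_row)), "every residue needs a CA atom to carry pLDDT")
  p <- model$atoms$b[rt$ca_row]
  scale <- params$plddt_scale
  if (scale == "auto") scale <- detect_plddt_scale(model)
  if (scale == "fraction") p <- p * 100
  p
}

#' Trim low-confidence residues from a predicted model
#'
#' Removes every residue whose pLDDT (the CA B-column value) is strictly
#' below the cutoff; residues exactly at the cutoff are kept.
#'
#' @param model predicted [atomic_model()].
#' @param params a [confidence_params()].
#' @return trimmed [atomic_model()]; chain and residue order preserved.
#' @export
trim_low_confidence <- function(model, params = confidence_params()) {
  p <- .residue_plddt(model, params)
  keep <- p >= params$plddt_cutoff
  .assert(any(keep), "all residues below the pLDDT cutoff: nothing left after trimming")
  select_residues(model, keep)
}

#' Convert pLDDT to an estimated atomic displacement parameter
#'
#' Uses the error-vs-lDDT fit d = 1.5 * exp(4 * (0.7 - lDDT)) Angstrom
#' (lDDT on the 0-1 scale) and B = (8 pi^2 / 3) d^2, so that the trim
#' boundary pLDDT = 70 maps to d = 1.5 A, B ~ 59.2 A^2. Strictly
#' decreasing in pLDDT.
#'
#' @param plddt numeric vector on the percent scale (0-100).
#' @return B values in Angstrom^2.
#' @export
plddt_to_adp <- function(plddt) {
  .assert(all(plddt >= 0 & plddt <= 100), "pLDDT must be within [0, 100]")
  d <- 1.5 * exp(4 * (0.7 - plddt / 100))
  (8 * pi^2 / 3) * d^2
}

#' Replace pLDDT values by estimated ADPs on a predicted model
#'
#' All atoms of a residue receive the ADP derived from the residue's
#' (CA) pLDDT. The provenance flag is kept as "predicted".
#'
#' @inheritParams trim_low_confidence
#' @return model with `b` holding estimated B factors (Angstrom^2).
#' @export
convert_plddt_to_adp <- function(model, params = confidence_params()) {
  p <- .residue_plddt(model, params)
  idx <- .residue_index(model)
  out <- model
  out$atoms$b <- plddt_to_adp(p)[idx]
  out
}

#' Split a model into spatially compact domains
#'
#' Builds a CA contact graph (contacts closer than `contact_distance`,
#' counting only pairs at sequence separation >= 3 so that an extended
#' linker does not glue domains together), takes connected components,
#' then merges any component smaller than `min_domain_residues` into the
#' spatially nearest larger component. The result is a partition of the
#' input residues; each domain is sequence-sorted internally.
#'
#' @param model an [atomic_model()] with at least one CA atom.
#' @param params a [confidence_params()].
#' @return list of [atomic_model()] domains.
#' @export
split_into_domains <- function(model, params = confidence_params()) {
  rt <- residue_table(model)
  n <- nrow(rt)
  .assert(n >= 1 && any(!is.na(rt$ca_row)), "model needs at least one residue with a CA atom")
  ca <- extract_ca(model)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  m <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  seqsep <- abs(outer(seq_len(m), seq_len(m), "-"))
  samechain <- outer(ca$chain, ca$chain, "==")
  adj <- d < params$contact_distance & (seqsep >= 3 | !samechain)
  diag(adj) <- FALSE
  comp <- .connected_components(adj)
  # merge under-sized components into the spatially nearest other component
  repeat {
    sizes <- table(comp)
    small <- names(sizes)[sizes < params$min_domain_residues]
    if (!length(small) || length(sizes) == 1L) break
    s <- small[1]
    members <- comp == s
    dmin <- apply(d[members, !members, drop = FALSE], 1, min)
    tgt_col <- which(!members)[apply(d[members, !members, drop = FALSE], 1,
                                     which.min)]
    # assign the whole small component to the component of its closest residue
    comp[members] <- comp[tgt_col[which.min(dmin)]]
  }
  comp <- match(comp, unique(comp[order(seq_len(m))]))
  # map CA-bearing residue components back onto all residues; CA-less
  # residues join the component of the nearest preceding CA residue
  res_comp <- rep(NA_integer_, n)
  res_comp[which(!is.na(rt$ca_row))] <- comp
  for (i in seq_len(n)) {
    if (is.na(res_comp[i])) {
      res_comp[i] <- if (i > 1) res_comp[i - 1] else res_comp[which(!is.na(res_comp))[1]]
    }
  }
  lapply(sort(unique(res_comp)), function(k) select_residues(model, res_comp == k))
}

# Connected components of a logical adjacency matrix (BFS).
.connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Process a predicted model: trim, convert pLDDT, optionally split
#'
#' Convenience wrapper composing [trim_low_confidence()],
#' [convert_plddt_to_adp()] and [split_into_domains()]; trimming happens
#' before splitting.
#'
#' @inheritParams trim_low_confidence
#' @param split if TRUE also return the domain decomposition.
#' @return list with `processed` (trimmed model with ADPs) and, when
#'   `split`, `domains` (list of models with ADPs).
#' @export
process_predicted_model <- function(model, params = confidence_params(),
                                    split = FALSE) {
  trimmed <- trim_low_confidence(model, params)
  processed <- convert_plddt_to_adp(trimmed, params)
  out <- list(processed = processed)
  if (split) out$domains <- split_into_domains(processed, params)
  out
}
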