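# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Residue key: one string per atom identifying its residue.
.res_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
}

#' Residue-level table of a model
#'
#' One row per residue in model order, with the atom-row indices of each
#' residue (`atom_rows`) and of its CA atom (`ca_row`, NA if absent).
#'
#' @param model an [atomic_model()].
#' @return data.frame with columns chain, resno, icode, resname,
#'   atom_rows (list), ca_row.
#' @export
residue_table <- function(model) {
  atoms <- model$atoms
  key <- .res_key(atoms)
  first <- !duplicated(key)
  tab <- data.frame(
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    icode = atoms$icode[first],
    resname = atoms$resname[first],
    stringsAsFactors = FALSE
  )
  idx <- match(key, key[first])
  tab$atom_rows <- split(seq_len(nrow(atoms)), idx)
  ca <- rep(NA_integer_, nrow(tab))
  is_ca <- which(atoms$atom == "CA")
  ca[idx[is_ca]] <- is_ca
  tab$ca_row <- ca
  tab
}

# Per-atom residue index (1-based, model residue order).
.residue_index <- function(model) {
  key <- .res_key(model$atoms)
  match(key, unique(key))
}

#' Subset a model to a residue keep-mask
#'
#' @param model an [atomic_model()].
#' @param keep logical vector aligned with [residue_table()] order.
#' @return the model restricted to the kept residues, atom order
#'   preserved.
#' @export
select_residues <- function(model, keep) {
  idx <- .residue_index(model)
  .assert(length(keep) == max(idx, 0L), "keep mask length != residue count")
  out <- model
  out$atoms <- model$atoms[keep[idx], , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Segment-start flags of a model
#'
#' TRUE at residue i when a new contiguous segment begins there: the
#' chain changes, the residue-number gap exceeds 1, or the CA-CA
#' distance to the previous residue exceeds `ca_gap`.
#'
#' @param model an [atomic_model()].
#' @param ca_gap chain-break CA-CA distance in Angstrom (default 4.2).
#' @return logical vector, one entry per residue.
#' @export
segment_starts <- function(model, ca_gap = 4.2) {
  rt <- residue_table(model)
  n <- nrow(rt)
  if (n == 0L) return(logical(0))
  starts <- rep(FALSE, n)
  starts[1] <- TRUE
  if (n == 1L) return(starts)
  for (i in 2:n) {
    if (rt$chain[i] != rt$chain[i - 1]) { starts[i] <- TRUE; next }
    if (rt$resno[i] - rt$resno[i - 1] > 1) { starts[i] <- TRUE; next }
    r1 <- rt$ca_row[i - 1]; r2 <- rt$ca_row[i]
    if (!is.na(r1) && !is.na(r2)) {
      d <- sqrt(sum((unlist(model$atoms[r2, c("x", "y", "z")]) -
                     unlist(model$atoms[r1, c("x", "y", "z")]))^2))
      if (d > ca_gap) starts[i] <- TRUE
    }
  }
  starts
}

# Segment id per residue from start flags.
.segment_ids <- function(starts) cumsum(starts)

# Electron counts for the elements seen in protein models.
.element_z <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15, SE = 34)

.atom_electrons <- function(element) {
  z <- .element_z[toupper(element)]
  z[is.na(z)] <- 6  # unknown elements treated as carbon
  unname(z)
}

# Infer element from a PDB atom name when the element column is absent.
.element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  el <- substr(nm, 1, 1)
  el[substr(nm, 1, 2) == "SE"] <- "SE"
  el[el %in% c("1", "2", "3")] <- "H"
  el
}

.xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])

# Rigid transform application: X %*% t(R) + t, rows are points.
.apply_rt <- function(xyz, rot, trans) {
  sweep(xyz %*% t(rot), 2, trans, "+")
}
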