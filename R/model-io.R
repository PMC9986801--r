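#' Atomic model container
#'
#' An `atomic_model` is a light hierarchy of chains, residues and atoms
#' stored as a single atom table in model order. Each row is one atom with
#' its chain id, residue number, insertion code, residue name, atom name,
#' element, Cartesian coordinates (Angstrom), isotropic B factor (or pLDDT
#' for predicted models) and occupancy. The `provenance` flag records
#' whether the model is a prediction (b column holds pLDDT), a rebuilt
#' model, or a deposited structure.
#'
#' @param atoms data.frame with columns chain, resno, icode, resname,
#'   atom, element, x, y, z, b, occ.
#' @param provenance one of "predicted", "rebuilt", "deposited".
#' @return object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, provenance = c("deposited", "predicted", "rebuilt")) {
  provenance <- match.arg(provenance)
  need <- c("chain", "resno", "icode", "resname", "atom", "element",
            "x", "y", "z", "b", "occ")
  missing <- setdiff(need, names(atoms))
  .assert(length(missing) == 0,
          paste("atoms table lacks columns:", paste(missing, collapse = ", ")))
  .assert(all(atoms$b >= 0), "negative b_iso")
  atoms <- atoms[, need, drop = FALSE]
  atoms$chain <- as.character(atoms$chain)
  atoms$icode <- as.character(atoms$icode)
  atoms$resname <- as.character(atoms$resname)
  atoms$atom <- as.character(atoms$atom)
  atoms$element <- as.character(atoms$element)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, provenance = provenance),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<atomic_model: %d chain(s), %d residue(s), %d atom(s), %s>\n",
              length(unique(rt$chain)), nrow(rt), nrow(x$atoms),
              x$provenance))
  invisible(x)
}

#' Number of residues in a model
#' @param model an `atomic_model`.
#' @return integer count.
#' @export
n_residues <- function(model) nrow(residue_table(model))

# Sort residues within each chain by (resno, icode); chains keep their
# order of first appearance, atoms keep their order within a residue.
.sort_model_atoms <- function(atoms) {
  chain_order <- match(atoms$chain, unique(atoms$chain))
  key <- .res_key(atoms)
  first_of <- match(key, unique(key))
  ord <- order(chain_order, atoms$resno, atoms$icode, first_of)
  atoms[ord, , drop = FALSE]
}

.detect_format <- function(path, format = "auto") {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head <- tryCatch(readLines(path, n = 50L, warn = FALSE), error = function(e) character())
  if (any(grepl("^data_|^loop_|^_atom_site", head))) return("mmcif")
  "pdb"
}

#' Read an atomic model from PDB or mmCIF
#'
#' Keeps protein ATOM records only: HETATM entries (waters, ligands,
#' ions) are dropped with a logged count, as are alternate conformations
#' other than blank or 'A'. Only the first model of a multi-model file is
#' read. Residues are sorted by (number, insertion code) within each
#' chain.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (detect from extension/content).
#' @param provenance provenance flag stored on the model.
#' @return an [atomic_model()]. The number of dropped HETATM records is
#'   attached as attribute `n_hetatm_dropped`.
#' @export
read_model <- function(path, format = c("auto", "pdb", "mmcif"),
                       provenance = "deposited") {
  format <- match.arg(format)
  .assert(file.exists(path), paste("file not found:", path))
  format <- .detect_format(path, format)
  parsed <- if (format == "pdb") .parse_pdb(path) else .parse_mmcif(path)
  .assert(nrow(parsed$atoms) > 0, paste("no atoms parsed from", path))
  atoms <- .sort_model_atoms(parsed$atoms)
  m <- atomic_model(atoms, provenance = provenance)
  attr(m, "n_hetatm_dropped") <- parsed$n_het
  m
}

.parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t]+$", "", lines)
  rec <- substr(lines, 1, 6)
  # first model only
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1, 6)
  n_het <- sum(trimws(rec) == "HETATM")
  keep <- trimws(rec) == "ATOM"
  lines <- lines[keep]
  if (!length(lines)) return(list(atoms = .empty_atoms(), n_het = n_het))
  altloc <- substr(lines, 17, 17)
  lines <- lines[altloc %in% c(" ", "", "A")]
  f <- function(a, b) substr(lines, a, b)
  element <- trimws(f(77, 78))
  name <- trimws(f(13, 16))
  element[element == ""] <- .element_from_name(name[element == ""])
  atoms <- data.frame(
    chain = trimws(f(22, 22)),
    resno = as.integer(f(23, 26)),
    icode = trimws(f(27, 27)),
    resname = trimws(f(18, 20)),
    atom = name,
    element = element,
    x = as.numeric(f(31, 38)),
    y = as.numeric(f(39, 46)),
    z = as.numeric(f(47, 54)),
    occ = as.numeric(f(55, 60)),
    b = as.numeric(f(61, 66)),
    stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  list(atoms = atoms, n_het = n_het)
}

.empty_atoms <- function() {
  data.frame(chain = character(), resno = integer(), icode = character(),
             resname = character(), atom = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(), b = numeric(),
             occ = numeric(), stringsAsFactors = FALSE)
}

# Minimal PDBx/mmCIF reader: the _atom_site loop only.
.parse_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_at <- grep("^\\s*loop_\\s*$", lines)
  for (start in loop_at) {
    i <- start + 1L
    fields <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      fields <- c(fields, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(grepl("^_atom_site\\.", fields))) next
    fields <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(#|loop_|_|data_)", ln)) break
      rows[[length(rows) + 1L]] <- scan(text = ln, what = character(),
                                        quiet = TRUE)
      i <- i + 1L
    }
    tab <- do.call(rbind, rows)
    colnames(tab) <- fields[seq_len(ncol(tab))]
    g <- function(nm, alt = NULL, default = NA_character_) {
      if (nm %in% colnames(tab)) return(tab[, nm])
      if (!is.null(alt) && alt %in% colnames(tab)) return(tab[, alt])
      rep(default, nrow(tab))
    }
    grp <- g("group_PDB", default = "ATOM")
    n_het <- sum(grp == "HETATM")
    sel <- grp == "ATOM"
    alt <- g("label_alt_id", default = ".")
    sel <- sel & alt %in% c(".", "?", "A", "")
    modnum <- g("pdbx_PDB_model_num", default = "1")
    if (any(sel)) sel <- sel & modnum == modnum[which(sel)[1]]
    tab <- tab[sel, , drop = FALSE]
    g2 <- function(nm, alt = NULL, default = NA_character_) {
      if (nm %in% colnames(tab)) return(tab[, nm])
      if (!is.null(alt) && alt %in% colnames(tab)) return(tab[, alt])
      rep(default, nrow(tab))
    }
    icode <- g2("pdbx_PDB_ins_code", default = "")
    icode[icode %in% c(".", "?")] <- ""
    atoms <- data.frame(
      chain = g2("auth_asym_id", "label_asym_id"),
      resno = as.integer(g2("auth_seq_id", "label_seq_id")),
      icode = icode,
      resname = g2("auth_comp_id", "label_comp_id"),
      atom = gsub('"', "", g2("label_atom_id", "auth_atom_id")),
      element = g2("type_symbol", default = ""),
      x = as.numeric(g2("Cartn_x")),
      y = as.numeric(g2("Cartn_y")),
      z = as.numeric(g2("Cartn_z")),
      b = as.numeric(g2("B_iso_or_equiv", default = "0")),
      occ = as.numeric(g2("occupancy", default = "1")),
      stringsAsFactors = FALSE
    )
    blank <- atoms$element == ""
    atoms$element[blank] <- .element_from_name(atoms$atom[blank])
    return(list(atoms = atoms, n_het = n_het))
  }
  list(atoms = .empty_atoms(), n_het = 0L)
}

#' Write an atomic model to PDB or mmCIF
#'
#' PDB output uses fixed v3.3 columns (coordinates %8.3f, B %6.2f) and is
#' refused for models with more than 99999 atoms or multi-character chain
#' ids; use mmCIF for those.
#'
#' @param model an [atomic_model()].
#' @param path output path.
#' @param format "pdb", "mmcif" or "auto" (from extension).
#' @export
write_model <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  .assert(nrow(model$atoms) > 0, "refusing to write an empty model")
  if (format == "pdb") .write_pdb(model, path) else .write_mmcif(model, path)
  invisible(path)
}

.write_pdb <- function(model, path) {
  a <- model$atoms
  .assert(nrow(a) <= 99999,
          "more than 99999 atoms: PDB format cannot hold this model, use mmCIF")
  .assert(all(nchar(a$chain) <= 1),
          "chain ids longer than 1 character: PDB format cannot hold them, use mmCIF")
  name <- ifelse(nchar(a$atom) < 4 & nchar(a$element) == 1,
                 paste0(" ", a$atom), a$atom)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name, a$resname, a$chain, a$resno,
    ifelse(a$icode == "", " ", a$icode), a$x, a$y, a$z, a$occ, a$b,
    toupper(a$element))
  writeLines(c(lines, "END"), path)
}

.write_mmcif <- function(model, path) {
  a <- model$atoms
  lines <- c(
    "data_model",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s %d %s %.3f %.3f %.3f %.2f %.2f 1",
            seq_len(nrow(a)), toupper(a$element), a$atom, a$resname,
            a$chain, a$resno, ifelse(a$icode == "", "?", a$icode),
            a$x, a$y, a$z, a$occ, a$b),
    "#")
  writeLines(lines, path)
}

#' Extract ordered C-alpha positions
#'
#' One entry per residue possessing a CA atom, in model order. Residues
#' lacking a CA are skipped; the skip count is attached as attribute
#' `n_skipped`.
#'
#' @param model an [atomic_model()].
#' @return data.frame with columns chain, resno, icode, x, y, z.
#' @export
extract_ca <- function(model) {
  rt <- residue_table(model)
  has <- !is.na(rt$ca_row)
  rows <- rt$ca_row[has]
  out <- data.frame(chain = rt$chain[has], resno = rt$resno[has],
                    icode = rt$icode[has],
                    x = model$atoms$x[rows], y = model$atoms$y[rows],
                    z = model$atoms$z[rows], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!has)
  out
}
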