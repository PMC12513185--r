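# Three-letter -> one-letter residue mapping is delegated to bio3d::aa321
# (which already maps MSE -> M); anything it does not know becomes X.
residue_one_letter <- function(resname) {
  out <- suppressWarnings(bio3d::aa321(resname))
  out[is.na(out) | !out %in% c(AA_LETTERS, "X")] <- "X"
  out
}

atom_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | !nzchar(el)
  if (any(miss)) {
    # fall back to the first alphabetic character of the atom name
    guess <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                 sub("^[0-9]+", "", elety[miss])), 1, 1))
    el[miss] <- guess
  }
  el
}

#' Parsed protein structure model
#'
#' `structure_model` objects hold one protein chain (ordered residues with
#' their atoms) plus any non-water HETATM groups of that chain as ligands.
#' They are produced by [read_structure()] and by the synthetic-structure
#' generators.
#'
#' @param id model identifier
#' @param chain_id one-letter chain identifier
#' @param atoms data frame of protein atoms with columns `name`, `element`,
#'   `resno`, `icode`, `resname`, `aa`, `x`, `y`, `z`, `occupancy`
#' @param ligands list of ligand groups, each a list with `het_code`,
#'   `resno` and an `atoms` data frame (`name`, `element`, `x`, `y`, `z`)
#' @param warnings character vector of non-fatal parse warnings
#' @return an object of class `structure_model`
#' @export
structure_model <- function(id, chain_id, atoms, ligands = list(),
                            warnings = character()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  need <- c("name", "element", "resno", "icode", "resname", "aa",
            "x", "y", "z", "occupancy")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates in model '", id, "'")
  key <- paste(atoms$resno, atoms$icode)
  ures <- !duplicated(key)
  residues <- data.frame(resno = atoms$resno[ures], icode = atoms$icode[ures],
                         aa = atoms$aa[ures], stringsAsFactors = FALSE)
  if (is.unsorted(residues$resno))
    stop("residues must be ordered by author numbering in model '", id, "'")
  has_ca <- vapply(seq_len(nrow(residues)), function(i) {
    any(atoms$name == "CA" &
          atoms$resno == residues$resno[i] & atoms$icode == residues$icode[i])
  }, logical(1))
  residues$has_ca <- has_ca
  if (any(!has_ca)) {
    warnings <- c(warnings, paste0("residue(s) without CA atom: ",
                                   paste(residues$resno[!has_ca], collapse = ", ")))
  }
  structure(list(id = id, chain_id = chain_id, atoms = atoms,
                 residues = residues, ligands = ligands, warnings = warnings),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s chain %s: %d residues, %d atoms, %d ligand group(s)\n",
              x$id, x$chain_id, nrow(x$residues), nrow(x$atoms),
              length(x$ligands)))
  if (length(x$ligands))
    cat("  ligands:", paste(vapply(x$ligands, `[[`, "", "het_code"),
                            collapse = ", "), "\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Read a protein chain (and its ligands) from a PDB file
#'
#' ATOM records of one chain become the protein; non-water HETATM groups of
#' the same chain become ligand groups. Alternate locations are resolved to
#' the highest-occupancy atom (ties: lexicographically first altloc).
#' Non-standard residues are mapped to `X` (selenomethionine to `M`).
#' Residues lacking a CA atom are recorded in `$warnings`, not fatal.
#'
#' @param path path to a PDB-format file
#' @param chain_id chain to extract; default: the first chain that contains
#'   ATOM records
#' @param id model identifier; default: file name without extension
#' @return a [structure_model()]
#' @export
read_structure <- function(path, chain_id = NULL, id = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stop("not a readable PDB file: ", path,
                                           " (", conditionMessage(e), ")"))
  at <- pdb$atom
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(prot)) stop("no ATOM records in ", path)
  if (is.null(chain_id)) chain_id <- prot$chain[1]
  if (is.na(chain_id)) chain_id <- "A"
  sel_chain <- function(d) d[is.na(d$chain) | d$chain == chain_id, , drop = FALSE]
  prot <- sel_chain(prot)
  if (!nrow(prot)) stop("no ATOM records for chain '", chain_id, "' in ", path)
  prot <- resolve_altloc(prot)
  icode <- ifelse(is.na(prot$insert), "", prot$insert)
  atoms <- data.frame(name = prot$elety,
                      element = atom_element(prot$elesy, prot$elety),
                      resno = prot$resno, icode = icode,
                      resname = prot$resid,
                      aa = residue_one_letter(prot$resid),
                      x = prot$x, y = prot$y, z = prot$z,
                      occupancy = ifelse(is.na(prot$o), 1, prot$o),
                      stringsAsFactors = FALSE)
  het <- at[at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
            drop = FALSE]
  het <- sel_chain(het)
  ligands <- list()
  if (nrow(het)) {
    het <- resolve_altloc(het)
    grp <- paste(het$resid, het$resno, ifelse(is.na(het$insert), "", het$insert))
    for (g in unique(grp)) {
      h <- het[grp == g, , drop = FALSE]
      ligands[[length(ligands) + 1L]] <-
        list(het_code = h$resid[1], resno = h$resno[1],
             atoms = data.frame(name = h$elety,
                                element = atom_element(h$elesy, h$elety),
                                x = h$x, y = h$y, z = h$z,
                                stringsAsFactors = FALSE))
    }
  }
  structure_model(id, chain_id, atoms, ligands)
}

# Keep, per (residue, atom name), the highest-occupancy alternate location;
# ties go to the lexicographically first altloc code.
resolve_altloc <- function(at) {
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert), at$elety)
  ord <- order(match(key, unique(key)), -occ, alt)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(key[ord]), , drop = FALSE]
}

#' Write a structure model to a PDB file
#'
#' Protein atoms are written as ATOM records, ligand groups as HETATM.
#'
#' @param model a [structure_model()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  type <- rep("ATOM", nrow(a))
  resid <- a$resname
  resno <- a$resno
  insert <- ifelse(nzchar(a$icode), a$icode, NA_character_)
  elety <- a$name
  elesy <- a$element
  o <- a$occupancy
  xyz <- rbind(a$x, a$y, a$z)
  for (lig in model$ligands) {
    la <- lig$atoms
    type <- c(type, rep("HETATM", nrow(la)))
    resid <- c(resid, rep(lig$het_code, nrow(la)))
    resno <- c(resno, rep(lig$resno, nrow(la)))
    insert <- c(insert, rep(NA_character_, nrow(la)))
    elety <- c(elety, la$name)
    elesy <- c(elesy, la$element)
    o <- c(o, rep(1, nrow(la)))
    xyz <- cbind(xyz, rbind(la$x, la$y, la$z))
  }
  n <- length(type)
  bio3d::write.pdb(pdb = NULL, file = path, xyz = as.numeric(xyz),
                   type = type, resno = resno, resid = resid,
                   eleno = seq_len(n), elety = elety,
                   chain = rep(model$chain_id, n), insert = insert,
                   o = o, b = rep(0, n), elesy = elesy)
  invisible(path)
}

#' Extract the CA trace of a structure model
#'
#' Residues lacking a CA atom are dropped (they cannot take part in a
#' superposition).
#'
#' @param model a [structure_model()]
#' @return a list with `xyz` (n x 3 matrix, Angstrom), `resno`, `icode` and
#'   `aa` (one vector entry per residue, in chain order)
#' @export
ca_trace <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  ca <- a[a$name == "CA", , drop = FALSE]
  key <- paste(ca$resno, ca$icode)
  ca <- ca[!duplicated(key), , drop = FALSE]
  list(xyz = cbind(x = ca$x, y = ca$y, z = ca$z),
       resno = ca$resno, icode = ca$icode, aa = ca$aa)
}

#' One-letter residue string of a structure model
#'
#' @param model a [structure_model()]
#' @param ca_only if `TRUE` (default) only residues with a CA atom
#'   contribute, matching the residues used for structural alignment
#' @return a single string
#' @export
residue_string <- function(model, ca_only = TRUE) {
  if (ca_only) paste(ca_trace(model)$aa, collapse = "")
  else paste(model$residues$aa, collapse = "")
}

#' Restrict a structure model to an author-numbered residue window
#'
#' @param model a [structure_model()]
#' @param from,to inclusive author residue numbers
#' @return a [structure_model()] containing only the residues in the window
#'   (ligands are kept unchanged)
#' @export
subset_residues <- function(model, from, to) {
  stopifnot(inherits(model, "structure_model"), from <= to)
  keep <- model$atoms$resno >= from & model$atoms$resno <= to
  if (!any(keep)) stop("no residues in window [", from, ", ", to, "]")
  structure_model(paste0(model$id, "[", from, "-", to, "]"),
                  model$chain_id, model$atoms[keep, , drop = FALSE],
                  model$ligands)
}
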