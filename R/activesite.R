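# residue chemical classes used only for the annotation column of site
# comparisons (never for the priority cut)
AA_CLASS <- c(A = "aliphatic", G = "aliphatic", V = "aliphatic",
              L = "aliphatic", I = "aliphatic", P = "aliphatic",
              M = "aliphatic", F = "aromatic", W = "aromatic", Y = "aromatic",
              S = "polar", T = "polar", C = "polar", N = "polar", Q = "polar",
              D = "acidic", E = "acidic", K = "basic", R = "basic",
              H = "basic", X = "unknown")

ligand_atoms <- function(ref, ligand_code, instance = NULL) {
  codes <- vapply(ref$ligands, `[[`, "", "het_code")
  hit <- which(codes == ligand_code)
  if (!length(hit))
    stop("ligand '", ligand_code, "' not found; available het codes: ",
         if (length(codes)) paste(unique(codes), collapse = ", ") else "(none)")
  if (!is.null(instance)) {
    hit <- hit[vapply(ref$ligands[hit], `[[`, 0, "resno") == instance]
    if (!length(hit))
      stop("no instance of ligand '", ligand_code, "' with residue number ",
           instance)
  }
  do.call(rbind, lapply(ref$ligands[hit], `[[`, "atoms"))
}

min_dist_to <- function(xyz_a, xyz_b) {
  # per-row-of-a minimum Euclidean distance to any row of b
  d2 <- outer(rowSums(xyz_a^2), rep(1, nrow(xyz_b))) +
    outer(rep(1, nrow(xyz_a)), rowSums(xyz_b^2)) - 2 * xyz_a %*% t(xyz_b)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Extract substrate-contact residues from a ligand-bound reference
#'
#' A residue is in contact when any of its non-hydrogen atoms lies within
#' `cutoff` (inclusive) of any non-hydrogen ligand atom.
#'
#' @param ref a [structure_model()] containing the ligand
#' @param ligand_code HETATM residue code of the ligand (e.g. `"PHE"` for a
#'   co-crystallized phenylalanine substrate)
#' @param cutoff contact distance in Angstrom (default 5)
#' @param instance optional ligand residue number selecting one instance
#'   when the code occurs more than once
#' @return data frame of contact residues sorted by position: `position`
#'   (author residue number), `aa`, `min_ligand_distance`,
#'   `polar_backbone_contact` (initialized `FALSE`; see
#'   [find_polar_backbone_contacts()])
#' @export
extract_contact_residues <- function(ref, ligand_code, cutoff = 5.0,
                                     instance = NULL) {
  stopifnot(inherits(ref, "structure_model"), cutoff > 0)
  lig <- ligand_atoms(ref, ligand_code, instance)
  lig <- lig[lig$element != "H", , drop = FALSE]
  at <- ref$atoms[ref$atoms$element != "H", , drop = FALSE]
  if (!nrow(lig) || !nrow(at)) stop("no heavy atoms to measure")
  dmin <- min_dist_to(cbind(at$x, at$y, at$z), cbind(lig$x, lig$y, lig$z))
  key <- paste(at$resno, at$icode)
  res_min <- tapply(dmin, factor(key, levels = unique(key)), min)
  sel <- which(as.numeric(res_min) <= cutoff)
  first <- !duplicated(key)
  pos <- at$resno[first][sel]
  aa <- at$aa[first][sel]
  ord <- order(pos)
  data.frame(position = pos[ord], aa = aa[ord],
             min_ligand_distance = as.numeric(res_min)[sel][ord],
             polar_backbone_contact = rep(FALSE, length(sel)),
             stringsAsFactors = FALSE)
}

#' Flag polar backbone contacts with the ligand
#'
#' Returns the author residue numbers whose backbone N or O atom lies
#' within `polar_cutoff` (inclusive) of a ligand nitrogen or oxygen. This
#' is an annotation (a standard donor/acceptor distance heuristic), never a
#' filter.
#'
#' @param ref a [structure_model()]
#' @param ligand_code HETATM residue code of the ligand
#' @param polar_cutoff distance in Angstrom (default 3.5)
#' @param instance optional ligand residue number
#' @return integer vector of residue positions, sorted
#' @export
find_polar_backbone_contacts <- function(ref, ligand_code, polar_cutoff = 3.5,
                                         instance = NULL) {
  stopifnot(inherits(ref, "structure_model"), polar_cutoff > 0)
  lig <- ligand_atoms(ref, ligand_code, instance)
  lig <- lig[lig$element %in% c("N", "O"), , drop = FALSE]
  bb <- ref$atoms[ref$atoms$name %in% c("N", "O"), , drop = FALSE]
  if (!nrow(lig) || !nrow(bb)) return(integer())
  dmin <- min_dist_to(cbind(bb$x, bb$y, bb$z), cbind(lig$x, lig$y, lig$z))
  sort(unique(bb$resno[dmin <= polar_cutoff]))
}

#' Seed-anchored active-site profile
#'
#' @param anchor_structure_id id of the ligand-bound reference the contacts
#'   came from
#' @param ligand_code the ligand's HETATM code
#' @param residues data frame with columns `position` (strictly
#'   increasing), `aa`, `min_ligand_distance`, `polar_backbone_contact`
#' @return an object of class `active_site_profile`
#' @export
active_site_profile <- function(anchor_structure_id, ligand_code, residues) {
  stopifnot(is.data.frame(residues),
            all(c("position", "aa", "min_ligand_distance",
                  "polar_backbone_contact") %in% names(residues)))
  if (nrow(residues) && any(diff(residues$position) <= 0))
    stop("profile positions must be strictly increasing")
  structure(list(anchor_structure_id = anchor_structure_id,
                 ligand_code = ligand_code, residues = residues),
            class = "active_site_profile")
}

#' @export
print.active_site_profile <- function(x, ...) {
  cat(sprintf("<active_site_profile> %d residue(s) anchored at %s (ligand %s)\n",
              nrow(x$residues), x$anchor_structure_id, x$ligand_code))
  if (nrow(x$residues))
    cat(" ", paste0(x$residues$aa, x$residues$position, collapse = " "), "\n")
  invisible(x)
}

#' Map reference contact residues onto the seed model
#'
#' Structurally aligns the seed model to the reference, then maps each
#' reference site residue to the seed residue whose CA is nearest after
#' superposition. Mappings farther than `max_dist` are reported unmapped
#' (attribute `"unmapped"`). This is a deterministic surrogate for the
#' visual inspection step typically done in a molecular-graphics program.
#'
#' @param ref a ligand-bound [structure_model()] (mapping source)
#' @param seed_model the seed's [structure_model()]
#' @param sites data frame from [extract_contact_residues()] (optionally
#'   with polar flags filled in)
#' @param max_dist rejection radius in Angstrom (default 5)
#' @param cfg optional [pipeline_config()] passed to the structural aligner
#' @return data frame of seed-numbered site residues (`position`, `aa`,
#'   `min_ligand_distance`, `polar_backbone_contact`, `ref_position`,
#'   `mapping_distance`), with unmapped reference positions in
#'   `attr(, "unmapped")`
#' @export
map_sites_to_seed <- function(ref, seed_model, sites, max_dist = 5.0,
                              cfg = NULL) {
  stopifnot(inherits(ref, "structure_model"),
            inherits(seed_model, "structure_model"), nrow(sites) > 0)
  aln <- align_structures(ref, seed_model, cfg = cfg)
  tr_ref <- ca_trace(ref); tr_seed <- ca_trace(seed_model)
  seed_in_ref_frame <- transform_coords(aln$superposition, tr_seed$xyz)
  rows <- list(); unmapped <- integer()
  for (k in seq_len(nrow(sites))) {
    i <- which(tr_ref$resno == sites$position[k])[1]
    if (is.na(i)) { unmapped <- c(unmapped, sites$position[k]); next }
    d <- sqrt(colSums((t(seed_in_ref_frame) - tr_ref$xyz[i, ])^2))
    j <- which.min(d)
    if (d[j] > max_dist) { unmapped <- c(unmapped, sites$position[k]); next }
    rows[[length(rows) + 1L]] <- data.frame(
      position = tr_seed$resno[j], aa = tr_seed$aa[j],
      min_ligand_distance = sites$min_ligand_distance[k],
      polar_backbone_contact = sites$polar_backbone_contact[k],
      ref_position = sites$position[k], mapping_distance = d[j],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("superposition failed to cover active site: no reference site ",
         "residue mapped within ", max_dist, " A")
  out <- do.call(rbind, rows)
  attr(out, "unmapped") <- unmapped
  out
}

#' Build per-domain active-site profiles for a multi-domain seed
#'
#' Multi-module enzymes (e.g. a two-module NRPS) carry one substrate pocket
#' per adenylation domain, so the reference must be superimposed onto each
#' domain independently. The caller supplies one author-numbered residue
#' window per domain; [map_sites_to_seed()] runs once per window.
#'
#' @param seed_model the seed's [structure_model()]
#' @param ref the ligand-bound reference [structure_model()]
#' @param ligand_code the ligand's HETATM code
#' @param windows list of `c(from, to)` author-number ranges, one per
#'   domain; a single window covering the whole chain reduces to the
#'   single-domain path. Windows must not overlap.
#' @param cfg a [pipeline_config()] supplying the contact and polar cutoffs
#' @return list of [active_site_profile()] objects, one per window
#' @export
multi_domain_profiles <- function(seed_model, ref, ligand_code,
                                  windows, cfg = pipeline_config()) {
  stopifnot(length(windows) >= 1)
  w <- do.call(rbind, lapply(windows, function(x) x[1:2]))
  w <- w[order(w[, 1]), , drop = FALSE]
  if (any(w[, 1] > w[, 2])) stop("window start must not exceed window end")
  if (nrow(w) > 1 && any(w[-1, 1] <= w[-nrow(w), 2]))
    stop("domain windows must not overlap")
  sites <- extract_contact_residues(ref, ligand_code, cfg$contact_cutoff)
  polar <- find_polar_backbone_contacts(ref, ligand_code, cfg$polar_cutoff)
  sites$polar_backbone_contact <- sites$position %in% polar
  lapply(windows, function(win) {
    dom <- subset_residues(seed_model, win[1], win[2])
    mapped <- map_sites_to_seed(ref, dom, sites, max_dist = cfg$contact_cutoff,
                                cfg = cfg)
    active_site_profile(ref$id, ligand_code, mapped)
  })
}

#' Transfer active-site positions from the seed onto a candidate
#'
#' Runs the affine-gap local alignment of the full seed and candidate
#' sequences, then reads off, for every profile position, the aligned
#' candidate residue. Positions falling in a gap or outside the local
#' alignment count as deletions. The comparison is exact string equality of
#' the amino-acid letters; a `conservative` annotation (same chemical
#' class) is reported for substitutions but never used for ranking.
#'
#' @param seed,cand [seq_record()] objects (full-length sequences)
#' @param profile an [active_site_profile()] whose positions index the seed
#'   sequence; the profile letters must agree with the seed sequence
#' @param scoring an [align_scoring()] object
#' @return an object of class `site_comparison`: `cand_id`, `mapped` (data
#'   frame with `seed_position`, `seed_aa`, `cand_position`, `cand_aa`,
#'   `outcome`, `conservative`), `status` (`"identical"`, `"substituted"`
#'   or `"deleted_positions"`), `n_identical`, `n_substituted`, `n_deleted`
#' @export
transfer_sites_to_candidate <- function(seed, cand, profile,
                                        scoring = align_scoring()) {
  stopifnot(inherits(seed, "seq_record"), inherits(cand, "seq_record"),
            inherits(profile, "active_site_profile"))
  prof <- profile$residues
  seed_chars <- strsplit(seed$residues, "")[[1]]
  bad <- which(prof$position < 1 | prof$position > seed$length |
                 seed_chars[prof$position] != prof$aa)
  if (length(bad))
    stop("profile/seed mismatch at position ", prof$position[bad[1]],
         ": profile has '", prof$aa[bad[1]], "', seed has '",
         if (prof$position[bad[1]] <= seed$length)
           seed_chars[prof$position[bad[1]]] else "(out of range)", "'")
  aln <- local_align(seed, cand, scoring)
  cand_chars <- strsplit(cand$residues, "")[[1]]
  lookup <- integer(seed$length)
  if (nrow(aln$aligned_pairs))
    lookup[aln$aligned_pairs[, 1]] <- aln$aligned_pairs[, 2]
  mapped <- do.call(rbind, lapply(seq_len(nrow(prof)), function(k) {
    p <- prof$position[k]
    j <- lookup[p]
    if (j == 0L) {
      data.frame(seed_position = p, seed_aa = prof$aa[k],
                 cand_position = NA_integer_, cand_aa = NA_character_,
                 outcome = "deleted", conservative = NA,
                 stringsAsFactors = FALSE)
    } else {
      ident <- cand_chars[j] == prof$aa[k]
      data.frame(seed_position = p, seed_aa = prof$aa[k],
                 cand_position = j, cand_aa = cand_chars[j],
                 outcome = if (ident) "identical" else "substituted",
                 conservative = if (ident) NA else
                   unname(AA_CLASS[cand_chars[j]] == AA_CLASS[prof$aa[k]]),
                 stringsAsFactors = FALSE)
    }
  }))
  n_identical <- sum(mapped$outcome == "identical")
  n_substituted <- sum(mapped$outcome == "substituted")
  n_deleted <- sum(mapped$outcome == "deleted")
  status <- if (n_deleted > 0) "deleted_positions"
  else if (n_substituted > 0) "substituted"
  else "identical"
  structure(list(cand_id = cand$id, mapped = mapped, status = status,
                 n_identical = n_identical, n_substituted = n_substituted,
                 n_deleted = n_deleted),
            class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("<site_comparison> %s: %s (%d identical, %d substituted, %d deleted)\n",
              x$cand_id, x$status, x$n_identical, x$n_substituted,
              x$n_deleted))
  invisible(x)
}
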