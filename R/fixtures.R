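# Synthetic sequences and structures with planted ground truth. These
# generators exist so that every pipeline stage can be exercised and
# oracle-checked without downloading anything.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

backbone_offsets <- function(u, tvec, zvec) {
  # plausible (not stereochemically exact) backbone positions around CA,
  # expressed in a local radial/tangent/axis frame; bond-scale distances
  list(N = -0.4 * u - 1.0 * tvec - 0.9 * zvec,
       C = -0.1 * u + 1.1 * tvec + 0.9 * zvec,
       O = 0.9 * u + 1.7 * tvec + 1.3 * zvec)
}

build_backbone_model <- function(id, sequence, ca, u, tvec, zvec) {
  n <- nrow(ca)
  aa <- strsplit(sequence, "")[[1]]
  resname <- vapply(aa, function(x) {
    r <- bio3d::aa123(x); if (is.na(r)) "UNK" else r
  }, "")
  rows <- lapply(seq_len(n), function(i) {
    off <- backbone_offsets(u[i, ], tvec[i, ], zvec[i, ])
    pos <- rbind(N = ca[i, ] + off$N, CA = ca[i, ], C = ca[i, ] + off$C,
                 O = ca[i, ] + off$O)
    data.frame(name = rownames(pos),
               element = c("N", "C", "C", "O"),
               resno = i, icode = "", resname = resname[i], aa = aa[i],
               x = round(pos[, 1], 3), y = round(pos[, 2], 3),
               z = round(pos[, 3], 3), occupancy = 1,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  structure_model(id, "A", do.call(rbind, rows))
}

#' Ideal alpha-helix CA trace with backbone atoms
#'
#' Generates an idealized alpha helix (1.5 Angstrom rise and 100 degrees of
#' twist per residue on a 2.3 Angstrom radius), giving the canonical
#' ~3.8 Angstrom consecutive CA-CA spacing, with N, CA, C and O backbone
#' atoms at fixed idealized offsets. Deterministic: two calls with the same
#' arguments give identical coordinates.
#'
#' @param n number of residues (>= 4)
#' @param sequence optional amino-acid string of length `n`; default
#'   poly-alanine
#' @param id model identifier
#' @return a [structure_model()]
#' @export
#' @examples
#' h <- make_helix(10)
#' d <- diff(ca_trace(h)$xyz)
#' round(sqrt(rowSums(d^2)), 1)  # all ~3.8
make_helix <- function(n, sequence = NULL, id = "helix") {
  if (n < 4) stop("a helix fixture needs at least 4 residues")
  if (is.null(sequence)) sequence <- strrep("A", n)
  if (nchar(sequence) != n) stop("sequence length must equal n")
  theta <- (seq_len(n) - 1) * 100 * pi / 180
  radius <- 2.3; rise <- 1.5
  ca <- cbind(radius * cos(theta), radius * sin(theta),
              rise * (seq_len(n) - 1))
  u <- cbind(cos(theta), sin(theta), 0)
  tvec <- cbind(-sin(theta), cos(theta), 0)
  zvec <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  build_backbone_model(id, sequence, ca, u, tvec, zvec)
}

#' Extended-chain CA trace with backbone atoms
#'
#' A straight chain with 3.8 Angstrom CA spacing: same local distance scale
#' as the helix fixture but a completely different global fold, so the two
#' make a structurally dissimilar pair.
#'
#' @inheritParams make_helix
#' @return a [structure_model()]
#' @export
make_extended <- function(n, sequence = NULL, id = "extended") {
  if (n < 4) stop("an extended-chain fixture needs at least 4 residues")
  if (is.null(sequence)) sequence <- strrep("A", n)
  if (nchar(sequence) != n) stop("sequence length must equal n")
  ca <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  u <- matrix(rep(c(0, 1, 0), each = n), ncol = 3)
  tvec <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
  zvec <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  build_backbone_model(id, sequence, ca, u, tvec, zvec)
}

#' Add Gaussian coordinate noise to a structure
#'
#' i.i.d. normal noise with standard deviation `sigma` is added to every
#' atom coordinate (protein and ligand). `sigma = 0` returns the input
#' unchanged; the same `rng_seed` always yields the same output.
#'
#' @param model a [structure_model()]
#' @param sigma noise standard deviation per coordinate (Angstrom, >= 0)
#' @param rng_seed integer seed
#' @param id optional new model id (default: input id)
#' @return a perturbed [structure_model()]
#' @export
perturb_structure <- function(model, sigma, rng_seed, id = model$id) {
  stopifnot(inherits(model, "structure_model"), sigma >= 0)
  if (sigma == 0) {
    model$id <- id
    return(model)
  }
  with_seed(rng_seed, {
    a <- model$atoms
    a$x <- round(a$x + rnorm(nrow(a), 0, sigma), 3)
    a$y <- round(a$y + rnorm(nrow(a), 0, sigma), 3)
    a$z <- round(a$z + rnorm(nrow(a), 0, sigma), 3)
    ligands <- lapply(model$ligands, function(lig) {
      la <- lig$atoms
      la$x <- round(la$x + rnorm(nrow(la), 0, sigma), 3)
      la$y <- round(la$y + rnorm(nrow(la), 0, sigma), 3)
      la$z <- round(la$z + rnorm(nrow(la), 0, sigma), 3)
      lig$atoms <- la
      lig
    })
    structure_model(id, model$chain_id, a, ligands)
  })
}

#' Generate a family of near-identical sequence variants
#'
#' Each member carries exactly `round((1 - target_identity) * length)`
#' substitutions at uniformly chosen positions, drawn from the 19
#' alternative amino acids, so the realized identity to the parent is known
#' by construction.
#'
#' @param seq parent [seq_record()]
#' @param n_members family size
#' @param target_identity identity fraction in (0, 1]
#' @param rng_seed integer seed
#' @return list of [seq_record()] (ids `<parent>_m1`, `<parent>_m2`, ...)
#'   with the realized identity in `attr(, "realized_identity")`
#' @export
mutate_family <- function(seq, n_members, target_identity, rng_seed) {
  stopifnot(inherits(seq, "seq_record"), n_members >= 1)
  if (!(target_identity > 0 && target_identity <= 1))
    stop("target_identity must be in (0, 1]")
  k <- round((1 - target_identity) * seq$length)
  if (k > seq$length) stop("requested more mutations than sequence length")
  with_seed(rng_seed, {
    fam <- lapply(seq_len(n_members), function(i) {
      mutate_sequence(seq, k, id = paste0(seq$id, "_m", i))
    })
    attr(fam, "realized_identity") <- (seq$length - k) / seq$length
    fam
  })
}

# substitute n_mut positions (uniform over 'allowed' positions) with a
# different residue; uses the current RNG state
mutate_sequence <- function(seq, n_mut, id,
                            allowed = seq_len(seq$length)) {
  chars <- strsplit(seq$residues, "")[[1]]
  if (n_mut > length(allowed)) stop("not enough mutable positions")
  pos <- if (n_mut > 0) sample(allowed, n_mut) else integer()
  for (p in pos) chars[p] <- sample(setdiff(AA_LETTERS, chars[p]), 1)
  seq_record(id, paste(chars, collapse = ""), seq$description)
}

#' Plant a synthetic ligand pocket into a structure
#'
#' Places one carbon probe atom radially off the CA of each residue listed
#' in `in_shell`, so that exactly those residues have an atom within
#' `cutoff` of the ligand while every other residue stays more than
#' `cutoff + 1` Angstrom away. The construction is verified atom-by-atom
#' against the same distance definitions the extractor uses, and the call
#' fails if the requested geometry is unsatisfiable (e.g. in-shell residues
#' too close to out-of-shell neighbours).
#'
#' @param model a [structure_model()] without ligands
#' @param ligand_code HETATM code to use for the planted ligand
#' @param in_shell residue positions that must be in contact
#' @param cutoff contact cutoff in Angstrom (default 5)
#' @return the model with the ligand added; the planted truth is stored in
#'   `attr(, "pocket_truth")` (`in_shell`)
#' @export
plant_pocket <- function(model, ligand_code, in_shell, cutoff = 5.0) {
  stopifnot(inherits(model, "structure_model"), cutoff > 0)
  in_shell <- sort(unique(as.integer(in_shell)))
  if (length(setdiff(in_shell, model$residues$resno)))
    stop("in_shell positions absent from the model: ",
         paste(setdiff(in_shell, model$residues$resno), collapse = ", "))
  at <- model$atoms
  centroid <- c(mean(at$x), mean(at$y), mean(at$z))
  tr <- ca_trace(model)
  # outward direction at residue i: away from the local CA centroid, i.e.
  # roughly perpendicular to the chain axis (points radially out of a helix)
  out_dir <- function(pos) {
    i <- which(tr$resno == pos)[1]
    n <- nrow(tr$xyz)
    w <- min(5, i - 1, n - i)     # symmetric window: no axial tilt at termini
    win <- (i - w):(i + w)
    u <- tr$xyz[i, ] - colMeans(tr$xyz[win, , drop = FALSE])
    if (sqrt(sum(u^2)) < 0.8) {
      v <- tr$xyz[min(i + 1, n), ] - tr$xyz[max(i - 1, 1), ]
      u <- c(v[2], -v[1], 0)            # perpendicular to the chain direction
      if (sqrt(sum(u^2)) < 1e-6) u <- c(1, 0, 0)
    }
    u / sqrt(sum(u^2))
  }
  lig_rows <- list()
  if (!length(in_shell)) {
    far <- max(sqrt((at$x - centroid[1])^2 + (at$y - centroid[2])^2 +
                      (at$z - centroid[3])^2))
    p <- centroid + c(far + cutoff + 10, 0, 0)
    lig_rows[[1]] <- data.frame(name = "C1", element = "C",
                                x = p[1], y = p[2], z = p[3],
                                stringsAsFactors = FALSE)
  } else {
    for (k in seq_along(in_shell)) {
      pos <- in_shell[k]
      res_at <- at[at$resno == pos, , drop = FALSE]
      u <- out_dir(pos)
      caw <- res_at[res_at$name == "CA", , drop = FALSE]
      p <- c(caw$x[1], caw$y[1], caw$z[1]) + (cutoff - 0.1) * u
      lig_rows[[k]] <- data.frame(name = sprintf("C%d", k), element = "C",
                                  x = p[1], y = p[2], z = p[3],
                                  stringsAsFactors = FALSE)
    }
  }
  lig_atoms <- do.call(rbind, lig_rows)
  lig_atoms$x <- round(lig_atoms$x, 3)
  lig_atoms$y <- round(lig_atoms$y, 3)
  lig_atoms$z <- round(lig_atoms$z, 3)
  out <- structure_model(model$id, model$chain_id, model$atoms,
                         c(model$ligands,
                           list(list(het_code = ligand_code,
                                     resno = max(model$residues$resno) + 10L,
                                     atoms = lig_atoms))))
  # verify the planted geometry against the actual distance definitions
  got <- extract_contact_residues(out, ligand_code, cutoff)
  if (!identical(sort(got$position), in_shell))
    stop("geometrically unsatisfiable pocket: requested in-shell {",
         paste(in_shell, collapse = ","), "} but realized {",
         paste(sort(got$position), collapse = ","), "}")
  others <- setdiff(model$residues$resno, in_shell)
  if (length(others) && length(in_shell)) {
    oth <- at[at$resno %in% others & at$element != "H", , drop = FALSE]
    dmin <- min_dist_to(cbind(oth$x, oth$y, oth$z),
                        cbind(lig_atoms$x, lig_atoms$y, lig_atoms$z))
    if (any(dmin <= cutoff + 1))
      stop("geometrically unsatisfiable pocket: out-of-shell residue(s) ",
           paste(unique(oth$resno[dmin <= cutoff + 1]), collapse = ", "),
           " fall within cutoff + 1 A of the ligand")
  }
  attr(out, "pocket_truth") <- list(in_shell = in_shell)
  out
}

#' Planted 20-candidate pipeline fixture
#'
#' Builds a complete synthetic input set for [run_pipeline()] with known
#' per-stage outcomes: 5 redundant near-copies, 5 sequences outside the
#' length window, 5 structurally dissimilar candidates (extended chains
#' against a helical seed), 3 candidates with a substituted active-site
#' position and 2 with an identical active site. The stage counts therefore
#' telescope 20 -> 15 -> 10 -> 5 -> \{2 class-1, 3 class-2\}.
#'
#' @param rng_seed integer seed driving every random choice
#' @param n_res seed length in residues (default 120)
#' @return list with `seed_seq`, `seed_model`, `ref_complex`, `candidates`,
#'   `models`, `cfg`, `ligand_code` and `truth` (planted expectations:
#'   stage counts, per-class candidate ids, site positions)
#' @export
make_pipeline_fixture <- function(rng_seed = 1L, n_res = 120L) {
  stopifnot(n_res >= 100L)
  site_pos <- round(n_res * c(1, 2.2, 3.4, 4.6) / 6)
  with_seed(rng_seed, {
    seed_chars <- sample(AA_LETTERS, n_res, replace = TRUE)
    # make each site letter locally unique so a planted site substitution can
    # never be rescued by re-pairing with an identical neighbouring residue
    for (p in site_pos) {
      win <- setdiff(max(1, p - 5):min(n_res, p + 5), p)
      seed_chars[p] <- sample(setdiff(AA_LETTERS, seed_chars[win]), 1)
    }
    seed_str <- paste(seed_chars, collapse = "")
    seed_seq <- seq_record("seed", seed_str, "synthetic seed enzyme")
    seed_model <- make_helix(n_res, seed_str, id = "seed")
    ref_complex <- plant_pocket(make_helix(n_res, seed_str, id = "refcomplex"),
                                "LIG", site_pos, cutoff = 5.0)
    # background mutations stay > 4 residues from every site position so
    # local realignments around them cannot reach a site column
    non_site <- Filter(function(i) all(abs(i - site_pos) > 4),
                       seq_len(n_res))

    candidates <- list(); models <- list()
    add_cand <- function(rec, model = NULL) {
      candidates[[length(candidates) + 1L]] <<- rec
      if (!is.null(model)) models[[rec$id]] <<- model
    }
    # class 1: substitutions only outside the site, near-native structure
    good_ids <- sprintf("cand_g%d", 1:2)
    for (i in seq_along(good_ids)) {
      rec <- mutate_sequence(seed_seq, 8L, good_ids[i], allowed = non_site)
      add_cand(rec, perturb_structure(seed_model, 0.3,
                                      rng_seed + 100L + i, id = rec$id))
    }
    # class 2: one substituted site position (plus non-site noise)
    sub_ids <- sprintf("cand_s%d", 1:3)
    for (i in seq_along(sub_ids)) {
      rec <- mutate_sequence(seed_seq, 7L, "tmp", allowed = non_site)
      hit <- sample(site_pos, 1)
      chars <- strsplit(rec$residues, "")[[1]]
      win <- max(1, hit - 5):min(n_res, hit + 5)
      chars[hit] <- sample(setdiff(AA_LETTERS, chars[win]), 1)
      rec <- seq_record(sub_ids[i], paste(chars, collapse = ""))
      add_cand(rec, perturb_structure(seed_model, 0.3,
                                      rng_seed + 200L + i, id = rec$id))
    }
    # class 3 by structure: similar sequence, unrelated (extended) fold
    far_ids <- sprintf("cand_f%d", 1:5)
    for (i in seq_along(far_ids)) {
      rec <- mutate_sequence(seed_seq, 12L, far_ids[i])
      add_cand(rec, make_extended(n_res, rec$residues, id = rec$id))
    }
    # class 3 by length: far outside the window around the seed length
    short_len <- round(n_res / 2); long_len <- round(n_res * 5 / 3)
    for (i in 1:3) {
      sub <- seq_record("tmp", substr(seed_str, 1, short_len))
      add_cand(mutate_sequence(sub, 5L, sprintf("cand_l%d", i)))
    }
    for (i in 4:5) {
      tail_str <- paste(sample(AA_LETTERS, long_len - n_res, replace = TRUE),
                        collapse = "")
      add_cand(seq_record(sprintf("cand_l%d", i),
                          paste0(seed_str, tail_str)))
    }
    # redundant near-copies (>= 99% identity) of five survivors; ids sort
    # after their originals so the originals stay representatives
    dup_of <- c("cand_g1", "cand_g2", "cand_s1", "cand_f1", "cand_f2")
    ids <- vapply(candidates, `[[`, character(1), "id")
    for (i in seq_along(dup_of)) {
      orig <- candidates[[match(dup_of[i], ids)]]
      add_cand(mutate_sequence(orig, 1L, sprintf("zdup%d", i)))
    }

    cfg <- pipeline_config(length_min = n_res - 20L, length_max = n_res + 20L)
    truth <- list(
      counts = list(n_input = 20L, n_nonredundant = 15L, n_length_pass = 10L,
                    n_with_structure = 10L, n_structural_pass = 5L,
                    n_class1 = 2L, n_class2 = 3L, n_class3 = 15L),
      class1_ids = good_ids, class2_ids = sub_ids,
      structural_fail_ids = far_ids,
      length_fail_ids = sprintf("cand_l%d", 1:5),
      redundant_ids = sprintf("zdup%d", 1:5),
      site_positions = site_pos)
    list(seed_seq = seed_seq, seed_model = seed_model,
         ref_complex = ref_complex, candidates = candidates,
         models = models, cfg = cfg, ligand_code = "LIG", truth = truth)
  })
}
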