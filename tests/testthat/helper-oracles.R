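# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: scores are computed from the scoring definition
# by exhaustive enumeration, distances by direct all-pairs scans.

random_aa_string <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

# Exhaustive local-alignment optimum: enumerate every strictly increasing
# set of aligned residue pairs (all C(n,k) x C(m,k) choices for every k);
# residues between consecutive pairs are forced into gap runs, charged
# open + (len-1)*extend per run per sequence. The best local alignment is
# the maximum over all such pair sets (or 0 for the empty alignment).
oracle_local_score <- function(a, b, scoring = align_scoring()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- 0
  for (k in seq_len(min(n, m))) {
    ia <- utils::combn(n, k); ib <- utils::combn(m, k)
    for (p in seq_len(ncol(ia))) {
      I <- ia[, p]
      da <- diff(I) - 1L
      cost_a <- sum(scoring$gap_open + (da[da > 0] - 1) * scoring$gap_extend)
      for (q in seq_len(ncol(ib))) {
        J <- ib[, q]
        s <- sum(ifelse(av[I] == bv[J] & av[I] != "X",
                        scoring$match, scoring$mismatch))
        db <- diff(J) - 1L
        s <- s + cost_a +
          sum(scoring$gap_open + (db[db > 0] - 1) * scoring$gap_extend)
        if (s > best) best <- s
      }
    }
  }
  best
}

# Brute-force substrate-contact scan: residue-by-residue, atom-by-atom
# double loop over heavy atoms (no vectorized trickery shared with the
# implementation).
oracle_contact_positions <- function(model, ligand_code, cutoff) {
  lig <- NULL
  for (lg in model$ligands)
    if (lg$het_code == ligand_code) lig <- rbind(lig, lg$atoms)
  lig <- lig[lig$element != "H", , drop = FALSE]
  hits <- integer()
  for (pos in unique(model$atoms$resno)) {
    res <- model$atoms[model$atoms$resno == pos &
                         model$atoms$element != "H", , drop = FALSE]
    found <- FALSE
    for (i in seq_len(nrow(res))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((res$x[i] - lig$x[j])^2 + (res$y[i] - lig$y[j])^2 +
                    (res$z[i] - lig$z[j])^2)
        if (d <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hits <- c(hits, pos)
  }
  hits
}

# Uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed to a
# proper rotation).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Apply a rigid motion to every atom (protein + ligands) of a model.
rigid_move_model <- function(model, R = random_rotation(),
                             t = rnorm(3, 0, 20), id = model$id) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]; a$y <- xyz[, 2] + t[2]; a$z <- xyz[, 3] + t[3]
  ligands <- lapply(model$ligands, function(lig) {
    la <- lig$atoms
    xyz <- as.matrix(la[, c("x", "y", "z")]) %*% t(R)
    la$x <- xyz[, 1] + t[1]; la$y <- xyz[, 2] + t[2]; la$z <- xyz[, 3] + t[3]
    lig$atoms <- la
    lig
  })
  structure_model(id, model$chain_id, a, ligands)
}

# Minimal hand-rolled seq_record list for filter tests
records_of_lengths <- function(lens, prefix = "s") {
  lapply(seq_along(lens), function(i)
    seq_record(sprintf("%s%02d", prefix, i), strrep("A", lens[i])))
}
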