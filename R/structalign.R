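#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `coords_b` onto `coords_a`. Reflections are corrected, so the returned
#' rotation always has determinant +1.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (Angstrom), N >= 3
#' @return an object of class `superposition`: `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Angstrom), such that
#'   `coords_b %*% t(rotation) + translation` superposes b onto a
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3L)
    stop("coordinate sets must be N x 3 matrices of equal size")
  n <- nrow(coords_a)
  if (n < 3L) stop("at least 3 point pairs are required")
  if (!all(is.finite(coords_a)) || !all(is.finite(coords_b)))
    stop("coordinates must be finite")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- crossprod(B, A)               # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    warning("(near-)collinear point set: superposition is ill-determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- B %*% t(R)
  rmsd <- sqrt(sum((A - fitted)^2) / n)
  structure(list(rotation = R, translation = as.numeric(ca - R %*% cb),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup a [kabsch()] superposition
#' @param coords N x 3 matrix
#' @return transformed N x 3 matrix
#' @export
transform_coords <- function(sup, coords) {
  stopifnot(inherits(sup, "superposition"))
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' TM-score distance scale d0
#'
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom so short
#' chains never yield a non-positive scale.
#'
#' @param l_target normalizing chain length (aa)
#' @return d0 in Angstrom
#' @export
tm_d0 <- function(l_target) {
  stopifnot(l_target >= 1)
  if (l_target <= 15) return(0.5)
  max(0.5, 1.24 * (l_target - 15)^(1 / 3) - 1.8)
}

#' TM-score from aligned-pair distances
#'
#' `TM = (1 / L_target) * sum_i 1 / (1 + (d_i / d0)^2)` over the aligned
#' residue pairs, with `d0 = max(0.5, 1.24 (L_target - 15)^(1/3) - 1.8)`.
#' Normalization by the target (seed) length makes the score directly
#' comparable across candidates of different sizes.
#'
#' @param distances aligned-pair CA distances d_i (Angstrom, >= 0)
#' @param l_target normalizing length (aa)
#' @return TM-score in \\[0, 1\\]; an empty distance vector yields 0 with a
#'   warning
#' @export
#' @examples
#' tm_score(rep(0, 100), 100)  # 1
tm_score <- function(distances, l_target) {
  stopifnot(l_target >= 1)
  if (!length(distances)) {
    warning("empty correspondence: TM-score is 0")
    return(0)
  }
  if (any(distances < 0)) stop("distances must be >= 0")
  if (length(distances) > l_target)
    stop("more aligned pairs than l_target residues")
  d0 <- tm_d0(l_target)
  sum(1 / (1 + (distances / d0)^2)) / l_target
}

# TM-score of a fixed correspondence under the best superposition found by
# iterative subset fitting (fit on all pairs, then refit on progressively
# distance-trimmed subsets, keeping the superposition that maximizes the
# score over ALL pairs). Returns the score, the winning superposition and
# the per-pair distances under it.
score_correspondence <- function(xa, xb, d0, l_target) {
  n <- nrow(xa)
  fit_subset <- function(idx) {
    if (length(idx) < 3L) return(NULL)
    sup <- suppressWarnings(kabsch(xa[idx, , drop = FALSE],
                                   xb[idx, , drop = FALSE]))
    d <- sqrt(rowSums((xa - transform_coords(sup, xb))^2))
    list(sup = sup, d = d, tm = sum(1 / (1 + (d / d0)^2)) / l_target)
  }
  best <- fit_subset(seq_len(n))
  if (is.null(best)) return(NULL)
  cur <- best
  for (cut in c(2 * d0, 1.5 * d0, d0, max(d0 / 2, 1.0))) {
    for (it in 1:4) {
      idx <- which(cur$d <= cut)
      nxt <- fit_subset(idx)
      if (is.null(nxt)) break
      if (nxt$tm > best$tm) best <- nxt
      if (max(abs(nxt$d - cur$d)) < 1e-9) { cur <- nxt; break }
      cur <- nxt
    }
  }
  best
}

#' Pairwise structural alignment of two CA traces
#'
#' TM-align-style heuristic alignment. Initial correspondences come from a
#' global sequence alignment of the residue strings and from gapless
#' sliding-window offsets. Each initialization is refined by iterating
#' \{superimpose on the current correspondence, recompute all CA-CA
#' distances, re-derive the correspondence by dynamic programming with
#' per-pair score `1/(1 + (d_ij/d0)^2)` and zero gap penalty\} until the
#' correspondence stops changing or `max_iter` iterations. The result with
#' the highest TM-score (normalized by the seed length) is returned.
#'
#' @param seed,cand [structure_model()] objects with at least 20 CA atoms
#' @param cfg optional [pipeline_config()]; controls the coverage
#'   denominator convention
#' @param max_iter refinement iteration cap per initialization
#' @param max_starts cap on the number of gapless-offset initializations
#'   (offsets are strided when there are more); small structures are
#'   covered exhaustively
#' @return an object of class `struct_align`: `seed_id`, `cand_id`,
#'   `correspondence` (k x 2 matrix of residue indices into the CA traces,
#'   strictly increasing), `superposition`, `tm_score`, `distances`,
#'   `seed_coverage`, `d0`, `converged`
#' @export
align_structures <- function(seed, cand, cfg = NULL, max_iter = 30L,
                             max_starts = 64L) {
  stopifnot(inherits(seed, "structure_model"),
            inherits(cand, "structure_model"))
  ta <- ca_trace(seed); tb <- ca_trace(cand)
  n <- nrow(ta$xyz); m <- nrow(tb$xyz)
  if (n < 20L || m < 20L)
    stop("both structures need at least 20 CA atoms (have ", n, " and ", m, ")")
  l_target <- n
  d0 <- tm_d0(l_target)

  inits <- list()
  seqaln <- nw_affine_cpp(paste(ta$aa, collapse = ""),
                          paste(tb$aa, collapse = ""), 2, -1, -0.5, -0.1)
  if (nrow(seqaln$pairs) >= 3L) inits[[1]] <- seqaln$pairs
  min_overlap <- max(5L, min(20L, floor(min(n, m) / 2)))
  offsets <- seq.int(-(m - min_overlap), n - min_overlap)
  if (length(offsets) > max_starts)
    offsets <- offsets[unique(round(seq(1, length(offsets),
                                        length.out = max_starts)))]
  for (o in offsets) {
    i <- seq_len(n); j <- i - o
    ok <- j >= 1 & j <= m
    if (sum(ok) >= max(3L, min_overlap))
      inits[[length(inits) + 1L]] <- cbind(i[ok], j[ok])
  }

  best <- NULL; best_converged <- FALSE
  for (C in inits) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      sc <- score_correspondence(ta$xyz[C[, 1], , drop = FALSE],
                                 tb$xyz[C[, 2], , drop = FALSE],
                                 d0, l_target)
      if (is.null(sc)) break
      if (is.null(best) || sc$tm > best$tm)
        best <- list(C = C, sup = sc$sup, d = sc$d, tm = sc$tm)
      xb_all <- transform_coords(sc$sup, tb$xyz)
      D2 <- outer(rowSums(ta$xyz^2), rep(1, m)) +
        outer(rep(1, n), rowSums(xb_all^2)) - 2 * ta$xyz %*% t(xb_all)
      S <- 1 / (1 + pmax(D2, 0) / d0^2)
      C2 <- nw_maxsim_cpp(S)
      if (nrow(C2) == nrow(C) && all(C2 == C)) { converged <- TRUE; break }
      C <- C2
    }
    if (converged && !is.null(best) && nrow(best$C) == nrow(C) &&
        all(best$C == C))
      best_converged <- TRUE
  }
  if (is.null(best)) stop("structural alignment failed to produce a correspondence")

  coverage_denom <- if (!is.null(cfg) && cfg$coverage_denominator == "alignment")
    nrow(best$C) else l_target
  colnames(best$C) <- c("seed_idx", "cand_idx")
  structure(list(seed_id = seed$id, cand_id = cand$id,
                 correspondence = best$C,
                 superposition = best$sup,
                 tm_score = best$tm,
                 distances = best$d,
                 seed_coverage = nrow(best$C) / coverage_denom,
                 d0 = d0, l_target = l_target,
                 converged = best_converged),
            class = "struct_align")
}

#' @export
print.struct_align <- function(x, ...) {
  cat(sprintf("<struct_align> %s vs %s: TM-score %.4f, seed coverage %.3f (%d pairs, d0 %.2f A)\n",
              x$seed_id, x$cand_id, x$tm_score, x$seed_coverage,
              nrow(x$correspondence), x$d0))
  invisible(x)
}

#' Global structural-similarity filter
#'
#' A candidate passes when its TM-score lies in the inclusive band
#' `[tm_min, tm_max]` and its seed coverage is at least `coverage_min`.
#'
#' @param r a `struct_align` result
#' @param cfg a [pipeline_config()]
#' @return logical
#' @export
passes_structural_filter <- function(r, cfg = pipeline_config()) {
  stopifnot(inherits(r, "struct_align"), inherits(cfg, "pipeline_config"))
  r$tm_score >= cfg$tm_min && r$tm_score <= cfg$tm_max &&
    r$seed_coverage >= cfg$coverage_min
}

#' Resolve the structure model used for a candidate
#'
#' A candidate with its own model in `model_index` is used directly.
#' Otherwise the highest-identity sequence in `proxy_pool` with identity at
#' least `cfg$proxy_identity_min` lends its model (ties: longer proxy, then
#' id ascending). A candidate with neither is excluded with reason
#' `"no model"` -- absence is a verdict, not an error.
#'
#' @param cand a [seq_record()]
#' @param model_index named list mapping sequence id -> [structure_model()]
#' @param proxy_pool list of [seq_record()] whose ids all appear in
#'   `model_index`
#' @param cfg a [pipeline_config()]
#' @return an object of class `proxy_resolution`: `cand_id`,
#'   `structure_source` (`"direct"`, `"proxy"` or `"none"`), `proxy_id`,
#'   `proxy_identity`, `model` (the resolved [structure_model()] or `NULL`),
#'   `reason`
#' @export
resolve_structure <- function(cand, model_index, proxy_pool = list(),
                              cfg = pipeline_config()) {
  stopifnot(inherits(cand, "seq_record"))
  if (cand$id %in% names(model_index)) {
    return(structure(list(cand_id = cand$id, structure_source = "direct",
                          proxy_id = NA_character_, proxy_identity = NA_real_,
                          model = model_index[[cand$id]], reason = NA_character_),
                     class = "proxy_resolution"))
  }
  if (length(proxy_pool)) {
    missing_models <- setdiff(vapply(proxy_pool, `[[`, "", "id"),
                              names(model_index))
    if (length(missing_models))
      stop("proxy pool sequence(s) without a model: ",
           paste(missing_models, collapse = ", "))
    ident <- vapply(proxy_pool, function(p)
      pairwise_identity(p, cand, cfg$align_scoring, cfg$identity_denominator),
      numeric(1))
    lens <- vapply(proxy_pool, `[[`, numeric(1), "length")
    ids <- vapply(proxy_pool, `[[`, character(1), "id")
    ord <- order(-ident, -lens, ids)
    k <- ord[1]
    if (ident[k] >= cfg$proxy_identity_min) {
      return(structure(list(cand_id = cand$id, structure_source = "proxy",
                            proxy_id = ids[k], proxy_identity = ident[k],
                            model = model_index[[ids[k]]],
                            reason = NA_character_),
                       class = "proxy_resolution"))
    }
  }
  structure(list(cand_id = cand$id, structure_source = "none",
                 proxy_id = NA_character_, proxy_identity = NA_real_,
                 model = NULL, reason = "no model"),
            class = "proxy_resolution")
}
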