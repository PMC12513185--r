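#' Affine-gap local sequence alignment (Smith-Waterman)
#'
#' Optimal local alignment under an affine gap model in which a gap run of
#' length L scores `gap_open + (L - 1) * gap_extend`. Among co-optimal
#' alignments the traceback deterministically prefers diagonal moves over
#' gaps in the second sequence over gaps in the first. `X` residues never
#' count as identical to anything, including another `X`.
#'
#' @param seed,other [seq_record()] objects (both non-empty)
#' @param scoring an [align_scoring()] object
#' @return an object of class `pairwise_alignment` with fields `seed_id`,
#'   `other_id`, `aligned_pairs` (k x 2 integer matrix of 1-based positions,
#'   strictly increasing in both columns), `score` and `identity` (identical
#'   columns / aligned columns; `NA` for an empty alignment)
#' @export
#' @examples
#' a <- seq_record("a", "ACDEFG")
#' local_align(a, a)$score  # 12: six matches at +2
local_align <- function(seed, other, scoring = align_scoring()) {
  stopifnot(inherits(seed, "seq_record"), inherits(other, "seq_record"),
            inherits(scoring, "align_scoring"))
  res <- sw_affine_cpp(seed$residues, other$residues, scoring$match,
                       scoring$mismatch, scoring$gap_open, scoring$gap_extend)
  pairs <- res$pairs
  colnames(pairs) <- c("seed_pos", "other_pos")
  identity <- NA_real_
  if (nrow(pairs)) {
    sa <- strsplit(seed$residues, "")[[1]][pairs[, 1]]
    oa <- strsplit(other$residues, "")[[1]][pairs[, 2]]
    identity <- mean(sa == oa & sa != "X")
  }
  structure(list(seed_id = seed$id, other_id = other$id,
                 aligned_pairs = pairs, score = res$score,
                 identity = identity),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s: score %.2f, %d aligned pairs%s\n",
              x$seed_id, x$other_id, x$score, nrow(x$aligned_pairs),
              if (is.na(x$identity)) ""
              else sprintf(", identity %.3f", x$identity)))
  invisible(x)
}

#' Global pairwise sequence identity
#'
#' Identical columns of a global (Needleman-Wunsch) alignment divided, by
#' default, by the length of the shorter sequence -- the convention used by
#' greedy redundancy clustering tools. `X` never counts as identical.
#'
#' @param a,b [seq_record()] objects
#' @param scoring an [align_scoring()] object used for the underlying
#'   global alignment
#' @param denominator `"shorter"` (default) or `"alignment"` (number of
#'   alignment columns including gap columns)
#' @return identity fraction in \\[0, 1\\]
#' @export
#' @examples
#' pairwise_identity(seq_record("a", "ACDEFGHIKL"),
#'                   seq_record("b", "ACDEFGHIKV"))  # 0.9
pairwise_identity <- function(a, b, scoring = align_scoring(),
                              denominator = c("shorter", "alignment")) {
  stopifnot(inherits(a, "seq_record"), inherits(b, "seq_record"))
  denominator <- match.arg(denominator)
  res <- nw_affine_cpp(a$residues, b$residues, scoring$match,
                       scoring$mismatch, scoring$gap_open, scoring$gap_extend)
  pairs <- res$pairs
  n_ident <- 0L
  if (nrow(pairs)) {
    av <- strsplit(a$residues, "")[[1]][pairs[, 1]]
    bv <- strsplit(b$residues, "")[[1]][pairs[, 2]]
    n_ident <- sum(av == bv & av != "X")
  }
  denom <- switch(denominator,
    shorter = min(a$length, b$length),
    # alignment columns = aligned pairs + residues of either sequence in gaps
    alignment = a$length + b$length - nrow(pairs))
  n_ident / denom
}

#' Greedy redundancy clustering by sequence identity
#'
#' Sequences are sorted by length descending (ties: id ascending) and each
#' one joins the first existing cluster whose representative is at least
#' `threshold` identical to it, otherwise it founds a new cluster. Because
#' representatives are encountered longest-first, every representative is
#' at least as long as its members and representatives are pairwise below
#' the threshold.
#'
#' @param seqs list of [seq_record()] objects with unique ids
#' @param threshold identity fraction in (0, 1]; default 0.99
#' @param cfg optional [pipeline_config()] supplying the identity
#'   denominator convention
#' @return an object of class `cluster_set`: list with `clusters` (each a
#'   list with `representative_id` and `member_ids`), `threshold` and
#'   `assignment` (named character vector member id -> representative id)
#' @export
greedy_cluster <- function(seqs, threshold = 0.99, cfg = NULL) {
  if (!(is.numeric(threshold) && threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]")
  check_unique_ids(seqs)
  denom <- if (is.null(cfg)) "shorter" else cfg$identity_denominator
  scoring <- if (is.null(cfg)) align_scoring() else cfg$align_scoring
  lens <- vapply(seqs, `[[`, numeric(1), "length")
  ids <- vapply(seqs, `[[`, character(1), "id")
  ord <- order(-lens, ids)
  reps <- list()
  members <- list()
  for (k in ord) {
    s <- seqs[[k]]
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (pairwise_identity(reps[[ci]], s, scoring, denom) >= threshold) {
        members[[ci]] <- c(members[[ci]], s$id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- s
      members[[length(members) + 1L]] <- s$id
    }
  }
  clusters <- lapply(seq_along(reps), function(ci) {
    list(representative_id = reps[[ci]]$id, member_ids = members[[ci]])
  })
  assignment <- unlist(lapply(clusters, function(cl) {
    stats::setNames(rep(cl$representative_id, length(cl$member_ids)),
                    cl$member_ids)
  }))
  structure(list(clusters = clusters, threshold = threshold,
                 assignment = assignment),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) at identity >= %.2f over %d sequence(s)\n",
              length(x$clusters), x$threshold, length(x$assignment)))
  invisible(x)
}

#' Representative ids of a cluster set
#' @param clusters a `cluster_set` from [greedy_cluster()]
#' @return character vector of representative ids, in cluster-founding order
#' @export
cluster_representatives <- function(clusters) {
  vapply(clusters$clusters, `[[`, character(1), "representative_id")
}

#' Filter sequences by length window
#'
#' Keeps sequences whose length lies in the inclusive window
#' `[min_len, max_len]`; input order is preserved. Sequences markedly longer
#' than the seed tend to carry extra unrelated domains, markedly shorter
#' ones to lack the primary activity, so a window around the seed length
#' enriches for candidates with the seed's global architecture.
#'
#' @param seqs list of [seq_record()] objects
#' @param min_len,max_len inclusive bounds (aa); `NULL` disables a bound
#' @return the surviving subset of `seqs`
#' @export
#' @examples
#' s <- lapply(c(a = 3, b = 5), function(n)
#'   seq_record(as.character(n), strrep("A", n)))
#' length(filter_by_length(s, 4, 10))  # 1
filter_by_length <- function(seqs, min_len = NULL, max_len = NULL) {
  lo <- if (is.null(min_len)) -Inf else min_len
  hi <- if (is.null(max_len)) Inf else max_len
  if (lo > hi) stop("min_len must not exceed max_len")
  keep <- vapply(seqs, function(s) s$length >= lo && s$length <= hi,
                 logical(1))
  seqs[keep]
}
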