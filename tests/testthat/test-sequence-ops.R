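test_that("local alignment reproduces the forced scoring examples", {
  a <- seq_record("a", "ACDEFG")
  self <- local_align(a, a)
  expect_equal(self$score, 12)                       # 6 matches x 2
  expect_equal(self$aligned_pairs[, 1], 1:6)
  expect_equal(self$aligned_pairs[, 2], 1:6)

  gap1 <- local_align(seq_record("a", "AD"), seq_record("b", "AXD"))
  expect_equal(gap1$score, 3.5)                      # 2 - 0.5 + 2
  expect_equal(unname(gap1$aligned_pairs),
               cbind(c(1L, 2L), c(1L, 3L)))

  none <- local_align(seq_record("a", "KKKK"), seq_record("b", "RRRR"))
  expect_equal(none$score, 0)
  expect_equal(nrow(none$aligned_pairs), 0)
})

test_that("self local alignment is the full diagonal at twice the length", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    s <- seq_record("s", random_aa_string(n))
    aln <- local_align(s, s)
    expect_equal(aln$score, 2 * n)
    expect_equal(aln$aligned_pairs[, 1], seq_len(n))
    expect_equal(aln$aligned_pairs[, 2], seq_len(n))
    expect_equal(aln$identity, 1)
  }
})

test_that("local alignment score is symmetric in its arguments", {
  set.seed(12)
  for (i in 1:25) {
    a <- seq_record("a", random_aa_string(sample(3:25, 1)))
    b <- seq_record("b", random_aa_string(sample(3:25, 1)))
    f <- local_align(a, b); r <- local_align(b, a)
    expect_equal(f$score, r$score)
  }
})

test_that("aligned pair positions are strictly increasing in both coordinates", {
  set.seed(13)
  for (i in 1:25) {
    a <- seq_record("a", random_aa_string(sample(5:40, 1)))
    b <- seq_record("b", random_aa_string(sample(5:40, 1)))
    p <- local_align(a, b)$aligned_pairs
    if (nrow(p) > 1) {
      expect_true(all(diff(p[, 1]) > 0))
      expect_true(all(diff(p[, 2]) > 0))
    }
  }
})

test_that("X residues never count as identical, even to X", {
  aln <- local_align(seq_record("a", "AXA"), seq_record("b", "AXA"))
  expect_equal(aln$score, 3)              # match - mismatch(X/X) + match
  expect_equal(pairwise_identity(seq_record("a", "AXC"),
                                 seq_record("b", "AXC")), 2 / 3)
})

test_that("pairwise identity follows the shorter-sequence convention", {
  a <- seq_record("a", "ACDEFGHIKL")
  expect_equal(pairwise_identity(a, a), 1)
  expect_equal(pairwise_identity(a, seq_record("b", "ACDEFGHIKV")), 0.9)

  set.seed(14)
  parent <- random_aa_string(30)
  chars <- strsplit(parent, "")[[1]]
  for (p in c(7, 22))
    chars[p] <- setdiff(c("A", "C", "D"), chars[p])[1]
  expect_equal(pairwise_identity(seq_record("p", parent),
                                 seq_record("q", paste(chars, collapse = ""))),
               28 / 30)

  # a perfect substring counts fully against the shorter length
  expect_equal(pairwise_identity(seq_record("s", "ACDEF"),
                                 seq_record("t", "ACD")), 1)
})

test_that("greedy clustering handles the degenerate cases", {
  s1 <- seq_record("a1", "ACDEFGHIKLMNPQRSTVWY")
  s2 <- seq_record("a2", "ACDEFGHIKLMNPQRSTVWY")
  cl <- greedy_cluster(list(s1, s2), 0.99)
  expect_length(cl$clusters, 1)
  expect_equal(cl$clusters[[1]]$representative_id, "a1")  # tie: id ascending
  expect_setequal(cl$clusters[[1]]$member_ids, c("a1", "a2"))

  set.seed(15)
  p <- random_aa_string(50)
  chars <- strsplit(p, "")[[1]]
  pos <- sample(50, 5)
  for (k in pos) chars[k] <- setdiff(c("A", "C", "D", "E"), chars[k])[1]
  far <- paste(chars, collapse = "")
  cl2 <- greedy_cluster(list(seq_record("x", p), seq_record("y", far)), 0.99)
  expect_length(cl2$clusters, 2)

  expect_error(greedy_cluster(list(s1), 0), "0, 1")
  expect_error(greedy_cluster(list(s1), 1.2), "0, 1")
})

test_that("greedy clustering recovers planted families exactly", {
  set.seed(16)
  parents <- lapply(1:5, function(i)
    seq_record(sprintf("fam%d", i), random_aa_string(100)))
  seqs <- list()
  for (i in 1:5) {
    fam <- mutate_family(parents[[i]], 3, 0.99, rng_seed = 160 + i)
    seqs <- c(seqs, parents[i], fam)
  }
  cl <- greedy_cluster(seqs, 0.99)
  expect_length(cl$clusters, 5)
  for (clu in cl$clusters) {
    expect_length(clu$member_ids, 4)
    fam <- sub("_m[0-9]+$", "", clu$member_ids)
    expect_length(unique(fam), 1)           # each cluster is one family
  }
  # oracle: member-representative identity above threshold, reps below
  by_id <- stats::setNames(seqs, vapply(seqs, `[[`, "", "id"))
  for (clu in cl$clusters) {
    rep <- by_id[[clu$representative_id]]
    for (mid in clu$member_ids)
      expect_gte(pairwise_identity(rep, by_id[[mid]]), 0.99)
  }
  reps <- lapply(cluster_representatives(cl), function(id) by_id[[id]])
  for (i in 1:4) for (j in (i + 1):5)
    expect_lt(pairwise_identity(reps[[i]], reps[[j]]), 0.99)
})

test_that("length filter uses inclusive bounds and preserves order", {
  seqs <- records_of_lengths(c(799, 800, 1500, 1501))
  kept <- filter_by_length(seqs, 800, 1500)
  expect_equal(vapply(kept, `[[`, numeric(1), "length"), c(800, 1500))

  expect_equal(filter_by_length(list(), 10, 20), list())
  expect_error(filter_by_length(seqs, 100, 50), "min_len")

  set.seed(17)
  lens <- sample(500:2000, 100, replace = TRUE)
  seqs <- records_of_lengths(lens)
  expected <- sum(lens >= 800 & lens <= 1500)
  kept <- filter_by_length(seqs, 800, 1500)
  expect_length(kept, expected)
  # subsequence of the input, and idempotent
  expect_true(all(vapply(kept, `[[`, "", "id") %in%
                    vapply(seqs, `[[`, "", "id")))
  expect_identical(filter_by_length(kept, 800, 1500), kept)
})
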