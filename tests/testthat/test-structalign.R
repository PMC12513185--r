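test_that("Kabsch superposition recovers rigid motions exactly", {
  tr <- ca_trace(make_helix(30))$xyz
  ident <- kabsch(tr, tr)
  expect_equal(ident$rmsd, 0, tolerance = 1e-12)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-9)

  set.seed(21)
  R <- random_rotation()
  moved <- tr %*% t(R) + matrix(rep(c(7, -4, 11), each = nrow(tr)), ncol = 3)
  sup <- kabsch(tr, moved)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-6)
  expect_equal(transform_coords(sup, moved), tr, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("Kabsch rejects too-small inputs and warns on collinear points", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabsch(line, line), "collinear")
})

test_that("Kabsch matches a numeric minimization oracle on noisy points", {
  set.seed(22)
  a <- matrix(rnorm(12), 4, 3)
  b <- a %*% t(random_rotation()) + matrix(rnorm(12, 0, 0.3), 4, 3)
  sup <- kabsch(a, b)
  # oracle: direct minimization over Euler angles + translation
  obj <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    fitted <- b %*% t(Rz %*% Ry %*% Rx) +
      matrix(rep(p[4:6], each = 4), ncol = 3)
    sqrt(mean(rowSums((a - fitted)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(pi / 2, 0, 0, 0, 0, 0),
                     c(0, pi / 2, 0, 0, 0, 0), c(1, 1, 1, 0, 0, 0),
                     c(-1, 2, -2, 1, 1, 1))) {
    fit <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  expect_equal(sup$rmsd, best, tolerance = 1e-6)
})

test_that("Kabsch RMSD dominates randomly sampled rotations", {
  set.seed(23)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, 0, 0.5), 10, 3)
  sup <- kabsch(a, b)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  sampled <- replicate(10000, {
    R <- random_rotation()
    sqrt(mean(rowSums((ac - bc %*% t(R))^2)))
  })
  expect_lte(sup$rmsd, min(sampled) + 1e-12)
})

test_that("TM-score formula and d0 floor behave as defined", {
  expect_equal(tm_score(rep(0, 100), 100), 1)
  d0 <- tm_d0(100)
  expect_identical(tm_score(rep(d0, 100), 100), 0.5)  # each term exactly 1/2
  # independent hand evaluation: 50 of 100 residues aligned at 2 A
  expected <- 50 * (1 / (1 + (2 / d0)^2)) / 100
  expect_equal(tm_score(rep(2, 50), 100), expected)
  # short chains: d0 floored at 0.5
  expect_equal(tm_d0(10), 0.5)
  expect_equal(tm_d0(16), 0.5)  # formula value would be negative
  expect_warning(val <- tm_score(numeric(), 50), "empty")
  expect_equal(val, 0)
  expect_error(tm_score(rep(0, 10), 5), "more aligned pairs")
})

test_that("structural self-alignment is exact and coverage complete", {
  h <- make_helix(40, id = "a")
  aln <- align_structures(h, make_helix(40, id = "b"))
  expect_equal(aln$tm_score, 1, tolerance = 1e-9)
  expect_equal(aln$seed_coverage, 1)
  # full coverage means every seed residue is in the correspondence
  expect_equal(nrow(aln$correspondence), nrow(ca_trace(h)$xyz))
})

test_that("structural alignment is invariant under rigid motions", {
  set.seed(24)
  h <- make_helix(30, id = "seed")
  frag <- structure_model("frag", "A",
                          subset_residues(h, 1, 24)$atoms)
  base <- align_structures(h, frag)$tm_score
  for (i in 1:20) {
    moved <- rigid_move_model(frag, id = "moved")
    expect_equal(align_structures(h, moved)$tm_score, base,
                 tolerance = 1e-6)
  }
})

test_that("a rigidly moved N-terminal 70% fragment scores tm = coverage = 0.7", {
  h <- make_helix(40, id = "seed")
  frag <- rigid_move_model(
    structure_model("frag", "A", subset_residues(h, 1, 28)$atoms))
  aln <- align_structures(h, frag)
  expect_equal(aln$seed_coverage, 0.7)
  expect_equal(aln$tm_score, 0.7, tolerance = 1e-6)
})

test_that("unrelated folds score below the same-fold threshold", {
  aln <- align_structures(make_helix(40), make_extended(40))
  expect_lt(aln$tm_score, 0.5)
})

test_that("TM-score decreases monotonically with coordinate noise", {
  h <- make_helix(60, id = "ref")
  tms <- vapply(c(0, 0.5, 1, 2), function(s) {
    p <- perturb_structure(h, s, rng_seed = 240 + round(10 * s), id = "noisy")
    align_structures(h, p)$tm_score
  }, numeric(1))
  expect_true(all(diff(tms) <= 1e-9))
  expect_equal(tms[1], 1, tolerance = 1e-9)
})

test_that("default initialization matches exhaustive-offset search on small cases", {
  set.seed(25)
  for (i in 1:5) {
    n <- sample(22:30, 1)
    h <- make_helix(n, id = "a")
    p <- perturb_structure(h, 0.8, rng_seed = 250 + i, id = "b")
    q <- rigid_move_model(p)
    default <- align_structures(h, q)
    exhaustive <- align_structures(h, q, max_starts = 100000L)
    expect_equal(default$tm_score, exhaustive$tm_score, tolerance = 1e-9)
  }
})

test_that("structural aligner enforces the minimum chain length", {
  expect_error(align_structures(make_helix(10), make_helix(40)),
               "at least 20")
})

test_that("the structural filter uses inclusive boundaries", {
  cfg <- pipeline_config()
  fake <- function(tm, cov) structure(
    list(seed_id = "s", cand_id = "c", tm_score = tm, seed_coverage = cov),
    class = "struct_align")
  expect_true(passes_structural_filter(fake(0.5, 0.70), cfg))
  expect_true(passes_structural_filter(fake(1.0, 1.0), cfg))
  expect_false(passes_structural_filter(fake(0.49, 0.99), cfg))
  expect_false(passes_structural_filter(fake(0.9, 0.69), cfg))
})

test_that("structure resolution prefers direct models, then qualifying proxies", {
  set.seed(26)
  cfg <- pipeline_config()
  base <- random_aa_string(100)
  cand <- seq_record("cand", base)
  model <- make_helix(100, id = "cand")
  direct <- resolve_structure(cand, list(cand = model), list(), cfg)
  expect_equal(direct$structure_source, "direct")

  # proxy at 96% identity qualifies; best identity below 95% does not
  mut <- function(s, k, id) {
    chars <- strsplit(s, "")[[1]]
    pos <- sample(length(chars), k)
    for (p in pos) chars[p] <- setdiff(c("A", "C", "D", "E"), chars[p])[1]
    seq_record(id, paste(chars, collapse = ""))
  }
  proxy96 <- mut(base, 4, "proxy96")
  proxy90 <- mut(base, 10, "proxy90")
  idx <- list(proxy96 = make_helix(100, id = "proxy96"),
              proxy90 = make_helix(100, id = "proxy90"))
  res <- resolve_structure(cand, idx["proxy96"], list(proxy96), cfg)
  expect_equal(res$structure_source, "proxy")
  expect_equal(res$proxy_id, "proxy96")
  expect_gte(res$proxy_identity, cfg$proxy_identity_min)

  none <- resolve_structure(cand, idx["proxy90"], list(proxy90), cfg)
  expect_equal(none$structure_source, "none")
  expect_equal(none$reason, "no model")
  # the better proxy wins when both qualify
  both <- resolve_structure(cand, idx, list(proxy96, proxy90), cfg)
  expect_equal(both$proxy_id, "proxy96")
})
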