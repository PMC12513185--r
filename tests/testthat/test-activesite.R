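# hand-built model: one CA atom per residue at given coordinates, plus an
# optional ligand; aa defaults to "A"
point_model <- function(ca_xyz, ligand_xyz = NULL, lig_elements = "C",
                        lig_code = "LIG", aa = NULL, id = "toy") {
  n <- nrow(ca_xyz)
  if (is.null(aa)) aa <- rep("A", n)
  atoms <- data.frame(name = "CA", element = "C", resno = seq_len(n),
                      icode = "", resname = "ALA", aa = aa,
                      x = ca_xyz[, 1], y = ca_xyz[, 2], z = ca_xyz[, 3],
                      occupancy = 1, stringsAsFactors = FALSE)
  ligands <- list()
  if (!is.null(ligand_xyz)) {
    ligands <- list(list(het_code = lig_code, resno = n + 10L,
                         atoms = data.frame(
                           name = paste0(lig_elements, seq_len(nrow(ligand_xyz))),
                           element = rep_len(lig_elements, nrow(ligand_xyz)),
                           x = ligand_xyz[, 1], y = ligand_xyz[, 2],
                           z = ligand_xyz[, 3], stringsAsFactors = FALSE)))
  }
  structure_model(id, "A", atoms, ligands)
}

test_that("contact extraction uses an inclusive any-heavy-atom cutoff", {
  # residues at 4.9, 5.0, 5.1 and 0 A from a single ligand atom at origin
  ca <- rbind(c(4.9, 0, 0), c(0, 5.0, 0), c(0, 0, 5.1), c(0, 0, 0))
  m <- point_model(ca, ligand_xyz = rbind(c(0, 0, 0)))
  hits <- extract_contact_residues(m, "LIG", cutoff = 5.0)
  expect_equal(hits$position, c(1, 2, 4))
  expect_equal(hits$min_ligand_distance, c(4.9, 5.0, 0))
})

test_that("contact extraction names available ligands when the code is absent", {
  m <- point_model(rbind(c(0, 0, 0)), ligand_xyz = rbind(c(1, 0, 0)))
  expect_error(extract_contact_residues(m, "PHE"), "LIG")
})

test_that("planted pockets agree exactly with a brute-force distance scan", {
  set.seed(31)
  h <- make_helix(50, id = "pocket")
  planted <- c(7, 19, 31, 38, 44)
  p <- plant_pocket(h, "LIG", planted)
  got <- extract_contact_residues(p, "LIG", 5.0)
  expect_equal(got$position, planted)
  expect_equal(oracle_contact_positions(p, "LIG", 5.0), planted)
})

test_that("polar backbone contacts use the N/O donor-acceptor cutoff", {
  # residue 1 backbone O at 3.0 A from a ligand N -> flagged;
  # residue 2 backbone O at 4.0 A -> not flagged
  atoms <- data.frame(
    name = c("CA", "O", "CA", "O"), element = c("C", "O", "C", "O"),
    resno = c(1L, 1L, 2L, 2L), icode = "", resname = "ALA", aa = "A",
    x = c(0, 1, 20, 21), y = 0, z = 0, occupancy = 1,
    stringsAsFactors = FALSE)
  lig <- list(list(het_code = "LIG", resno = 50L,
                   atoms = data.frame(name = c("N1", "C2"),
                                      element = c("N", "C"),
                                      x = c(4, 22), y = 0, z = 0,
                                      stringsAsFactors = FALSE)))
  m <- structure_model("polar", "A", atoms, lig)
  expect_equal(find_polar_backbone_contacts(m, "LIG", 3.5), 1L)
  # carbon ligand atoms never create polar contacts even when close
  expect_equal(extract_contact_residues(m, "LIG", 5)$position, c(1L, 2L))
})

test_that("two planted polar contacts are recovered exactly", {
  atoms <- data.frame(
    name = rep(c("CA", "O"), 5), element = rep(c("C", "O"), 5),
    resno = rep(1:5, each = 2), icode = "", resname = "ALA", aa = "A",
    x = rep(20 * (0:4), each = 2) + rep(c(0, 1), 5), y = 0, z = 0,
    occupancy = 1, stringsAsFactors = FALSE)
  lig <- list(list(het_code = "LIG", resno = 90L,
                   atoms = data.frame(
                     name = c("N1", "O2"), element = c("N", "O"),
                     x = c(1 + 2.8, 61 + 3.2), y = 0, z = 0,
                     stringsAsFactors = FALSE)))
  m <- structure_model("polar2", "A", atoms, lig)
  expect_equal(find_polar_backbone_contacts(m, "LIG", 3.5), c(1L, 4L))
})

test_that("site mapping is the identity when seed equals the reference", {
  h <- make_helix(40, id = "ref")
  ref <- plant_pocket(h, "LIG", c(10, 20, 30))
  sites <- extract_contact_residues(ref, "LIG", 5.0)
  seed <- make_helix(40, id = "seed")
  mapped <- map_sites_to_seed(ref, seed, sites)
  expect_equal(mapped$position, c(10, 20, 30))
  expect_equal(mapped$mapping_distance, rep(0, 3), tolerance = 1e-9)
  # order-preserving: increasing reference positions map increasingly
  expect_true(all(diff(mapped$position) > 0))
})

test_that("site mapping follows author renumbering and rigid motion", {
  h <- make_helix(40, id = "ref")
  ref <- plant_pocket(h, "LIG", c(10, 20, 30))
  sites <- extract_contact_residues(ref, "LIG", 5.0)
  seed_at <- h$atoms
  seed_at$resno <- seed_at$resno + 100L
  seed <- rigid_move_model(structure_model("seed", "A", seed_at))
  mapped <- map_sites_to_seed(ref, seed, sites)
  expect_equal(mapped$position, c(110, 120, 130))
})

test_that("site transfer on the seed itself is the identity", {
  set.seed(32)
  seed <- seq_record("seed", random_aa_string(60))
  chars <- strsplit(seed$residues, "")[[1]]
  prof <- active_site_profile("ref", "LIG", data.frame(
    position = c(12, 25, 40), aa = chars[c(12, 25, 40)],
    min_ligand_distance = c(3, 4, 4.5), polar_backbone_contact = FALSE,
    stringsAsFactors = FALSE))
  cmp <- transfer_sites_to_candidate(seed, seed, prof)
  expect_equal(cmp$status, "identical")
  expect_equal(cmp$n_identical, 3)
  expect_equal(cmp$mapped$cand_position, c(12, 25, 40))
})

test_that("site transfer classifies substitutions and deletions", {
  set.seed(33)
  seed <- seq_record("seed", random_aa_string(40))
  chars <- strsplit(seed$residues, "")[[1]]
  pos <- c(10, 20, 30)
  prof <- active_site_profile("ref", "LIG", data.frame(
    position = pos, aa = chars[pos], min_ligand_distance = 4,
    polar_backbone_contact = FALSE, stringsAsFactors = FALSE))

  sub_chars <- chars
  sub_chars[20] <- setdiff(c("W", "H", "M"),
                           sub_chars[c(15:25)])[1]  # locally unique letter
  sub <- seq_record("sub", paste(sub_chars, collapse = ""))
  cmp <- transfer_sites_to_candidate(seed, sub, prof)
  expect_equal(cmp$status, "substituted")
  expect_equal(cmp$n_substituted, 1)
  expect_equal(cmp$n_identical, 2)

  # 3-residue deletion spanning profile position 20
  del <- seq_record("del", paste(chars[-(19:21)], collapse = ""))
  cmp2 <- transfer_sites_to_candidate(seed, del, prof)
  expect_equal(cmp2$status, "deleted_positions")
  expect_equal(cmp2$n_deleted, 1)
  expect_equal(cmp2$n_identical, 2)
  expect_true(is.na(cmp2$mapped$cand_position[2]))
})

test_that("profile/seed inconsistency is reported with the position", {
  seed <- seq_record("seed", "ACDEFGHIKL")
  prof <- active_site_profile("ref", "LIG", data.frame(
    position = 3, aa = "W", min_ligand_distance = 4,
    polar_backbone_contact = FALSE, stringsAsFactors = FALSE))
  expect_error(transfer_sites_to_candidate(seed, seed, prof), "position 3")
})

test_that("substitutions outside the profile never break an identical site", {
  set.seed(34)
  seed <- seq_record("seed", random_aa_string(80))
  chars <- strsplit(seed$residues, "")[[1]]
  pos <- c(15, 35, 55)
  prof <- active_site_profile("ref", "LIG", data.frame(
    position = pos, aa = chars[pos], min_ligand_distance = 4,
    polar_backbone_contact = FALSE, stringsAsFactors = FALSE))
  non_site <- setdiff(5:75, pos)
  for (i in 1:25) {
    mut <- chars
    for (p in sample(non_site, 6)) {
      mut[p] <- sample(setdiff(c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                                 "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                                 "W", "Y"), mut[max(1, p - 5):min(80, p + 5)]), 1)
    }
    cand <- seq_record("cand", paste(mut, collapse = ""))
    cmp <- transfer_sites_to_candidate(seed, cand, prof)
    expect_equal(cmp$status, "identical")
  }
})

test_that("multi-domain profiles repeat per window and shift with the domain", {
  h <- make_helix(60, id = "ref")
  ref <- plant_pocket(h, "LIG", c(15, 30, 45))
  cfg <- pipeline_config()

  # one window covering the whole chain: identical to the single-domain path
  single <- multi_domain_profiles(make_helix(60, id = "seed"), ref, "LIG",
                                  list(c(1, 60)), cfg)
  expect_length(single, 1)
  expect_equal(single[[1]]$residues$position, c(15, 30, 45))
  expect_true(single[[1]]$residues$polar_backbone_contact[1] %in% c(TRUE, FALSE))

  # two concatenated copies of the fold: second-domain positions shift by 60
  a1 <- h$atoms
  a2 <- h$atoms
  a2$resno <- a2$resno + 60L
  a2$x <- a2$x + 150
  two_dom <- structure_model("twodom", "A", rbind(a1, a2))
  profs <- multi_domain_profiles(two_dom, ref, "LIG",
                                 list(c(1, 60), c(61, 120)), cfg)
  expect_length(profs, 2)
  expect_equal(profs[[1]]$residues$position, c(15, 30, 45))
  expect_equal(profs[[2]]$residues$position, c(75, 90, 105))

  expect_error(multi_domain_profiles(two_dom, ref, "LIG",
                                     list(c(1, 70), c(61, 120)), cfg),
               "overlap")
})
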