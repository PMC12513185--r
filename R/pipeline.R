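#' Run the full structure-filtered candidate search
#'
#' Applies, in order: greedy redundancy clustering (representatives
#' proceed), the sequence-length window, structure resolution (direct model
#' or \eqn{\ge}95\%-identity proxy), the global structural filter (TM-score
#' band and seed coverage), active-site transfer, and priority ranking.
#' Every eliminated candidate keeps its elimination reason, and the stage
#' counts telescope in the returned manifest.
#'
#' @param seed_seq the seed [seq_record()]
#' @param seed_model the seed's [structure_model()]
#' @param ref_complex ligand-bound reference [structure_model()] supplying
#'   the substrate-contact residues
#' @param candidates list of candidate [seq_record()]s (unique ids)
#' @param models named list id -> [structure_model()] of available models
#' @param cfg a [pipeline_config()]
#' @param ligand_code HETATM code of the substrate in `ref_complex`;
#'   default: the code of its first ligand group
#' @param proxy_pool optional list of [seq_record()]s with models (ids in
#'   `models`) that may lend proxy structures
#' @param domain_windows optional list of `c(from, to)` author-number
#'   windows for multi-domain seeds; default: one window covering the seed
#' @return a list with `verdicts` (data frame, one row per candidate,
#'   ordered by priority class then rank) and `manifest` (config snapshot,
#'   telescoping stage counts, input inventory)
#' @export
run_pipeline <- function(seed_seq, seed_model, ref_complex, candidates,
                         models, cfg = pipeline_config(), ligand_code = NULL,
                         proxy_pool = list(), domain_windows = NULL) {
  stopifnot(inherits(seed_seq, "seq_record"),
            inherits(seed_model, "structure_model"),
            inherits(ref_complex, "structure_model"),
            inherits(cfg, "pipeline_config"))
  check_unique_ids(candidates)
  if (is.null(ligand_code)) {
    if (!length(ref_complex$ligands))
      stop("reference complex carries no ligand and no ligand_code was given")
    ligand_code <- ref_complex$ligands[[1]]$het_code
  }
  if (is.null(domain_windows))
    domain_windows <- list(range(seed_model$residues$resno))

  # active-site profile(s), anchored on the seed numbering
  profiles <- multi_domain_profiles(seed_model, ref_complex, ligand_code,
                                    domain_windows, cfg)
  profiles <- lapply(profiles, function(p) {
    active_site_profile(p$anchor_structure_id, p$ligand_code, p$residues)
  })

  ids <- vapply(candidates, `[[`, character(1), "id")
  v <- data.frame(
    cand_id = ids, priority_class = 3L, rank = NA_integer_,
    passed_redundancy = FALSE, cluster_rep = NA_character_,
    passed_length = NA, has_structure = NA, structure_source = NA_character_,
    proxy_id = NA_character_, proxy_identity = NA_real_,
    passed_structural = NA, tm_score = NA_real_, seed_coverage = NA_real_,
    site_status = NA_character_, n_identical = NA_integer_,
    n_substituted = NA_integer_, n_deleted = NA_integer_,
    reason = NA_character_, stringsAsFactors = FALSE)
  rownames(v) <- ids

  # stage 1: redundancy clustering; representatives proceed
  clusters <- greedy_cluster(candidates, cfg$redundancy_identity, cfg)
  reps <- cluster_representatives(clusters)
  v$cluster_rep <- unname(clusters$assignment[ids])
  v$passed_redundancy <- ids %in% reps
  v$reason[!v$passed_redundancy] <-
    paste0("redundant (clustered with ", v$cluster_rep[!v$passed_redundancy], ")")
  stage1 <- candidates[match(reps, ids)]

  # stage 2: sequence-length window
  stage2 <- filter_by_length(stage1, cfg$length_min, cfg$length_max)
  ids1 <- vapply(stage1, `[[`, character(1), "id")
  ids2 <- vapply(stage2, `[[`, character(1), "id")
  v[ids1, "passed_length"] <- ids1 %in% ids2
  v$reason[rownames(v) %in% setdiff(ids1, ids2)] <- "length outside window"

  # stage 3: structure resolution (direct model or proxy)
  resolutions <- lapply(stage2, resolve_structure, model_index = models,
                        proxy_pool = proxy_pool, cfg = cfg)
  for (r in resolutions) {
    v[r$cand_id, "has_structure"] <- r$structure_source != "none"
    v[r$cand_id, "structure_source"] <- r$structure_source
    v[r$cand_id, "proxy_id"] <- r$proxy_id
    v[r$cand_id, "proxy_identity"] <- r$proxy_identity
    if (r$structure_source == "none") v[r$cand_id, "reason"] <- r$reason
  }
  stage3 <- resolutions[vapply(resolutions, function(r)
    r$structure_source != "none", logical(1))]

  # stage 4: global structural similarity
  survivors <- character()
  for (r in stage3) {
    aln <- align_structures(seed_model, r$model, cfg)
    ok <- passes_structural_filter(aln, cfg)
    v[r$cand_id, "tm_score"] <- aln$tm_score
    v[r$cand_id, "seed_coverage"] <- aln$seed_coverage
    v[r$cand_id, "passed_structural"] <- ok
    if (!ok) {
      v[r$cand_id, "reason"] <- sprintf(
        "structurally dissimilar (tm %.3f, coverage %.3f)",
        aln$tm_score, aln$seed_coverage)
    } else {
      survivors <- c(survivors, r$cand_id)
    }
  }

  # stage 5: active-site transfer on all structural survivors
  for (cid in survivors) {
    cand <- candidates[[match(cid, ids)]]
    comps <- lapply(profiles, function(p)
      transfer_sites_to_candidate(seed_seq, cand, p, cfg$align_scoring))
    n_id <- sum(vapply(comps, `[[`, integer(1), "n_identical"))
    n_sub <- sum(vapply(comps, `[[`, integer(1), "n_substituted"))
    n_del <- sum(vapply(comps, `[[`, integer(1), "n_deleted"))
    status <- if (n_del > 0) "deleted_positions"
    else if (n_sub > 0) "substituted" else "identical"
    v[cid, c("n_identical", "n_substituted", "n_deleted")] <-
      list(n_id, n_sub, n_del)
    v[cid, "site_status"] <- status
    v[cid, "priority_class"] <- if (status == "identical") 1L else 2L
    if (status != "identical")
      v[cid, "reason"] <- paste0("active site not identical (", status, ")")
  }

  v <- rank_candidates(v)
  counts <- list(
    n_input = length(candidates),
    n_nonredundant = length(stage1),
    n_length_pass = length(stage2),
    n_with_structure = length(stage3),
    n_structural_pass = length(survivors),
    n_class1 = sum(v$priority_class == 1L),
    n_class2 = sum(v$priority_class == 2L),
    n_class3 = sum(v$priority_class == 3L))
  manifest <- list(
    config = unclass(cfg)[setdiff(names(unclass(cfg)), "align_scoring")],
    align_scoring = unclass(cfg$align_scoring),
    ligand_code = ligand_code,
    seed_id = seed_seq$id, seed_length = seed_seq$length,
    seed_model_id = seed_model$id, ref_complex_id = ref_complex$id,
    domain_windows = domain_windows,
    n_profiles = length(profiles),
    profile_positions = lapply(profiles, function(p) p$residues$position),
    counts = counts,
    candidate_ids = ids,
    package_version = as.character(utils::packageVersion("structfilter")))
  list(verdicts = v, manifest = manifest)
}

#' Assign priority classes and ranks to a verdict table
#'
#' Class 1: passed the structural filter with an identical active-site
#' residue composition; class 2: passed the structural filter with a
#' substituted or deleted site; class 3: eliminated earlier. Within each
#' class candidates are ordered by seed coverage descending, then TM-score
#' descending, then id ascending; ranks restart at 1 within each class.
#'
#' @param verdicts verdict data frame (as built by [run_pipeline()])
#' @return the data frame ordered by class and rank, with `priority_class`
#'   and `rank` filled in
#' @export
rank_candidates <- function(verdicts) {
  stopifnot(is.data.frame(verdicts), "cand_id" %in% names(verdicts))
  v <- verdicts
  if (!"priority_class" %in% names(v) || any(is.na(v$priority_class))) {
    ok <- !is.na(v$passed_structural) & v$passed_structural
    v$priority_class <- ifelse(ok & !is.na(v$site_status) &
                                 v$site_status == "identical", 1L,
                               ifelse(ok, 2L, 3L))
  }
  cov <- ifelse(is.na(v$seed_coverage), -Inf, v$seed_coverage)
  tm <- ifelse(is.na(v$tm_score), -Inf, v$tm_score)
  ord <- order(v$priority_class, -cov, -tm, v$cand_id)
  v <- v[ord, , drop = FALSE]
  v$rank <- stats::ave(seq_len(nrow(v)), v$priority_class,
                       FUN = seq_along)
  rownames(v) <- v$cand_id
  v
}
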