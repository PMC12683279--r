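# helper: brute-force recount of time-point detections for one triple
count_tp_detections <- function(presence, md, subj, site, fam) {
  rows <- md[md$sample_class == "skin" & md$subject_id == subj & md$site == site, ]
  sum(vapply(unique(rows$time_point), function(tp) {
    ids <- rows$sample_id[rows$time_point == tp]
    any(presence[fam, ids] > 0)
  }, logical(1)))
}

test_that("site_stability counts time points and applies the 2-of-3 rule", {
  md <- design_metadata(n_subjects = 1)
  pres <- matrix(0, 2, nrow(md),
                 dimnames = list(c("famA", "famB"), md$sample_id))
  # famA on the forehead at t0 and t2 -> stable; famB at t1 only -> not
  pres["famA", c("S1_forehead_t0", "S1_forehead_t2")] <- 1
  pres["famB", "S1_forehead_t1"] <- 1
  calls <- site_stability(pres, md, min_timepoints = 2)
  fh <- calls[calls$site == "forehead", ]
  expect_true(fh$stable[fh$family == "famA"])
  expect_identical(fh$n_timepoints_detected[fh$family == "famA"], 2L)
  expect_false(fh$stable[fh$family == "famB"])

  # counting oracle on random presence over the full design
  md <- design_metadata(n_subjects = 3)
  set.seed(20)
  pres <- matrix(rbinom(5 * nrow(md), 1, 0.5), 5, nrow(md),
                 dimnames = list(paste0("fam", 1:5), md$sample_id))
  calls <- site_stability(pres, md, min_timepoints = 2)
  expect_identical(nrow(calls), 3L * 3L * 5L)
  for (k in sample(nrow(calls), 20)) {
    row <- calls[k, ]
    n <- count_tp_detections(pres, md, row$subject_id, row$site, row$family)
    expect_identical(row$n_timepoints_detected, as.integer(n))
    expect_identical(row$stable, n >= 2)
  }
})

test_that("stable_families applies the all-three-sites rule per subject", {
  grid <- expand.grid(subject_id = c("S1", "S3"),
                      site = c("forehead", "left_hand", "right_hand"),
                      family = c("famX", "famY"), stringsAsFactors = FALSE)
  grid$n_timepoints_detected <- 2L
  # famX stable at all sites for S3 only; famY at two sites per subject
  grid$stable <- with(grid, (family == "famX" & subject_id == "S3") |
                        (family == "famY" & site != "forehead"))
  expect_identical(stable_families(grid, min_subjects = 1), "famX")
  expect_identical(stable_families(grid, min_subjects = 2), character(0))
  # relaxed mode: famY has a stable subject at only two of three sites
  expect_identical(stable_families(grid, require_all_sites = FALSE), "famX")
  expect_identical(stable_families(grid[0, ]), character(0))
})

test_that("transmissible_families applies the 2-of-4 rule with host anchoring", {
  md <- design_metadata(n_subjects = 2)
  pres <- matrix(0, 2, nrow(md),
                 dimnames = list(c("famA", "famB"), md$sample_id))
  # famA: S2 cell phone + fabric, and on S2 skin -> transmissible
  pres["famA", c("S2_cell_phone", "S2_fabric", "S2_forehead_t0")] <- 1
  # famB: door handle only -> not transmissible
  pres["famB", c("S1_door_handle", "S1_forehead_t0")] <- 1
  res <- transmissible_families(pres, md)
  expect_identical(res$families, "famA")
  calls <- res$calls
  expect_identical(
    calls$n_objects_detected[calls$subject_id == "S2" & calls$family == "famA"], 2L)
  expect_false(any(calls$transmissible[calls$family == "famB"]))

  # host anchoring: famA absent from S2 skin fails host_required
  pres["famA", "S2_forehead_t0"] <- 0
  expect_identical(transmissible_families(pres, md)$families, character(0))
  expect_identical(
    transmissible_families(pres, md, host_required = FALSE)$families, "famA")

  # counting oracle on random data
  set.seed(30)
  pres <- matrix(rbinom(4 * nrow(md), 1, 0.4), 4, nrow(md),
                 dimnames = list(paste0("fam", 1:4), md$sample_id))
  res <- transmissible_families(pres, md, host_required = FALSE)
  obj_md <- md[md$sample_class == "object", ]
  for (k in seq_len(nrow(res$calls))) {
    row <- res$calls[k, ]
    ids <- obj_md$sample_id[obj_md$subject_id == row$subject_id]
    n <- sum(vapply(ids, function(id) pres[row$family, id] > 0, logical(1)))
    expect_identical(row$n_objects_detected, as.integer(n))
  }
})

test_that("object_transfer_profile tallies per-object proportions", {
  md <- design_metadata(n_subjects = 2)
  pres <- matrix(0, 2, nrow(md),
                 dimnames = list(c("famA", "famB"), md$sample_id))
  pres["famA", c("S1_door_handle", "S2_door_handle")] <- 1
  pres["famB", c("S1_cell_phone", "S1_plastic", "S2_plastic")] <- 1
  calls <- data.frame(subject_id = "S1", family = c("famA", "famB"),
                      n_objects_detected = 1:2,
                      transmissible = c(TRUE, TRUE))
  prof <- object_transfer_profile(calls, pres, md)
  expect_equal(prof["famA", ], c(cell_phone = 0, door_handle = 1,
                                 fabric = 0, plastic = 0))
  expect_equal(prof["famB", "fabric"], 0)    # never on fabric
  expect_equal(unname(rowSums(prof)), c(1, 1))
  expect_equal(prof["famB", "plastic"], 2 / 3)
})

test_that("select_markers intersects sets and collects detected species", {
  tax <- data.frame(
    taxon_id = c("s1", "s2", "s3"), species = c("s1", "s2", "s3"),
    family = c("B", "B", "A"), higher_rank = "x", stringsAsFactors = FALSE
  )
  pres <- matrix(1, 3, 2, dimnames = list(c("s1", "s2", "s3"), c("k1", "k2")))
  res <- select_markers(c("A", "B"), c("B", "C"), pres, tax)
  expect_identical(res$marker_families, "B")
  expect_identical(res$marker_species, c("s1", "s2"))

  # undetected species of a marker family are excluded
  pres["s2", ] <- 0
  expect_identical(select_markers(c("A", "B"), c("B", "C"), pres, tax)$marker_species,
                   "s1")
  expect_warning(res0 <- select_markers("A", "C", pres, tax), "do not intersect")
  expect_length(res0$marker_families, 0)
})

test_that("occurrence_matrix reports relative occurrence percentages", {
  md <- design_metadata(n_subjects = 2)
  pres <- matrix(0, 2, nrow(md),
                 dimnames = list(c("sp1", "sp2"), md$sample_id))
  skin1 <- md$sample_id[md$subject_id == "S1" & md$sample_class == "skin"]
  pres["sp1", skin1] <- 1                       # 9 of 9 skin samples
  pres["sp2", "S2_fabric"] <- 1                 # 1 of 4 objects
  occ <- occurrence_matrix(pres, md, c("sp1", "sp2"))
  expect_equal(occ$skin["S1", "sp1"], 100)
  expect_equal(occ$skin["S2", "sp1"], 0)
  expect_equal(occ$objects["S2", "sp2"], 25)
  expect_equal(occ$objects["S1", "sp2"], 0)

  # brute-force per-cell tally on random data
  set.seed(40)
  pres <- matrix(rbinom(3 * nrow(md), 1, 0.5), 3, nrow(md),
                 dimnames = list(paste0("sp", 1:3), md$sample_id))
  occ <- occurrence_matrix(pres, md, paste0("sp", 1:3))
  for (subj in c("S1", "S2")) for (sp in paste0("sp", 1:3)) {
    ids <- md$sample_id[md$subject_id == subj & md$sample_class == "skin"]
    expect_equal(occ$skin[subj, sp], 100 * mean(pres[sp, ids] > 0))
  }
  expect_error(occurrence_matrix(pres, md, character(0)), "non-empty")
})

test_that("within/between comparisons match hand computation", {
  md <- rbind(meta_row("a1", "A"), meta_row("a2", "A", site = "left_hand"),
              meta_row("b1", "B"), meta_row("b2", "B", site = "left_hand"))
  d <- matrix(0, 4, 4, dimnames = list(md$sample_id, md$sample_id))
  d["a1", "a2"] <- d["a2", "a1"] <- 0.2
  d["b1", "b2"] <- d["b2", "b1"] <- 0.4
  cross <- rbind(c(0.7, 0.8), c(0.9, 1.0))
  d[c("a1", "a2"), c("b1", "b2")] <- cross
  d[c("b1", "b2"), c("a1", "a2")] <- t(cross)
  wb <- within_between_skin(d, md)
  expect_equal(wb$per_subject_within, c(A = 0.2, B = 0.4))
  expect_equal(wb$per_subject_between, c(A = mean(cross), B = mean(cross)))

  # all-identical samples: within = between = 0, Wilcoxon p = 1
  d0 <- matrix(0, 4, 4, dimnames = dimnames(d))
  wb0 <- within_between_skin(d0, md)
  expect_equal(unname(wb0$per_subject_within), c(0, 0))
  expect_equal(wb0$wilcoxon$p_value, 1)

  # subjects lacking two samples are dropped with a warning
  md1 <- rbind(md[1:3, ])
  expect_warning(wb1 <- within_between_skin(d[1:3, 1:3], md1), "dropped")
  expect_named(wb1$per_subject_within, "A")
})

test_that("signature-world within-subject distances fall below between", {
  st <- generate_study(study_config(detection_prob = 0.95, transfer_prob = 0.9,
                                    seed = 60))
  rep <- run_marker_analysis(st$table, st$taxonomy, st$metadata,
                             marker_config(seed = 1))
  for (cmp in list(rep$skin_comparison, rep$object_comparison)) {
    expect_true(all(cmp$per_subject_within < cmp$per_subject_between))
    expect_lt(cmp$wilcoxon$p_value, 0.01)
  }
})

test_that("run_marker_analysis handles degenerate inputs and echoes config", {
  empty <- matrix(0, 0, 0, dimnames = list(character(0), character(0)))
  md <- design_metadata(1)
  tax <- simple_taxonomy(character(0))
  expect_warning(rep <- run_marker_analysis(empty, tax, md), "empty")
  expect_length(rep$marker_families, 0)
  expect_null(rep$skin_comparison)

  cfg <- marker_config(min_timepoints = 3, min_objects = 4, seed = 9)
  st <- generate_study(noiseless_config(2))
  rep <- run_marker_analysis(st$table, st$taxonomy, st$metadata, cfg)
  expect_identical(rep$config$min_timepoints, 3L)
  expect_identical(rep$config$min_objects, 4L)
  expect_identical(rep$config$seed, 9L)
})

test_that("marker sets are contained in both parent sets and reports serialize", {
  st <- generate_study(study_config(seed = 71))
  rep <- run_marker_analysis(st$table, st$taxonomy, st$metadata,
                             marker_config(seed = 1))
  expect_true(all(rep$marker_families %in% rep$stable_families))
  expect_true(all(rep$marker_families %in% rep$transmissible_families))
  fam_of <- setNames(st$taxonomy$family, st$taxonomy$species)
  expect_true(all(fam_of[rep$marker_species] %in% rep$marker_families))
  expect_true(all(rep$occurrence$skin >= 0 & rep$occurrence$skin <= 100))

  path <- withr::local_tempfile(fileext = ".json")
  write_marker_report(rep, path)
  back <- read_marker_report(path)
  expect_identical(unlist(back$marker_families), rep$marker_families)
  expect_identical(unlist(back$marker_species), rep$marker_species)
  expect_equal(back$skin_comparison$wilcoxon$p_value,
               rep$skin_comparison$wilcoxon$p_value)
  expect_identical(back$config$min_timepoints, 2L)
})

test_that("raising thresholds never enlarges the selected family sets", {
  for (seed in 1:5) {
    st <- generate_study(study_config(detection_prob = 0.7,
                                      transfer_prob = 0.6, seed = 100 + seed))
    pres <- remove_control_taxa(binarize(st$table, 1), st$metadata)
    fam <- (aggregate_to_rank(pres, st$taxonomy, "family") > 0) * 1
    prev_stable <- NULL
    for (mt in 1:3) {
      calls <- site_stability(fam, st$metadata, min_timepoints = mt)
      stab <- stable_families(calls)
      if (!is.null(prev_stable)) expect_true(all(stab %in% prev_stable))
      prev_stable <- stab
    }
    prev_trans <- NULL
    for (mo in 1:4) {
      tr <- transmissible_families(fam, st$metadata, min_objects = mo)
      if (!is.null(prev_trans)) expect_true(all(tr$families %in% prev_trans))
      prev_trans <- tr$families
    }
  }
})
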