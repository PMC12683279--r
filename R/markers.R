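#' Per-site temporal stability calls
#'
#' For every (subject, anatomical site, family) combination among skin
#' samples, counts the number of sampling time points at which the family was
#' detected and flags it stable when the count reaches `min_timepoints`
#' (default 2 of the 3 visits). A family detected in any sample of a
#' (subject, site, time point) cell counts as detected at that time point.
#'
#' @param presence binary matrix at family rank (families x samples).
#' @param metadata validated metadata; only skin samples are used.
#' @param min_timepoints detections required for stability (default 2).
#' @return data.frame with columns `subject_id`, `site`, `family`,
#'   `n_timepoints_detected`, `stable`.
#' @export
site_stability <- function(presence, metadata, min_timepoints = 2L) {
  validate_abundance_table(presence)
  metadata <- validate_metadata(metadata)
  if (min_timepoints < 1) vm_validation_stop("`min_timepoints` must be >= 1")
  skin <- metadata[metadata$sample_class == "skin" &
                     metadata$sample_id %in% colnames(presence), ]
  out <- list()
  for (subj in unique(skin$subject_id)) {
    for (site in setdiff(unique(skin$site[skin$subject_id == subj]), NONE)) {
      rows <- skin[skin$subject_id == subj & skin$site == site, ]
      tps <- unique(rows$time_point)
      if (!length(tps)) {
        vm_warn("subject ", subj, " site ", site, " has no time points; skipped")
        next
      }
      # detected at a time point if any sample of that cell detects it
      det <- vapply(tps, function(tp) {
        ids <- rows$sample_id[rows$time_point == tp]
        rowSums(presence[, ids, drop = FALSE] > 0) > 0
      }, logical(nrow(presence)))
      n_det <- rowSums(matrix(det, nrow = nrow(presence)))
      out[[length(out) + 1L]] <- data.frame(
        subject_id = subj, site = site, family = rownames(presence),
        n_timepoints_detected = as.integer(n_det),
        stable = n_det >= min_timepoints,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  if (!length(out)) {
    return(data.frame(subject_id = character(0), site = character(0),
                      family = character(0),
                      n_timepoints_detected = integer(0),
                      stable = logical(0)))
  }
  do.call(rbind, out)
}

#' Select temporally stable families from stability calls
#'
#' Default (strict) semantics: a family qualifies when at least
#' `min_subjects` subjects are each stable for it at *all three* of their
#' anatomical sites. The relaxed mode (`require_all_sites = FALSE`) instead
#' requires, for every site, at least `min_subjects` subjects stable at that
#' site — possibly different subjects per site.
#'
#' @param calls output of [site_stability()].
#' @param require_all_sites strict per-subject all-sites rule (default TRUE).
#' @param min_subjects subjects required (default 1).
#' @return Sorted character vector of family labels.
#' @export
stable_families <- function(calls, require_all_sites = TRUE, min_subjects = 1L) {
  if (!nrow(calls)) return(character(0))
  sites <- setdiff(SITES, NONE)
  fams <- unique(calls$family)
  keep <- vapply(fams, function(fam) {
    sub <- calls[calls$family == fam & calls$stable, ]
    if (require_all_sites) {
      per_subject <- tapply(sub$site, sub$subject_id,
                            function(s) all(sites %in% s))
      sum(unlist(per_subject)) >= min_subjects
    } else {
      all(vapply(sites, function(s) {
        length(unique(sub$subject_id[sub$site == s])) >= min_subjects
      }, logical(1)))
    }
  }, logical(1))
  sort(fams[keep])
}

#' Skin-to-object transmissibility calls and family selection
#'
#' For each subject, counts on how many of their contacted object types a
#' family was detected. A family is transmissible for a subject when the
#' count reaches `min_objects` (default 2 of the 4 objects) and — when
#' `host_required` (default) — the family is also detected somewhere on that
#' subject's own skin, so that the transfer is anchored to the host's virome.
#' A family is selected when at least `min_subjects` subjects show
#' transmissibility.
#'
#' @param presence binary matrix at family rank covering skin and object
#'   samples.
#' @param metadata validated metadata.
#' @param min_objects object types required (default 2).
#' @param min_subjects subjects required (default 1).
#' @param host_required require detection on the subject's skin (default TRUE).
#' @return List with `families` (sorted character vector) and `calls`
#'   (data.frame `subject_id`, `family`, `n_objects_detected`,
#'   `transmissible`).
#' @export
transmissible_families <- function(presence, metadata, min_objects = 2L,
                                   min_subjects = 1L, host_required = TRUE) {
  validate_abundance_table(presence)
  metadata <- validate_metadata(metadata)
  if (min_objects < 1) vm_validation_stop("`min_objects` must be >= 1")
  obj <- metadata[metadata$sample_class == "object" &
                    metadata$sample_id %in% colnames(presence), ]
  skin <- metadata[metadata$sample_class == "skin" &
                     metadata$sample_id %in% colnames(presence), ]
  out <- list()
  for (subj in unique(obj$subject_id)) {
    rows <- obj[obj$subject_id == subj, ]
    otypes <- unique(rows$object_type)
    if (length(otypes) < 4L) {
      vm_warn("subject ", subj, " has ", length(otypes),
              " object types; counting over those available")
    }
    det <- vapply(otypes, function(ot) {
      ids <- rows$sample_id[rows$object_type == ot]
      rowSums(presence[, ids, drop = FALSE] > 0) > 0
    }, logical(nrow(presence)))
    n_det <- rowSums(matrix(det, nrow = nrow(presence)))
    trans <- n_det >= min_objects
    if (host_required) {
      skin_ids <- skin$sample_id[skin$subject_id == subj]
      on_skin <- rowSums(presence[, skin_ids, drop = FALSE] > 0) > 0
      trans <- trans & on_skin
    }
    out[[length(out) + 1L]] <- data.frame(
      subject_id = subj, family = rownames(presence),
      n_objects_detected = as.integer(n_det), transmissible = trans,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  calls <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(subject_id = character(0), family = character(0),
               n_objects_detected = integer(0), transmissible = logical(0))
  }
  n_subj <- tapply(calls$transmissible, calls$family, sum)
  fams <- sort(names(n_subj)[!is.na(n_subj) & n_subj >= min_subjects])
  list(families = fams, calls = calls)
}

#' Per-family object-type transfer profile
#'
#' For each transmissible family, the proportion of its object detections
#' (pooled over subjects) attributable to each of the four object types.
#' Rows sum to 1 for families detected on at least one object.
#'
#' @param calls `calls` component of [transmissible_families()] — defines the
#'   family rows (transmissible for >= 1 subject).
#' @param presence binary family-rank matrix.
#' @param metadata validated metadata.
#' @return Matrix families x object types (columns `cell_phone`,
#'   `door_handle`, `fabric`, `plastic`).
#' @export
object_transfer_profile <- function(calls, presence, metadata) {
  validate_abundance_table(presence)
  metadata <- validate_metadata(metadata)
  fams <- sort(unique(calls$family[calls$transmissible]))
  otypes <- setdiff(OBJECT_TYPES, NONE)
  obj <- metadata[metadata$sample_class == "object" &
                    metadata$sample_id %in% colnames(presence), ]
  counts <- matrix(0, length(fams), length(otypes),
                   dimnames = list(fams, otypes))
  for (ot in otypes) {
    ids <- obj$sample_id[obj$object_type == ot]
    if (length(ids) && length(fams)) {
      counts[, ot] <- rowSums(presence[fams, ids, drop = FALSE] > 0)
    }
  }
  totals <- rowSums(counts)
  props <- counts
  nz <- totals > 0
  props[nz, ] <- counts[nz, , drop = FALSE] / totals[nz]
  props
}

#' Intersect stability and transmissibility into marker taxa
#'
#' Marker families are the intersection of the stable and transmissible
#' family sets. Marker species are every species observed in at least one
#' sample whose family is a marker family.
#'
#' @param stable character vector of stable families.
#' @param transmissible character vector of transmissible families.
#' @param presence_species binary matrix at species rank.
#' @param taxonomy taxonomy data.frame mapping species to family.
#' @return List with `marker_families` and `marker_species` (both sorted).
#' @export
select_markers <- function(stable, transmissible, presence_species, taxonomy) {
  validate_abundance_table(presence_species)
  taxonomy <- validate_taxonomy(taxonomy)
  marker_families <- sort(intersect(stable, transmissible))
  if (!length(marker_families)) {
    vm_warn("stable and transmissible family sets do not intersect; empty marker set")
    return(list(marker_families = character(0), marker_species = character(0)))
  }
  sp2fam <- unique(taxonomy[, c("species", "family")])
  fam_of <- stats::setNames(sp2fam$family, sp2fam$species)
  detected <- rownames(presence_species)[rowSums(presence_species > 0) > 0]
  marker_species <- sort(detected[!is.na(fam_of[detected]) &
                                    fam_of[detected] %in% marker_families])
  list(marker_families = marker_families, marker_species = marker_species)
}

#' Relative occurrence of markers per subject (0-100%)
#'
#' For each subject and marker species, the percentage of that subject's
#' skin samples (all sites and time points pooled) and, separately, of their
#' object samples in which the marker was detected.
#'
#' @param presence_species binary matrix at species rank.
#' @param metadata validated metadata.
#' @param markers non-empty character vector of marker species (rows of
#'   `presence_species`).
#' @return List of two subject x marker percentage matrices: `skin` and
#'   `objects`.
#' @export
occurrence_matrix <- function(presence_species, metadata, markers) {
  validate_abundance_table(presence_species)
  metadata <- validate_metadata(metadata)
  if (!length(markers)) vm_validation_stop("`markers` must be non-empty")
  missing <- setdiff(markers, rownames(presence_species))
  if (length(missing)) {
    vm_validation_stop("markers absent from table: ", paste(missing, collapse = ", "))
  }
  subjects <- sort(unique(metadata$subject_id[metadata$sample_class != "negative_control"]))
  tally <- function(class) {
    m <- matrix(0, length(subjects), length(markers),
                dimnames = list(subjects, markers))
    for (subj in subjects) {
      ids <- metadata$sample_id[metadata$subject_id == subj &
                                  metadata$sample_class == class]
      ids <- intersect(ids, colnames(presence_species))
      if (length(ids)) {
        m[subj, ] <- 100 * rowSums(presence_species[markers, ids, drop = FALSE] > 0) /
          length(ids)
      }
    }
    m
  }
  list(skin = tally("skin"), objects = tally("object"))
}

within_between_core <- function(d, metadata, class, min_samples = 2L) {
  validate_dissimilarity(d, tol = 1e-8)
  metadata <- validate_metadata(metadata)
  keep <- metadata[metadata$sample_class == class &
                     metadata$sample_id %in% colnames(d), ]
  ids <- keep$sample_id
  d <- d[ids, ids, drop = FALSE]
  subj_of <- stats::setNames(keep$subject_id, keep$sample_id)
  subjects <- unique(keep$subject_id)
  within <- between <- stats::setNames(rep(NA_real_, length(subjects)), subjects)
  for (subj in subjects) {
    own <- ids[subj_of[ids] == subj]
    other <- ids[subj_of[ids] != subj]
    if (length(own) < min_samples) {
      vm_warn("subject ", subj, " has < ", min_samples, " ", class,
              " samples; dropped from within/between comparison")
      next
    }
    dw <- d[own, own, drop = FALSE]
    within[subj] <- mean(dw[upper.tri(dw)])
    between[subj] <- if (length(other)) mean(d[own, other]) else NA_real_
  }
  ok <- !is.na(within) & !is.na(between)
  within <- within[ok]
  between <- between[ok]
  if (length(within) < 1L) {
    vm_validation_stop("no subject has enough ", class,
                       " samples for a within/between comparison")
  }
  test <- wilcoxon_rank_sum(within, between, alternative = "two_sided")
  structure(
    list(per_subject_within = within, per_subject_between = between,
         wilcoxon = test, sample_class = class),
    class = "viromark_within_between"
  )
}

#' Within- vs between-subject dissimilarity on skin samples
#'
#' Per subject: the within-subject dissimilarity is the mean of all pairwise
#' Jaccard distances among that subject's skin samples (sites and time
#' points pooled); the between-subject dissimilarity is the mean distance
#' from the subject's skin samples to every other subject's skin samples.
#' The two collections of per-subject means are compared by a two-sided
#' Wilcoxon rank-sum test. Subjects with fewer than two skin samples are
#' dropped with a warning.
#'
#' @param d dissimilarity matrix whose dimnames cover the skin samples.
#' @param metadata validated metadata.
#' @return `viromark_within_between`: per-subject within and between means
#'   plus the Wilcoxon result.
#' @export
within_between_skin <- function(d, metadata) {
  within_between_core(d, metadata, class = "skin")
}

#' Within- vs between-subject dissimilarity on object samples
#'
#' Within = mean of the pairwise distances among the (up to four) objects a
#' subject touched; between = mean distance from the subject's objects to
#' all other subjects' object samples; compared by a two-sided Wilcoxon
#' rank-sum test on the per-subject means.
#'
#' @inheritParams within_between_skin
#' @return `viromark_within_between`.
#' @export
within_between_objects <- function(d, metadata) {
  within_between_core(d, metadata, class = "object")
}

#' @export
print.viromark_within_between <- function(x, ...) {
  cat(sprintf(
    "Within/between-subject dissimilarity (%s, %d subjects):\n",
    x$sample_class, length(x$per_subject_within)
  ))
  cat(sprintf("  mean within  = %.4f\n", mean(x$per_subject_within)))
  cat(sprintf("  mean between = %.4f\n", mean(x$per_subject_between)))
  cat(sprintf("  Wilcoxon rank-sum p = %.4g (%s)\n",
              x$wilcoxon$p_value, x$wilcoxon$method))
  invisible(x)
}
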