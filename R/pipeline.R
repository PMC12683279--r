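#' Pipeline configuration for the marker analysis
#'
#' Collects every tunable threshold in one validated object so that reports
#' can embed the exact configuration they were produced under.
#'
#' @param min_count detection threshold for [binarize()] (default 1 mapped
#'   unit — the most permissive reading of presence/absence).
#' @param min_timepoints time points (of 3) required for temporal stability
#'   (default 2).
#' @param min_objects object types (of 4) required for transmissibility
#'   (default 2).
#' @param min_subjects subjects required to confirm a family (default 1).
#' @param require_all_sites strict all-three-sites stability rule (default TRUE).
#' @param host_required transmissibility anchored to the subject's own skin
#'   (default TRUE).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param alpha nominal test level recorded in reports (default 0.05).
#' @param shannon_base log base for Shannon diversity (`"ln"` or `"log2"`).
#' @param wilcoxon_mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param seed integer seed used by any randomized step.
#' @return A validated list of class `viromark_config`.
#' @export
marker_config <- function(min_count = 1, min_timepoints = 2L, min_objects = 2L,
                          min_subjects = 1L, require_all_sites = TRUE,
                          host_required = TRUE, n_permutations = 999L,
                          alpha = 0.05, shannon_base = "ln",
                          wilcoxon_mode = "auto", seed = 1L) {
  cfg <- list(
    min_count = min_count, min_timepoints = as.integer(min_timepoints),
    min_objects = as.integer(min_objects),
    min_subjects = as.integer(min_subjects),
    require_all_sites = isTRUE(require_all_sites),
    host_required = isTRUE(host_required),
    n_permutations = as.integer(n_permutations), alpha = alpha,
    shannon_base = match.arg(shannon_base, c("ln", "log2")),
    wilcoxon_mode = match.arg(wilcoxon_mode, c("auto", "exact", "normal_approx")),
    seed = as.integer(seed)
  )
  if (cfg$min_count < 1) vm_validation_stop("min_count must be >= 1")
  if (cfg$min_timepoints < 1 || cfg$min_timepoints > 3) {
    vm_validation_stop("min_timepoints must be in 1..3")
  }
  if (cfg$min_objects < 1 || cfg$min_objects > 4) {
    vm_validation_stop("min_objects must be in 1..4")
  }
  if (cfg$min_subjects < 1) vm_validation_stop("min_subjects must be >= 1")
  if (cfg$n_permutations < 1) vm_validation_stop("n_permutations must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) vm_validation_stop("alpha must be in (0, 1)")
  structure(cfg, class = "viromark_config")
}

# Presence at a coarser rank: a family (or species pooled over contigs) is
# present iff any member taxon is present.
presence_at_rank <- function(presence, taxonomy, rank, drop_unclassified = TRUE) {
  agg <- aggregate_to_rank(presence, taxonomy, rank = rank,
                           drop_unclassified = drop_unclassified)
  (agg > 0) * 1
}

#' Run the full marker-selection and specificity analysis
#'
#' Orchestrates the pipeline: binarize counts, filter taxa seen in negative
#' controls, derive family- and species-rank presence, call temporal
#' stability and skin-to-object transmissibility, intersect to marker
#' families and species, tabulate per-subject occurrence, and compare
#' within- versus between-subject Jaccard dissimilarities on skin and object
#' samples restricted to the marker species.
#'
#' @param table taxon-by-sample count matrix.
#' @param taxonomy taxonomy data.frame.
#' @param metadata validated metadata.
#' @param config a [marker_config()].
#' @return `viromark_marker_report`: list with `stable_families`,
#'   `transmissible_families`, `marker_families`, `marker_species`,
#'   `stability_calls`, `transfer_calls`, `transfer_profile`, `occurrence`
#'   (list skin/objects), `skin_comparison`, `object_comparison` (possibly
#'   NULL when markers are too few), and the resolved `config`.
#' @export
run_marker_analysis <- function(table, taxonomy, metadata,
                                config = marker_config()) {
  taxonomy <- validate_taxonomy(taxonomy)
  metadata <- validate_metadata(metadata)
  stopifnot(inherits(config, "viromark_config"))

  empty_report <- function(stability_calls = NULL, transfer_calls = NULL) {
    structure(
      list(stable_families = character(0),
           transmissible_families = character(0),
           marker_families = character(0), marker_species = character(0),
           stability_calls = stability_calls, transfer_calls = transfer_calls,
           transfer_profile = NULL, occurrence = NULL,
           skin_comparison = NULL, object_comparison = NULL,
           config = config),
      class = "viromark_marker_report"
    )
  }
  if (NROW(table) == 0L || NCOL(table) == 0L) {
    vm_warn("empty abundance table; returning empty marker report")
    return(empty_report())
  }
  validate_abundance_table(table)

  presence <- binarize(table, config$min_count)
  presence <- remove_control_taxa(presence, metadata)
  fam_presence <- presence_at_rank(presence, taxonomy, "family")
  sp_presence <- presence_at_rank(presence, taxonomy, "species")
  if (nrow(fam_presence) == 0L) {
    vm_warn("no family-classified taxa after filtering; returning empty report")
    return(empty_report())
  }

  stab_calls <- site_stability(fam_presence, metadata, config$min_timepoints)
  stable <- stable_families(stab_calls,
                            require_all_sites = config$require_all_sites,
                            min_subjects = config$min_subjects)
  trans <- transmissible_families(fam_presence, metadata,
                                  min_objects = config$min_objects,
                                  min_subjects = config$min_subjects,
                                  host_required = config$host_required)
  markers <- select_markers(stable, trans$families, sp_presence, taxonomy)

  transfer_profile <- object_transfer_profile(trans$calls, fam_presence, metadata)

  occurrence <- NULL
  skin_cmp <- NULL
  obj_cmp <- NULL
  if (length(markers$marker_species)) {
    occurrence <- occurrence_matrix(sp_presence, metadata, markers$marker_species)
    marker_presence <- sp_presence[markers$marker_species, , drop = FALSE]
    skin_ids <- metadata$sample_id[metadata$sample_class == "skin"]
    skin_ids <- intersect(skin_ids, colnames(marker_presence))
    if (length(skin_ids) >= 2L) {
      d_skin <- jaccard_matrix(marker_presence[, skin_ids, drop = FALSE])
      skin_cmp <- within_between_skin(d_skin, metadata)
    }
    obj_ids <- metadata$sample_id[metadata$sample_class == "object"]
    obj_ids <- intersect(obj_ids, colnames(marker_presence))
    if (length(obj_ids) >= 2L) {
      d_obj <- jaccard_matrix(marker_presence[, obj_ids, drop = FALSE])
      obj_cmp <- within_between_objects(d_obj, metadata)
    }
  }

  structure(
    list(stable_families = stable, transmissible_families = trans$families,
         marker_families = markers$marker_families,
         marker_species = markers$marker_species,
         stability_calls = stab_calls, transfer_calls = trans$calls,
         transfer_profile = transfer_profile, occurrence = occurrence,
         skin_comparison = skin_cmp, object_comparison = obj_cmp,
         config = config),
    class = "viromark_marker_report"
  )
}

#' @export
print.viromark_marker_report <- function(x, ...) {
  cat("Virome marker report\n")
  cat("  stable families:       ", length(x$stable_families), "\n")
  cat("  transmissible families:", length(x$transmissible_families), "\n")
  cat("  marker families:       ", length(x$marker_families), "\n")
  cat("  marker species:        ", length(x$marker_species), "\n")
  if (!is.null(x$skin_comparison)) {
    cat(sprintf("  skin within/between Wilcoxon p = %.4g\n",
                x$skin_comparison$wilcoxon$p_value))
  }
  if (!is.null(x$object_comparison)) {
    cat(sprintf("  object within/between Wilcoxon p = %.4g\n",
                x$object_comparison$wilcoxon$p_value))
  }
  invisible(x)
}

test_to_list <- function(t) {
  if (is.null(t)) return(NULL)
  list(statistic = t$statistic, p_value = t$p_value, method = t$method,
       alternative = t$alternative)
}

wb_to_list <- function(wb) {
  if (is.null(wb)) return(NULL)
  list(per_subject_within = as.list(wb$per_subject_within),
       per_subject_between = as.list(wb$per_subject_between),
       wilcoxon = test_to_list(wb$wilcoxon))
}

#' Serialize a marker report to JSON
#'
#' Sets become sorted arrays; the occurrence matrices become nested objects;
#' the resolved configuration (including the seed) is embedded for
#' provenance. The written file reads back to the same report content via
#' [read_marker_report()] (the S3 classes of nested test objects are not
#' reconstructed).
#'
#' @param report a `viromark_marker_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_report <- function(report, path) {
  stopifnot(inherits(report, "viromark_marker_report"))
  obj <- list(
    stable_families = as.list(sort(report$stable_families)),
    transmissible_families = as.list(sort(report$transmissible_families)),
    marker_families = as.list(sort(report$marker_families)),
    marker_species = as.list(sort(report$marker_species)),
    occurrence = if (is.null(report$occurrence)) NULL else list(
      skin = apply(report$occurrence$skin, 1, as.list, simplify = FALSE),
      objects = apply(report$occurrence$objects, 1, as.list, simplify = FALSE)
    ),
    skin_comparison = wb_to_list(report$skin_comparison),
    object_comparison = wb_to_list(report$object_comparison),
    config = unclass(report$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a serialized marker report
#' @param path path written by [write_marker_report()].
#' @return Named list mirroring the JSON structure.
#' @export
read_marker_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
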