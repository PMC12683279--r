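#' Validate a taxon-by-sample abundance table
#'
#' An abundance table is a numeric matrix with unique taxon ids as row names
#' and unique sample ids as column names; all entries must be finite and
#' non-negative. Counts (integers) and relative abundances (reals) share the
#' same container.
#'
#' @param table numeric matrix with dimnames.
#' @return The validated matrix, invisibly usable downstream.
#' @export
validate_abundance_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table)) {
    vm_validation_stop("abundance table must be a numeric matrix")
  }
  if (is.null(rownames(table)) || is.null(colnames(table))) {
    vm_validation_stop("abundance table must have taxon row names and sample column names")
  }
  dup_taxa <- rownames(table)[duplicated(rownames(table))]
  if (length(dup_taxa)) {
    vm_validation_stop("duplicate taxon_id: ", paste(unique(dup_taxa), collapse = ", "))
  }
  dup_samples <- colnames(table)[duplicated(colnames(table))]
  if (length(dup_samples)) {
    vm_validation_stop("duplicate sample_id: ", paste(unique(dup_samples), collapse = ", "))
  }
  bad <- which(!is.finite(table) | table < 0)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(table)) + 1
    j <- ((bad[1] - 1) %/% nrow(table)) + 1
    vm_validation_stop(
      "negative or non-numeric entry at taxon ", deparse(rownames(table)[i]),
      ", sample ", deparse(colnames(table)[j])
    )
  }
  table
}

#' Read a taxon-by-sample abundance table from TSV
#'
#' File dialect: UTF-8, tab-separated, header row of sample ids, first column
#' named `taxon_id`, remaining cells non-negative numbers. Row and column
#' order are preserved.
#'
#' @param path path to the TSV file.
#' @return Numeric matrix (taxa x samples) with dimnames.
#' @export
read_abundance_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) {
    vm_validation_stop("abundance table needs a taxon_id column and >=1 sample column")
  }
  sample_ids <- header[-1]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) {
    vm_validation_stop("duplicate sample_id in header: ", paste(unique(dup), collapse = ", "))
  }
  raw <- utils::read.delim(path, header = FALSE, skip = 1L, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) != length(header)) {
    vm_validation_stop("row width does not match header width in ", path)
  }
  taxa <- raw[[1]]
  mat <- suppressWarnings(
    vapply(seq_along(sample_ids), function(j) as.numeric(raw[[j + 1L]]),
           numeric(nrow(raw)))
  )
  mat <- matrix(mat, nrow = nrow(raw), ncol = length(sample_ids),
                dimnames = list(taxa, sample_ids))
  na_cells <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(na_cells)) {
    vm_validation_stop(
      "non-numeric cell at row ", na_cells[1, 1] + 1L, " (taxon ",
      deparse(taxa[na_cells[1, 1]]), "), column ", na_cells[1, 2] + 1L,
      " (sample ", deparse(sample_ids[na_cells[1, 2]]), ")"
    )
  }
  validate_abundance_table(mat)
}

#' Write an abundance table to TSV
#'
#' Inverse of [read_abundance_table()]: the written file reads back to an
#' identical matrix.
#'
#' @param table validated abundance (or presence) matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  validate_abundance_table(table)
  df <- data.frame(taxon_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `subject_id`, `sample_class`,
#' `site`, `time_point`, `object_type`. Every record is validated: skin
#' samples carry a site and time point but no object type; object samples
#' carry an object type but no site; negative controls use the subject id
#' sentinel `"none"`.
#'
#' @param path path to the metadata TSV.
#' @return A data.frame of validated sample records, one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE)
  validate_metadata(df)
}

#' Validate a metadata data.frame against the sample-record invariants
#'
#' @param metadata data.frame with the six metadata columns.
#' @return The validated data.frame (character columns, original row order).
#' @export
validate_metadata <- function(metadata) {
  required <- c("sample_id", "subject_id", "sample_class", "site",
                "time_point", "object_type")
  missing <- setdiff(required, names(metadata))
  if (length(missing)) {
    vm_validation_stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  for (col in required) metadata[[col]] <- as.character(metadata[[col]])
  dup <- metadata$sample_id[duplicated(metadata$sample_id)]
  if (length(dup)) {
    vm_validation_stop("duplicate sample_id in metadata: ", paste(unique(dup), collapse = ", "))
  }
  for (i in seq_len(nrow(metadata))) {
    rec <- metadata[i, ]
    match_enum(rec$sample_class, SAMPLE_CLASSES, "sample_class")
    match_enum(rec$site, SITES, "site")
    match_enum(rec$time_point, TIME_POINTS, "time_point")
    match_enum(rec$object_type, OBJECT_TYPES, "object_type")
    id <- deparse(rec$sample_id)
    if (rec$sample_class == "skin") {
      if (rec$site == NONE || rec$time_point == NONE) {
        vm_validation_stop("skin sample ", id, " must have a site and time_point")
      }
      if (rec$object_type != NONE) {
        vm_validation_stop("skin sample ", id, " must not have an object_type")
      }
    } else if (rec$sample_class == "object") {
      if (rec$object_type == NONE) {
        vm_validation_stop("object sample ", id, " must have an object_type")
      }
      if (rec$site != NONE) {
        vm_validation_stop("object sample ", id, " must not have a site")
      }
    } else { # negative_control
      if (rec$subject_id != NONE) {
        vm_validation_stop("negative control ", id, " must have subject_id = \"none\"")
      }
    }
  }
  metadata
}

#' Write sample metadata to TSV
#' @param metadata validated metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  metadata <- validate_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with columns `taxon_id`, `species`, `family`, `higher_rank`; the
#' literal token `UNCLASSIFIED` marks unresolved ranks. `taxon_id` must be
#' unique.
#'
#' @param path path to the taxonomy TSV.
#' @return A data.frame with the four character columns.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE)
  validate_taxonomy(df)
}

#' Validate a taxonomy data.frame
#' @param taxonomy data.frame with columns taxon_id, species, family, higher_rank.
#' @return The validated data.frame.
#' @export
validate_taxonomy <- function(taxonomy) {
  required <- c("taxon_id", "species", "family", "higher_rank")
  missing <- setdiff(required, names(taxonomy))
  if (length(missing)) {
    vm_validation_stop("taxonomy missing column(s): ", paste(missing, collapse = ", "))
  }
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  for (col in required) taxonomy[[col]] <- as.character(taxonomy[[col]])
  dup <- taxonomy$taxon_id[duplicated(taxonomy$taxon_id)]
  if (length(dup)) {
    vm_validation_stop("duplicate taxon_id in taxonomy: ", paste(unique(dup), collapse = ", "))
  }
  taxonomy
}

#' Write a taxonomy table to TSV
#' @param taxonomy validated taxonomy data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  taxonomy <- validate_taxonomy(taxonomy)
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binarize an abundance table into a presence/absence matrix
#'
#' A taxon is called present in a sample when its count reaches `min_count`
#' mapped units. The threshold is deliberately exposed: presence/absence
#' profiling is sensitive to it and no universal value exists.
#'
#' @param table abundance matrix.
#' @param min_count detection threshold, a positive number (default 1).
#' @return Binary matrix with the same dimnames.
#' @export
binarize <- function(table, min_count = 1) {
  validate_abundance_table(table)
  if (!is.numeric(min_count) || length(min_count) != 1L || min_count < 1) {
    vm_validation_stop("`min_count` must be a single number >= 1")
  }
  out <- (table >= min_count) * 1
  dimnames(out) <- dimnames(table)
  out
}

#' Aggregate a table to a taxonomic rank
#'
#' Rows are summed within each label at the requested rank. Taxa whose label
#' at that rank is `UNCLASSIFIED` are removed before summing when
#' `drop_unclassified` is set; otherwise they are pooled under the
#' `UNCLASSIFIED` label. Column totals over retained taxa are conserved
#' exactly (integer arithmetic when the input is integral).
#'
#' @param table abundance or presence matrix; every row name must appear in
#'   `taxonomy$taxon_id`.
#' @param taxonomy taxonomy data.frame (see [read_taxonomy()]).
#' @param rank one of `"species"`, `"family"`, `"higher_rank"`.
#' @param drop_unclassified drop taxa unresolved at `rank`? Default `TRUE`.
#' @return Matrix with rank labels as row names (sorted), samples unchanged.
#' @export
aggregate_to_rank <- function(table, taxonomy,
                              rank = c("species", "family", "higher_rank"),
                              drop_unclassified = TRUE) {
  validate_abundance_table(table)
  taxonomy <- validate_taxonomy(taxonomy)
  rank <- match.arg(rank)
  idx <- match(rownames(table), taxonomy$taxon_id)
  if (anyNA(idx)) {
    vm_validation_stop(
      "taxon missing from taxonomy: ",
      paste(rownames(table)[is.na(idx)], collapse = ", ")
    )
  }
  labels <- taxonomy[[rank]][idx]
  keep <- rep(TRUE, nrow(table))
  if (drop_unclassified) keep <- labels != UNCLASSIFIED
  if (!any(keep)) {
    return(matrix(0, nrow = 0, ncol = ncol(table),
                  dimnames = list(character(0), colnames(table))))
  }
  out <- rowsum(table[keep, , drop = FALSE], group = labels[keep])
  out[order(rownames(out)), , drop = FALSE]
}

#' Convert counts to within-sample relative abundances
#'
#' Each column is divided by its total so that proportions sum to 1. An
#' all-zero sample is an error unless `zero_ok` is set, in which case its
#' column stays zero and a warning is raised.
#'
#' @param table abundance matrix.
#' @param zero_ok permit all-zero samples? Default `FALSE`.
#' @return Matrix of proportions with the same dimnames.
#' @export
relative_abundance <- function(table, zero_ok = FALSE) {
  validate_abundance_table(table)
  totals <- colSums(table)
  zero <- totals == 0
  if (any(zero)) {
    if (!zero_ok) {
      vm_validation_stop(
        "all-zero sample column(s): ",
        paste(colnames(table)[zero], collapse = ", ")
      )
    }
    vm_warn("all-zero sample column(s) kept as zeros: ",
            paste(colnames(table)[zero], collapse = ", "))
    totals[zero] <- 1
  }
  sweep(table, 2, totals, "/")
}

#' Pool a subject's skin profile across sites and time points
#'
#' Sums the subject's skin-sample columns elementwise — all anatomical sites
#' and all time points — into one host-level column, the profile used when
#' comparing a host against the objects it touched.
#'
#' @param table abundance matrix.
#' @param metadata validated metadata covering the table's samples.
#' @param subject_id subject to pool.
#' @return Single-column matrix named after the subject.
#' @export
host_pooled_profile <- function(table, metadata, subject_id) {
  validate_abundance_table(table)
  metadata <- validate_metadata(metadata)
  skin_ids <- metadata$sample_id[metadata$sample_class == "skin" &
                                   metadata$subject_id == subject_id]
  skin_ids <- intersect(skin_ids, colnames(table))
  if (!length(skin_ids)) {
    vm_validation_stop("no skin samples in table for subject ", deparse(subject_id))
  }
  out <- matrix(rowSums(table[, skin_ids, drop = FALSE]), ncol = 1,
                dimnames = list(rownames(table), subject_id))
  out
}

#' Top-k features by total abundance
#'
#' Returns the `k` row labels with the largest row sums in descending order.
#' Ties are broken lexicographically by label so output is deterministic.
#'
#' @param table abundance matrix.
#' @param k number of features to return (>= 1); if the table has fewer rows,
#'   all are returned.
#' @return Character vector of row labels.
#' @export
top_k_features <- function(table, k) {
  validate_abundance_table(table)
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    vm_validation_stop("`k` must be a single positive integer")
  }
  sums <- rowSums(table)
  ord <- order(-sums, rownames(table))
  rownames(table)[ord][seq_len(min(k, nrow(table)))]
}

#' Remove taxa detected in negative controls
#'
#' Table-level contamination filter: any taxon present in any negative
#' control sample is zeroed across all samples, and control columns are
#' dropped from the output. This approximates read-level decontamination
#' against control contigs, but at the resolution of classified taxa.
#'
#' @param presence binary presence matrix including control columns.
#' @param metadata validated metadata.
#' @return Presence matrix without control columns; contaminant rows zeroed.
#' @export
remove_control_taxa <- function(presence, metadata) {
  validate_abundance_table(presence)
  metadata <- validate_metadata(metadata)
  ctrl_ids <- intersect(
    metadata$sample_id[metadata$sample_class == "negative_control"],
    colnames(presence)
  )
  out <- presence[, setdiff(colnames(presence), ctrl_ids), drop = FALSE]
  if (length(ctrl_ids)) {
    contaminated <- rowSums(presence[, ctrl_ids, drop = FALSE] > 0) > 0
    out[contaminated, ] <- 0
  }
  out
}
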