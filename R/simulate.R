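#' Configuration for a synthetic skin-virome study
#'
#' Describes a study shaped like the sampling design the pipeline targets:
#' `n_subjects` subjects each swabbed at three anatomical sites (forehead,
#' left hand, right hand) at three time points (0, 6 and 12 weeks), plus one
#' sample from each of four contacted object types (cell phone, door handle,
#' fabric, plastic) per subject, plus negative control swabs.
#'
#' Community structure: each subject carries a disjoint set of persistent
#' *signature* species drawn from `n_signature_families` families (species
#' are spread over families as evenly as possible, `n_signature_species`
#' total); *shared* cosmopolitan species appear in any sample with
#' probability `shared_prevalence`; *transient* species are sprinkled at
#' `transient_rate`; dedicated *contaminant* species appear in negative
#' controls with probability `contamination_rate` and leak into real samples
#' at `contaminant_sample_rate`. A skin sampling event detects each latent
#' taxon with probability `detection_prob`; each taxon on the subject's skin
#' at the time of contact (time point t2) transfers to an object of type `o`
#' with probability `transfer_prob[o]`. Counts for present taxa are
#' log-normal (`count_meanlog`, `count_sdlog`), rounded up so that a count of
#' at least 1 always marks a present taxon.
#'
#' With `null_model = TRUE` subject signatures are switched off: every
#' signature-pool species appears independently in any skin sample with
#' probability `null_presence_prob` and in any object sample with probability
#' `null_presence_prob * mean(transfer_prob)`, making subjects exchangeable —
#' the null world for calibrating the within/between tests.
#'
#' @param n_subjects number of subjects (default 8).
#' @param n_signature_families planted marker families (default 15).
#' @param n_signature_species planted marker species in total (default 54).
#' @param n_shared_families cosmopolitan families (default 4).
#' @param shared_species_per_family species per cosmopolitan family (default 2).
#' @param n_transient_species occasional environmental species (default 20).
#' @param n_contaminant_species reagent-contaminant species (default 5).
#' @param detection_prob per-event skin detection probability (default 0.9).
#' @param transfer_prob per-object-type transfer probability; scalar or
#'   length-4 named vector over cell_phone, door_handle, fabric, plastic
#'   (default 0.8).
#' @param shared_prevalence per-sample presence probability of shared species
#'   (default 0.8).
#' @param transient_rate per-sample presence probability of transient species
#'   (default 0.05).
#' @param contamination_rate contaminant presence probability in a negative
#'   control (default 0.3).
#' @param contaminant_sample_rate contaminant leak rate into real samples
#'   (default 0.05).
#' @param count_meanlog,count_sdlog log-normal count model (defaults 3, 1).
#' @param n_controls negative control samples (default 2).
#' @param unclassified_fraction fraction of species marked UNCLASSIFIED at
#'   family rank (default 0).
#' @param null_model exchangeable-subjects null world (default FALSE).
#' @param null_presence_prob per-sample presence probability under the null
#'   (default 0.5).
#' @param seed mandatory integer seed.
#' @return A validated list of class `viromark_study_config`.
#' @export
study_config <- function(n_subjects = 8L, n_signature_families = 15L,
                         n_signature_species = 54L, n_shared_families = 4L,
                         shared_species_per_family = 2L,
                         n_transient_species = 20L,
                         n_contaminant_species = 5L,
                         detection_prob = 0.9, transfer_prob = 0.8,
                         shared_prevalence = 0.8, transient_rate = 0.05,
                         contamination_rate = 0.3,
                         contaminant_sample_rate = 0.05,
                         count_meanlog = 3, count_sdlog = 1,
                         n_controls = 2L, unclassified_fraction = 0,
                         null_model = FALSE, null_presence_prob = 0.5,
                         seed) {
  if (missing(seed)) vm_validation_stop("`seed` is mandatory for a study config")
  otypes <- setdiff(OBJECT_TYPES, NONE)
  if (length(transfer_prob) == 1L) {
    transfer_prob <- stats::setNames(rep(transfer_prob, 4), otypes)
  }
  if (length(transfer_prob) != 4L || is.null(names(transfer_prob)) ||
      !setequal(names(transfer_prob), otypes)) {
    vm_validation_stop("`transfer_prob` must be scalar or named over the four object types")
  }
  transfer_prob <- transfer_prob[otypes]
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    sites = setdiff(SITES, NONE), time_points = setdiff(TIME_POINTS, NONE),
    object_types = otypes,
    n_signature_families = as.integer(n_signature_families),
    n_signature_species = as.integer(n_signature_species),
    n_shared_families = as.integer(n_shared_families),
    shared_species_per_family = as.integer(shared_species_per_family),
    n_transient_species = as.integer(n_transient_species),
    n_contaminant_species = as.integer(n_contaminant_species),
    detection_prob = detection_prob, transfer_prob = transfer_prob,
    shared_prevalence = shared_prevalence, transient_rate = transient_rate,
    contamination_rate = contamination_rate,
    contaminant_sample_rate = contaminant_sample_rate,
    count_meanlog = count_meanlog, count_sdlog = count_sdlog,
    n_controls = as.integer(n_controls),
    unclassified_fraction = unclassified_fraction,
    null_model = isTRUE(null_model), null_presence_prob = null_presence_prob,
    seed = as.integer(seed)
  )
  probs <- c(cfg$detection_prob, cfg$transfer_prob, cfg$shared_prevalence,
             cfg$transient_rate, cfg$contamination_rate,
             cfg$contaminant_sample_rate, cfg$unclassified_fraction,
             cfg$null_presence_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    vm_validation_stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$n_subjects < 1 || cfg$n_signature_families < 1 ||
      cfg$n_signature_species < cfg$n_signature_families) {
    vm_validation_stop("need >= 1 subject and >= 1 species per signature family")
  }
  structure(cfg, class = "viromark_study_config")
}

# Even split of n species over k families: first (n mod k) families get one
# extra species. Deterministic.
species_split <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

#' Generate a synthetic taxonomy
#'
#' Species labels with family and higher-rank (viral class) labels matching
#' the study config; a seeded fraction of species can be marked UNCLASSIFIED
#' at family rank to exercise the exclusion rules.
#'
#' @param config a [study_config()].
#' @param seed seed for the unclassified draw (default `config$seed`).
#' @return Taxonomy data.frame (`taxon_id`, `species`, `family`,
#'   `higher_rank`).
#' @export
generate_taxonomy <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "viromark_study_config"))
  classes <- c("Caudoviricetes", "Papovaviricetes", "Megaviricetes")
  rows <- list()
  add <- function(species, family, class_label) {
    rows[[length(rows) + 1L]] <<- data.frame(
      taxon_id = species, species = species, family = family,
      higher_rank = class_label, stringsAsFactors = FALSE
    )
  }
  sig_sizes <- species_split(config$n_signature_species,
                             config$n_signature_families)
  for (f in seq_len(config$n_signature_families)) {
    fam <- sprintf("Sigfamviridae_%02d", f)
    for (s in seq_len(sig_sizes[f])) {
      add(sprintf("sig_sp_%02d_%02d", f, s), fam,
          classes[(f - 1) %% length(classes) + 1])
    }
  }
  for (f in seq_len(config$n_shared_families)) {
    fam <- sprintf("Sharedfamviridae_%02d", f)
    for (s in seq_len(config$shared_species_per_family)) {
      add(sprintf("shared_sp_%02d_%02d", f, s), fam, "Caudoviricetes")
    }
  }
  for (s in seq_len(config$n_transient_species)) {
    add(sprintf("transient_sp_%02d", s),
        sprintf("Transfamviridae_%02d", (s - 1) %/% 4 + 1), "Papovaviricetes")
  }
  for (s in seq_len(config$n_contaminant_species)) {
    add(sprintf("contam_sp_%02d", s), sprintf("Contamfamviridae_%02d", s),
        "Megaviricetes")
  }
  tax <- do.call(rbind, rows)
  if (config$unclassified_fraction > 0) {
    n_un <- round(config$unclassified_fraction * nrow(tax))
    idx <- with_seed(seed, sample.int(nrow(tax), n_un))
    tax$family[idx] <- UNCLASSIFIED
  }
  validate_taxonomy(tax)
}

study_metadata <- function(config) {
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    subj <- sprintf("S%d", i)
    for (site in config$sites) {
      for (tp in config$time_points) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste(subj, site, tp, sep = "_"), subject_id = subj,
          sample_class = "skin", site = site, time_point = tp,
          object_type = NONE, stringsAsFactors = FALSE
        )
      }
    }
    for (ot in config$object_types) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste(subj, ot, sep = "_"), subject_id = subj,
        sample_class = "object", site = NONE, time_point = NONE,
        object_type = ot, stringsAsFactors = FALSE
      )
    }
  }
  for (k in seq_len(config$n_controls)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("NC%d", k), subject_id = NONE,
      sample_class = "negative_control", site = NONE, time_point = NONE,
      object_type = NONE, stringsAsFactors = FALSE
    )
  }
  validate_metadata(do.call(rbind, rows))
}

#' Generate a complete synthetic study
#'
#' Produces the abundance table, metadata, taxonomy and the ground truth that
#' generated them, fully determined by `config$seed`. See [study_config()]
#' for the statistical model.
#'
#' @param config a [study_config()].
#' @return List of class `viromark_study` with elements `table` (counts,
#'   species x samples), `metadata`, `taxonomy`, `truth` (list with
#'   `signature_species` per subject, `signature_families`, `shared_species`,
#'   `transient_species`, `contaminant_species`, and `latent` — the binary
#'   pre-dropout presence matrix), and `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "viromark_study_config"))
  taxonomy <- generate_taxonomy(config)
  metadata <- study_metadata(config)
  species <- taxonomy$taxon_id
  sig_species <- grep("^sig_sp_", species, value = TRUE)
  shared_species <- grep("^shared_sp_", species, value = TRUE)
  transient_species <- grep("^transient_sp_", species, value = TRUE)
  contam_species <- grep("^contam_sp_", species, value = TRUE)
  subjects <- sprintf("S%d", seq_len(config$n_subjects))

  # round-robin assignment of signature species to subjects: disjoint sets,
  # every signature family spread across subjects
  assign_idx <- ((seq_along(sig_species) - 1) %% config$n_subjects) + 1
  signature_of <- split(sig_species, subjects[assign_idx])
  signature_of <- signature_of[subjects[subjects %in% names(signature_of)]]

  n_sp <- length(species)
  sample_ids <- metadata$sample_id
  n_samp <- length(sample_ids)
  latent <- matrix(0L, n_sp, n_samp, dimnames = list(species, sample_ids))
  realized <- latent

  out <- with_seed(config$seed, {
    draw <- function(p, n) stats::runif(n) < p
    for (j in seq_len(n_samp)) {
      rec <- metadata[j, ]
      lat <- logical(n_sp)
      names(lat) <- species
      if (rec$sample_class == "skin") {
        if (config$null_model) {
          lat[sig_species] <- draw(config$null_presence_prob, length(sig_species))
        } else {
          lat[signature_of[[rec$subject_id]]] <- TRUE
        }
        lat[shared_species] <- draw(config$shared_prevalence, length(shared_species))
        lat[transient_species] <- draw(config$transient_rate, length(transient_species))
        lat[contam_species] <- draw(config$contaminant_sample_rate, length(contam_species))
        det <- lat & draw(config$detection_prob, n_sp)
        if (config$null_model) det <- lat   # null world: occupancy already iid
      } else if (rec$sample_class == "negative_control") {
        lat[contam_species] <- draw(config$contamination_rate, length(contam_species))
        det <- lat
      } else {
        det <- lat # objects filled after all skin samples below
      }
      latent[, j] <- as.integer(lat)
      realized[, j] <- as.integer(det)
    }
    # object samples: transfer from the subject's skin at time of contact (t2)
    for (j in which(metadata$sample_class == "object")) {
      rec <- metadata[j, ]
      tau <- config$transfer_prob[[rec$object_type]]
      if (config$null_model) {
        p <- config$null_presence_prob * mean(config$transfer_prob)
        lat <- logical(n_sp)
        lat[match(sig_species, species)] <- draw(p, length(sig_species))
        lat[match(shared_species, species)] <-
          draw(config$shared_prevalence * tau, length(shared_species))
        det <- lat
      } else {
        contact_ids <- metadata$sample_id[metadata$subject_id == rec$subject_id &
                                            metadata$sample_class == "skin" &
                                            metadata$time_point == "t2"]
        source_profile <- rowSums(latent[, contact_ids, drop = FALSE]) > 0
        lat <- source_profile
        det <- lat & draw(tau, n_sp)
      }
      latent[, j] <- as.integer(lat)
      realized[, j] <- as.integer(det)
    }
    counts <- matrix(0, n_sp, n_samp, dimnames = dimnames(latent))
    present <- which(realized == 1L)
    counts[present] <- pmax(1, ceiling(stats::rlnorm(
      length(present), meanlog = config$count_meanlog, sdlog = config$count_sdlog
    )))
    list(latent = latent, counts = counts)
  })

  truth <- list(
    signature_species = signature_of,
    signature_families = sort(unique(
      taxonomy$family[taxonomy$taxon_id %in% sig_species &
                        taxonomy$family != UNCLASSIFIED]
    )),
    shared_species = shared_species, transient_species = transient_species,
    contaminant_species = contam_species, latent = out$latent
  )
  structure(
    list(table = out$counts, metadata = metadata, taxonomy = taxonomy,
         truth = truth, config = config),
    class = "viromark_study"
  )
}

#' Precision and recall of a marker report against planted truth
#'
#' @param truth `truth` component of a [generate_study()] result.
#' @param report a `viromark_marker_report` from the same study universe.
#' @return List with `family` and `species` components, each holding
#'   `precision` and `recall`. Precision is 1 when nothing was selected and
#'   nothing was planted, and `NA` when nothing was selected but markers were
#'   planted; recall is 1 when nothing was planted.
#' @export
recovery_metrics <- function(truth, report) {
  pr <- function(selected, planted) {
    hits <- length(intersect(selected, planted))
    precision <- if (length(selected)) {
      hits / length(selected)
    } else if (!length(planted)) 1 else NA_real_
    recall <- if (length(planted)) hits / length(planted) else 1
    list(precision = precision, recall = recall)
  }
  list(
    family = pr(report$marker_families, truth$signature_families),
    species = pr(report$marker_species,
                 sort(unique(unlist(truth$signature_species))))
  )
}

#' Write a synthetic study to disk
#'
#' Emits the same TSV formats the readers consume (`table.tsv`,
#' `metadata.tsv`, `taxonomy.tsv`) plus the ground truth and resolved config
#' as JSON (`truth.json`, `config.json`).
#'
#' @param study a `viromark_study`.
#' @param dir output directory (created if needed).
#' @return Named vector of the five file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "viromark_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    table = file.path(dir, "table.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.json")
  )
  write_abundance_table(study$table, paths["table"])
  write_metadata(study$metadata, paths["metadata"])
  write_taxonomy(study$taxonomy, paths["taxonomy"])
  truth <- study$truth
  jsonlite::write_json(
    list(signature_species = lapply(truth$signature_species, as.list),
         signature_families = as.list(truth$signature_families),
         shared_species = as.list(truth$shared_species),
         transient_species = as.list(truth$transient_species),
         contaminant_species = as.list(truth$contaminant_species)),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  cfg <- unclass(study$config)
  cfg$transfer_prob <- as.list(cfg$transfer_prob)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
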