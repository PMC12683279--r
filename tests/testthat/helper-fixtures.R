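# Small in-code fixtures and independent brute-force oracles shared across
# test files. Everything is generated programmatically; no data files.

tiny_table <- function() {
  matrix(c(3, 1, 0, 5), nrow = 2,
         dimnames = list(c("taxA", "taxB"), c("s1", "s2")))
}

random_table <- function(n_taxa = 12, n_samples = 6, seed = 1, max_count = 20) {
  set.seed(seed)
  matrix(rpois(n_taxa * n_samples, 3) %% (max_count + 1), n_taxa, n_samples,
         dimnames = list(sprintf("tax%02d", seq_len(n_taxa)),
                         sprintf("s%02d", seq_len(n_samples))))
}

random_presence <- function(n_taxa = 15, n_samples = 8, seed = 1, p = 0.4) {
  set.seed(seed)
  matrix(rbinom(n_taxa * n_samples, 1, p), n_taxa, n_samples,
         dimnames = list(sprintf("tax%02d", seq_len(n_taxa)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# one metadata row; defaults describe a valid skin sample
meta_row <- function(sample_id, subject_id = "S1", sample_class = "skin",
                     site = "forehead", time_point = "t0",
                     object_type = "none") {
  data.frame(sample_id = sample_id, subject_id = subject_id,
             sample_class = sample_class, site = site,
             time_point = time_point, object_type = object_type,
             stringsAsFactors = FALSE)
}

# complete metadata for n subjects x 3 sites x 3 time points + 4 objects,
# plus controls — mirrors the study design without using the generator
design_metadata <- function(n_subjects = 2, n_controls = 1) {
  rows <- list()
  for (i in seq_len(n_subjects)) {
    subj <- paste0("S", i)
    for (site in c("forehead", "left_hand", "right_hand")) {
      for (tp in c("t0", "t1", "t2")) {
        rows[[length(rows) + 1]] <-
          meta_row(paste(subj, site, tp, sep = "_"), subj, "skin", site, tp)
      }
    }
    for (ot in c("cell_phone", "door_handle", "fabric", "plastic")) {
      rows[[length(rows) + 1]] <-
        meta_row(paste(subj, ot, sep = "_"), subj, "object", "none", "none", ot)
    }
  }
  for (k in seq_len(n_controls)) {
    rows[[length(rows) + 1]] <-
      meta_row(paste0("NC", k), "none", "negative_control", "none", "none", "none")
  }
  do.call(rbind, rows)
}

simple_taxonomy <- function(taxa, families = NULL) {
  taxa <- as.character(taxa)
  if (is.null(families)) families <- sprintf("fam_%s", taxa)
  data.frame(taxon_id = taxa, species = sprintf("sp_%s", taxa),
             family = families,
             higher_rank = rep("Caudoviricetes", length(taxa)),
             stringsAsFactors = FALSE)
}

# independent set-based Jaccard oracle for a single pair of binary vectors
jaccard_oracle <- function(a, b) {
  sa <- which(a > 0)
  sb <- which(b > 0)
  u <- union(sa, sb)
  if (!length(u)) return(0)
  1 - length(intersect(sa, sb)) / length(u)
}

# noiseless study config: realized presence == planted signatures exactly
noiseless_config <- function(seed) {
  study_config(detection_prob = 1, transfer_prob = 1, shared_prevalence = 0,
               transient_rate = 0, contamination_rate = 0,
               contaminant_sample_rate = 0, seed = seed)
}
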