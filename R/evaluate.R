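# Evaluation against a known community: precision/recall of predicted
# taxa, correlation of estimated and true abundances, simple diversity
# summaries and the end-to-end benchmark driver.

#' Precision and recall of predicted taxa against a known community
#'
#' A unique predicted taxon is a true positive when it matches the
#' `level`-label of any community member (duplicate predictions of one
#' member count once, and are neither TP nor FP); otherwise it is a false
#' positive. Community members with relative abundance strictly above
#' `threshold` that attracted no true positive are false negatives.
#'
#' @param predicted_taxa Character vector of predicted taxon labels at
#'   `level` (NAs dropped).
#' @param truth_profile Community profile whose `taxon_id`s are reference
#'   ids covered by `tax`.
#' @param tax Taxonomy table used to label the truth at `level`.
#' @param level One of [tax_ranks()].
#' @param threshold Abundance threshold for the false-negative pool
#'   (default 0.001, the 0.1% rule).
#' @return One-row data.frame: `level`, `threshold`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
precision_recall <- function(predicted_taxa, truth_profile, tax, level,
                             threshold = 0.001) {
  stopifnot(level %in% tax_ranks())
  validate_profile(truth_profile)
  if (nrow(truth_profile) == 0L) stop("empty truth profile", call. = FALSE)
  labels <- tax[[level]][match(truth_profile$taxon_id, tax$id)]
  if (anyNA(labels)) {
    stop("truth taxon without taxonomy: ",
         truth_profile$taxon_id[which(is.na(labels))[1L]], call. = FALSE)
  }
  truth_ab <- rowsum(truth_profile$abundance, labels)[, 1L]
  truth_ab <- truth_ab[nzchar(names(truth_ab))]
  pred <- unique(predicted_taxa[!is.na(predicted_taxa)])
  tp_set <- intersect(pred, names(truth_ab))
  fp <- length(setdiff(pred, names(truth_ab)))
  tp <- length(tp_set)
  fn <- sum(truth_ab > threshold & !(names(truth_ab) %in% tp_set))
  data.frame(level = level, threshold = threshold, tp = tp, fp = fp, fn = fn,
             precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Aggregate a reference-id profile to a taxonomic level
#'
#' @param profile Profile keyed by reference ids.
#' @param tax Taxonomy table.
#' @param level One of [tax_ranks()]; members with an empty label at the
#'   level are dropped (and the rest renormalized).
#' @return Profile keyed by the level's labels.
#' @export
aggregate_profile <- function(profile, tax, level) {
  stopifnot(level %in% tax_ranks())
  labels <- tax[[level]][match(profile$taxon_id, tax$id)]
  if (anyNA(labels)) {
    stop("profile taxon without taxonomy: ",
         profile$taxon_id[which(is.na(labels))[1L]], call. = FALSE)
  }
  ok <- nzchar(labels)
  agg <- rowsum(profile$abundance[ok], labels[ok])
  ab <- agg[, 1L] / sum(agg[, 1L])
  o <- order(-ab, names(ab))
  data.frame(taxon_id = names(ab)[o], abundance = unname(ab[o]),
             stringsAsFactors = FALSE)
}

#' Pearson correlation of estimated and true abundances
#'
#' Computed on linear abundances over the union of taxa, with 0 for a
#' taxon absent from either side; on the log scale (`log = TRUE`) taxa
#' absent from either side are dropped instead.
#'
#' @param estimated,truth Profiles keyed in the same label space (e.g.
#'   both through [aggregate_profile()]).
#' @param log Correlate log10 abundances over shared taxa instead.
#' @return Pearson r.
#' @export
abundance_correlation <- function(estimated, truth, log = FALSE) {
  taxa <- union(estimated$taxon_id, truth$taxon_id)
  if (length(taxa) < 3L) stop("need at least 3 taxa", call. = FALSE)
  e <- estimated$abundance[match(taxa, estimated$taxon_id)]
  t_ <- truth$abundance[match(taxa, truth$taxon_id)]
  e[is.na(e)] <- 0; t_[is.na(t_)] <- 0
  if (log) {
    keep <- e > 0 & t_ > 0
    if (sum(keep) < 3L) stop("fewer than 3 shared taxa", call. = FALSE)
    e <- log10(e[keep]); t_ <- log10(t_[keep])
  }
  if (stats::sd(e) == 0 || stats::sd(t_) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(e, t_)
}

#' Observed richness and Shannon index of a profile
#'
#' @param profile Community profile.
#' @return Named numeric vector with `richness` (taxon count) and
#'   `shannon` (H = -sum p log p, natural log).
#' @export
diversity_summary <- function(profile) {
  p <- profile$abundance
  c(richness = length(p), shannon = -sum(p * log(p)))
}

#' Draw a mock community from the amplifiable references
#'
#' Samples `n_taxa` reference ids (deterministically for a seed) and
#' attaches a staggered abundance profile.
#'
#' @param amplicon_ids Character vector of amplifiable reference ids.
#' @param n_taxa Community size.
#' @param seed Integer seed.
#' @param min_ab,max_ab Pre-normalization abundance anchors (defaults
#'   0.005 and 0.10, keeping every member above the 0.5% line).
#' @return Community profile keyed by reference ids.
#' @export
sample_community <- function(amplicon_ids, n_taxa = 30L, seed = 1L,
                             min_ab = 0.005, max_ab = 0.10) {
  if (length(amplicon_ids) < n_taxa) {
    stop("fewer amplifiable references than community taxa", call. = FALSE)
  }
  .with_seed(seed + 1000L, {
    ids <- sample(amplicon_ids, n_taxa)
    make_profile("staggered", n = n_taxa, taxon_ids = ids,
                 min_ab = min_ab, max_ab = max_ab)
  })
}

#' Run the full in-silico benchmark once
#'
#' Generates a synthetic reference database, draws a mock community,
#' simulates paired shotgun reads over the 338F*/1061R amplicons,
#' preprocesses them, and evaluates both analysis routes:
#' EM reconstruction + best-hit classification, and the paired-read
#' same-OTU concordance classifier against pre-clustered amplicon
#' centroids.
#'
#' @param seed Integer seed driving the database, the community and the
#'   simulation.
#' @param arch Database architecture, default [db_architecture()].
#' @param n_taxa Community size (default 30).
#' @param n_pairs Simulated pair count (default 100000).
#' @param read_len,insert_mean,insert_sd Read geometry (75, 160, 40).
#' @param error_profile Per-cycle quality profile; default
#'   [default_error_profile()].
#' @param min_abundance Abundance floor for reconstruction output and
#'   profiles (default 0.001).
#' @param top_pairs Highest-quality pairs retained (default 100000).
#' @param max_iter EM iteration cap.
#' @param error_free Use a zero-error simulation (overrides
#'   `error_profile` rates with 0 while keeping its quality strings).
#' @return List with the community `truth`, reconstruction output
#'   `reconstruction`, per-level evaluation rows `em_eval` (species and
#'   genus), `correlation_species`, paired-OTU evaluation rows
#'   `paired_eval`, and the intermediate objects (`db`, `tax`,
#'   `amplicons`, `centroids`).
#' @export
run_benchmark <- function(seed = 1L, arch = db_architecture(),
                          n_taxa = 30L, n_pairs = 100000L,
                          read_len = 75L, insert_mean = 160, insert_sd = 40,
                          error_profile = default_error_profile(read_len),
                          min_abundance = 0.001, top_pairs = 100000L,
                          max_iter = 40L, error_free = FALSE) {
  ref <- generate_reference_db(arch, seed)
  pcr <- insilico_pcr(ref$db, default_primer_pair())
  amps <- amplicon_set(pcr, "full")
  truth <- sample_community(amps$id, n_taxa, seed)
  pairs <- simulate_pairs(amps, truth, n_pairs, read_len,
                          insert_mean, insert_sd, error_profile,
                          seed = seed, error_free = error_free)
  pre <- trim_and_filter(pairs)
  pre <- select_top_reads(pre, top_pairs)
  recon <- reconstruct_amplicons(pre, amps, error_profile,
                                 max_iter = max_iter,
                                 min_abundance = min_abundance)
  cls <- best_hit_classify(recon, ref$db, ref$tax,
                           levels = c("species", "genus"))
  em_eval <- do.call(rbind, lapply(c("species", "genus"), function(lv) {
    pred <- cls$taxon[cls$level == lv]
    precision_recall(pred, truth, ref$tax, lv, min_abundance)
  }))
  # abundance correlation at species level over the taxon union
  sp <- cls[cls$level == "species" & cls$assigned, , drop = FALSE]
  est_sp <- profile_from_assignments(
    ref_ids = sp$ref_id, tax = ref$tax, level = "species",
    weights = recon$abundance[match(sp$query_id, recon$id)],
    min_abundance = min_abundance)
  truth_sp <- aggregate_profile(truth, ref$tax, "species")
  correlation_species <- abundance_correlation(est_sp, truth_sp)
  # paired-read same-OTU route against pre-clustered amplicon centroids
  cl <- greedy_cluster(amps$seq, 0.97, ids = amps$id)
  cen_ids <- unique(cl$assignments$centroid_id)
  centroids <- amps[match(cen_ids, amps$id), , drop = FALSE]
  po <- paired_otu_assign(pre, centroids, identity = 0.97)
  paired_eval <- do.call(rbind, lapply(c("species", "genus"), function(lv) {
    prof <- profile_from_assignments(po$otu, ref$tax, lv,
                                     min_abundance = min_abundance)
    precision_recall(prof$taxon_id, truth, ref$tax, lv, min_abundance)
  }))
  list(seed = seed, truth = truth, reconstruction = recon,
       classification = cls, em_eval = em_eval,
       correlation_species = correlation_species,
       paired_assignments = po, paired_eval = paired_eval,
       db = ref$db, tax = ref$tax, amplicons = amps, centroids = centroids,
       n_pairs_used = nrow(pre))
}

#' End-to-end pipeline report over one or more seeds
#'
#' Runs [run_benchmark()] per seed and binds the evaluation rows, with
#' medians across seeds — the package's summary of how well the two
#' analysis routes recover a known community.
#'
#' @param seeds Integer vector of seeds.
#' @param ... Passed to [run_benchmark()].
#' @return List with `per_seed` (data.frame of per-seed metrics) and
#'   `median` (named vector of the headline medians).
#' @export
end_to_end_report <- function(seeds = 1:5, ...) {
  rows <- lapply(seeds, function(s) {
    r <- run_benchmark(seed = s, ...)
    data.frame(
      seed = s,
      em_precision_species = r$em_eval$precision[r$em_eval$level == "species"],
      em_precision_genus = r$em_eval$precision[r$em_eval$level == "genus"],
      em_recall_species = r$em_eval$recall[r$em_eval$level == "species"],
      em_recall_genus = r$em_eval$recall[r$em_eval$level == "genus"],
      correlation_species = r$correlation_species,
      paired_recall_genus = r$paired_eval$recall[r$paired_eval$level == "genus"],
      paired_precision_genus =
        r$paired_eval$precision[r$paired_eval$level == "genus"],
      stringsAsFactors = FALSE)
  })
  per_seed <- do.call(rbind, rows)
  med <- vapply(per_seed[, -1L, drop = FALSE], stats::median, numeric(1L))
  list(per_seed = per_seed, median = med)
}
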