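# Taxonomic assignment of reconstructed amplicons (best local-alignment
# hit with per-rank identity thresholds) and the paired-read same-OTU
# concordance classifier.

#' Default per-level identity thresholds (percent)
#'
#' 97% at species, 95% at genus and 80% at phylum.
#'
#' @return Named numeric vector.
#' @export
classification_thresholds <- function() {
  c(species = 97, genus = 95, phylum = 80)
}

# Local alignment of one query against a shortlist of references; the
# strand is picked by shared-k-mer counts (ties align both). Hits are
# ordered by the deterministic tie-break chain.
.local_hits <- function(query, db, shortlist, fwd_cnt, rev_cnt) {
  qs <- list("+" = Biostrings::DNAString(query),
             "-" = Biostrings::DNAString(revcomp(query)))
  rows <- list()
  for (j in shortlist) {
    strands <- if (fwd_cnt[j] > rev_cnt[j]) "+"
               else if (rev_cnt[j] > fwd_cnt[j]) "-"
               else c("+", "-")
    best <- NULL
    for (sd in strands) {
      a <- Biostrings::pairwiseAlignment(
        pattern = qs[[sd]], subject = Biostrings::DNAString(db$seq[j]),
        type = "local", substitutionMatrix = .substitution_matrix(),
        gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
      row <- data.frame(
        ref_id = db$id[j], score = Biostrings::score(a),
        identity = 100 * Biostrings::nmatch(a) / Biostrings::nchar(a),
        aln_len = Biostrings::nchar(a), strand = sd,
        stringsAsFactors = FALSE)
      if (is.null(best) || row$score > best$score) best <- row
    }
    rows[[length(rows) + 1L]] <- best
  }
  hits <- do.call(rbind, rows)
  hits[order(-hits$score, -hits$identity, -hits$aln_len, hits$ref_id), ,
       drop = FALSE]
}

#' Best-hit taxonomic classification
#'
#' Each query is aligned locally (match +1, mismatch -1, gap open -2, gap
#' extend -1) against the reference database on both strands; hits are
#' ordered by score, then percent identity, then alignment length, then
#' reference id — a deterministic surrogate for an E-value/bit-score sort
#' — and only the top hit is used. At each level the query is assigned
#' the top hit's taxon iff the hit's identity meets the level threshold,
#' and left unassigned otherwise. References are shortlisted by shared
#' k-mer counts before alignment.
#'
#' @param queries Data.frame with columns `id` and `seq` (e.g.
#'   [em_finalize()] output) or a character vector of sequences.
#' @param db Reference table (`id`, `seq`).
#' @param tax Taxonomy table covering the reference ids.
#' @param levels Taxonomic levels to evaluate (default species, genus,
#'   phylum).
#' @param thresholds Named percent-identity thresholds, default
#'   [classification_thresholds()].
#' @param top_n Number of shortlisted references per query (default 10).
#' @param k Shortlisting k-mer length.
#' @return Data.frame with one row per query and level: `query_id`,
#'   `level`, `taxon` (NA when unassigned), `ref_id`, `identity`,
#'   `assigned`.
#' @export
best_hit_classify <- function(queries, db, tax,
                              levels = c("species", "genus", "phylum"),
                              thresholds = classification_thresholds(),
                              top_n = 10L, k = 12L) {
  if (is.character(queries)) {
    queries <- data.frame(id = paste0("q", seq_along(queries)),
                          seq = queries, stringsAsFactors = FALSE)
  }
  if (nrow(db) == 0L) stop("empty reference database", call. = FALSE)
  if (any(!nzchar(queries$seq))) stop("empty query sequence", call. = FALSE)
  stopifnot(all(levels %in% tax_ranks()), all(levels %in% names(thresholds)))
  km <- cpp_kmer_hits(db$seq, queries$seq, as.integer(k))
  out <- list()
  for (i in seq_len(nrow(queries))) {
    cnt <- km$fwd[i, ] + km$rev[i, ]
    shortlist <- order(-cnt, seq_along(cnt))[seq_len(min(top_n, nrow(db)))]
    hits <- .local_hits(queries$seq[i], db, shortlist, km$fwd[i, ],
                        km$rev[i, ])
    top <- hits[1L, ]
    ti <- match(top$ref_id, tax$id)
    for (lv in levels) {
      ok <- top$identity >= thresholds[[lv]] && !is.na(ti) &&
        nzchar(tax[[lv]][ti])
      out[[length(out) + 1L]] <- data.frame(
        query_id = queries$id[i], level = lv,
        taxon = if (ok) tax[[lv]][ti] else NA_character_,
        ref_id = top$ref_id, identity = top$identity,
        assigned = ok, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Paired-read same-OTU concordance assignment
#'
#' Each mate is independently assigned to its best centroid by ungapped
#' identity, scanning both strands; the pair is accepted only when both
#' mates reach `identity` on the same centroid. Mirrors closed-reference
#' OTU picking with a both-mates-agree filter.
#'
#' @param pairs Pair table (columns `seq1`, `seq2`).
#' @param centroids Data.frame with columns `id`, `seq` — a pre-clustered
#'   centroid set, e.g. from [greedy_cluster()] over database amplicons.
#' @param identity Identity threshold (default 0.97).
#' @param k Seed k-mer length for placement.
#' @return Data.frame with one row per pair: `id`, `otu` (centroid id or
#'   NA) and `reason` (`assigned`, `below-identity` or
#'   `discordant-mates`).
#' @export
paired_otu_assign <- function(pairs, centroids, identity = 0.97, k = 15L) {
  stopifnot(all(c("id", "seq") %in% names(centroids)))
  n <- nrow(pairs)
  a1 <- cpp_map_single(centroids$seq, pairs$seq1, as.integer(k))
  a2 <- cpp_map_single(centroids$seq, pairs$seq2, as.integer(k))
  pick <- function(a) {
    cand <- rep(NA_integer_, n)
    ok <- (1 - a$mm / a$len) >= identity
    cand[a$read[ok]] <- a$cand[ok]
    cand
  }
  c1 <- pick(a1); c2 <- pick(a2)
  otu <- rep(NA_character_, n)
  reason <- rep("below-identity", n)
  both <- !is.na(c1) & !is.na(c2)
  agree <- both & c1 == c2
  reason[both & !agree] <- "discordant-mates"
  reason[agree] <- "assigned"
  otu[agree] <- centroids$id[c1[agree]]
  data.frame(id = pairs$id, otu = otu, reason = reason,
             stringsAsFactors = FALSE)
}

#' Single-read OTU assignment (no concordance filter)
#'
#' The one-mate counterpart of [paired_otu_assign()], useful for
#' quantifying what the concordance filter buys.
#'
#' @param reads Character vector of read sequences.
#' @param centroids Centroid table (`id`, `seq`).
#' @param identity Identity threshold (default 0.97).
#' @param k Seed k-mer length.
#' @return Character vector of centroid ids (NA where unassigned).
#' @export
single_otu_assign <- function(reads, centroids, identity = 0.97, k = 15L) {
  a <- cpp_map_single(centroids$seq, reads, as.integer(k))
  out <- rep(NA_character_, length(reads))
  ok <- (1 - a$mm / a$len) >= identity
  out[a$read[ok]] <- centroids$id[a$cand[ok]]
  out
}

#' Aggregate assignments into a community profile at a taxonomic level
#'
#' Assigned items are weighted (uniformly for read counts, or by
#' reconstructed abundance for EM output), aggregated by the taxon label
#' their reference carries at `level`, filtered at `min_abundance` and
#' renormalized.
#'
#' @param ref_ids Character vector of assigned reference/OTU ids (NAs are
#'   dropped).
#' @param tax Taxonomy table.
#' @param level One of [tax_ranks()].
#' @param weights Optional per-item weights (default 1 per item).
#' @param min_abundance Relative-abundance floor applied after aggregation
#'   (default 0.001).
#' @return Profile data.frame (`taxon_id` = level label, `abundance`).
#' @export
profile_from_assignments <- function(ref_ids, tax, level, weights = NULL,
                                     min_abundance = 0.001) {
  stopifnot(level %in% tax_ranks())
  if (is.null(weights)) weights <- rep(1, length(ref_ids))
  stopifnot(length(weights) == length(ref_ids))
  keep <- !is.na(ref_ids)
  ref_ids <- ref_ids[keep]; weights <- weights[keep]
  if (length(ref_ids) == 0L) stop("zero assigned items", call. = FALSE)
  labels <- tax[[level]][match(ref_ids, tax$id)]
  ok <- !is.na(labels) & nzchar(labels)
  if (!any(ok)) stop("no assigned item is labelled at level ", level,
                     call. = FALSE)
  agg <- rowsum(weights[ok], labels[ok])
  ab <- agg[, 1L] / sum(agg[, 1L])
  ab <- ab[ab >= min_abundance]
  if (length(ab) == 0L) stop("all taxa fall below the abundance floor",
                             call. = FALSE)
  ab <- ab / sum(ab)
  o <- order(-ab, names(ab))
  data.frame(taxon_id = names(ab)[o], abundance = unname(ab[o]),
             stringsAsFactors = FALSE)
}
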