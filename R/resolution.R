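# Resolution of end-read vs whole-amplicon sequencing strategies:
# extract the region a strategy would observe, cluster greedily at an
# identity threshold (97% ~ species, 95% ~ genus) and measure how many
# OTUs each strategy can distinguish, plus the taxonomic purity of the
# resulting clusters.

.substitution_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
    }
    m
  }
})

# Alignment scoring used for identity everywhere in the package:
# match +1, mismatch -1, gap open -2, gap extend -1.
.GAP_OPEN <- 1
.GAP_EXT <- 1

#' Extract the region a sequencing strategy reads from an amplicon
#'
#' @param amplicon_seq Amplicon sequence (5'->3').
#' @param mode `"whole"` (the full amplicon), `"end5"` (first `read_len`
#'   bases) or `"end3"` (last `read_len` bases, reported 5'->3' as read,
#'   i.e. reverse-complemented).
#' @param read_len Read length for the end modes (default 76).
#' @return The extracted sequence; end windows are truncated to the
#'   amplicon length when the amplicon is shorter than `read_len`.
#' @export
extract_region <- function(amplicon_seq, mode = c("whole", "end5", "end3"),
                           read_len = 76L) {
  mode <- match.arg(mode)
  stopifnot(read_len > 0L, nchar(amplicon_seq) > 0L)
  n <- nchar(amplicon_seq)
  switch(mode,
         whole = amplicon_seq,
         end5 = substr(amplicon_seq, 1L, min(read_len, n)),
         end3 = revcomp(substr(amplicon_seq, max(1L, n - read_len + 1L), n)))
}

#' Global-alignment identity between two sequences
#'
#' Needleman-Wunsch alignment (match +1, mismatch -1, gap open -2, gap
#' extend -1); identity is matches divided by alignment columns, gap
#' columns included.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  identity_to_set(a, b)[1L]
}

# Identity of one sequence against many, one vectorized alignment call.
# Columns are counted on the gapped pattern (terminal gaps included).
identity_to_set <- function(seq, set) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(set),
    subject = Biostrings::DNAString(seq),
    type = "global", substitutionMatrix = .substitution_matrix(),
    gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / cols
}

# Identity against many with a threshold screen. Under the scoring used
# here (match +1, mismatch -1, every gap column costs at least 1 plus the
# opening point), an alignment with matches >= t * cols and cols >= Lmax
# has score >= t*cols - 2*(1-t)*cols = (3t-2)*cols >= (3t-2)*Lmax. A
# score-only pass (cheap: no traceback) below that bound therefore proves
# identity < t, and only surviving pairs get the full alignment.
identity_to_set_screened <- function(seq, set, threshold) {
  out <- numeric(length(set))
  bound <- 3 * threshold - 2
  if (bound <= 0) return(identity_to_set(seq, set))
  sc <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(set),
    subject = Biostrings::DNAString(seq),
    type = "global", substitutionMatrix = .substitution_matrix(),
    gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT, scoreOnly = TRUE)
  keep <- which(sc >= bound * pmax(nchar(seq), nchar(set)))
  if (length(keep)) out[keep] <- identity_to_set(seq, set[keep])
  out
}

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are processed in order of decreasing length (ties keep input
#' order). Each sequence joins the first existing centroid it matches at
#' `identity >= threshold`; otherwise it founds a new cluster. The
#' procedure is deterministic.
#'
#' @param seqs Character vector of sequences.
#' @param threshold Identity threshold in (0, 1].
#' @param ids Optional sequence ids (default `seq1`, `seq2`, ...).
#' @return An object of class `otu_clusters`: list with `assignments`
#'   (data.frame `id`, `seq_len`, `centroid_id`, `identity`) and
#'   `threshold`. Centroids have identity 1 to themselves.
#' @export
greedy_cluster <- function(seqs, threshold, ids = NULL) {
  stopifnot(threshold > 0, threshold <= 1, length(seqs) > 0L)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  ord <- order(-nchar(seqs), seq_along(seqs))
  cen_seq <- character(); cen_id <- character(); cen_len <- integer()
  out_centroid <- character(length(seqs))
  out_ident <- numeric(length(seqs))
  for (i in ord) {
    s <- seqs[i]; n <- nchar(s)
    assigned <- FALSE
    if (length(cen_seq)) {
      # identity <= min(len)/max(len): skip centroids this bound rules out
      bound <- pmin(n, cen_len) / pmax(n, cen_len)
      cand <- which(bound >= threshold)
      if (length(cand)) {
        idn <- identity_to_set_screened(s, cen_seq[cand], threshold)
        hit <- which(idn >= threshold)
        if (length(hit)) {
          k <- cand[hit[1L]]          # first centroid in founding order
          out_centroid[i] <- cen_id[k]
          out_ident[i] <- idn[hit[1L]]
          assigned <- TRUE
        }
      }
    }
    if (!assigned) {
      cen_seq <- c(cen_seq, s); cen_id <- c(cen_id, ids[i])
      cen_len <- c(cen_len, n)
      out_centroid[i] <- ids[i]
      out_ident[i] <- 1
    }
  }
  structure(list(
    assignments = data.frame(id = ids, seq_len = nchar(seqs),
                             centroid_id = out_centroid,
                             identity = out_ident, stringsAsFactors = FALSE),
    threshold = threshold), class = "otu_clusters")
}

#' @export
print.otu_clusters <- function(x, ...) {
  cat(sprintf("otu_clusters: %d sequences in %d clusters at %.2f identity\n",
              nrow(x$assignments), length(unique(x$assignments$centroid_id)),
              x$threshold))
  invisible(x)
}

#' Number of clusters in a clustering
#'
#' @param clusters An `otu_clusters` object.
#' @return Integer cluster count.
#' @export
n_clusters <- function(clusters) {
  length(unique(clusters$assignments$centroid_id))
}

#' Fraction of taxonomically pure clusters
#'
#' A cluster is pure when all its members that carry a non-empty label at
#' `level` share one label; members with an empty label abstain, and a
#' cluster with no labelled member counts as pure.
#'
#' @param clusters An `otu_clusters` object from [greedy_cluster()].
#' @param tax Taxonomy table from [read_taxonomy()]; every member id must
#'   appear in it.
#' @param level One of [tax_ranks()].
#' @param otu_ids Optional named character vector mapping member id to an
#'   OTU id; when given, labels at `level` are taken from it instead of the
#'   taxonomy (mirrors species-level purity measured on database OTU ids).
#' @return Fraction in [0, 1].
#' @export
cluster_purity <- function(clusters, tax, level, otu_ids = NULL) {
  stopifnot(inherits(clusters, "otu_clusters"), level %in% tax_ranks())
  a <- clusters$assignments
  if (nrow(a) == 0L) stop("empty clustering", call. = FALSE)
  if (is.null(otu_ids)) {
    miss <- setdiff(a$id, tax$id)
    if (length(miss)) stop("no taxonomy for member: ", miss[1L], call. = FALSE)
    labels <- tax[[level]][match(a$id, tax$id)]
  } else {
    labels <- unname(otu_ids[a$id])
    labels[is.na(labels)] <- ""
  }
  pure <- vapply(split(labels, a$centroid_id), function(lab) {
    lab <- lab[nzchar(lab)]
    length(unique(lab)) <= 1L
  }, logical(1L))
  mean(pure)
}

#' Resolution table: OTU counts and purity per strategy
#'
#' Runs in-silico PCR for each primer pair, extracts the region each
#' sequencing strategy observes, clusters at each identity threshold and
#' reports cluster counts with taxonomic purity — the whole-amplicon
#' strategies can be compared directly against 5'/3' end windows.
#'
#' @param db Reference table (`id`, `seq`).
#' @param tax Taxonomy table.
#' @param pairs Named list of [primer_pair()] objects.
#' @param modes Character vector of region modes, see [extract_region()].
#' @param read_len End-window read length (default 76).
#' @param thresholds Named numeric vector mapping evaluation level to
#'   identity threshold, default `c(species = 0.97, genus = 0.95)`.
#' @param trim_primers Cluster primer-trimmed amplicons (default) or full
#'   products.
#' @return Data.frame with columns `pair`, `mode`, `level`, `threshold`,
#'   `n_seqs`, `n_otus`, `purity`.
#' @export
resolution_table <- function(db, tax, pairs,
                             modes = c("whole", "end5", "end3"),
                             read_len = 76L,
                             thresholds = c(species = 0.97, genus = 0.95),
                             trim_primers = TRUE) {
  if (is.null(names(pairs))) names(pairs) <- paste0("pair", seq_along(pairs))
  rows <- list()
  for (pname in names(pairs)) {
    amps <- insilico_pcr(db, pairs[[pname]])
    if (nrow(amps) == 0L) stop("no record amplifiable by pair ", pname,
                               call. = FALSE)
    base <- if (trim_primers) amps$trimmed_seq else amps$full_seq
    for (mode in modes) {
      regions <- vapply(base, extract_region, character(1L),
                        mode = mode, read_len = read_len, USE.NAMES = FALSE)
      for (lv in names(thresholds)) {
        cl <- greedy_cluster(regions, thresholds[[lv]], ids = amps$ref_id)
        rows[[length(rows) + 1L]] <- data.frame(
          pair = pname, mode = mode, level = lv,
          threshold = thresholds[[lv]], n_seqs = nrow(amps),
          n_otus = n_clusters(cl),
          purity = cluster_purity(cl, tax, lv), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
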