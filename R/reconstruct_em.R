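# Expectation-maximization reconstruction of amplicon sequences and their
# relative abundances from paired short reads.
#
# The mixture model: each read pair arises from one of K candidate
# amplicon sequences with prior pi_k; given the (ungapped) placement of
# the pair on a candidate, each base matches the candidate with
# probability 1 - eps_i and mismatches with probability eps_i / 3, where
# eps_i is the per-cycle substitution rate of the error profile. The
# E-step computes pair-to-candidate responsibilities, the M-step updates
# pi; every few iterations the candidate consensus sequences themselves
# are re-estimated from posterior-weighted base counts (allowing recovery
# of variants absent from the starting reference set) and near-identical
# candidates are merged.

#' Map read pairs onto candidate amplicons
#'
#' Ungapped seed-and-extend placement of both mates at a consistent
#' insert, on both strands; a (pair, candidate) alignment is kept when the
#' combined mismatch rate over both mates is at most `max_mismatch_rate`.
#'
#' @param pairs Pair table (columns `seq1`, `seq2`).
#' @param candidates Data.frame with columns `id`, `seq` — typically the
#'   reference database's amplicons from [insilico_pcr()]/[amplicon_set()].
#' @param max_mismatch_rate Combined mismatch-rate cutoff (default 0.06,
#'   about twice the 97% species radius).
#' @param k Seed k-mer length.
#' @return A `read_alignments` object: list with `map` (data.frame `pair`,
#'   `cand`, `off1`, `off2`, `mm`, `orient`), `n_pairs`, `n_mapped` and
#'   `unmapped` (indices of pairs with no retained candidate).
#' @export
build_candidate_alignments <- function(pairs, candidates,
                                       max_mismatch_rate = 0.06, k = 15L) {
  if (nrow(candidates) == 0L) stop("no candidates", call. = FALSE)
  stopifnot(all(c("id", "seq") %in% names(candidates)),
            all(c("seq1", "seq2") %in% names(pairs)))
  map <- cpp_map_pairs(candidates$seq, pairs$seq1, pairs$seq2,
                       as.integer(k), max_mismatch_rate)
  mapped <- unique(map$pair)
  structure(list(map = map, n_pairs = nrow(pairs),
                 n_mapped = length(mapped),
                 unmapped = setdiff(seq_len(nrow(pairs)), mapped)),
            class = "read_alignments")
}

#' Initialize the EM mixture state
#'
#' @param pairs Pair table the alignments were built from.
#' @param candidates Candidate table (`id`, `seq`).
#' @param alignments Output of [build_candidate_alignments()].
#' @param error_profile Per-cycle quality profile (see
#'   [default_error_profile()]); its error rates parameterize the
#'   emission model.
#' @return A `mixture_state` object with uniform pi.
#' @export
mixture_state <- function(pairs, candidates, alignments, error_profile) {
  stopifnot(inherits(alignments, "read_alignments"))
  if (alignments$n_mapped == 0L) stop("zero mapped pairs", call. = FALSE)
  eps <- error_rates(error_profile)
  st <- structure(list(
    cand_id = candidates$id,
    cand_seq = candidates$seq,
    pi = rep(1 / nrow(candidates), nrow(candidates)),
    map = alignments$map,
    m1 = pairs$seq1, m2 = pairs$seq2,
    eps = eps,
    n_mapped = alignments$n_mapped,
    loglik = NA_real_, trace = numeric(),
    resp = NULL), class = "mixture_state")
  .refresh_emissions(st)
}

.refresh_emissions <- function(state) {
  em <- cpp_log_emissions(state$cand_seq, state$m1, state$m2,
                          state$map$pair, state$map$cand,
                          state$map$off1, state$map$off2,
                          state$map$orient, state$eps)
  state$map$loge <- em$loge
  state$map$mm <- em$mm
  state
}

# One E-step: responsibilities per mapping row and total log-likelihood of
# the mapped pairs.
.estep <- function(state) {
  out <- cpp_estep(state$map$loge, state$map$pair, state$map$cand,
                   log(pmax(state$pi, 1e-300)), length(state$m1))
  list(resp = out$resp, loglik = out$loglik)
}

#' Run EM iterations on a mixture state
#'
#' Alternates E- and M-steps until `max(|delta pi|) < tol` or `max_iter`
#' iterations. Every `consensus_every` iterations the candidate sequences
#' are re-estimated (see [consensus_update()]) and candidates at
#' `merge_identity` or above are merged; both events reset the
#' log-likelihood baseline, which is otherwise non-decreasing.
#'
#' @param state A `mixture_state`.
#' @param max_iter,tol Convergence controls (defaults 40, 1e-5).
#' @param consensus_every,merge_every Period, in iterations, of consensus
#'   re-estimation and of merging (default 5; use `Inf` to disable).
#' @param merge_identity Identity at or above which candidates merge
#'   (default 0.97).
#' @param consensus_ratio Challenger-to-incumbent weight ratio required to
#'   flip a consensus base (default 1.5).
#' @return The converged `mixture_state`; `$trace` holds the per-iteration
#'   log-likelihood and `$monotone` whether it was non-decreasing across
#'   consecutive pure EM iterations.
#' @export
em_iterate <- function(state, max_iter = 40L, tol = 1e-5,
                       consensus_every = 5L, merge_every = 5L,
                       merge_identity = 0.97, consensus_ratio = 1.5) {
  stopifnot(inherits(state, "mixture_state"))
  monotone <- TRUE
  baseline_reset <- TRUE
  for (it in seq_len(max_iter)) {
    es <- .estep(state)
    if (!baseline_reset && length(state$trace) &&
        es$loglik < utils::tail(state$trace, 1L) - 1e-6) {
      monotone <- FALSE
    }
    state$trace <- c(state$trace, es$loglik)
    state$loglik <- es$loglik
    state$resp <- es$resp
    baseline_reset <- FALSE
    # M-step
    pi_new <- rep(0, length(state$pi))
    agg <- rowsum(es$resp, state$map$cand)
    pi_new[as.integer(rownames(agg))] <- agg[, 1L]
    pi_new <- pi_new / state$n_mapped
    delta <- max(abs(pi_new - state$pi))
    state$pi <- pi_new
    structural <- FALSE
    if (is.finite(consensus_every) && it %% consensus_every == 0L) {
      new_seq <- consensus_update(state, ratio = consensus_ratio)
      if (!identical(new_seq, state$cand_seq)) {
        state$cand_seq <- new_seq
        state <- .refresh_emissions(state)
        structural <- TRUE
      }
    }
    if (is.finite(merge_every) && it %% merge_every == 0L) {
      nold <- length(state$pi)
      state <- merge_similar(state, identity = merge_identity)
      if (length(state$pi) != nold) structural <- TRUE
    }
    if (structural) baseline_reset <- TRUE
    if (delta < tol && !structural) break
  }
  state <- merge_similar(state, identity = merge_identity)
  state$monotone <- monotone
  state
}

#' Posterior-weighted consensus re-estimation
#'
#' For every candidate position, mapped reads vote with their current
#' responsibilities for the base they carry; the incumbent base is
#' replaced by the top challenger iff the challenger's weight is at least
#' `ratio` times the incumbent's (ties keep the incumbent).
#'
#' @param state A `mixture_state` with responsibilities computed.
#' @param ratio Replacement weight ratio (default 1.5).
#' @param min_weight Minimum posterior weight (in read-equivalents) the
#'   challenger must reach (default 0.5). Without this floor, candidates
#'   that attract no reads of their own drift along vanishing
#'   responsibilities from neighbouring mixture components and can bridge
#'   two real sequences at the merge threshold.
#' @return Character vector of updated candidate sequences.
#' @export
consensus_update <- function(state, ratio = 1.5, min_weight = 0.5) {
  stopifnot(inherits(state, "mixture_state"))
  if (is.null(state$resp)) stop("run an E-step first", call. = FALSE)
  cpp_consensus_update(state$cand_seq, state$m1, state$m2,
                       state$map$pair, state$map$cand,
                       state$map$off1, state$map$off2, state$map$orient,
                       state$resp, ratio, min_weight)
}

# Ungapped identity for equal-length sequences, alignment identity
# otherwise (candidate consensus drift is substitution-only, so equal
# lengths are the common case).
.consensus_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    ra <- charToRaw(a); rb <- charToRaw(b)
    sum(ra == rb) / length(ra)
  } else {
    pairwise_identity(a, b)
  }
}

#' Merge near-identical candidates
#'
#' Candidate pairs whose consensus identity is at least `identity` are
#' merged single-linkage; the merged candidate keeps the id and sequence
#' of its highest-pi member and the summed pi.
#'
#' @param state A `mixture_state`.
#' @param identity Merge threshold (default 0.97).
#' @return The (possibly reduced) `mixture_state`.
#' @export
merge_similar <- function(state, identity = 0.97) {
  stopifnot(inherits(state, "mixture_state"))
  K <- length(state$pi)
  if (K <= 1L) return(state)
  len <- nchar(state$cand_seq)
  group <- seq_len(K)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  for (i in seq_len(K - 1L)) {
    for (j in seq.int(i + 1L, K)) {
      if (min(len[i], len[j]) / max(len[i], len[j]) < identity) next
      if (find(i) == find(j)) next
      if (.consensus_identity(state$cand_seq[i], state$cand_seq[j]) >=
          identity) {
        group[find(j)] <- find(i)
      }
    }
  }
  group <- vapply(seq_len(K), find, integer(1L))
  if (length(unique(group)) == K) return(state)
  # representative = highest-pi member of each group
  reps <- vapply(split(seq_len(K), group), function(idx) {
    idx[which.max(state$pi[idx])]
  }, integer(1L))
  newidx <- integer(K)          # old candidate -> new (compact) index
  newidx[as.integer(names(reps))] <- seq_along(reps)
  tonew <- newidx[group]
  pi_new <- as.vector(rowsum(state$pi, tonew))
  state$cand_id <- state$cand_id[reps]
  state$cand_seq <- state$cand_seq[reps]
  state$pi <- pi_new
  m <- state$map
  m$cand <- tonew[m$cand]
  # one mapping per (pair, candidate): keep the best placement
  o <- order(m$pair, m$cand, m$mm)
  m <- m[o, , drop = FALSE]
  m <- m[!duplicated(m[, c("pair", "cand")]), , drop = FALSE]
  state$map <- m
  state$resp <- NULL
  .refresh_emissions(state)
}

#' Final abundance calls from a converged mixture state
#'
#' Candidates below `min_abundance` are dropped and the survivors
#' renormalized to sum to 1, sorted by abundance descending.
#'
#' @param state A `mixture_state` after [em_iterate()].
#' @param min_abundance Relative-abundance floor (default 0.001, the 0.1%
#'   rule).
#' @return Data.frame with columns `id`, `seq`, `abundance`.
#' @export
em_finalize <- function(state, min_abundance = 0.001) {
  stopifnot(inherits(state, "mixture_state"))
  keep <- which(state$pi >= min_abundance)
  if (length(keep) == 0L) {
    stop("all candidates fall below the abundance floor", call. = FALSE)
  }
  ab <- state$pi[keep] / sum(state$pi[keep])
  o <- order(-ab, seq_along(ab))
  data.frame(id = state$cand_id[keep][o], seq = state$cand_seq[keep][o],
             abundance = ab[o], stringsAsFactors = FALSE)
}

#' Reconstruct amplicons from read pairs: map, EM, merge, filter
#'
#' Convenience wrapper running [build_candidate_alignments()],
#' [mixture_state()], [em_iterate()] and [em_finalize()].
#'
#' @inheritParams build_candidate_alignments
#' @inheritParams mixture_state
#' @inheritParams em_iterate
#' @inheritParams em_finalize
#' @return Data.frame of reconstructed sequences with abundances (see
#'   [em_finalize()]); the converged state is attached as attribute
#'   `state`.
#' @export
reconstruct_amplicons <- function(pairs, candidates, error_profile,
                                  max_mismatch_rate = 0.06, k = 15L,
                                  max_iter = 40L, tol = 1e-5,
                                  merge_identity = 0.97,
                                  min_abundance = 0.001) {
  aln <- build_candidate_alignments(pairs, candidates, max_mismatch_rate, k)
  st <- mixture_state(pairs, candidates, aln, error_profile)
  st <- em_iterate(st, max_iter = max_iter, tol = tol,
                   merge_identity = merge_identity)
  out <- em_finalize(st, min_abundance)
  attr(out, "state") <- st
  out
}

#' @export
print.mixture_state <- function(x, ...) {
  cat(sprintf("mixture_state: %d candidates, %d mapped pairs, loglik %.2f\n",
              length(x$pi), x$n_mapped, x$loglik))
  invisible(x)
}
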