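# Synthetic 16S-like reference databases, community abundance profiles and
# paired-end shotgun read simulation over amplicons.
#
# The generator emulates the block architecture of the 16S gene: conserved
# stretches (which carry the primer sites and two internal blocks shared by
# every taxon) alternating with variable regions that diverge between
# genera and, through disjoint per-species "barcode" substitutions, between
# species of a genus. Species of one genus differ by a fixed ~4.3% over the
# trimmed amplicon, i.e. below the 97% species radius but above the 95%
# genus radius, so identity clustering separates species and merges genera
# by construction.

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Architecture of the synthetic 16S-like reference database
#'
#' @param n_species,n_genera Number of species and genera; species are
#'   distributed over genera round-robin.
#' @param gene_length Full gene length in bases.
#' @param fwd_site_start 0-based start of the planted forward-primer site
#'   (a concrete expansion of 338F*).
#' @param product_length Full amplicon length, primer sites included; must
#'   fall in the default 700-1000 product window.
#' @param conserved_blocks 2-column matrix of 0-based half-open intervals,
#'   relative to the gene, held identical across all taxa (in addition to
#'   the two primer sites).
#' @param barcode_size Number of species-specific substitution positions;
#'   within-genus pairwise divergence over the trimmed amplicon is exactly
#'   `2 * barcode_size`.
#' @param genus_divergence Per-site substitution rate applied to variable
#'   positions when deriving each genus backbone from the master sequence.
#' @param dropout Fraction of species whose forward-primer site is
#'   scrambled and which are therefore not amplifiable (default 0.08,
#'   i.e. ~92% primer coverage).
#' @return A `db_architecture` list.
#' @export
db_architecture <- function(n_species = 150L, n_genera = 40L,
                            gene_length = 1450L,
                            fwd_site_start = 300L,
                            product_length = 740L,
                            conserved_blocks = rbind(c(550L, 630L),
                                                     c(800L, 870L)),
                            barcode_size = 15L,
                            genus_divergence = 0.30,
                            dropout = 0.08) {
  fwd_site <- "ACTCCTACGGGAGGCAGC"            # concrete expansion of 338F*
  rev_site <- revcomp("CAACACGAGCTGACGAC")    # concrete expansion of 1061R
  stopifnot(n_species >= n_genera, n_genera >= 1L)
  f0 <- fwd_site_start; f1 <- f0 + nchar(fwd_site)
  e1 <- f0 + product_length; e0 <- e1 - nchar(rev_site)
  if (e1 > gene_length) stop("product extends past gene end", call. = FALSE)
  iv <- rbind(c(f0, f1), conserved_blocks, c(e0, e1))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  if (any(iv[-1L, 1L] < iv[-nrow(iv), 2L])) {
    stop("architecture sites overlap", call. = FALSE)
  }
  if (any(conserved_blocks[, 1L] < f1) || any(conserved_blocks[, 2L] > e0)) {
    stop("conserved blocks must lie inside the trimmed amplicon",
         call. = FALSE)
  }
  structure(list(n_species = as.integer(n_species),
                 n_genera = as.integer(n_genera),
                 gene_length = as.integer(gene_length),
                 fwd_site = fwd_site, rev_site = rev_site,
                 fwd_site_start = as.integer(f0),
                 product_length = as.integer(product_length),
                 conserved_blocks = conserved_blocks,
                 barcode_size = as.integer(barcode_size),
                 genus_divergence = genus_divergence,
                 dropout = dropout), class = "db_architecture")
}

.BASES <- c("A", "C", "G", "T")

# Substitute chars[idx] by a uniformly chosen different base.
.mutate_positions <- function(chars, idx) {
  if (length(idx) == 0L) return(chars)
  cur <- match(chars[idx], .BASES)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  chars
}

#' Generate a synthetic 16S-like reference database with taxonomy
#'
#' Deterministic for a fixed seed. Every record is amplifiable by the
#' default 338F*/1061R pair except the `dropout` fraction, whose
#' forward-primer site is scrambled.
#'
#' @param arch A [db_architecture()].
#' @param seed Integer seed.
#' @return List with `db` (reference table: `id`, `seq`), `tax` (taxonomy
#'   table, see [read_taxonomy()]) and `arch`.
#' @export
generate_reference_db <- function(arch = db_architecture(), seed = 1L) {
  stopifnot(inherits(arch, "db_architecture"))
  .with_seed(seed, {
    L <- arch$gene_length
    f0 <- arch$fwd_site_start
    f1 <- f0 + nchar(arch$fwd_site)
    e1 <- f0 + arch$product_length
    e0 <- e1 - nchar(arch$rev_site)
    master <- sample(.BASES, L, replace = TRUE)
    master[(f0 + 1L):f1] <- strsplit(arch$fwd_site, "")[[1L]]
    master[(e0 + 1L):e1] <- strsplit(arch$rev_site, "")[[1L]]
    fixed <- logical(L)
    fixed[(f0 + 1L):f1] <- TRUE
    fixed[(e0 + 1L):e1] <- TRUE
    for (b in seq_len(nrow(arch$conserved_blocks))) {
      blk <- arch$conserved_blocks[b, ]
      fixed[(blk[1L] + 1L):blk[2L]] <- TRUE
    }
    # 1-based variable positions inside the trimmed amplicon (barcode pool)
    interior <- setdiff((f1 + 1L):e0, which(fixed))
    genus_of <- rep(seq_len(arch$n_genera), length.out = arch$n_species)
    genus_of <- sort(genus_of)
    n_per_genus <- tabulate(genus_of, arch$n_genera)
    if (max(n_per_genus) * arch$barcode_size > length(interior)) {
      stop("not enough variable amplicon positions for species barcodes",
           call. = FALSE)
    }
    ids <- sprintf("ref%03d", seq_len(arch$n_species))
    seqs <- character(arch$n_species)
    sp <- 0L
    for (g in seq_len(arch$n_genera)) {
      backbone <- master
      varpos <- which(!fixed)
      mut <- varpos[stats::runif(length(varpos)) < arch$genus_divergence]
      backbone <- .mutate_positions(backbone, mut)
      bar_pool <- sample(interior)       # disjoint barcodes within the genus
      for (j in seq_len(n_per_genus[g])) {
        sp <- sp + 1L
        take <- bar_pool[((j - 1L) * arch$barcode_size + 1L):
                           (j * arch$barcode_size)]
        seqs[sp] <- paste(.mutate_positions(backbone, take), collapse = "")
      }
    }
    # primer-site dropout: scramble three bases of the forward site
    drop_idx <- which(stats::runif(arch$n_species) < arch$dropout)
    for (i in drop_idx) {
      ch <- strsplit(seqs[i], "")[[1L]]
      at <- f0 + c(3L, 9L, 15L)
      ch[at] <- .BASES[(match(ch[at], .BASES) %% 4L) + 1L]
      # the scrambled positions face concrete primer letters, so the
      # degenerate primer can no longer match this site
      seqs[i] <- paste(ch, collapse = "")
    }
    ranks <- tax_ranks()
    tax <- data.frame(id = ids, stringsAsFactors = FALSE)
    tax$kingdom <- "Bacteria"
    tax$phylum <- sprintf("phy%02d", ((genus_of - 1L) %% 4L) + 1L)
    tax$class <- sprintf("cls%02d", ((genus_of - 1L) %% 8L) + 1L)
    tax$order <- sprintf("ord%02d", ((genus_of - 1L) %% 12L) + 1L)
    tax$family <- sprintf("fam%02d", ((genus_of - 1L) %/% 2L) + 1L)
    tax$genus <- sprintf("g%02d", genus_of)
    tax$species <- sprintf("s%03d", seq_len(arch$n_species))
    stopifnot(identical(names(tax), c("id", ranks)))
    list(db = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
         tax = tax, arch = arch)
  })
}

#' Build a community abundance profile
#'
#' @param kind Profile shape:
#'   * `"even"` — `n` equal abundances;
#'   * `"staggered"` — `n` log-spaced abundances between `min_ab` and
#'     `max_ab`, renormalized;
#'   * `"lognormal"` — `n` abundances drawn log-normally (`meanlog`,
#'     `sdlog`), renormalized;
#'   * `"complex_like"` — 67 taxa, log-spaced pre-normalization between
#'     1.03e-6 and 0.103 (0.000103% to 10.3%), then renormalized;
#'   * `"abc33_like"` — 33 equal abundances (an equimolar mock community).
#' @param n Number of taxa (fixed at 67 / 33 for the `complex_like` /
#'   `abc33_like` kinds).
#' @param taxon_ids Optional taxon ids, default `taxon001`, ...
#' @param min_ab,max_ab Pre-normalization anchors for `"staggered"`.
#' @param meanlog,sdlog Log-normal parameters for `"lognormal"`.
#' @param seed Seed, used by the `"lognormal"` kind only.
#' @return A data.frame with columns `taxon_id` and `abundance` (summing
#'   to 1); the pre-normalization abundances are kept in attribute
#'   `pre_norm`.
#' @export
make_profile <- function(kind = c("even", "staggered", "lognormal",
                                  "complex_like", "abc33_like"),
                         n = NULL, taxon_ids = NULL,
                         min_ab = 0.005, max_ab = 0.10,
                         meanlog = 0, sdlog = 1, seed = 1L) {
  kind <- match.arg(kind)
  n <- switch(kind, complex_like = 67L, abc33_like = 33L,
              if (is.null(n)) stop("n is required for kind ", kind,
                                   call. = FALSE) else as.integer(n))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  raw <- switch(kind,
    even = rep(1 / n, n),
    abc33_like = rep(1 / 33, 33L),
    staggered = exp(seq(log(min_ab), log(max_ab), length.out = n)),
    complex_like = exp(seq(log(1.03e-6), log(0.103), length.out = 67L)),
    lognormal = .with_seed(seed, stats::rlnorm(n, meanlog, sdlog)))
  if (is.null(taxon_ids)) taxon_ids <- sprintf("taxon%03d", seq_len(n))
  stopifnot(length(taxon_ids) == n, !anyDuplicated(taxon_ids))
  out <- data.frame(taxon_id = taxon_ids, abundance = raw / sum(raw),
                    stringsAsFactors = FALSE)
  attr(out, "pre_norm") <- raw
  validate_profile(out)
}

#' Validate a community profile
#'
#' @param profile Data.frame with columns `taxon_id`, `abundance`.
#' @return The profile, invisibly checked: abundances positive and summing
#'   to 1 within 1e-9, unique taxon ids.
#' @export
validate_profile <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("taxon_id", "abundance") %in% names(profile)))
  if (anyDuplicated(profile$taxon_id)) {
    stop("duplicate taxon_id in profile", call. = FALSE)
  }
  if (any(profile$abundance <= 0)) {
    stop("profile abundances must be positive", call. = FALSE)
  }
  if (abs(sum(profile$abundance) - 1) > 1e-9) {
    stop("profile abundances must sum to 1", call. = FALSE)
  }
  profile
}

#' Read / write a community profile (taxon_id<TAB>abundance)
#'
#' @param path TSV path.
#' @return `read_profile`: validated profile data.frame.
#' @export
read_profile <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("taxon_id", "abundance"),
                         colClasses = c("character", "numeric"), quote = "")
  validate_profile(x)
}

#' @rdname read_profile
#' @param profile Profile data.frame.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile[, c("taxon_id", "abundance")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Per-cycle sequencing error profile
#'
#' Mean Phred score per cycle; the substitution probability at cycle i is
#' `10^(-Q_i/10)`, with the erroneous base uniform over the three
#' alternatives. The default is a linear decline from Q34 at the first
#' cycle to Q20 at the last, a representative short-read shape; measured
#' profiles can be loaded with [read_error_profile()].
#'
#' @param read_len Read length.
#' @param q_start,q_end Phred score at the first and last cycle.
#' @return Data.frame with columns `cycle` (0-based) and `q`.
#' @export
default_error_profile <- function(read_len = 75L, q_start = 34, q_end = 20) {
  q <- seq(q_start, q_end, length.out = read_len)
  if (any(q < 2) || any(q > 41)) stop("Q must be in [2, 41]", call. = FALSE)
  data.frame(cycle = seq_len(read_len) - 1L, q = q)
}

#' Read / write an error profile (cycle<TAB>meanQ)
#'
#' @param path TSV path.
#' @return `read_error_profile`: data.frame with columns `cycle`, `q`.
#' @export
read_error_profile <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("cycle", "q"),
                         colClasses = c("integer", "numeric"), quote = "")
  if (any(x$q < 2) || any(x$q > 41)) stop("Q must be in [2, 41]", call. = FALSE)
  x
}

#' @rdname read_error_profile
#' @param profile Error-profile data.frame.
#' @export
write_error_profile <- function(profile, path) {
  utils::write.table(profile[, c("cycle", "q")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Error probabilities per cycle for an error profile
#'
#' @param error_profile Data.frame with columns `cycle`, `q`.
#' @return Numeric vector of per-cycle substitution probabilities.
#' @export
error_rates <- function(error_profile) {
  10^(-error_profile$q / 10)
}

#' Simulate paired-end shotgun reads over amplicons
#'
#' Templates are drawn proportionally to community abundance; the fragment
#' (insert) length is Normal(`insert_mean`, `insert_sd`) rounded, redrawn
#' (up to 100 times, then clamped) until it falls in `[read_len, amplicon
#' length]`; the fragment start is uniform over valid positions. Mate 1 is
#' the 5' `read_len` bases of the fragment; mate 2 is the reverse
#' complement of its 3' end. Substitution errors are applied per sequencing
#' cycle at rate `10^(-Q_i/10)` and every read carries the profile's
#' quality string. Deterministic for a fixed seed.
#'
#' @param amplicons Data.frame with columns `id` and `seq` (ACGT only), one
#'   row per community taxon; e.g. [insilico_pcr()] output via
#'   [amplicon_set()].
#' @param profile Community profile (`taxon_id`, `abundance`); every taxon
#'   must have an amplicon with the matching id.
#' @param n_pairs Number of read pairs.
#' @param read_len,insert_mean,insert_sd Read geometry (defaults 75,
#'   160, 40).
#' @param error_profile Per-cycle quality profile, default
#'   [default_error_profile()].
#' @param seed Integer seed.
#' @param error_free Suppress substitutions entirely (quality strings are
#'   still taken from the profile); the exactness limit of the simulator.
#' @return Pair table (see [read_fastq_pairs()]) with truth columns
#'   `taxon_id`, `frag_start` (0-based on the amplicon) and `insert_len`.
#' @export
simulate_pairs <- function(amplicons, profile, n_pairs,
                           read_len = 75L, insert_mean = 160, insert_sd = 40,
                           error_profile = default_error_profile(read_len),
                           seed = 1L, error_free = FALSE) {
  validate_profile(profile)
  stopifnot(n_pairs >= 1L, read_len >= 1L,
            all(c("id", "seq") %in% names(amplicons)))
  miss <- setdiff(profile$taxon_id, amplicons$id)
  if (length(miss)) {
    stop("profile taxon without amplicon: ", miss[1L], call. = FALSE)
  }
  amp <- amplicons$seq[match(profile$taxon_id, amplicons$id)]
  alen <- nchar(amp)
  if (any(alen < read_len)) {
    stop("amplicon shorter than read length: ",
         profile$taxon_id[which(alen < read_len)[1L]], call. = FALSE)
  }
  if (nrow(error_profile) != read_len) {
    stop("error profile length must equal read length", call. = FALSE)
  }
  eps <- if (error_free) rep(0, read_len) else error_rates(error_profile)
  .with_seed(seed, {
    ti <- sample.int(nrow(profile), n_pairs, replace = TRUE,
                     prob = profile$abundance)
    lo <- read_len; hi <- alen[ti]
    ins <- round(stats::rnorm(n_pairs, insert_mean, insert_sd))
    for (k in seq_len(100L)) {
      bad <- which(ins < lo | ins > hi)
      if (length(bad) == 0L) break
      ins[bad] <- round(stats::rnorm(length(bad), insert_mean, insert_sd))
    }
    ins <- pmin(pmax(ins, lo), hi)
    start <- floor(stats::runif(n_pairs) * (hi - ins + 1))
    frag <- substr(amp[ti], start + 1L, start + ins)
    m1 <- substr(frag, 1L, read_len)
    m2 <- revcomp(substr(frag, ins - read_len + 1L, ins))
    m1 <- .apply_cycle_errors(m1, eps)
    m2 <- .apply_cycle_errors(m2, eps)
    qual <- phred_to_qual(error_profile$q)
    data.frame(id = sprintf("p%07d", seq_len(n_pairs)),
               seq1 = m1, qual1 = qual, seq2 = m2, qual2 = qual,
               taxon_id = profile$taxon_id[ti],
               frag_start = as.integer(start),
               insert_len = as.integer(ins), stringsAsFactors = FALSE)
  })
}

# Substitute bases cycle by cycle at rate eps[i]; reads all of length
# length(eps). Erroneous base uniform over the three alternatives.
.apply_cycle_errors <- function(reads, eps) {
  if (all(eps == 0)) return(reads)
  n <- length(reads)
  mat <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
                nrow = n, byrow = TRUE)
  for (i in seq_along(eps)) {
    hit <- which(stats::runif(n) < eps[i])
    if (length(hit)) {
      cur <- match(mat[hit, i], .BASES)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      mat[hit, i] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
  }
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Turn in-silico PCR hits into an amplicon table for simulation
#'
#' @param pcr_hits Output of [insilico_pcr()].
#' @param use `"full"` (primer sites included, the sheared product) or
#'   `"trimmed"`.
#' @return Data.frame with columns `id` (the reference id) and `seq`.
#' @export
amplicon_set <- function(pcr_hits, use = c("full", "trimmed")) {
  use <- match.arg(use)
  data.frame(id = pcr_hits$ref_id,
             seq = if (use == "full") pcr_hits$full_seq else
               pcr_hits$trimmed_seq,
             stringsAsFactors = FALSE)
}

#' Quality-trim reads and drop short pairs
#'
#' Removes each read's maximal trailing run of bases with quality at or
#' below `qual_floor`, then drops whole pairs in which either trimmed mate
#' is shorter than `min_len` bases.
#'
#' @param pairs Pair table.
#' @param qual_floor Phred floor for trailing-base removal (default 2).
#' @param min_len Minimum surviving mate length (default 60).
#' @return Filtered pair table.
#' @export
trim_and_filter <- function(pairs, qual_floor = 2L, min_len = 60L) {
  keep_len <- function(qual) {
    vapply(qual, function(q) {
      s <- as.integer(charToRaw(q)) - 33L
      ok <- which(s > qual_floor)
      if (length(ok)) ok[length(ok)] else 0L
    }, integer(1L), USE.NAMES = FALSE)
  }
  k1 <- keep_len(pairs$qual1)
  k2 <- keep_len(pairs$qual2)
  pairs$seq1 <- substr(pairs$seq1, 1L, k1)
  pairs$qual1 <- substr(pairs$qual1, 1L, k1)
  pairs$seq2 <- substr(pairs$seq2, 1L, k2)
  pairs$qual2 <- substr(pairs$qual2, 1L, k2)
  out <- pairs[k1 >= min_len & k2 >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the highest-quality read pairs
#'
#' Pairs are ranked by mean Phred score over both mates, descending, ties
#' keeping input order, and the first `n` are retained.
#'
#' @param pairs Pair table.
#' @param n Number of pairs to keep (default 100000; all if fewer).
#' @return Pair table of at most `n` rows.
#' @export
select_top_reads <- function(pairs, n = 100000L) {
  if (nrow(pairs) <= n) return(pairs)
  meanq <- vapply(seq_len(nrow(pairs)), function(i) {
    q <- c(as.integer(charToRaw(pairs$qual1[i])),
           as.integer(charToRaw(pairs$qual2[i]))) - 33L
    mean(q)
  }, numeric(1L))
  out <- pairs[order(-meanq, seq_len(nrow(pairs)))[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
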