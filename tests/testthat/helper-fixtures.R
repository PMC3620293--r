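# Shared fixtures: tiny sequences and databases built in code.

# Concrete expansions of the default degenerate pair (Y->C, R->G, W->A for
# the forward; R->A,A for the reverse), used to embed binding sites.
FWD_SITE <- "ACTCCTACGGGAGGCAGC"            # expansion of 338F*
REV_PRIMER_CONCRETE <- "CAACACGAGCTGACGAC"  # expansion of 1061R
REV_SITE <- amplishot::revcomp(REV_PRIMER_CONCRETE)  # as seen on the + strand

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A reference carrying one 338F*/1061R product of the given interior length.
ref_with_product <- function(interior = 702L, lead = 0L, tail = 0L) {
  paste0(if (lead > 0) random_dna(lead) else "",
         FWD_SITE, strrep("A", interior), REV_SITE,
         if (tail > 0) random_dna(tail) else "")
}

# Mutate `n` distinct positions of a sequence (rotating each base).
mutate_seq <- function(seq, positions) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(seq, "")[[1L]]
  ch[positions] <- bases[(match(ch[positions], bases) %% 4L) + 1L]
  paste(ch, collapse = "")
}

# Small synthetic database + amplicons, cached per options to keep the
# suite fast.
local({
  cache <- new.env(parent = emptyenv())
  small_ref <<- function(n_species = 30L, n_genera = 10L, dropout = 0,
                         seed = 1L) {
    key <- paste(n_species, n_genera, dropout, seed, sep = "_")
    if (is.null(cache[[key]])) {
      arch <- amplishot::db_architecture(n_species = n_species,
                                         n_genera = n_genera,
                                         dropout = dropout)
      ref <- amplishot::generate_reference_db(arch, seed = seed)
      ref$pcr <- amplishot::insilico_pcr(ref$db, amplishot::default_primer_pair())
      ref$amps <- amplishot::amplicon_set(ref$pcr, "full")
      cache[[key]] <- ref
    }
    cache[[key]]
  }
})

# A flat-quality error profile (constant Q at every cycle).
flat_profile <- function(read_len = 75L, q = 30) {
  data.frame(cycle = seq_len(read_len) - 1L, q = rep(q, read_len))
}
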