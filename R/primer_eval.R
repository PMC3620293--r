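# Degenerate-primer matching, universality scoring and in-silico PCR.
#
# Matching semantics: a primer letter matches a reference letter iff their
# IUPAC allowed-base sets intersect ("perfect match after fully accounting
# for ambiguous letters"). No mismatches are tolerated anywhere in the
# primer site, so reported coverage is a lower bound on what would amplify
# in practice.

# 4-bit encoding of IUPAC allowed-base sets (A=1, C=2, G=4, T=8).
.IUPAC_BITS <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(strsplit(map, ""), function(b) sum(bit[b]), integer(1L))
})

.iupac_bits <- function(seq) {
  b <- .IUPAC_BITS[strsplit(seq, "")[[1L]]]
  if (anyNA(b)) stop("non-IUPAC character in '", seq, "'", call. = FALSE)
  unname(b)
}

#' Does a degenerate primer match a same-length window exactly?
#'
#' True iff at every position the IUPAC allowed-base set of the primer
#' letter intersects that of the window letter. Both arguments may contain
#' ambiguity codes; `N` matches anything.
#'
#' @param primer_seq IUPAC primer string, 5'->3'.
#' @param window Reference window of the same length.
#' @return Logical scalar.
#' @export
iupac_match <- function(primer_seq, window) {
  if (nchar(primer_seq) != nchar(window)) {
    stop("primer and window lengths differ", call. = FALSE)
  }
  all(bitwAnd(.iupac_bits(toupper(primer_seq)),
              .iupac_bits(toupper(window))) > 0L)
}

#' Scan a reference for degenerate-primer binding sites
#'
#' Orientation `"forward"` scans the primer as given against the stored
#' strand; `"reverse"` scans the reverse complement of the primer, i.e. the
#' binding site a reverse PCR primer leaves on the stored strand.
#'
#' @param ref_seq Reference sequence (IUPAC string).
#' @param primer_seq Primer sequence, 5'->3'.
#' @param orientation `"forward"` or `"reverse"`.
#' @return Integer vector of 0-based start positions, ascending (empty when
#'   there is no site).
#' @export
scan_primer <- function(ref_seq, primer_seq, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  pat <- toupper(primer_seq)
  if (orientation == "reverse") pat <- revcomp(pat)
  if (nchar(ref_seq) < nchar(pat)) return(integer())
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(toupper(ref_seq)),
                                fixed = FALSE)
  sort(Biostrings::start(m)) - 1L
}

#' Fraction of database records matched by one primer
#'
#' A record counts as hit when the primer has at least one perfect
#' degenerate match in either orientation on the stored strand (which also
#' covers reverse-deposited entries).
#'
#' @param db Reference table (`id`, `seq`), see [read_fasta()].
#' @param primer_seq Primer sequence, 5'->3'.
#' @return Fraction in [0, 1].
#' @export
primer_hit_fraction <- function(db, primer_seq) {
  if (nrow(db) == 0L) stop("empty reference database", call. = FALSE)
  hit <- vapply(db$seq, function(s) {
    length(scan_primer(s, primer_seq, "forward")) > 0L ||
      length(scan_primer(s, primer_seq, "reverse")) > 0L
  }, logical(1L), USE.NAMES = FALSE)
  mean(hit)
}

#' Construct a primer pair with a product-length window
#'
#' The default window of 700-1000 bases mirrors gel purification of the
#' expected V3-V6 product.
#'
#' @param forward,reverse IUPAC primer sequences, each 5'->3'.
#' @param min_product,max_product Allowed full product length in bases
#'   (primer sites included).
#' @param names Optional character vector of length 2 with primer names.
#' @return A `primer_pair` list.
#' @export
primer_pair <- function(forward, reverse, min_product = 700L,
                        max_product = 1000L, names = c("fwd", "rev")) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (nchar(p) < 10L) stop("primer shorter than 10 bases: ", p, call. = FALSE)
    .iupac_bits(p)
  }
  if (!(min_product > 0L && min_product <= max_product)) {
    stop("need 0 < min_product <= max_product", call. = FALSE)
  }
  structure(list(forward = forward, reverse = reverse,
                 min_product = as.integer(min_product),
                 max_product = as.integer(max_product),
                 names = names),
            class = "primer_pair")
}

# One amplicon for one reference and strand, or NULL.
# Policy: leftmost forward site, then the nearest downstream reverse site
# giving a product inside the length window.
.pcr_one_strand <- function(seq, left_pat, right_pat, minp, maxp) {
  f <- scan_primer(seq, left_pat, "forward")
  if (length(f) == 0L) return(NULL)
  r <- scan_primer(seq, right_pat, "reverse")
  if (length(r) == 0L) return(NULL)
  rlen <- nchar(right_pat)
  for (fs in f) {
    ends <- r + rlen                       # half-open product ends
    len <- ends - fs
    ok <- which(len >= minp & len <= maxp)
    if (length(ok)) return(c(fs, ends[ok[1L]]))
  }
  NULL
}

#' In-silico PCR: extract amplicons from a reference table
#'
#' For each record, searches the stored strand for a forward-primer site
#' followed by a reverse-primer binding site with product length inside the
#' pair's window; the complement-strand layout (reverse-deposited entries)
#' is searched as well. At most one amplicon is reported per record: the
#' leftmost forward site with the nearest qualifying reverse site, with the
#' stored-strand product taking precedence. Hits found on the complement
#' are reported reverse-complemented, i.e. in amplicon orientation.
#'
#' @param db Reference table (`id`, `seq`) or a single sequence given as a
#'   one-row data.frame.
#' @param pair A [primer_pair()].
#' @return Data.frame with one row per amplifiable record: `ref_id`,
#'   `start`, `end` (0-based half-open on the stored sequence), `strand`,
#'   `full_seq` (primer sites included) and `trimmed_seq` (both
#'   primer-length flanks removed).
#' @export
insilico_pcr <- function(db, pair) {
  stopifnot(inherits(pair, "primer_pair"))
  fl <- nchar(pair$forward); rl <- nchar(pair$reverse)
  rows <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    s <- db$seq[i]
    hit <- .pcr_one_strand(s, pair$forward, pair$reverse,
                           pair$min_product, pair$max_product)
    strand <- "+"
    if (is.null(hit)) {
      # reverse-deposited entry: reverse primer reads forward at the left,
      # the forward primer's reverse complement closes the product
      hit <- .pcr_one_strand(s, pair$reverse, pair$forward,
                             pair$min_product, pair$max_product)
      strand <- "-"
    }
    if (is.null(hit)) next
    full <- substr(s, hit[1L] + 1L, hit[2L])
    if (strand == "-") full <- revcomp(full)
    trimmed <- substr(full, fl + 1L, nchar(full) - rl)
    rows[[i]] <- data.frame(ref_id = db$id[i], start = hit[1L], end = hit[2L],
                            strand = strand, full_seq = full,
                            trimmed_seq = trimmed, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(ref_id = character(), start = integer(), end = integer(),
                      strand = character(), full_seq = character(),
                      trimmed_seq = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Fraction of database records amplifiable by a primer pair
#'
#' @param db Reference table (`id`, `seq`).
#' @param pair A [primer_pair()].
#' @return Fraction in [0, 1].
#' @export
pair_amplifiable_fraction <- function(db, pair) {
  if (nrow(db) == 0L) stop("empty reference database", call. = FALSE)
  nrow(insilico_pcr(db, pair)) / nrow(db)
}

#' Bundled 16S primer panel
#'
#' Primers at the classical E. coli positions used for V3-V6 amplicon
#' work. 338F* and 1061R are the degenerate pair this package defaults to;
#' the remaining entries are the standard published variants at their
#' positions and are included for universality reports.
#'
#' @return Data.frame with columns `name` and `seq`.
#' @export
primer_panel <- function() {
  data.frame(
    name = c("338F", "338F*", "341F", "533R*", "805R", "907F", "1061R"),
    seq = c("ACTCCTACGGGAGGCAGC",     # 338F (EUB338)
            "ACTYCTACGGRAGGCWGC",     # 338F*, degenerate
            "CCTACGGGAGGCAGCAG",      # 341F
            "TTACCGCGGCKGCTGGCAC",    # 533R*, degenerate
            "GACTACHVGGGTATCTAATCC",  # 805R
            "AAACTYAAAKGAATTGACGG",   # 907F
            "CRRCACGAGCTGACGAC"),     # 1061R
    stringsAsFactors = FALSE)
}

#' Read a primer table (name<TAB>sequence)
#'
#' @param path Path to a two-column TSV file.
#' @return Data.frame with columns `name` and `seq`.
#' @export
read_primers <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("name", "seq"),
                         colClasses = "character", quote = "")
  x$seq <- toupper(x$seq)
  for (p in x$seq) .iupac_bits(p)
  x
}

#' Per-primer universality report
#'
#' @param db Reference table (`id`, `seq`).
#' @param primers Data.frame with columns `name` and `seq`; defaults to the
#'   bundled [primer_panel()].
#' @return Data.frame with columns `name`, `seq`, `hit_fraction`, sorted by
#'   decreasing hit fraction.
#' @export
primer_report <- function(db, primers = primer_panel()) {
  primers$hit_fraction <- vapply(primers$seq, primer_hit_fraction,
                                 numeric(1L), db = db, USE.NAMES = FALSE)
  primers[order(-primers$hit_fraction, primers$name), , drop = FALSE]
}

#' The default 338F*/1061R primer pair
#'
#' @param min_product,max_product Product-length window, defaults 700-1000.
#' @return A [primer_pair()].
#' @export
default_primer_pair <- function(min_product = 700L, max_product = 1000L) {
  panel <- primer_panel()
  primer_pair(panel$seq[panel$name == "338F*"],
              panel$seq[panel$name == "1061R"],
              min_product, max_product, names = c("338F*", "1061R"))
}
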