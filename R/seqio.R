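# Sequence, quality and taxonomy I/O.
#
# Conventions used throughout the package:
#  * sequences are uppercase DNA over the IUPAC alphabet; U is normalized
#    to T on load, any other character is a hard error
#  * FASTQ is Phred+33 only; Phred scores are integers in [0, 41]
#  * all coordinates are 0-based, half-open
#  * tables of records are plain data.frames, one row per record

IUPAC_LETTERS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                   "V", "H", "D", "B", "N")

#' Names of the seven taxonomic ranks, kingdom to species
#'
#' @return Character vector of length 7.
#' @export
tax_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

.check_dna <- function(seq, what = "sequence") {
  bad <- grepl(paste0("[^", paste(IUPAC_LETTERS, collapse = ""), "]"), seq)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(seq[bad][1L], "")))
    chars <- setdiff(chars, IUPAC_LETTERS)
    stop(sprintf("non-IUPAC character '%s' in %s", chars[1L], what),
         call. = FALSE)
  }
  invisible(seq)
}

.normalize_seq <- function(seq) {
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

#' Read a FASTA file into a reference table
#'
#' Sequences are uppercased and U is normalized to T. Any character outside
#' the IUPAC nucleotide alphabet is an error, as are empty sequences and
#' empty or duplicated ids.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (first whitespace-delimited token
#'   of the header) and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) {
    if (all(!nzchar(trimws(lines)))) {
      return(data.frame(id = character(), seq = character(),
                        stringsAsFactors = FALSE))
    }
    stop("malformed FASTA: no header at line 1", call. = FALSE)
  }
  if (any(nzchar(trimws(lines[seq_len(hdr[1L] - 1L)])))) {
    stop("malformed FASTA: sequence before first header at line 1",
         call. = FALSE)
  }
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    stop(sprintf("malformed FASTA: empty header at line %d",
                 hdr[which(!nzchar(ids))[1L]]), call. = FALSE)
  }
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(trimws(lines[starts[i]:ends[i]]), collapse = "")
  }, character(1L))
  if (any(!nzchar(seqs))) {
    stop(sprintf("malformed FASTA: empty sequence for record at line %d",
                 hdr[which(!nzchar(seqs))[1L]]), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  seqs <- .normalize_seq(seqs)
  .check_dna(seqs, "FASTA sequence")
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}

#' Write a reference table to FASTA
#'
#' @param db Data.frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(db, path, width = 70L) {
  stopifnot(is.data.frame(db), all(c("id", "seq") %in% names(db)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(db))) {
    writeLines(paste0(">", db$id[i]), con)
    s <- db$seq[i]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a Greengenes-dialect taxonomy table
#'
#' Expects a two-column tab-separated file: sequence id, then a
#' semicolon-separated lineage whose ranks may carry single-letter prefixes
#' such as `k__`. Prefixes are stripped and missing trailing ranks become
#' empty strings.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with column `id` plus the seven rank columns of
#'   [tax_ranks()].
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ranks <- tax_ranks()
  if (length(lines) == 0L) {
    out <- c(list(id = character()),
             stats::setNames(rep(list(character()), 7L), ranks))
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 2L)) {
    stop(sprintf("taxonomy line %d has %d columns, expected 2",
                 which(nc != 2L)[1L], nc[nc != 2L][1L]), call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate taxonomy id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  lineages <- vapply(parts, `[[`, character(1L), 2L)
  mat <- t(vapply(lineages, parse_lineage, character(7L), USE.NAMES = FALSE))
  out <- data.frame(id = ids, mat, stringsAsFactors = FALSE)
  names(out) <- c("id", ranks)
  out
}

#' Parse one semicolon-separated lineage string
#'
#' @param lineage A string such as `"k__Bacteria; p__Firmicutes"`.
#' @return Character vector of length 7 (kingdom..species), empty strings
#'   for unstated ranks.
#' @export
parse_lineage <- function(lineage) {
  fields <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1L]])
  fields <- sub("^[a-zA-Z]__", "", fields)
  if (length(fields) > 7L) {
    stop("lineage has more than 7 ranks: ", lineage, call. = FALSE)
  }
  c(fields, rep("", 7L - length(fields)))
}

#' Write a taxonomy table in the Greengenes dialect
#'
#' @param tax Data.frame as returned by [read_taxonomy()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_taxonomy <- function(tax, path) {
  ranks <- tax_ranks()
  stopifnot(all(c("id", ranks) %in% names(tax)))
  pref <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  lin <- apply(tax[, ranks, drop = FALSE], 1L, function(r) {
    paste0(pref, r, collapse = "; ")
  })
  writeLines(paste(tax$id, lin, sep = "\t"), path)
  invisible(path)
}

# IUPAC reverse-complement table (complement applied per letter, then the
# string is reversed); R<->Y, K<->M, B<->V, D<->H, W/S/N self-complementary.
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                 M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
                 V = "B", H = "D", D = "H", B = "V", N = "N")

#' IUPAC-aware reverse complement
#'
#' @param seq Character vector of IUPAC nucleotide strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(seq) {
  seq <- toupper(seq)
  .check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Convert a Phred+33 quality string to integer scores
#'
#' @param qual Quality string (one character per base).
#' @return Integer vector of Phred scores.
#' @export
qual_to_phred <- function(qual) {
  q <- as.integer(charToRaw(qual)) - 33L
  if (length(q) && (min(q) < 0L || max(q) > 41L)) {
    stop("Phred score out of range [0, 41]; is this Phred+33?", call. = FALSE)
  }
  q
}

#' Convert integer Phred scores to a Phred+33 quality string
#'
#' @param phred Integer vector of Phred scores in [0, 41].
#' @return Quality string.
#' @export
phred_to_qual <- function(phred) {
  phred <- as.integer(round(phred))
  if (length(phred) && (min(phred) < 0L || max(phred) > 41L)) {
    stop("Phred score out of range [0, 41]", call. = FALSE)
  }
  rawToChar(as.raw(phred + 33L))
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to an uncompressed FASTQ file with 4-line records.
#' @return A data.frame with columns `id`, `seq` and `qual` (the raw
#'   Phred+33 quality string; decode with [qual_to_phred()]).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ file is not made of 4-line records: ", path, call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  at <- function(k) lines[seq.int(k, by = 4L, length.out = n)]
  hdr <- at(1L)
  if (any(substr(hdr, 1L, 1L) != "@")) {
    stop(sprintf("FASTQ record at line %d does not start with '@'",
                 (which(substr(hdr, 1L, 1L) != "@")[1L] - 1L) * 4L + 1L),
         call. = FALSE)
  }
  seqs <- .normalize_seq(at(2L))
  quals <- at(4L)
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    stop(sprintf("sequence/quality length mismatch in FASTQ record at line %d",
                 (which(bad)[1L] - 1L) * 4L + 1L), call. = FALSE)
  }
  .check_dna(seqs, "FASTQ sequence")
  allq <- as.integer(charToRaw(paste(quals, collapse = ""))) - 33L
  if (length(allq) && (min(allq) < 0L || max(allq) > 41L)) {
    stop("Phred score out of range [0, 41]; only Phred+33 is supported",
         call. = FALSE)
  }
  data.frame(id = sub("\\s.*$", "", sub("^@", "", hdr)),
             seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence/quality length mismatch", call. = FALSE)
  }
  out <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read a pair of matched FASTQ files into a pair table
#'
#' Mate files must list the same pairs in the same order; ids are matched
#' after stripping a trailing `/1` or `/2`.
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @return A pair table: data.frame with columns `id` (shared pair id),
#'   `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (nrow(r1) != nrow(r2)) {
    stop("mate files differ in read count", call. = FALSE)
  }
  id1 <- sub("/[12]$", "", r1$id)
  id2 <- sub("/[12]$", "", r2$id)
  if (!identical(id1, id2)) {
    stop("mate files are not pair-matched in order", call. = FALSE)
  }
  data.frame(id = id1, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

#' Write a pair table to two matched FASTQ files
#'
#' @param pairs Pair table (see [read_fastq_pairs()]).
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with `/1` and `/2` mate suffixes.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  write_fastq(data.frame(id = paste0(pairs$id, "/1"), seq = pairs$seq1,
                         qual = pairs$qual1), p1)
  write_fastq(data.frame(id = paste0(pairs$id, "/2"), seq = pairs$seq2,
                         qual = pairs$qual2), p2)
  invisible(c(p1, p2))
}
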