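test_that("reference generation is deterministic and amplifiable", {
  arch <- db_architecture(n_species = 20L, n_genera = 5L, dropout = 0)
  a <- generate_reference_db(arch, seed = 9L)
  b <- generate_reference_db(arch, seed = 9L)
  expect_identical(a, b)
  expect_equal(pair_amplifiable_fraction(a$db, default_primer_pair()), 1.0)
  expect_false(identical(a$db$seq, generate_reference_db(arch, 10L)$db$seq))
})

test_that("primer-site dropout removes roughly the requested fraction", {
  arch <- db_architecture(n_species = 100L, n_genera = 20L, dropout = 0.5)
  fr <- vapply(1:3, function(s) {
    ref <- generate_reference_db(arch, seed = s)
    pair_amplifiable_fraction(ref$db, default_primer_pair())
  }, numeric(1L))
  # binomial(100, 0.5): 4 sigma = 0.2
  expect_true(all(abs(fr - 0.5) < 0.2))
})

test_that("generated divergences respect the clustering radii", {
  ref <- small_ref(n_species = 12L, n_genera = 4L, dropout = 0, seed = 5L)
  amp <- ref$pcr$trimmed_seq
  genus <- ref$tax$genus[match(ref$pcr$ref_id, ref$tax$id)]
  ham_div <- function(a, b) {
    mean(charToRaw(a) != charToRaw(b))
  }
  for (i in 1:(length(amp) - 1L)) for (j in (i + 1L):length(amp)) {
    d <- ham_div(amp[i], amp[j])
    if (genus[i] == genus[j]) {
      expect_gt(d, 0.03); expect_lt(d, 0.05)
    } else {
      expect_gt(d, 0.05)
    }
  }
  expect_true(all(nchar(ref$pcr$full_seq) >= 700 &
                  nchar(ref$pcr$full_seq) <= 1000))
})

test_that("profile kinds match their stated shapes", {
  p <- make_profile("complex_like")
  expect_equal(nrow(p), 67L)
  pre <- attr(p, "pre_norm")
  expect_equal(min(pre), 1.03e-6)
  expect_equal(max(pre), 0.103)
  expect_equal(sum(p$abundance), 1, tolerance = 1e-12)

  p33 <- make_profile("abc33_like")
  expect_equal(p33$abundance, rep(1 / 33, 33))

  p4 <- make_profile("even", n = 4)
  expect_equal(p4$abundance, rep(0.25, 4))

  expect_error(make_profile("even", n = 0), ">= 1")
  stag <- make_profile("staggered", n = 30)
  expect_true(all(stag$abundance >= 0.005))
})

test_that("profiles round-trip through TSV and are validated", {
  p <- make_profile("staggered", n = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, f)
  expect_equal(read_profile(f), p, ignore_attr = TRUE)
  bad <- data.frame(taxon_id = c("a", "b"), abundance = c(0.6, 0.6))
  expect_error(validate_profile(bad), "sum to 1")
})

test_that("error-free simulation yields exact amplicon substrings", {
  ref <- small_ref(n_species = 12L, n_genera = 4L, dropout = 0, seed = 5L)
  prof <- make_profile("even", n = 3, taxon_ids = ref$amps$id[1:3])
  pairs <- simulate_pairs(ref$amps, prof, 200, seed = 2L, error_free = TRUE)
  for (i in seq_len(nrow(pairs))) {
    amp <- ref$amps$seq[ref$amps$id == pairs$taxon_id[i]]
    frag <- substr(amp, pairs$frag_start[i] + 1L,
                   pairs$frag_start[i] + pairs$insert_len[i])
    expect_equal(pairs$seq1[i], substr(frag, 1L, 75L))
    expect_equal(pairs$seq2[i],
                 revcomp(substr(frag, nchar(frag) - 74L, nchar(frag))))
  }
})

test_that("read counts track community abundances", {
  ref <- small_ref(n_species = 12L, n_genera = 4L, dropout = 0, seed = 5L)
  prof <- data.frame(taxon_id = ref$amps$id[1:2], abundance = c(0.9, 0.1))
  pairs <- simulate_pairs(ref$amps, prof, 10000, seed = 3L)
  counts <- table(factor(pairs$taxon_id, levels = prof$taxon_id))
  # binomial 4 sigma around 9000/1000
  expect_lt(abs(counts[[1L]] - 9000), 4 * sqrt(10000 * 0.9 * 0.1))
  expect_lt(abs(counts[[2L]] - 1000), 4 * sqrt(10000 * 0.9 * 0.1))
})

test_that("simulation is deterministic per seed and errors on missing taxa", {
  ref <- small_ref(n_species = 12L, n_genera = 4L, dropout = 0, seed = 5L)
  prof <- make_profile("even", n = 3, taxon_ids = ref$amps$id[1:3])
  a <- simulate_pairs(ref$amps, prof, 500, seed = 4L)
  b <- simulate_pairs(ref$amps, prof, 500, seed = 4L)
  expect_identical(a, b)
  expect_false(identical(a$seq1, simulate_pairs(ref$amps, prof, 500,
                                                seed = 5L)$seq1))
  bad <- make_profile("even", n = 2, taxon_ids = c(ref$amps$id[1], "ghost"))
  expect_error(simulate_pairs(ref$amps, bad, 10), "ghost")
})

test_that("per-cycle substitution rates converge to the error profile", {
  ref <- small_ref(n_species = 12L, n_genera = 4L, dropout = 0, seed = 5L)
  prof <- make_profile("even", n = 1, taxon_ids = ref$amps$id[1])
  eprof <- flat_profile(75L, q = 20)        # eps = 0.01 at every cycle
  n <- 4000L
  pairs <- simulate_pairs(ref$amps, prof, n, error_profile = eprof, seed = 6L)
  amp <- ref$amps$seq[1L]
  truth1 <- substr(rep(amp, n), pairs$frag_start + 1L, pairs$frag_start + 75L)
  mm <- mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
               pairs$seq1, truth1)
  rate <- sum(mm) / (n * 75)
  expect_lt(abs(rate - 0.01), 4 * sqrt(0.01 * 0.99 / (n * 75)))
})

test_that("insert lengths follow the truncated normal they are drawn from", {
  ref <- small_ref(n_species = 12L, n_genera = 4L, dropout = 0, seed = 5L)
  prof <- make_profile("even", n = 1, taxon_ids = ref$amps$id[1])
  n <- 20000L
  pairs <- simulate_pairs(ref$amps, prof, n, insert_mean = 160,
                          insert_sd = 40, seed = 7L)
  # oracle: moments of the integer-rounded normal truncated to [75, 740]
  support <- 75:740
  w <- stats::pnorm(support + 0.5, 160, 40) - stats::pnorm(support - 0.5, 160, 40)
  w <- w / sum(w)
  mu <- sum(support * w)
  sdv <- sqrt(sum((support - mu)^2 * w))
  expect_lt(abs(mean(pairs$insert_len) - mu), 4 * sdv / sqrt(n))
  expect_lt(abs(stats::sd(pairs$insert_len) - sdv), 4 * sdv / sqrt(n))
  expect_true(all(pairs$insert_len >= 75 & pairs$insert_len <= 740))
})

test_that("quality trimming removes trailing low-quality runs only", {
  mk <- function(q) phred_to_qual(q)
  pairs <- data.frame(
    id = c("a", "b", "c"),
    seq1 = strrep("A", 75), qual1 = c(
      mk(c(rep(30, 65), rep(2, 10))),     # trailing run trimmed to 65
      mk(c(rep(30, 30), 2, rep(30, 44))), # internal low base untouched
      mk(c(rep(30, 59), rep(1, 16)))),    # trimmed to 59 -> pair dropped
    seq2 = strrep("C", 75), qual2 = mk(rep(30, 75)),
    stringsAsFactors = FALSE)
  out <- trim_and_filter(pairs, qual_floor = 2L, min_len = 60L)
  expect_equal(out$id, c("a", "b"))
  expect_equal(nchar(out$seq1), c(65L, 75L))
  expect_equal(nchar(out$qual1), nchar(out$seq1))
  expect_true(all(nchar(out$seq2) == 75L))
})

test_that("top-quality selection ranks by mean Phred with stable ties", {
  q <- function(x, n = 75) phred_to_qual(rep(x, n))
  pairs <- data.frame(id = c("lo", "hi", "mid", "mid2"),
                      seq1 = strrep("A", 75),
                      qual1 = c(q(20), q(40), q(30), q(30)),
                      seq2 = strrep("C", 75),
                      qual2 = c(q(20), q(40), q(30), q(30)),
                      stringsAsFactors = FALSE)
  expect_equal(select_top_reads(pairs, 2L)$id, c("hi", "mid"))
  expect_equal(select_top_reads(pairs, 3L)$id, c("hi", "mid", "mid2"))
  expect_equal(select_top_reads(pairs, 10L), pairs)
})
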