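# Tiny mixture fixtures: candidates long enough for seeding (>= 75 bases),
# reads simulated straight from them.

make_candidates <- function(n = 2L, len = 200L, diverge = 20L) {
  set.seed(31)
  base <- random_dna(len)
  seqs <- c(base, vapply(seq_len(n - 1L), function(i) {
    mutate_seq(base, sample(len, diverge))
  }, ""))
  data.frame(id = paste0("cand", seq_len(n)), seq = seqs,
             stringsAsFactors = FALSE)
}

sim_from <- function(cands, weights, n_pairs, seed = 1L, q = 30,
                     error_free = FALSE) {
  keep <- weights > 0
  prof <- data.frame(taxon_id = cands$id[seq_along(weights)][keep],
                     abundance = weights[keep] / sum(weights))
  simulate_pairs(cands, prof, n_pairs, read_len = 75L, insert_mean = 120,
                 insert_sd = 20, error_profile = flat_profile(75L, q),
                 seed = seed, error_free = error_free)
}

test_that("pair mapping retains the source candidate and filters divergence", {
  cands <- make_candidates(n = 3L, diverge = 25L)
  pairs <- sim_from(cands, c(1, 0, 0), 50, error_free = TRUE)
  aln <- build_candidate_alignments(pairs, cands)
  expect_equal(aln$n_mapped, 50L)
  m1 <- aln$map[aln$map$cand == 1L, ]
  expect_equal(sort(unique(m1$pair)), 1:50)
  expect_true(all(m1$mm == 0L))
  # a source 20% diverged from every candidate leaves pairs unmapped
  set.seed(32)
  far <- data.frame(id = "far",
                    seq = mutate_seq(cands$seq[1], sample(200, 40)),
                    stringsAsFactors = FALSE)
  farpairs <- sim_from(far, 1, 20, error_free = TRUE)
  aln2 <- build_candidate_alignments(farpairs, cands)
  expect_equal(aln2$n_mapped, 0L)
  expect_equal(aln2$unmapped, 1:20)
})

test_that("a pair equidistant to two candidates is retained against both", {
  set.seed(33)
  base <- random_dna(200)
  cands <- data.frame(id = c("a", "b"), seq = c(base, base),
                      stringsAsFactors = FALSE)
  pairs <- sim_from(cands[1L, ], 1, 10, error_free = TRUE)
  aln <- build_candidate_alignments(pairs, cands)
  expect_equal(sum(aln$map$cand == 1L), 10L)
  expect_equal(sum(aln$map$cand == 2L), 10L)
})

test_that("E-step responsibilities match the closed-form two-candidate case", {
  set.seed(34)
  base <- random_dna(200)
  other <- mutate_seq(base, 100L)       # one interior substitution
  cands <- data.frame(id = c("a", "b"), seq = c(base, other),
                      stringsAsFactors = FALSE)
  # one error-free pair whose mate1 covers position 100
  pairs <- data.frame(id = "p1", seq1 = substr(base, 50, 124),
                      qual1 = phred_to_qual(rep(20, 75)),
                      seq2 = revcomp(substr(base, 100, 174)),
                      qual2 = phred_to_qual(rep(20, 75)),
                      stringsAsFactors = FALSE)
  aln <- build_candidate_alignments(pairs, cands)
  st <- mixture_state(pairs, cands, aln, flat_profile(75L, 20))
  es <- amplishot:::.estep(st)
  # candidate b disagrees at two read positions (one per mate); eps = 0.01
  eps <- 0.01
  lr <- ((eps / 3) / (1 - eps))^2
  expect_equal(sort(es$resp), sort(c(1, lr) / (1 + lr)), tolerance = 1e-12)
})

test_that("EM collapses to the generating candidate in degenerate cases", {
  cands <- make_candidates(n = 5L, diverge = 25L)
  pairs <- sim_from(cands, c(1, 0, 0, 0, 0), 300, seed = 35L)
  st <- em_iterate(mixture_state(pairs, cands,
                                 build_candidate_alignments(pairs, cands),
                                 flat_profile(75L, 30)))
  expect_equal(max(st$pi), 1, tolerance = 1e-4)
  expect_equal(st$cand_id[which.max(st$pi)], "cand1")
  expect_equal(sum(st$pi), 1, tolerance = 1e-9)
  # single candidate: pi = 1 immediately
  one <- cands[1L, ]
  p1 <- sim_from(one, 1, 50, seed = 36L)
  st1 <- em_iterate(mixture_state(p1, one,
                                  build_candidate_alignments(p1, one),
                                  flat_profile(75L, 30)), max_iter = 1L)
  expect_equal(st1$pi, 1)
})

test_that("EM recovers a 50/50 mixture within binomial error", {
  cands <- make_candidates(n = 2L, diverge = 20L)
  err <- vapply(1:10, function(s) {
    pairs <- sim_from(cands, c(0.5, 0.5), 2000, seed = 40L + s)
    st <- em_iterate(mixture_state(pairs, cands,
                                   build_candidate_alignments(pairs, cands),
                                   flat_profile(75L, 30)))
    st$pi[st$cand_id == "cand1"] - 0.5
  }, numeric(1L))
  expect_true(all(abs(err) < 0.05))
  expect_lt(abs(mean(err)), 0.02)
})

test_that("log-likelihood never decreases across pure EM iterations", {
  cands <- make_candidates(n = 3L, diverge = 25L)
  pairs <- sim_from(cands, c(0.6, 0.3, 0.1), 1500, seed = 50L)
  st <- em_iterate(mixture_state(pairs, cands,
                                 build_candidate_alignments(pairs, cands),
                                 flat_profile(75L, 30)))
  expect_true(st$monotone)
  expect_equal(sum(st$pi), 1, tolerance = 1e-9)
})

test_that("EM output is deterministic for fixed inputs", {
  cands <- make_candidates(n = 3L, diverge = 25L)
  pairs <- sim_from(cands, c(0.7, 0.2, 0.1), 800, seed = 51L)
  run <- function() {
    em_iterate(mixture_state(pairs, cands,
                             build_candidate_alignments(pairs, cands),
                             flat_profile(75L, 30)))
  }
  a <- run(); b <- run()
  expect_identical(a$cand_seq, b$cand_seq)
  expect_equal(a$pi, b$pi, tolerance = 1e-12)
})

test_that("consensus updates follow the weighted-majority rule", {
  set.seed(52)
  base <- random_dna(200)
  cands <- data.frame(id = "a", seq = base, stringsAsFactors = FALSE)
  pairs <- sim_from(cands, 1, 200, error_free = TRUE)
  aln <- build_candidate_alignments(pairs, cands)
  st <- mixture_state(pairs, cands, aln, flat_profile(75L, 30))
  st$resp <- amplishot:::.estep(st)$resp
  # all reads agree with the candidate: no change
  expect_equal(consensus_update(st), base)
  # all reads carry a variant the candidate lacks: unanimous override
  variant <- mutate_seq(base, 100L)
  vcands <- data.frame(id = "a", seq = variant, stringsAsFactors = FALSE)
  aln2 <- build_candidate_alignments(pairs, vcands, max_mismatch_rate = 0.06)
  st2 <- mixture_state(pairs, vcands, aln2, flat_profile(75L, 30))
  st2$resp <- amplishot:::.estep(st2)$resp
  expect_equal(consensus_update(st2), base)
})

test_that("a 50/50 base split keeps the incumbent base", {
  set.seed(53)
  base <- random_dna(200)
  variant <- mutate_seq(base, 100L)
  cands <- data.frame(id = "a", seq = base, stringsAsFactors = FALSE)
  both <- data.frame(id = c("x", "y"), seq = c(base, variant),
                     stringsAsFactors = FALSE)
  pairs <- rbind(sim_from(both[1L, ], 1, 100, seed = 1L, error_free = TRUE),
                 sim_from(both[2L, ], 1, 100, seed = 2L, error_free = TRUE))
  aln <- build_candidate_alignments(pairs, cands)
  st <- mixture_state(pairs, cands, aln, flat_profile(75L, 30))
  st$resp <- amplishot:::.estep(st)$resp
  new <- consensus_update(st)
  expect_equal(substr(new, 100L, 100L), substr(base, 100L, 100L))
})

test_that("near-identical candidates merge single-linkage, keeping top pi", {
  set.seed(54)
  base <- random_dna(200)
  mk_state <- function(seqs, pi) {
    structure(list(cand_id = paste0("c", seq_along(seqs)), cand_seq = seqs,
                   pi = pi,
                   map = data.frame(pair = 1L, cand = 1L, off1 = 0L,
                                    off2 = 0L, mm = 0L, orient = 1L),
                   m1 = substr(seqs[1], 1, 75), m2 = revcomp(substr(seqs[1], 126, 200)),
                   eps = rep(0.01, 75), n_mapped = 1L,
                   loglik = NA_real_, trace = numeric(), resp = NULL),
              class = "mixture_state")
  }
  st <- merge_similar(mk_state(c(base, base), c(0.4, 0.6)))
  expect_equal(length(st$pi), 1L)
  expect_equal(st$pi, 1)
  expect_equal(st$cand_id, "c2")          # higher-pi member keeps the id
  # 90% identity: no merge
  far <- mutate_seq(base, 1:20)
  st2 <- merge_similar(mk_state(c(base, far), c(0.5, 0.5)))
  expect_equal(length(st2$pi), 2L)
  # chain of three mutually >= 0.97: one candidate remains
  a <- base; b <- mutate_seq(base, 1:3); c_ <- mutate_seq(base, 4:6)
  st3 <- merge_similar(mk_state(c(a, b, c_), c(0.2, 0.5, 0.3)))
  expect_equal(length(st3$pi), 1L)
  expect_equal(st3$cand_id, "c2")
})

test_that("abundance finalization applies the 0.1% floor strictly", {
  mk <- function(pi) {
    structure(list(cand_id = paste0("c", seq_along(pi)),
                   cand_seq = rep(strrep("A", 80), length(pi)), pi = pi,
                   map = NULL, m1 = NULL, m2 = NULL, eps = NULL,
                   n_mapped = 1L, loglik = NA_real_, trace = numeric()),
              class = "mixture_state")
  }
  out <- em_finalize(mk(c(0.9995, 0.0005)))
  expect_equal(nrow(out), 1L)
  expect_equal(out$abundance, 1)
  out2 <- em_finalize(mk(c(0.5, 0.4, 0.1)))
  expect_equal(out2$abundance, c(0.5, 0.4, 0.1))
  expect_equal(out2$id, c("c1", "c2", "c3"))
  out3 <- em_finalize(mk(c(0.999, 0.001 - 1e-9)))
  expect_equal(nrow(out3), 1L)
  expect_error(em_finalize(mk(c(0.0004, 0.0006) / 1)), "floor")
})
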