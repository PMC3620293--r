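test_that("best-hit classification respects per-level identity thresholds", {
  ref <- small_ref(n_species = 12L, n_genera = 4L, dropout = 0, seed = 5L)
  # query identical to a reference amplicon
  q <- data.frame(id = "q1", seq = ref$amps$seq[3L], stringsAsFactors = FALSE)
  res <- best_hit_classify(q, ref$db, ref$tax)
  sp <- res[res$level == "species", ]
  expect_true(sp$assigned)
  expect_equal(sp$ref_id, ref$amps$id[3L])
  expect_equal(sp$taxon, ref$tax$species[ref$tax$id == ref$amps$id[3L]])
  expect_equal(sp$identity, 100)
  expect_true(all(res$assigned))

  # ~10% diverged query: dropped at species/genus, assigned at phylum
  set.seed(61)
  far <- mutate_seq(ref$amps$seq[3L], sample(100:600, 70))
  res2 <- best_hit_classify(data.frame(id = "q2", seq = far), ref$db, ref$tax)
  expect_false(res2$assigned[res2$level == "species"])
  expect_true(is.na(res2$taxon[res2$level == "species"]))
  expect_false(res2$assigned[res2$level == "genus"])
  expect_true(res2$assigned[res2$level == "phylum"])
})

test_that("reverse-strand queries classify to the same reference", {
  ref <- small_ref(n_species = 12L, n_genera = 4L, dropout = 0, seed = 5L)
  q <- data.frame(id = c("f", "r"),
                  seq = c(ref$amps$seq[5L], revcomp(ref$amps$seq[5L])),
                  stringsAsFactors = FALSE)
  res <- best_hit_classify(q, ref$db, ref$tax, levels = "species")
  expect_equal(res$ref_id, rep(ref$amps$id[5L], 2L))
  expect_true(all(res$assigned))
})

test_that("the tie-break chain is a deterministic total order", {
  set.seed(62)
  s <- random_dna(300)
  db <- data.frame(id = c("zeta", "alpha"), seq = c(s, s),
                   stringsAsFactors = FALSE)
  tax <- data.frame(id = c("zeta", "alpha"), kingdom = "B", phylum = "P",
                    class = "C", order = "O", family = "F", genus = "G",
                    species = c("sz", "sa"), stringsAsFactors = FALSE)
  q <- data.frame(id = "q", seq = substr(s, 50, 250))
  r1 <- best_hit_classify(q, db, tax, levels = "species")
  r2 <- best_hit_classify(q, db, tax, levels = "species")
  expect_identical(r1, r2)
  expect_equal(r1$ref_id, "alpha")   # equal score/identity/length: id order
})

test_that("paired concordance assignment requires both mates on one OTU", {
  ref <- small_ref(n_species = 12L, n_genera = 4L, dropout = 0, seed = 5L)
  cen <- ref$amps
  amp <- cen$seq[2L]
  ok <- data.frame(id = "ok", seq1 = substr(amp, 10, 84),
                   qual1 = strrep("I", 75),
                   seq2 = revcomp(substr(amp, 120, 194)),
                   qual2 = strrep("I", 75), stringsAsFactors = FALSE)
  res <- paired_otu_assign(ok, cen)
  expect_equal(res$otu, cen$id[2L])
  expect_equal(res$reason, "assigned")

  # mates from different taxa: discordant
  disc <- ok
  disc$seq2 <- revcomp(substr(cen$seq[7L], 120, 194))
  res2 <- paired_otu_assign(disc, cen)
  expect_true(is.na(res2$otu))
  expect_equal(res2$reason, "discordant-mates")

  # one mate below the identity threshold everywhere: unassigned
  set.seed(63)
  low <- ok
  low$seq2 <- mutate_seq(low$seq2, sample(75, 8))   # ~89% identity
  res3 <- paired_otu_assign(low, cen)
  expect_true(is.na(res3$otu))
  expect_equal(res3$reason, "below-identity")
})

test_that("paired concordance beats single-read precision on confusable taxa", {
  # two community members of the same genus: windows that cannot tell
  # siblings apart are tie-broken arbitrarily by the single-read route and
  # dropped by the concordance filter
  prec <- vapply(1:3, function(s) {
    ref <- small_ref(n_species = 12L, n_genera = 3L, dropout = 0,
                     seed = 70L + s)
    genus <- ref$tax$genus[match(ref$amps$id, ref$tax$id)]
    sib <- which(genus == genus[1L])[1:2]
    prof <- data.frame(taxon_id = ref$amps$id[sib], abundance = c(0.6, 0.4))
    pairs <- simulate_pairs(ref$amps, prof, 1500, seed = s)
    po <- paired_otu_assign(pairs, ref$amps)
    pp <- profile_from_assignments(po$otu, ref$tax, "species")
    ps <- profile_from_assignments(single_otu_assign(pairs$seq1, ref$amps),
                                   ref$tax, "species")
    paired <- precision_recall(pp$taxon_id, prof, ref$tax, "species")$precision
    single <- precision_recall(ps$taxon_id, prof, ref$tax, "species")$precision
    c(paired = paired, single = single)
  }, numeric(2L))
  expect_gte(mean(prec["paired", ]), mean(prec["single", ]))
})

test_that("assignment profiles aggregate, filter and renormalize", {
  tax <- data.frame(id = c("r1", "r2", "r3"), kingdom = "B", phylum = "P",
                    class = "C", order = "O", family = "F",
                    genus = c("gA", "gA", "gB"),
                    species = c("sA", "sA2", "sB"), stringsAsFactors = FALSE)
  ids <- c(rep("r1", 900), rep("r3", 100))
  p <- profile_from_assignments(ids, tax, "species")
  expect_equal(p$taxon_id, c("sA", "sB"))
  expect_equal(p$abundance, c(0.9, 0.1))
  # below-floor taxa are dropped, the rest renormalized
  ids2 <- c(rep("r1", 9991), rep("r3", 9))
  p2 <- profile_from_assignments(ids2, tax, "species")
  expect_equal(p2$taxon_id, "sA")
  expect_equal(p2$abundance, 1)
  # EM output: weights for two sequences of one species are summed
  p3 <- profile_from_assignments(c("r1", "r2", "r3"), tax, "genus",
                                 weights = c(0.5, 0.3, 0.2))
  expect_equal(p3$taxon_id, c("gA", "gB"))
  expect_equal(p3$abundance, c(0.8, 0.2))
  expect_error(profile_from_assignments(NA_character_, tax, "species"),
               "zero assigned")
})
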