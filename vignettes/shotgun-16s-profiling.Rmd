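---
title: "Shotgun 16S amplicon profiling in silico: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shotgun 16S amplicon profiling in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplishot)
```

## The problem

Classical Illumina 16S rRNA surveys read a fixed window at one end of a
short amplicon. Because a 75-base window captures only a sliver of the
gene's variable content, such end-sequencing saturates quickly: many
species collapse into the same operational taxonomic unit (OTU). An
alternative is to amplify a *long* stretch of the gene — here the V3–V6
region between the degenerate primers 338F\*
(`ACTYCTACGGRAGGCWGC`) and 1061R (`CRRCACGAGCTGACGAC`), a product of
roughly 700–1000 bases — shear the amplicons, and sequence random
fragments as short paired-end reads. The full amplicon must then be
reconstructed computationally before it can be classified, which is the
price paid for species-level resolution.

`amplishot` implements the complete in-silico side of this protocol:

1. **Primer evaluation** — IUPAC-aware universality scoring and in-silico
   PCR against a reference database.
2. **Resolution analysis** — how many OTUs whole amplicons resolve versus
   76-base end windows, with cluster taxonomic purity.
3. **Simulation** — a synthetic 16S-like reference generator and a
   paired-end shotgun read simulator with an empirical per-cycle error
   profile.
4. **Reconstruction** — an expectation–maximization (EM) mixture model
   that recovers amplicon sequences and their relative abundances from
   the read pairs.
5. **Classification** — best-hit taxonomy assignment with per-rank
   identity thresholds, and a paired-read same-OTU concordance
   classifier as the clustering-based alternative.
6. **Evaluation** — precision/recall against the known community and
   Pearson correlation of estimated versus true abundances.

## Primer matching and in-silico PCR

A degenerate primer letter denotes a set of bases (Y = {C,T}, R = {A,G},
W = {A,T}, ...). We score a *perfect* match: at every position the
primer letter's set must intersect the reference letter's set
(references may themselves carry ambiguity codes; `N` matches
anything). Intersection is the permissive reading of "fully accounting
for ambiguous letters" and handles ambiguous database entries
gracefully. No mismatches are tolerated, so reported coverage is a
lower bound on what would amplify in practice.

In-silico PCR requires a forward site followed by a reverse-primer
binding site on the same strand with a product length inside a window
(default 700–1000 bases, mirroring gel purification of the expected
product). Both strand layouts are searched so that reverse-deposited
database entries are still amplified; minus-strand products are
reported reverse-complemented, i.e. in amplicon orientation. When a
reference admits several products, we keep the one defined by the
leftmost forward site and its nearest qualifying reverse site — a
deterministic stand-in for the dominant PCR product — and report at
most one amplicon per record, stored-strand hits taking precedence.

## Resolution of end windows versus whole amplicons

Amplicons (primer-trimmed by default) are reduced to what each strategy
would observe — the whole product, the first 76 bases, or the last 76
bases read 5'→3' — and clustered greedily: sequences are processed in
decreasing length order and join the first existing centroid at or
above the identity threshold (0.97 ≈ species, 0.95 ≈ genus), else found
a new cluster. Identity is global-alignment identity with gap columns
in the denominator (match +1, mismatch −1, gap open −2, gap extend −1),
computed with `Biostrings::pairwiseAlignment()`. This is deliberately
*not* a re-implementation of any particular OTU-picking tool: the
clustering is used only as a resolution yardstick, where determinism
and oracle-checkability matter more than fidelity to a specific
heuristic; absolute OTU counts from public databases are
database-version-dependent and are not a target of this package.
Cluster purity is the fraction of clusters whose labelled members agree
at the evaluation rank; members with an empty rank label abstain, and a
fully unlabelled cluster counts as pure.

## The synthetic reference generator

Public rRNA databases cannot be bundled, so the package generates a
reference database that emulates the architecture that makes 16S
analysis work: conserved blocks (two primer sites plus two internal
blocks, defaults of 80 and 70 bases inside the amplicon) alternating
with variable regions. Defaults: 150 species in 40 genera, gene length
1450, product length 740 (inside the 700–1000 window).

* **Between genera** — each genus backbone mutates every variable
  position of a master sequence independently with probability 0.30,
  yielding ~35% pairwise divergence over the amplicon: unambiguously
  distinct at any clustering radius.
* **Within a genus** — each species substitutes a private "barcode" of
  15 positions (disjoint between the species of a genus) drawn from the
  variable positions inside the trimmed amplicon. Two siblings
  therefore differ at exactly 30 of 705 amplicon positions (4.26%):
  below the 97% species radius, above the 95% genus radius, so identity
  clustering separates species and merges genera *by construction*.
* **Primer dropout** — a configurable fraction of species (default
  0.08, echoing ~92% database coverage of the chosen pair) has its
  forward site scrambled and is not amplifiable.

What the generator does **not** emulate: indels and length variation
between taxa, chimeras, intragenomic 16S copy variation, GC/PCR bias,
and the long-tailed divergence structure of real genera. Passing tests
on this database show the pipeline's machinery is correct under its own
model assumptions — substitution-only errors, well-separated taxa — not
that real-data performance will match.

Community profiles: `even`, `staggered` (log-spaced between 0.5% and
10% before normalization — the benchmark community), `lognormal`,
`complex_like` (67 taxa log-spaced from 0.000103% to 10.3%
pre-normalization, the shape of a published complex mock community) and
`abc33_like` (33 equal entries, an equimolar mock).

## Read simulation

Templates are drawn in proportion to community abundance. The fragment
length is Normal(160, 40) rounded, redrawn (up to 100 times, then
clamped) until it lies in [read length, amplicon length] — redraw keeps
the distribution a proper truncated normal rather than piling mass on
the bounds. Fragment starts are uniform. Mate 1 is the fragment's 5'
75 bases; mate 2 the reverse complement of its 3' end. Substitutions
are applied per sequencing cycle at rate `10^(-Q_i/10)` with the
erroneous base uniform over the three alternatives; indels are not
simulated, matching the substitution-dominated error spectrum of the
short-read platform and keeping the EM emission model exact. Every read
carries the profile's quality string ("uniformly applied"), so the
error profile is both the generative and the inferential model.

The default profile declines linearly from Q34 at cycle 1 to Q20 at
cycle 75 — a representative short-read shape chosen once, not fit to
any dataset; measured profiles load from a two-column TSV. All
randomness flows from one integer seed through one generator instance,
in a documented order (templates, inserts, starts, mate-1 errors by
cycle, mate-2 errors by cycle), so simulated FASTQ files are
byte-identical across reruns.

Preprocessing mirrors the sequencing protocol: trailing bases with
Q ≤ 2 are removed, pairs with a mate shorter than 60 bases are dropped
whole, and analysis can be limited to the highest-mean-quality 100,000
pairs (pairs, not single reads, since the reconstruction consumes
pairs; ties keep input order).

## EM reconstruction

Reads are placed on candidate amplicons (the database's own amplicons —
a closed-reference start) by ungapped seed-and-extend mapping of both
mates at a consistent insert on either strand; a (pair, candidate)
alignment is kept when the combined mismatch rate is ≤ 0.06, about
twice the species radius. With substitution-only simulation, ungapped
placement is exact, which keeps the whole likelihood analytically
clean.

The mixture model, with `pi_k` the abundance of candidate `k` and
`eps_i` the error rate at cycle `i`:

* **E-step**: `r(p,k) ∝ pi_k * prod_i [match_i ? (1 - eps_i) : eps_i/3]`,
  normalized over the candidates each pair maps to.
* **M-step**: `pi_k = sum_p r(p,k) / N_mapped`; unmapped pairs are
  excluded from the denominator.
* **Consensus update** (every 5 iterations): per candidate position,
  reads vote with their responsibilities; the incumbent base is replaced
  by the top challenger only if the challenger's weight is ≥ 1.5× the
  incumbent's **and** reaches 0.5 posterior read-equivalents. The
  absolute floor matters: without it, candidates that attract no reads
  of their own drift along vanishingly small responsibilities borrowed
  from neighbouring mixture components, and such drifted "bridges" can
  connect two genuine community members at the merge threshold and fuse
  them. A base is never rewritten on negligible evidence.
* **Merging** (every 5 iterations and at convergence): candidates at
  ≥ 0.97 consensus identity merge single-linkage; the highest-abundance
  member keeps its id and sequence, abundances are summed.

Iteration stops when `max |Δpi| < 1e-5` or after 40 iterations. The
mapped-pair log-likelihood is non-decreasing across iterations in which
the consensus and candidate set are unchanged (asserted in the test
suite); consensus or merge events reset the baseline. Finally,
candidates below the 0.1% abundance floor are dropped *before*
classification and the survivors renormalized.

The E-step takes `eps_i` from the error profile rather than per-read
quality strings; with the simulator's uniformly applied profile the two
are identical, and the profile route keeps the emission model exactly
matched to the generative model.

## Classification

Reconstructed sequences are aligned locally (same scoring as above)
against the full-length reference genes on both strands. References are
shortlisted by shared 12-mer counts before alignment — the same word
seeding idea any local-search tool uses — and hits are ordered by
score, then percent identity, then alignment length, then reference id:
a deterministic total order standing in for an E-value/bit-score sort,
so reruns give identical assignments. Only the top hit is used, and it
assigns taxonomy at a level only if its identity meets that level's
threshold: 97% species, 95% genus, 80% phylum. A query can therefore be
species-unassigned yet phylum-assigned.

The paired-read concordance classifier works directly on reads: each
mate is assigned to its best centroid (ungapped identity, both strands,
ties to the lowest centroid index) from a pre-clustered reference set
(our greedy clustering at 0.97 over the database amplicons). Best-match
rather than first-above-threshold assignment mirrors how
closed-reference OTU pickers behave. A pair counts only when both mates
reach 97% on the *same* centroid; discordant or sub-threshold pairs are
reported with reason codes. Profiles from either route drop taxa below
0.1% relative abundance and renormalize; for the paired route the
filter is applied after concordance.

## Evaluation

A unique predicted taxon is a true positive if it matches the
evaluation-rank label of any community member — duplicates of one
member count once and are neither TP nor FP, since the object of the
count is community members, and the EM can emit redundant variants.
Predictions matching nothing are false positives. Community members
with abundance strictly above the threshold (0.1%) that attracted no
true positive are false negatives; a prediction matching a
below-threshold member still counts as a TP because the member is
genuinely in the community. Abundance correlation is Pearson's r on
linear abundances over the union of predicted and true taxa, absent
entries as zero (a log-scale variant over shared taxa is available).

## Problem sizes, defaults and determinism

The packaged benchmark (`run_benchmark()`, also driven by
`scripts/acceptance.R`) uses the generator defaults — 150 species / 40
genera — with a 30-taxon staggered community (every member ≥ 0.5%),
100,000 pairs, and the default error profile, replicated over five
seeds with the median reported; these sizes were chosen as the smallest
at which the claim-level bounds are meaningfully exercised while a
replicate stays around a minute on one core. The unit suite uses
databases of 12–40 species and simulations of a few thousand pairs.
Every stochastic step takes an explicit integer seed; the database,
community and read set for replicate *s* all derive from *s*, and the
RNG state of the caller is restored afterwards.

## Known limitations

* Ungapped read mapping and substitution-only simulation go together;
  neither models indels, so real data with indel errors (or length
  polymorphism between the candidate and the truth) needs a gapped
  mapper before the EM machinery applies.
* The closed-reference candidate start means a community member absent
  from the reference database can only be recovered through consensus
  drift of a related candidate, and only if it is within the mapping
  mismatch cutoff of one.
* The E-value surrogate ordering reproduces the *decision structure* of
  a best-hit search, not any particular tool's scores.
* Synthetic divergences are block-uniform; real genera are not, so the
  benchmark's separation of the 97%/95% radii is cleaner than nature's.
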