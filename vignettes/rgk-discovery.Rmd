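---
title: "Signature-based discovery of RGK-family GTPases: methods and design"
author: "rgkscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-based discovery of RGK-family GTPases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgkscan)
```

# The problem

RGK proteins (Gem, Rad, Rem1, Rem2) are an atypical branch of the Ras
superfamily: small GTP-binding proteins that bind the Cavbeta subunit of
high-voltage-activated calcium channels and suppress calcium current. Unlike
classical Ras proteins they carry long, poorly conserved N-termini, a
degenerate switch-I region, and -- most usefully for homolog discovery -- a
C-terminal eleven-residue signature built around an invariant cysteine seven
residues from the protein end. BLAST-style searches driven by overall
G-domain similarity drown distant RGK homologs in hits to other Ras-family
proteins (Rit1/Rit2 are the classic contaminants); the signature, which no
other Ras-superfamily member carries, separates them.

`rgkscan` implements that discovery logic as a reusable, fully testable
pipeline: signature scanning, G-motif-anchored G-domain extraction, an
iterative profile search seeded by pattern hits, conservation analytics over
family alignments, and a rule-based classifier -- plus a synthetic-proteome
generator that makes every stage verifiable without touching external
databases.

# Patterns and the C-terminal signature

Patterns use a minimal PROSITE-like grammar: residue letters, bracketed
classes, and the wildcard `x`. The RGK signature is

```{r}
renderPattern(rgkSignature())
```

eleven position classes with exactly one singleton-cysteine position.
Anchored at the C-terminus (the default for `scanCTerminus()`, since the
signature is defined as the *last* eleven residues), pattern position 5 is
offset -7 from the end -- the "C-7" cysteine. Matching is mismatch-count
based: a hit at tolerance *m* violates at most *m* non-wildcard positions.
The unknown residue `X` never satisfies a non-wildcard class.

Under i.i.d. uniform residues the probability that a random 11-mer matches
the signature is the product of class sizes over $20^{11}$:

```{r}
prod(lengths(patternClasses(rgkSignature()))) / 20^11
```

about $2.25\times10^{-10}$, which is why an anchored signature scan is
essentially specific: the test suite verifies by Monte Carlo that a million
uniform 11-mers yield at most a couple of hits.

# G-motifs and G-domain extraction

The catalog models the G-boxes as they appear in this family: G1 (P-loop)
`GxxGxGKS`, G3 `DxWE` (the family's variant of the canonical DxxG), G4 core
`NK`, and G5 `ExSA`. G4 is annotation-only -- two fixed positions are too
little to anchor a boundary. Because G1/G3/G5 conservation decays outside
vertebrates, a *tolerant* mode allows one fixed-position mismatch per motif,
and every tolerant hit is flagged with its mismatch count so downstream
consumers can distinguish exact from relaxed evidence.

The G-domain interval is anchored on motifs: it starts 6 residues before G1
(clamped at residue 1, with a `truncated` flag) and ends 30 residues from
the G5 anchor. Two end conventions circulate for this family and both are
implemented behind the `convention` argument:

* `"g5-start+30"` (default): the 30 residues count from the first G5
  residue;
* `"g5-end+30"`: they count from the residue after the motif, giving a
  domain exactly one G5-length (4 residues) longer.

The sources describing this family state both rules in different places;
neither is endorsed here -- the default follows the more prominent
formulation, the property suite pins the exact 4-residue relationship
between the two, and reports always name the convention used. When a
sequence offers several G1/G5 pairings, the pairing whose domain length is
closest to 175 residues wins (the midpoint of the 170--180 residues typical
of the family), with ties resolved to the leftmost G1 then leftmost G5 --
deterministic and anchored in the family's observed geometry.

# The iterative profile search

Classical discovery of remote homologs uses a pattern-hit-initiated search
followed by a position-specific iteration. `rgkscan` re-expresses that
protocol with transparent, dependency-free statistics; it deliberately does
*not* reproduce database-search E-values (Karlin--Altschul statistics are out
of scope).

* **Profile.** A PSSM over the terminal 40 alignment columns (the span over
  which the family's C-termini align), with pseudocount frequencies
  $p_a = (c_a + \alpha q_a)/(N + \alpha)$ and scores $\log_2(p_a/q_a)$ bits.
  Defaults: $\alpha = 0.5$, uniform background $q$. Gaps and `X` are
  excluded from counts; an unobserved column collapses to the background and
  scores zero everywhere, so all-gap columns are neutral.
* **Null.** `empiricalNull()` scores random background sequences against the
  profile; a query's z-score is measured against that simulation null
  (default 500 draws, seeded). The default inclusion threshold is $z \ge 5$.
* **Iteration 1** admits only records with an anchored signature hit and
  scores their terminal window. **Iteration 2** rebuilds the profile from
  the seed rows plus iteration-1 inclusions and rescores *all* records --
  the pattern gate is dropped, mirroring the relaxation from pattern-seeded
  to profile-only search. Records included at iteration 1 stay included
  (persistent inclusion, as iterative search tools behave in practice),
  which also makes "iteration-2 inclusions are a superset of iteration-1" a
  structural invariant; the scientifically interesting content -- that
  signature-less near-miss homologs are recovered only at iteration 2 -- is
  tested on generated benchmarks. Two iterations are the default; `maxIter`
  allows more.

The original protocol's database-specific settings (inclusion E-values,
maximum target list sizes) have no analog in this reimplementation and are
intentionally not emulated.

# Conservation analytics

Per-column conservation is information content, $\log_2 20 - H$ bits with
$H$ the Shannon entropy of the column's non-gap residue frequencies. This is
a deliberate substitution for Bayesian phylogenetic rate estimation (the
ConSurf family of methods), which belongs to other software and requires a
tree. Information content is transparent, dependency-free, and reproduces
the qualitative shape of conservation profiles; it is *not* comparable
numerically to evolutionary-rate scores.

Numerical conventions, all chosen once and stated in the interfaces:

* Frequencies are over non-gap residues only; columns whose gap fraction
  exceeds `gapCutoff` (default 0.5) are masked -- still scored, never
  silently dropped, so column indexing stays stable for reference maps.
* Smoothing is a centred moving average (default `w = 5` residues, matching
  how family conservation histograms are usually drawn), truncated at the
  edges and skipping masked columns; masked columns smooth to `NA`.
* Differential conservation between two subfamily alignments is compared
  through a shared reference row (`mapColumns()` gives the
  residue-number-to-column map) and reported as *family A minus family B*,
  unsmoothed, with positive values meaning A is more conserved. The sign
  convention is fixed and documented rather than guessed from ambiguous
  precedent.
* Logo quantities follow the standard definition: $R = \log_2 20 - H$ per
  column, letter heights $f_a R$. The small-sample correction
  $19/(2\ln 2\, n)$ is available but off by default, matching common logo
  servers.
* `percentIdentity()` counts identical residues over co-aligned (both
  non-gap) columns. Published "similarity" percentages for this family are
  metric-ambiguous (possibly substitution-matrix positives), so only percent
  identity is implemented and no published similarity value is asserted
  anywhere in the package.

# Classification

`classifyRecord()` applies an explicit decision ladder:

1. no usable G1/G5 anchor pair &rarr; `no-G-domain`;
2. G-domain but no anchored signature &rarr; `Ras-like-non-RGK`;
3. G-domain plus signature &rarr; `RGK-like`.

The ladder is a made-explicit version of how hits are adjudicated in
practice; no formal inclusion rule exists in the literature this follows,
so every rule firing is logged in the `evidence` column. The G-domain length
window [170, 180] is *advisory* -- reported as `g_domain_length_ok` but never
a verdict gate, because genuine family members with G-domain insertions fall
outside it. Key Cavbeta-interaction residues (R196, V223, H225 in mouse Gem
numbering; V223 accepts V/L/I, the hydrophobic substitutions known to keep
the interaction) are checked only when the user supplies an alignment
containing a reference Gem row: the package never constructs alignments
itself, and absent that input the field reports "not evaluated" rather than
silently passing.

# The synthetic benchmark

`generateBenchmark()` realises a `BenchmarkSpec` from one seeded random
stream; identical (spec, seed) pairs are byte-identical. The default spec --
200 RGK-like records, 200 decoys, 600 background sequences, tail noise 0.05,
near-miss fraction 0.1, seed 42 in the acceptance suite -- is the package's
standing benchmark and is not tuned per test.

Records emulate the family's architecture: a random N-terminus of 60--150
residues (spanning both the vertebrate and the longer invertebrate ranges),
a G-domain scaffold with exact planted G1/G3/G4/G5 at Gem-like spacings (G5
start 139 residues after G1 start, so the default extraction yields
175-residue domains), a 40-residue tail with K/R enrichment (rate 0.6) in
the polybasic window (offsets -35..-15) and the last eleven residues drawn
uniformly from the signature classes. Decoys share the G-domain but their
tails are rejection-sampled to miss the signature; a configurable fraction
are *near misses* -- signature-conforming tails mutated exactly at the
invariant cysteine -- which fail a strict scan, hit at tolerance 1, and are
the designed test case for iteration-2 recovery. Background records are
i.i.d. residues.

**Noise anchoring.** `tailNoise` substitutes tail residues uniformly over
the 20 amino acids. Which positions it may touch is governed by
`anchorMode`:

* `"fixed"` (default): all class-constrained signature positions are
  protected; noise touches the wildcard position and the 29 non-signature
  tail residues. A record labelled RGK then always carries its signature,
  so truth labels remain consistent with what the pipeline can detect --
  the property a recovery benchmark needs. This is the package's own design
  choice for the default benchmark.
* `"cysteine"`: only the invariant cysteine is protected, so noise can
  knock a planted signature out of its classes. The per-sequence retention
  has the closed form $\prod_k (1 - p(1 - k/20))$ over the nine unprotected
  constrained positions (class sizes $k$), $\approx 0.669$ at $p = 0.05$ --
  a useful, analytically checkable model of family members whose signatures
  have genuinely decayed, but the wrong default for measuring classifier
  sensitivity, since a third of the "positives" would be positives in label
  only.

Both modes are exercised by the test suite: the default benchmark must give
classifier sensitivity at least 0.95 at false-positive rate at most 0.01,
and the `"cysteine"` mode's empirical retention must sit inside the 99%
binomial interval of its closed form.

**What the generator does not emulate.** No indel process (planted domains
never vary in length, so the 175-residue default is recovered exactly --
real family members vary over 170--180 and beyond with insertions); no
phylogenetic correlation between records (every record is independent, so
conservation structure in generated alignments comes from the explicit
layout, not descent); background composition is uniform rather than
proteome-like; N-termini are random rather than low-complexity. Passing
tests therefore demonstrate correctness of the machinery on data with
planted truth, not performance on real proteomes.

# Problem sizes and reproducibility

The shipped suites use: 1,000-case oracle equivalence sweeps for the
scanners, $10^6$ Monte Carlo trials for the signature false-positive rate,
the 1,000-record default benchmark for classifier recovery, 500-draw
simulation nulls, and a few-hundred-record benchmark for the iterative
search; these sizes make every stochastic check stable under its fixed seed
while keeping the suite quick. All generators and the pipeline driver take
explicit seeds; `runPipeline()` writes a JSON manifest (parameters, seed,
input digests) and byte-identical reports on rerun. Coordinates are 1-based
inclusive everywhere, following R and Bioconductor convention; C-terminal
offsets are negative with the final residue at -1.

# Known limitations

* The signature and G-motif catalog encode this family's motifs; the
  scanner is general but the defaults are not a generic motif library.
* The profile search scores a fixed-length terminal window; there is no
  gapped profile alignment, so homologs with C-terminal extensions beyond
  the modelled window would be penalised.
* The z-score null is a simulation against an i.i.d. background; scores are
  comparable within a run, not across databases, and are not E-values.
* Interaction-residue checks depend entirely on the quality of the supplied
  alignment; a misaligned reference row silently shifts the checked columns.
* The exact set of tolerated G1/G5 deviations in distant homologs is not
  machine-readable from the sources this package follows; the
  one-mismatch tolerant mode is a stated approximation, and every tolerant
  hit is flagged so users can audit it.
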