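---
title: "Mining a satellitome from unassembled reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining a satellitome from unassembled reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Satellite DNA (satDNA) consists of long head-to-tail arrays of a short
repeated unit, the *monomer*. Because such arrays collapse in genome
assemblies, the satellitome — the full set of distinct satDNA families in a
genome — is most reliably characterized directly from raw sequencing reads.
`satmine` implements that read-level workflow for two sex-labelled paired-end
libraries: iterative de novo monomer discovery, catalog construction with
nested homology tiers, per-sex abundance and divergence estimation,
male/female bias calls for sex-linked repeats, and haplotype networks of
short monomers. A built-in simulator plants satellite arrays with exactly
known truth so that every stage can be validated end to end.

## The discovery model

A tandem array of a monomer of length $m$ has a periodic k-mer structure:
with any $k$, the set of k-mers of a long array has exactly $m$ distinct
members, and the graph whose nodes are those k-mers with edges between
$(k-1)$-overlapping neighbours is a single simple cycle of length $m$. This
holds whether $m$ is smaller or larger than $k$ or the read length, which is
what lets cycle detection recover monomers longer than a read (consensus
support then comes from edge weights rather than single reads).

`detect_monomers()` therefore:

1. counts canonical k-mers (lexicographic minimum of a k-mer and its reverse
   complement) over the quality-filtered read subsample, keeping k-mers and
   adjacency edges with count at least `min_kmer_count`;
2. splits the surviving graph into connected components;
3. inside each component searches for a high-mean-weight simple cycle with a
   greedy highest-weight-first walk and backtracking, bounded by a multiple
   of the component size, trying start nodes in lexicographic order;
4. spells each cycle as the candidate monomer and discards cycle-free
   components, which correspond to dispersed (non-tandem) repeats.

The count threshold separates satellite k-mers from single-copy background:
a satellite with $c$ copies sequenced at depth $d$ has k-mer coverage near
$c \times d$, while background sits near $d$. The default rule
(`recommend_min_kmer_count()`) takes a quarter of the expected coverage of
the rarest satellite of interest, floored at 5. Per-copy divergence $\delta$
and base error $e$ thin consensus k-mer coverage by roughly
$((1-\delta)(1-e))^k$; at the defaults ($k = 21$, $\delta \le 2\%$,
$e = 1\%$) about half survives, which the quarter-coverage rule absorbs.

Discovery is wrapped in the iterative mine–mask–repeat protocol
(`iterate_mining()`): subsample pairs from each sex, mine the joint
male+female subsample, keep candidates novel against everything found so far
(rotation/strand-aware identity below the variant threshold), mask the full
working libraries with the cumulative catalog, and stop when a round yields
nothing new (or after `max_rounds`, with a warning). Joint mining is used
because the catalog must contain both sexes' satellites, including Y-linked
families absent from the female library.

## Alignment and masking

Reads are compared to monomers with a seed-anchored local aligner: each
monomer is tiled head-to-tail until a full read fits inside the reference
(at least a dimer, so alignments can cross the arbitrary phase boundary of a
circular repeat), a positional index of exact 12-mers locates candidate
diagonals on each strand, and Smith–Waterman (match +1, mismatch −1, gap −2)
runs in a ±16 bp window around each seeded diagonal cluster. A read is
masked when some alignment reaches `masking_min_identity` (default 0.80)
over at least `masking_min_read_coverage` (default 0.50) of the read; the
best hit — highest identity, ties to the lower monomer index, then the
forward strand — is credited with the aligned read bases. Setting
`seed_kmer = 0` disables the anchor and aligns every read against every
monomer exhaustively; the anchored and exhaustive paths give identical hits
on substitution-only data, and the anchor can only miss reads whose every
sampled 12-mer is disrupted, i.e. reads far below the masking identity
threshold anyway.

## Catalog and homology tiers

Monomers have arbitrary phase and strand, so the catalog stores each
sequence in canonical form: the lexicographic minimum over all rotations of
the sequence and its reverse complement. Identity between monomers is
computed by fitting the shorter sequence into the dimer of the longer
(global on the shorter, free end gaps on the dimer) on both strands and
dividing matches by alignment columns. This metric uses a deliberately
stiff gap cost (−12): satellite families diverge almost entirely by
substitution, and with a permissive gap cost the optimal alignment converts
mismatches into gap-flanked matches, inflating the apparent identity of
*unrelated* monomers above the superfamily threshold. With the stiff cost,
pairs constructed at 97/85/60/40% point identity measure at their nominal
values while unrelated pairs measure well below 0.5. Sequences shorter than
50 bp are tiled head-to-tail to at least 50 bp before aligning (exact under
circular equivalence): with very few columns the maximum over placements of
a random alignment drifts toward the superfamily threshold, and lengthening
the alignment removes that selection bias without changing the identity of
true homologs.

Tiers follow the conventional thresholds — variants at ≥ 0.95, families at
≥ 0.80, superfamilies at ≥ 0.50 — with closed lower bounds (the ranges are
otherwise ambiguous at their ends) and single-linkage clustering, since
homology grouping is connectivity-based; complete linkage is available via
`build_partition(..., linkage = "complete")`. Threshold ordering makes the
partitions nest, and this is asserted on every run. Catalog names are
assigned by decreasing mean abundance across sexes with a lexicographic
tie-break, and superfamily labels SF1, SF2, … by decreasing summed
abundance.

## Abundance, K2P landscapes and sex bias

Abundance is the masked-bp fraction of the subsampled library (the
RepeatMasker convention): robust to partial-read hits at array boundaries;
a read-count mode is available (`quantify(..., unit = "reads")`). For every
best hit the aligner records transition and transversion fractions $P$ and
$Q$ over aligned pairs, giving the Kimura two-parameter distance

$$K = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\,\sqrt{1 - 2Q}\big),$$

undefined (saturated) when $1-2P-Q \le 0$ or $1-2Q \le 0$; saturated hits
are excluded and counted. Landscapes bin masked bp by $K$ in 1% bins from 0
to 50% (with a final overflow bin) and conserve base pairs exactly.

The male/female ratio of abundances flags sex-linked amplification. The
classical rule calls any M/F above 1.0; because sampling noise makes 1.0
trivially exceedable at desk scale, the package defaults to a margin of 1.5
(male-biased above 1.5, female-biased below 1/1.5); setting
`mf_bias_ratio = 1.0` restores the strict rule. A family present only on
the Y yields a zero female fraction; the ratio is then flagged infinite
rather than divided.

## Haplotype networks

For monomers short enough that a complete copy fits inside one read
(`mst_max_monomer_length`, default the read length), `extract_haplotypes()`
aligns each read to the periodic extension of the monomer without gaps
(every phase, both strands), keeps reads at or above
`min_identity_for_extraction` (default 0.8) over their full length, and cuts
the read substring spanning one full monomer window re-phased to monomer
coordinate 0, so identical variants sampled at different offsets collapse.
Excluding gapped reads keeps all haplotypes equal-length and
Hamming-comparable, which removes the need for a multiple alignment step;
indel-rich satellites are outside this analysis. Haplotypes seen fewer than
`min_haplotype_count` times (default 2 — singletons) are dropped as likely
sequencing errors. The minimum spanning tree over Hamming distances is built
with Kruskal's algorithm under a total edge order (distance, then the
lexicographic endpoint-sequence pair), so results are reproducible
bit-for-bit; tests verify minimality against exhaustive enumeration of all
spanning trees via Prüfer sequences on instances of up to six haplotypes.

## The simulator and what it does (not) emulate

`build_genomes()` plants each family as one uninterrupted head-to-tail array
(no higher-order repeat structure) at a random position and strand in an
i.i.d. random background of configurable GC. Copies are mutated
independently by substitutions only — no indels — so planted abundance,
copy divergence and haplotype phase stay exactly computable; indel
robustness enters only through alignment tolerances. Both sexes share the
background and the same mutated autosomal arrays; Y-linked arrays go into
the male genome only, and each genome is exactly `genome_length` long so
planted fractions are exact. Background that shares a k-mer with any
planted monomer is redrawn, so discovery cannot be confounded by chance
collisions. Reads follow the standard Illumina emulation: normal fragment
lengths (rounded, clamped), uniform positions, random fragment strand, FR
mates, i.i.d. substitution errors, and either constant-quality strings or a
two-state model with a low-quality 3′ tail that exercises the Q ≥ 20 filter.

What passing tests on these data do **not** show: tolerance to indels and
structural heterogeneity inside arrays, PCR/optical duplicates, coverage
biases (GC, mappability), higher-order repeats, or transposable-element
interspersion — real libraries contain all of these, and the in-silico
purity property replaces the study-style manual screening of non-satellite
repeats.

## Reference conditions and problem sizes

The package's reference validation simulates 2 Mb per sex with ten planted
satellites spanning abundances 0.1–5% and monomer lengths 20–300 bp (copy
numbers stay ≥ 80, as befits satellite arrays), per-copy divergence up to
2%, one family with true M/F = 3 (autosomal plus Y-linked extra copies) and
one strictly Y-linked family, sequenced at 10× per sex with 150 bp pairs and
1% base error. At these sizes the whole pipeline runs in a few minutes on
one core; unit tests use smaller designs (60–300 kb) chosen so that each
assertion's sampling noise is small relative to the property being checked.
The sex-bias replicate experiment in particular plants its families with
enough copies (25 + 50 Y-linked vs 50, at 10×) that each abundance estimate
rests on a few hundred reads: the M/F ratio then carries a 5–10% sampling
CV, so replicate outcomes test the calling rule rather than estimator noise
— a scaled-down mirror of the precision that full-size libraries give the
same estimates.
Where a tolerance in a test is wider than the corresponding large-scale
property (for example ±30% on a 2.4 kb array sampled by ~100 reads), the
test comments state the sampling-noise arithmetic that justifies it.

Two statistical facts shape the test suite rather than the code: per-base
coverage of uniformly placed 150 bp reads at 10× is Poisson with CV ≈ 0.32,
so sampler uniformity is judged on 5 kb windowed coverage (CV ≈ 0.08 when
uniform, while positional bias would survive the averaging); and k-mer
counts of a 1× background follow a Poisson tail that does reach small
thresholds occasionally, which is why background rejection relies on the
coverage-scaled threshold rule, not on background counts never reaching 5.

## Numerical and degenerate-input choices

* QC implements "every base ≥ Q20" as whole-read (and mate) drop, not
  trimming, preserving the fixed read length that haplotype extraction
  requires.
* All tie-breaks are lexicographic (component order, cycle start, masking
  best-hit, catalog naming, MST edge order) for bit-reproducibility; all
  randomness flows from `sat_config()$seed` through documented per-stage
  derivations (`derive_seed()`), and seeded sections restore the caller's
  RNG state.
* Empty inputs are defined: an empty FASTQ is an empty stream; a
  satellite-free design runs to completion with an empty catalog and empty
  downstream tables; a single haplotype yields an empty tree; an empty
  landscape is an all-zero table.
* Saturated K2P hits are excluded with a counter rather than clamped.
* Monomers longer than twice the read length are discoverable (the k-mer
  cycle can exceed the read length) but their consensus support rests on
  edge weights; monomer lengths far beyond the read length have reduced
  masking sensitivity since any single read covers only part of a unit.
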