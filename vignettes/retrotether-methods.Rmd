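---
title: "Methods: mining, classifying and dating aRH-bearing LTR retrotransposons at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining, classifying and dating aRH-bearing LTR retrotransposons at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ty3/gypsy LTR retrotransposons of the plant Tat clade acquired an additional,
archaeal-type ribonuclease H domain (aRH) on top of the native RH encoded in
*pol*. Two observations make this system informative about early retroviral
evolution: the aRH occupies five distinct positions relative to the other
domains (S1–S5 below), and wherever an aRH is present the native RH shows
*tether-like degradation* — the fold persists, but the four catalytic
carboxylates of the active center (the DEDD motif) are substituted away.

Genome-scale surveys of this phenomenon are not reproducible on a desk: they
require dozens of public assemblies, a specific profile-search engine, and
maximum-likelihood phylogenetics. This package implements the complete
analytical procedure in a form whose every stage can be validated against
synthetic genomes with planted, machine-readable ground truth. What a green
test establishes is therefore *methodological correctness on the stated
synthetic world*, never a biological claim about real genomes.

# The synthetic world

`plant_elements()` emits genomes containing elements drawn by
`build_element()` from an `element_blueprint()`:

* **Domain library** (`make_profile_library`): six domains with
  seed-deterministic random consensus sequences — GAG 80 aa, PR 100, RT 200,
  RH 130, aRH 130 (the aRH domain is short, ~130 residues), INT 150. RH-type
  domains carry a DEDD core at fixed relative positions (8%, 37%, 69%, 91% of
  the domain length). The aRH consensus is drawn independently of RH
  (regenerated if pairwise identity were ever ≥ 60%), so the two RH types are
  separable by scoring while sharing the catalytic motif — mirroring their
  real phylogenetic distinctness.
* **Architecture**: each structural variant is a fixed ORF layout
  (`structure_orf_map()`); ORFs are `ATG + domains (+ short random linkers)
  + stop`, back-translated with uniform synonymous codon usage (no codon
  table is specified for this system; uniform is the maximum-entropy choice).
  Inter-ORF spacers are 20–200 bp and ATG-free so no spurious ORF starts are
  planted. The canonical pol order is PR–RT–RH–INT (non-chromoviral
  convention); `int_position = "after_pr"` switches to the chromoviral
  PR–INT–RT–RH arrangement.
* **Divergence**: LTRs are exact copies mutated apart by `ltr_divergence`
  (substitutions only); domains are mutated from consensus at
  `domain_divergence` with catalytic positions frozen. Degraded cores are
  substituted to residues from {A, N, S, T, G} *before* mutation (and then
  frozen), so a degraded position can neither revert nor read as a
  conservative D↔E swap.
* **Placement**: elements go on seed-chosen strands at seed-deterministic
  positions into i.i.d. background at the requested GC (default 0.40, a
  typical plant intergenic value). Two placement guards define the stated
  world rather than tune it: a contig **margin** (default 6 kb, one LTR
  search flank plus slack) keeps flank windows on-contig, and a minimum
  **inter-element gap** (default 15 kb, above the 10 kb chaining gap) keeps
  planted elements resolvable. Unconstrained placement would routinely abut
  insertions and create chimeric chains — that is the nested-graveyard world,
  which this generator explicitly does not emulate (no nested insertions, no
  solo LTRs, no target-site duplications, no insertion-age distribution).

Defaults for the simulated cohorts (5% LTR and domain divergence, native RH
degraded in every aRH-bearing element, distal aRH degraded in S5) are the
conditions under which the tether phenomenon is defined; they are fixed in
`default_config()` and never adjusted per test.

# Mining

**PSSMs.** Profiles are per-position log-odds matrices in bits,
`score[i,a] = log2((n_i(a) + τ q_a) / (N_i + τ) / q_a)` with pseudocount
τ = 1 and uniform background; gaps are excluded from counts. Scanning is
gapless over all six frames; windows containing a stop or any non-standard
residue are discarded; maximal-scoring non-overlapping windows above
`min_bits` are kept greedily by score. The default threshold is 0.4 × the
profile self-score — high enough that a 10 kb random translate yields a hit
in well under 1% of seeds, low enough to call domains at 10–15% divergence.

**Chaining.** Single-linkage on same-strand hits with genomic gaps ≤ 10 kb
(config-exposed); within a chain, hits are ordered element 5'→3', i.e.
descending genomic start on the minus strand. Overlapping same-profile hits
resolve to the higher score. Opposite-strand overlaps are both reported.

**LTR detection.** The pair is the best local alignment (match +1, mismatch
−1, linear gap −2) between the 5 kb flanks of the chain span. An optimal
local path can pick up short chance extensions beyond the true repeat
(expected maximal random excursions grow with the log of the search space),
which inflates length and deflates identity by a few points; terminal
segments are therefore trimmed to the maximal-scoring subsegment under
match +1, mismatch/gap −3 (ends must hold ≈75% identity). After trimming,
estimated identities track 100·(1 − d) within 2 points for divergences up to
at least 10%. Chains closer than one flank to a contig edge are flagged
`edge_truncated` with no LTR call; the flag feeds the lineage filter.

**Completeness and preclustering.** No formula for a completeness score is
published for the original mining tool; the declared stand-in is
`0.8 · (distinct core domains among GAG, PR, RT, RH, INT)/5 + 0.2 · [LTR
pair]`. Preclustering is single-linkage on pairwise RT identity from global
BLOSUM62 alignment (threshold 80%), the representative being the most
complete chain (ties: longer span, then lexicographic id).

# Structure classification

`assign_orfs()` finds maximal ATG→stop ORFs (≥ 60 codons by default, below
the smallest planted ORF of 81) in the padded chain span on the element
strand, assigns each hit to the ORF containing ≥ 80% of its span, and numbers
hit-bearing ORFs in element order. Classification then applies ordered rules
on element-ordered domains:

| label | rule |
|---|---|
| NO_ARH | no aRH hit |
| S5 | two contiguous aRHs after the native RH, inside pol |
| S1 | one aRH immediately after the native RH, inside pol |
| S2 | one aRH before RT, inside pol |
| S3 | one aRH alone in its own ORF, between gag and pol |
| S4 | one aRH alone in its own ORF, before gag |
| UNKNOWN | anything else |

Decisions embedded here: "immediately after" tolerates ≤ 600 bp of linker
(config-exposed) — linkers exist in real elements; S5 checks precede S1 so a
dual-aRH element is never truncated to S1; a chain with aRH but no native
RT/RH is UNKNOWN rather than guessed, because the variants are *defined*
relative to the native domains; and an aRH contained in no ORF is UNKNOWN.
S3's "between gag and pol" follows the literal placement of the aRH ORF after
the gag ORF — whether real S3 elements ever put it 5' of gag on some copies
is not resolvable from published text, and such copies would classify S4.
Classification reads element order only, so hit insertion order is
irrelevant (property-tested).

# Catalytic-core degradation

A candidate RH-type sequence is globally aligned to its profile consensus
with the profile's own log-odds columns as substitution scores and linear
gaps. The residues mapped to the four catalytic positions give `core_state`
(`-` when gapped); `severity = 4 − #exact matches`; `degraded` at severity ≥ 1
(one lost carboxylate abolishes catalysis; threshold config-exposed).
Matching is exact — no D↔E credit — because conservative swaps at these
positions are still reported in `core_state` for inspection.

Two numerical choices deserve note. Gaps are linear, not affine: the domains
are short and the test oracle (a plain quadratic DP) stays trivial. The
default gap penalty is **−6 bits rather than −4**: at −4, in about 1% of
5%-diverged domains a background substitution that creates a D adjacent to a
fully degraded core position pays for a gap-pair shift (cost 8 bits, gain up
to ~7 plus neighborhood effects) that "rescues" one catalytic position and
misreads severity 4 as 3. At −6 the shift costs 12 bits and the misread
disappears (0/200 in a stress test at 8% divergence) while genuine indel
placement is unaffected. The penalty remains a parameter.

# Phylogenetics, credibility, scenario

Large-scale analyses use MAFFT + ML inference with ultrafast bootstrap and
aLRT; this package deliberately substitutes deterministic desk-scale
machinery with the *same decision semantics*:

* `progressive_align()` — guide tree from 3-mer set distances
  (average-linkage), progressive profile–profile Needleman–Wunsch with
  BLOSUM62 column scores, linear gap −4. Deterministic; adequate for the
  substitution-only families the generator emits.
* `distance_matrix()` — p-distance; a Poisson correction `−ln(1 − p)` is
  available behind a flag. Pairs with zero comparable columns get the
  maximum observed distance + 0.1, with a warning.
* `nj_tree()` — canonical neighbor joining (Q-criterion, standard
  branch-length formulas), negative branch lengths clamped to zero, Q ties
  broken by the lexicographically smallest taxon pair. On additive matrices
  it reproduces the generating tree exactly (path-length matrices equal to
  1e−9), which is the acceptance oracle.
* `bootstrap_support()` — Felsenstein bootstrap: resample columns, rebuild,
  count each internal bipartition of the full-data tree. The credibility
  threshold defaults to 95, the ultrafast-bootstrap side of the published
  80/95 rule, and `credible_clusters()` is inclusive at the boundary.
* `test_monophyly()` — exact bipartition membership; trivial splits (single
  tip or its complement) are monophyletic with `NA` support.
* `filter_lineages()` — a lineage is removed iff ≥ 2 of: (1) it falls in no
  credible cluster with another lineage of its taxon group (the taxon-group
  map is user-supplied; the "sequenced by the same institute" component of
  the published criterion is metadata outside sequence analysis), (2) its
  structure is unique in the cohort, (3) it is edge-truncated or lacks an
  LTR pair. The rule is monotone in the flags (property-tested).
* `fitch_parsimony()` — bottom-up intersection/union over state sets on a
  rooted **binary** species tree, polymorphic tips allowed (a tip edge is
  free iff the parent state lies in the tip's set). The count equals
  exhaustive enumeration over internal labelings (acceptance-tested on 50
  random trees); the binary restriction exists because the classic count is
  exact only there, and violating trees raise an error rather than return an
  approximation. The reconstruction reports minimal changes without
  labeling their mechanism (recombination vs loss), which is narrative, not
  computable, at this scale.

# Pipeline and reproducibility

`cmd_simulate` / `cmd_annotate` / `cmd_report` (and `run_all`, or the
`exec/retrotether` CLI) wire the stages together. The configuration is one
JSON file (`default_config()` → `write_config()`/`read_config()`); JSON is
used instead of YAML because the target environment provides no R YAML
parser, and the round-trip is lossless. All randomness flows from a single
`seed` through `derive_seed()` tags, so identical configs give byte-identical
FASTA/TSV/newick outputs; `--threads` is accepted for interface completeness
and ignored (everything is deterministic single-thread). Thresholds actually
used are logged to stderr and `run.log`. Exit codes: 0 success, 2
configuration/capacity errors, 1 anything else.

# Limitations

* The synthetic world omits nested insertions, solo LTRs, target-site
  duplications, codon bias, indel mutation and sequencing error; green tests
  bound method behavior only on that world.
* Gapless PSSM scanning cannot span indels inside a domain; at the planted
  (substitution-only) divergences this costs nothing, but on real genomes a
  domain with internal indels would score lower or split.
* NJ + bootstrap is a stand-in: topologies and supports are not expected to
  match ML analyses on real data, only to carry the same downstream logic
  (credibility at ≥ 95, monophyly, filtering).
* Real-data use requires user-supplied profile alignments with annotated
  catalytic positions (`catalytic.tsv`); the generator's fixed DEDD layout
  is a synthetic convention, and published alignments do not state exact
  column indices.
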