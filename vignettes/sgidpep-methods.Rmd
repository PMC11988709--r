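---
title: "Methods and design of the sgidpep screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the sgidpep screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgidpep)
```

# The screening problem

Simulated gastrointestinal digestion (SGID) of a food protein concentrate
produces gastric and intestinal digests whose peptide pools are sequenced
de novo by LC-MS/MS. A peptide of the intestinal digest (ID) that matches
a peptide already present in the undigested concentrate (SPC) is called
*SGID-resistant*: it survived both digestion phases intact. Resistant
peptides are the candidates worth characterizing further, because only
they can plausibly reach the intestine in active form.

`sgidpep` implements this identification step and the characterization
that follows it (physicochemical descriptors, terminal-motif screening),
plus the two plate-assay calculators used around such experiments, and a
simulator that manufactures realistic inputs with known ground truth.

# Resistance matching

## Model

Each peptide is reduced to its 20-dimensional amino-acid composition
count vector. Two peptides are compared by the cosine of their count
vectors; a query from the ID pool is accepted as resistant when its best
SPC reference has cosine similarity strictly greater than the threshold
*and* the two sequence lengths differ by at most `max_len_diff` residues.
Composition cosine is scale-invariant — `AAAA` and `AA` are
indistinguishable — which is exactly why the length-difference guard is
part of the rule.

## Parameters

| parameter      | default | units      | rationale                         |
|----------------|---------|------------|-----------------------------------|
| `threshold`    | 0.95    | cosine     | standard operating point for composition matching of short peptides; strict `>` comparison |
| `max_len_diff` | 8       | residues   | discards pairs whose length difference makes composition similarity meaningless |
| `min_alc`      | 85      | percent    | conventional confidence cut for de novo peptide calls |
| `merge_il`     | FALSE   | flag       | de novo sequencing cannot distinguish I from L; merging is opt-in because published peptide lists typically keep both letters |

The comparison object (raw residue counts, not normalized frequencies,
not k-mer vectors) was a genuinely open choice: counts are the simplest
object for which cosine between peptide sequences is well defined, and
cosine is itself scale-invariant, so count and frequency vectors give
identical similarities. The matching is implemented as one normalized
matrix product over all pairs; the unit tests pin it against an explicit
all-pairs brute-force implementation.

## Tie-breaking and determinism

A query may pass the rule with several references. One match record per
query is reported: the highest similarity, ties broken by smaller length
difference, then by reference pool order. The choice of best reference
does not affect the resistant set, only the audit trail; an `audit` mode
reports every passing pair. Similarities within 1e-12 of 1 are snapped to
exactly 1, since proportional integer compositions are exactly parallel
and only floating-point drift of the matrix product says otherwise.

# Physicochemical descriptors

* **Molecular weight** is the sum of standard average residue masses plus
  one water (18.015 g/mol). The mass table is part of the swappable
  `residue_tables()` configuration. Additivity
  (`mw(ab) = mw(a) + mw(b) − water`) is tested as an invariant.
* **Net charge** at a given pH is the Henderson–Hasselbalch sum over all
  ionizable groups: both termini, plus D, E, C, Y (acidic) and H, K, R
  (basic) side chains. The shipped pKa set is the Lehninger-style one
  (N-term 9.60, C-term 2.34, D 3.65, E 4.25, C 8.33, Y 10.07, H 6.00,
  K 10.53, R 12.48). Web calculators use undisclosed, slightly different
  sets, so computed pI values are validated structurally (against an
  independent fine-grid scan) rather than against published pI numbers.
* **Isoelectric point** is the unique zero of the strictly decreasing
  charge curve, found by bisection on [0, 14]. Bisection stops when the
  bracket is narrower than 1e-7 pH units. Stopping on the bracket rather
  than on `|charge|` matters: near the pI of a peptide with no ionizable
  side chains the charge curve is nearly flat, and a charge-based stop
  can halt several hundredths of a pH unit away from the true root. Every
  peptide with two termini crosses zero, so no degenerate case exists.
* **Composition percentages** use the four-class residue scheme common in
  peptide characterization tables: hydrophobic A, C, F, G, H, I, L, M, P,
  V, W, Y; acidic D, E; basic K, R; neutral N, Q, S, T. (Isoleucine is
  absent from many published convention lists because de novo callers
  collapse it into leucine; it is classed hydrophobic here so the map
  covers all 20 residues.) Percentages are rounded to two decimals, so
  the four values sum to 100 within 0.01.
* **Length classes** are short (2–5), medium (6–10) and long (>10)
  residues. Single residues are rejected: a free amino acid is not a
  peptide.
* **Solubility** is a deliberately simple composition rule in the style
  of web peptide calculators: soluble iff length < 5 or
  (count of D, E, K, R) + 1 ≥ length/5, the `+1` standing for the charged
  termini. It is deterministic and reversal-invariant, and it is exposed
  through `residue_tables()` precisely so users can substitute a better
  rule; it makes no claim of matching any particular web tool.

# Terminal-motif screening

α-Amylase-inhibitory peptides show position preferences at their terminal
residues. The screen counts how many rules a peptide satisfies at the
ultimate (N1/C1), penultimate (N2/C2) and antepenultimate (N3/C3)
positions, bins pools into 0 / 1 / 2 / 3 / ≥4 criteria met, and selects
candidates: medium peptides meeting ≥3 rules, long peptides meeting ≥4,
short peptides never.

Two design points were open:

* **The criteria themselves are configuration.** Published screens rest
  on curated criteria that are not reproducible from summary tables
  alone, so `criteria_set()` accepts any position→residues map (also from
  YAML). The shipped `default_criteria_set()` (R/K at N1 and C1, aromatic
  at N2, hydrophobic at N3, H/P at C2, W/L/F at C3) is a demonstration
  approximation motivated by the terminal preferences reported for
  α-amylase inhibitors — not a reproduction of any curated set.
* **Overlapping positions in short peptides.** In a 4-mer, N3 and C2 are
  the same residue. Each rule is still evaluated independently at its own
  index (and rules whose index does not exist are skipped). This keeps
  the count well defined for every length ≥ 2 without inventing exclusion
  rules.

# Assay calculators

The maltose and NaNO₂ standard curves are ordinary least-squares lines
(replicate signals at a concentration are averaged first); inversion is
exact inside the fitted range and out-of-range inversions are flagged as
extrapolated rather than refused. Percent α-amylase inhibition is

    100 − 100 · (maltose_sample − maltose_blank) / maltose_negative_control

the only reading of the assay formula under which a sample releasing no
maltose beyond its blank scores 100% and one releasing as much as the
uninhibited control scores 0%. Values outside [0, 100] are reported as
computed: they are chemically meaningful (activation, or a blank above
the sample). Maltose values entering the formula are replicate means by
default.

# The digestion simulator

## What it emulates

* **Parents.** Seeded random proteins, uniform residue frequencies by
  default; a `gly_rich` option (G weighted 5×, S 3×) mimics the
  low-complexity glycine-rich peptides typical of seed-storage protein
  digests.
* **Digestion.** Gastric phase: pepsin, modeled as cleavage C-terminal to
  F, L, W, Y; intestinal phase: trypsin (K, R) then chymotrypsin
  (F, W, Y) standing in for pancreatin. All rules carry the proline
  guard. Each eligible site is independently missed with probability
  `missed_cleavage_prob` (default 0.1). Fragments tile the parent exactly
  and carry 0-based half-open coordinates.
* **Resistant peptides.** A planted set of parent substrings (default
  200, lengths 6–15) appears intact in the SPC pool and passes through
  both phases uncleaved into the ID pool. The planted fraction of the ID
  pool is a free parameter of the scenario; at the default pool sizes it
  is roughly a fifth to a third.
* **Observation.** Every underlying peptide is observed `n_obs = 3`
  times, mirroring triplicate digests and fractions in real designs.
  Each observation passes through the noise model: per-residue
  substitution (default 0.02), per-I/L swap (0.01), single-terminal
  truncation (0.01). ALC confidence is drawn from a clipped normal,
  mean 92 / sd 5 for error-free observations and 20 points lower for
  observations carrying at least one error — the property that makes the
  ALC ≥ 85 filter meaningful, since its whole purpose in real pipelines
  is to remove miscalled sequences.
* **Fractionation.** Ultrafiltration is modeled as sharp molecular-weight
  cutoffs (default <3 kDa, 3–10 kDa, >10 kDa). Real membranes are fuzzy;
  sharp bins keep the partition property exactly testable.

The replicate-observation and error-penalized-ALC mechanisms were chosen
from a first-principles calculation: with per-residue error 0.02, a
single observation of a 10-mer is error-free with probability ~0.82, so
single-observation pools could not support high planted-set recall, while
three observations per pool raise the chance of at least one clean,
confident call above 0.95 — matching how replicate MS runs rescue
low-abundance peptides in practice.

## Ground-truth separation

The ground truth is only meaningful if negatives are unambiguous. Two
guards enforce this at generation time. Non-resistant SPC peptides are
drawn longer (12–30 residues) than typical digest fragments — undigested
material genuinely skews long — and any candidate that is a near-copy of
an ID-pool sequence (composition cosine > 0.93 within a length difference
of 10, i.e. the match rule plus a safety margin for noise) is rejected
during sampling, as is any planted candidate that shadows a genuine
digest fragment. Consequently, with zero noise the SPC∩ID sequence
intersection equals the planted set exactly, and false positives of the
matcher against ground truth reflect the matcher, not label ambiguity.

## What it does not emulate

Kinetics and enzyme concentrations; spectra and their interpretation
(noise is injected at the sequence level); bile chemistry; fuzzy membrane
cutoffs; homology structure among parents (real storage proteins are
families of similar sequences, which would make matching harder);
abundance-dependent detection. Passing the recovery benchmarks therefore
shows that the matcher implements its rule correctly and robustly under
sequence-level noise — not that the rule itself has any particular
sensitivity on real MS data.

# Determinism and problem sizes

All stochastic components are pure functions of their seeds: structural
randomness (digestion, sampling) is governed by the `digestion_spec`
seed, observation noise by the `noise_spec` seed, and reruns are
byte-identical down to the FASTA outputs. The test suite exercises the
matcher against the brute-force oracle up to 500×500 pools, the pI solver
against a 1e-4 fine-grid oracle on ~1000 random peptides plus the
13 published ones, tiling on 100 random proteins, and planted-set
recovery on pools from 20 parents of 250–400 residues with 200 planted
peptides — sizes chosen to make every property cheap to verify exactly
while remaining in the regime of a real experiment's pool sizes
(hundreds of peptides after filtering).

# Known limitations

* pI and net charge depend on the pKa set; comparisons against web
  calculators will differ by up to a few tenths of a pH unit.
* The default terminal criteria are a demonstration set; screens meant to
  support biological claims must supply curated criteria.
* Composition cosine is blind to residue order: permuted sequences are
  identical to it. This is inherent to the published rule, not a defect
  of the implementation; the length guard is the only sequence-level
  constraint.
* The solubility verdict is a heuristic with no experimental calibration.
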