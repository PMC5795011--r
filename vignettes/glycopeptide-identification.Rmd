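---
title: "Methods: intact glycopeptide identification with linearized glycans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intact glycopeptide identification with linearized glycans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glysearch)
```

## The model

Intact glycopeptide MS2 spectra carry two kinds of information at once:
glycosidic fragments (the peptide retaining a shrinking portion of its
glycan, classically called Y ions) and peptide-backbone fragments. The
central idea implemented here is to make both interpretable by a
*standard peptide search*: each monosaccharide is given a one-letter
residue code with a monoisotopic residue (condensation) mass, a glycan
structure is flattened to a linear string over those codes, and that
string is prepended to the peptide N-terminus. Under the usual fragment
arithmetic

$$ b_i = \sum_{j \le i} m_j + m_{\mathrm{H^+}}, \qquad
   y_i = \sum_{j > n-i} m_j + m_{\mathrm{H_2O}} + m_{\mathrm{H^+}}, $$

the glycosidic Y series becomes the high-ordinal part of the y series,
and the leading residues of the glycan string produce the familiar
oxonium ions as b1–b3.

Three letters are free once 20 amino acids and the ambiguity codes B, X
and Z are excluded: O (HexNAc, 203.0794 Da), J (Hex, 162.0528 Da) and U
(Neu5Ac, 291.0954 Da). Fucose (+146.0579 Da) is not a residue letter but
a *variable modification on O*, which is what lets a single database
entry represent all fucoforms. These four masses are cross-checked in
the test suite against their elemental compositions (C8H13NO5, C6H10O5,
C11H17NO8, C6H10O4) to within 1e-3 Da, the precision of 4-decimal
tabulated values.

### Assumptions

* Glycan topology and linkage are *not* represented; two structures with
  the same linear sequence are indistinguishable, and the linearization
  is chosen for spectral coverage, not structural fidelity.
* The glycan always sits at the peptide N-terminus regardless of the
  actual site position within the peptide. Consequently peptide b ions
  are not usable (every b ion spans the glycan) and peptide evidence
  comes from y ions only — acceptable for tryptic peptides, whose HCD
  spectra are y-dominated.
* Fragments are singly protonated, with doubly protonated companions
  for fragments above a neutral-mass threshold; c/z ions (ETD) and
  neutral losses other than the glycosidic ladder are out of scope.

## The canonical N-glycan linearization grammar

Only qualitative criteria constrain the encoding (cover the intense
peaks; read as a glycosidic-loss ladder), so the package fixes one
canonical grammar for complex sialylated N-glycans with $a$ antennae
($2 \le a \le 4$) and $s$ terminal sialic acids ($1 \le s \le a$):

```
sequence = "OJU"                        # one antenna, core -> terminal
         + "UJO" * (s - 1)              # remaining sialylated antennae,
         + "JO"  * (a - s)              #   terminal -> core; asialo last
         + "JJJ"                        # trimannosyl core
         + "OO"                         # chitobiose core, peptide end last
```

The first antenna is written core→terminal so b1/b2/b3 are the HexNAc /
HexNAc-Hex / HexNAc-Hex-Neu5Ac oxonium ions; everything after it is
written terminal→core so successive y ions strip residues in
glycosidic-loss order. For $(a,s) = (2,2)$ this yields `OJUUJOJJJOO`,
the worked di-sialylated biantennary example, and enumerating all valid
$(a,s)$ pairs gives the nine shipped library entries. Real serum-scale
sialylated glycan libraries are somewhat larger (on the order of 20
sequences), the remainder being fucosylated or truncated variants the
grammar does not generate; users supply those as extra TSV rows
(`name<TAB>sequence`). Library names may not contain whitespace or
`|` because they become FASTA header tokens.

For O-glycans only the prefix is pinned by the printed b ions (292.102,
454.155, 657.233 fix `UJO…`); the shipped di-sialylated core-1 encoding
`UUJO` is one of several defensible orderings and is deliberately a
plain data file (`inst/extdata/glycans_core1_O.tsv`), not code.

## Database construction

Proteins are digested with trypsin (cleave after K/R), by default with
the Keil rule (no cleavage before proline) because that is the trypsin
definition of the major search engines; a flag disables it. Peptides of
5–30 residues carrying at least one site are retained: N-mode requires
the N-x-T/S/C sequon (x unrestricted by default; a strict mode excludes
proline at x), O-mode accepts any S/T. The minimum length of 5 follows
the stated digestion parameters; a 6-residue minimum also appears in one
worked example in the source material, so the bound is a parameter
rather than a constant. Non-standard letters (B, X, Z, U, O, J) in input
proteins would collide with glycan codes or lack masses, so peptides
containing them are excluded with a warning.

Each retained peptide is crossed with every library glycan — the
database size is exactly (eligible peptides) × (glycans), a law the
tests verify against brute-force enumeration. A peptide with several
sequons yields *one* entry per glycan (the full sequence is identical
regardless of which sequon carries the glycan); all site positions are
recorded and the first reported as primary. Output is FASTA with the
header grammar `>accession|start-end|siteN|glycan_name`, peptide-centric
by default since scoring is per-glycopeptide; protein-centric output
moves the coordinates into the description so the accession groups
entries. Ordering is deterministic (accession, peptide start, library
order), making database builds byte-reproducible.

Decoys reverse the peptide while keeping a C-terminal K/R in place and
leave the glycan untouched: decoys are exactly mass-matched to their
targets, so the decoy competition tests fragment evidence, not precursor
separation.

## Search and scoring

Candidates are selected within ±10 ppm of the observed precursor at the
spectrum's charge. Theoretical ions for each candidate form are all y
ions (1+, plus 2+ for fragments above 900 Da neutral — large
glycan-retaining y ions are commonly doubly charged; the threshold is a
parameter) and the glycan b1–b3 only; glycan-spanning b ions beyond b3
are generated but not scored. Matching is greedy in descending peak
intensity with one-to-one consumption at ±0.05 Da; on instances whose
ion spacing exceeds twice the tolerance (the realistic case) this equals
the exhaustive optimal assignment, which the tests check.

The proprietary ion score of commercial engines cannot be reproduced, so
an open **binomial-tail score** stands in its place. Under the null that
peaks are uniform in the scored m/z range, each of the $n$ scored ions
matches by chance with probability $q = 2\,\mathrm{tol}\cdot\rho$, where
$\rho$ is the observed peak density over that range. With $k$ matched
ions the match probability is $p = P(X \ge k)$, $X \sim
\mathrm{Bin}(n, q)$, and the score is $-10\log_{10} p$, computed in log
space and capped at 300. On noise-only spectra the fraction of
candidates reaching $p < 0.001$ is measured at or below the nominal
rate (the acceptance script reruns this on 10,000 trials), i.e. the
score behaves as a valid significance bound. The conventional acceptance
rules are kept: per spectrum keep the top-ranked match with score ≥ 25
and $p < 0.001$. Note that under this particular score $p < 0.001$ is
equivalent to score > 30, so the p-value rule is the binding one at the
defaults; both are exposed because users may re-anchor either threshold.

Ranking ties deserve a note: fucoforms of one entry share the full
sequence *and* the precursor mass, and on clean spectra several can
saturate the 300-point cap. Ties are therefore broken first by total
matched-ion count (the placement explaining the most peaks wins), then
by absolute precursor error, then lexicographically by sequence and
fucose positions. Ranking is fully deterministic; no random seed ever
affects search results.

### Fucose localization

Whether fucose rides on the peptide-proximal (core) HexNAc or on an
antenna is read from the Y1 ion (peptide + core HexNAc): a peak
146.0579 Da above Y1 ⇒ `core`; Y1 present without the +146 companion
while larger fucose-bearing y ions match ⇒ `antenna`; no Y1 ⇒
`undetermined`. "Core" here means the peptide-adjacent O of the linear
sequence — the encoding cannot distinguish the two chitobiose GlcNAcs
beyond their ladder order.

## The spectrum simulator

The simulator emulates the *composite* spectra obtained by stepping the
collision energy, as three independently switchable regimes:

* low energy → the glycosidic ladder: y ions retaining the full peptide
  plus $k = 1 \ldots g$ glycan residues. The top rung ($k = g$) is the
  intact species and is emitted as `[M+H]+`, since a y ion of ordinal
  $n$ does not exist; a ladder-only spectrum of the `OJUUJOJJJOO` form
  therefore has exactly 11 glycosidic peaks plus 3 oxonium ions.
* high energy → peptide-backbone y ions (ordinals 1..peptide length),
  carrying no glycan;
* oxonium b1–b3 throughout.

Intensities are class-based constants (oxonium 100, ladder 60, backbone
20) — a deliberate non-physical choice, since no intensity model is
available and matching/scoring only needs peak presence and relative
prominence. Peaks are jittered with Gaussian SD 0.005 Da (a tenth of the
matching tolerance, typical for a calibrated Orbitrap-class instrument),
and 30 uniform noise peaks are added per spectrum, rejected within
0.1 Da of any true peak so ground truth stays unambiguous. Simulated
peaks are singly charged; precursors are 2+ up to 3000 Da neutral and 3+
above. Everything is deterministic under a fixed seed, with one RNG
stream per batch so fixture files are reproducible end to end.

What passing tests on these fixtures shows — and does not show: the
pipeline recovers the generating form as the top hit in the presence of
calibrated-level jitter and sparse noise, and the score's null
calibration holds under uniform noise. Real spectra add co-isolation,
isotope envelopes, intensity structure, in-source decay and
retention-time effects that the simulator does not model, so recovery
rates here are upper bounds on real-data behaviour, not estimates of it.

## Numerical choices and degenerate inputs

* Constants: proton 1.007276 Da, water 18.010565 Da, standard amino-acid
  monoisotopic residue masses; carbamidomethyl +57.02146 applied as a
  fixed modification on every C; oxidation +15.99491 variable on M.
* Printed reference ion values (204.086 etc.) sit 1–2 mDa below exact
  theory — display rounding — so identity checks use 2–10 mDa
  tolerances, never exact equality.
* An empty glycan has mass 0 (used internally for bare-peptide forms);
  an empty library or a proteome with no eligible peptides produces an
  empty database with a warning, not an error.
* A spectrum without a CHARGE line is parsed, flagged, and skipped by
  the search with a warning; malformed MGF blocks fail with the line
  number.
* `q` is clamped to (1e-12, 0.999) so degenerate spectra (empty scored
  range, saturated peak density) cannot produce NaN scores; `k = 0`
  scores 0 by definition.

## Problem sizes

The test suite and the acceptance script exercise: a 200-entry synthetic
database (~3,000 searchable forms after fucoform expansion) with 50
simulated spectra per noise condition for recovery; 10,000 noise-only
spectra for score calibration; 100+ random glycopeptide forms for the
b/y complementarity identity (max error observed ~1e-12 Da); and
exhaustive-oracle comparisons (peak assignment, candidate selection,
database counting) on small instances where enumeration is exact. These
sizes give stable statistics for the properties being measured while
keeping a full run in the order of a minute.

## Known limitations

* No linkage/topology information; isobaric glycans with the same
  linear sequence are one entry.
* One glycan per peptide entry; multiply O-glycosylated forms are out
  of scope.
* The ion score is *not* numerically comparable to any commercial
  engine's score, even though the conventional threshold of 25 is kept
  as a default.
* FDR reporting is plain decoy/target counting above threshold; no
  glycan-aware FDR model is attempted.
* Quantification (XIC extraction, ratio statistics) is out of scope;
  `summarize_by_composition()` only aggregates externally supplied
  ratios.
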