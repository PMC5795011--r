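# glysearch

Identification of intact N- and O-linked glycopeptides from MS2 spectra
using a **linearized glycan encoding**.

Most search engines treat a peptide as a string of one-letter residue
codes. Three Latin letters are unused once the 20 amino acids and the
ambiguity codes B/X/Z are excluded, and this package assigns them to the
basic monosaccharides of complex glycans:

| code | residue                     | monoisotopic residue mass (Da) |
|------|-----------------------------|--------------------------------|
| O    | HexNAc (GlcNAc, GalNAc)     | 203.0794                       |
| J    | Hex (Gal, Man)              | 162.0528                       |
| U    | Neu5Ac (sialic acid)        | 291.0954                       |
| Fuc  | deoxyhexose, variable on O  | +146.0579                      |

A glycan structure is written as a *linear sequence* over these codes and
prepended to the peptide N-terminus. The glycosidic Y ions of the intact
glycopeptide (peptide + shrinking glycan) then become ordinary peptide
**y ions**, and the first three glycan residues are chosen so that
b1/b2/b3 reproduce the diagnostic oxonium ions — m/z 204.087 (HexNAc),
366.140 (HexNAc-Hex) and 657.235 (HexNAc-Hex-Neu5Ac) for N-glycans, or
292.103 (Neu5Ac) and 454.156 (Neu5Ac-Hex) for sialylated O-glycans. A
di-sialylated biantennary N-glycan, for example, is written
`OJUUJOJJJOO` (4 HexNAc, 5 Hex, 2 Neu5Ac).

On top of this encoding the package provides the full identification
pipeline:

* **glycan model** — the O/J/U alphabet, linear glycan parsing,
  compositions and masses, and a canonical generator for mono- to
  tetra-sialylated bi/tri/tetra-antennary N-glycans;
* **protein digestion** — in-silico trypsin (Keil rule optional),
  N-glycosylation sequon scanning (N-x-T/S/C) and S/T site scanning,
  peptide length filtering (5–30 residues by default);
* **database building** — combinatorial glycopeptide FASTA databases
  (peptide- or protein-centric), reversed-peptide decoys, and
  unimod-style residue/modification exports;
* **fragment model** — neutral masses, precursor m/z and theoretical b/y
  ions over the mixed glycan+peptide alphabet, with fucoform enumeration
  (fucose as a variable modification on O, oxidation on M,
  carbamidomethyl fixed on C);
* **spectrum search** — an MGF reader/writer, candidate selection at
  10 ppm precursor tolerance, 0.05 Da fragment matching, an open
  binomial-tail ion score (`-10 log10 P(X >= k)`), the
  top-match / score ≥ 25 / p < 0.001 acceptance rules, fucose
  core-vs-antenna localization via the Y1 + 146 Da diagnostic, and
  per-glycan-composition summaries;
* **spectrum simulation** — a seedable generator of stepped-collision-
  energy-like composite spectra with ground truth, so the whole pipeline
  is testable without instrument data.

## Worked example

Build a database from the shipped synthetic example proteins and the nine
canonical sialylated N-glycans, simulate ten spectra, and search them:

```r
library(glysearch)
ab <- default_alphabet()

proteins <- read_protein_fasta(system.file("extdata",
  "example_proteins.fasta", package = "glysearch"))
library <- read_glycan_library(system.file("extdata",
  "glycans_sialylated.tsv", package = "glysearch"))

db <- build_database(proteins, library)
db
#> glycopeptide database (N-linked): 18 entries, 442 residues
#>   from 2 protein(s), 1 with candidate peptides

cfg <- simulation_config(seed = 7)
make_fixture_dataset(db, 10, cfg, "spectra.mgf", "truth.tsv")

forms <- db_to_forms(db, ab, decoys = TRUE)
psms  <- glyco_search(read_mgf("spectra.mgf"), forms, ab)
hits  <- rank_and_filter(psms)   # rank 1, score >= 25, p < 0.001
nrow(hits)
#> [1] 10

hits[1:3, c("glycan_name", "n_fucose", "fucose_class", "score")]
#>                   glycan_name n_fucose   fucose_class score
#>   mono-sialylated_biantennary        1           core   300
#>  di-sialylated_tetraantennary        0 not_applicable   300
#>     di-sialylated_biantennary        0 not_applicable   300

summarize_by_composition(hits, ab)
#>   composition n_fucose n_psms
#> 1    O6 J7 U3        0      2
#> 2    O4 J5 U1        1      1
#> ...
```

Two synthetic proteins yield two sequon-bearing tryptic peptides; crossed
with nine glycans that is 18 database entries (the second protein carries
only S/T sites, so it contributes in O-mode). All ten simulated spectra
are recovered as rank-1 hits at the default thresholds: `score` is the
binomial-tail ion score (capped at 300), `n_fucose` the number of fucose
residues on the identified form, and `fucose_class` reports whether a
peak 146.0579 Da above the peptide+HexNAc (Y1) ion placed the fucose on
the core HexNAc. The composition table groups identifications by
monosaccharide counts irrespective of the protein, e.g. `O4 J5 U2` is
the di-sialylated biantennary glycan.

The same steps are available from a shell via the thin CLI:

```sh
exec/glytools build    --fasta proteins.fa --glycans glycans.tsv -o db.fa
exec/glytools simulate --fasta proteins.fa -n 50 --seed 7 -o fixtures/
exec/glytools search   --mgf fixtures/spectra.mgf --fasta proteins.fa \
                       --decoys -o report.tsv
```

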