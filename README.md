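# fsapminer

Discovery of skin-secreted peptides of the Frog Skin Active Peptide (FSAP)
superfamily from assembled skin transcriptomes, in R.

Frog skin poison peptides are cleaved from precursor proteins with a
conserved architecture: an N-terminal signal peptide, an Asp/Glu-rich acidic
spacer, and one to three mature peptides bounded by prohormone-convertase
cleavage motifs — Lys-Arg (`KR`), Arg-Arg (`RR`), or the furin-like
`R-X-X-R`. `fsapminer` turns assembled transcript contigs into an annotated
peptide catalogue:

1. **ORF finding** — ATG-initiated, stop-terminated frames above a strict
   nucleotide cutoff, both strands, 0-based half-open coordinates.
2. **Precursor annotation** — a pluggable signal-peptide call (built-in
   Kyte-Doolittle hydropathy-window heuristic, or an external prediction
   table), cleavage-motif scanning with deterministic overlap resolution
   (leftmost-first, `RXXR` > `KR` > `RR`), and classification of inter-motif
   segments as acidic spacer vs. peptide candidate.
3. **Mature-peptide prediction** — motifs excised, spacers dropped, a
   Gly immediately before a motif read as a C-terminal amidation donor
   (peptide flagged amidated, Gly removed).
4. **Property panel** — length; average mass
   `MW = Σ residue + 18.015 (− 0.985 if amidated)` Da; monoisotopic mass;
   formal net charge at pH 7 (`+1` K/R, `−1` D/E, His 0, free termini
   cancel, amidated termini net `+1`); GRAVY (mean Kyte-Doolittle);
   helicity % from an external secondary-structure string.
5. **LC-MS confirmation** — theoretical `[M + zH]^z+` ladders
   (`m/z = (M + z·1.00728)/z`, ESI+ window 100–3000), greedy unique peak
   assignment by smallest |Δm/z|, ties to lower z.
6. **Sequence search** — single-substitution variant libraries
   (`Σ(1 + 19·L)` members for non-overlapping originals) and exact
   substring search over translated libraries.
7. **Expression report** — per-family contig counts and summed TPM, and
   strict `TPM > 100` threshold counts.
8. **Assay arithmetic** — broth-microdilution MIC (with above-range
   markers and skipped-well handling) and neutral-red cytotoxicity
   `100 × (OD_obs − OD_0)/(OD_100 − OD_0)`.

A seeded synthetic-transcriptome generator (`generate_transcriptome()`)
emits Trinity-style contigs embedding FSAP-like precursors with known
ground truth among three decoy classes, with log-normal TPM renormalised to
a million and a configurable high-expression tail — so every stage is
testable end to end without external data.

## Worked example

```r
library(fsapminer)

tx  <- generate_transcriptome(n_precursors = 4, n_decoys = 8, seed = 6)
run <- run_pipeline(tx$contigs, annotation = tx$annotation)
run
#> <fsap_run>
#>   contigs: 12   ORFs: 11   precursors with signal: 7
#>   predicted peptides: 8 (1 amidated)
```

Twelve contigs yield eleven ORFs; seven translated ORFs carry a
signal-peptide call (four true precursors plus signal-bearing decoys, whose
motif-free post-signal regions are held back as low-confidence and excluded
from the mature table), and the four true precursors release eight mature
peptides, one amidated — exactly the generator's ground truth
(`tx$truth`). `tidy(run)` returns the peptide table joined with its
property panel; `glance(run)` gives the one-row run summary.

Recomputing the published reference panel from sequence alone:

```r
props <- peptide_properties(phrynomantin_table())
dplyr::select(props, peptide, seq, length, avg_mass, net_charge, gravy)
#> # A tibble: 19 × 6
#>   peptide          seq            length avg_mass net_charge gravy
#>   <chr>            <chr>           <int>    <dbl>      <int> <dbl>
#> 1 phrynomantin-1Ba GLVTNLLSSVR        11    1158.          1 0.827
#> 2 phrynomantin-1Bb GLVPDLDLPVDL       12    1265.         -3 0.792
#> 3 phrynomantin-1Bc GIVNNLLSTVL        11    1142.          0 1.4
#> 4 phrynomantin-1Bd GPVFDYLSQVYPVR     14    1640.          0 0.05
#> 5 phrynomantin-1Be GLVKDILSLDVL       12    1285.         -1 1.33
#> # ℹ 14 more rows
```

Average masses agree with the published MW column within 0.1 Da on all 19
rows, net charges exactly on all 19, and GRAVY to 0.01 on 18 of 19 (the
remaining row is a documented rounding artefact in the published table).

`plot_property_panel()`, `plot_mass_matches()`, `plot_family_tpm()` and
`autoplot()` provide ggplot2 views of the result types; `write_run()`
emits all reports as TSV/FASTA plus a run manifest.

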