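---
title: "Mining FSAP-superfamily skin peptides from transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining FSAP-superfamily skin peptides from transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsapminer)
```

## The problem

Many frogs secrete defensive peptides from skin poison glands. Most of these
peptides are cleaved from precursor proteins of the Frog Skin Active Peptide
(FSAP) superfamily, which share a stereotyped architecture: an N-terminal
secretory signal peptide, one or more Asp/Glu-rich "acidic spacer" segments,
and one to three mature peptides bounded by prohormone-convertase cleavage
motifs — the dibasic sites Lys-Arg (KR) and Arg-Arg (RR) and the furin-like
R-X-X-R. Skin transcriptome assemblies expose these precursors as transcript
contigs; turning contigs into an annotated peptide catalogue requires a chain
of small inferences (ORF finding, signal-peptide detection, motif scanning,
segment classification, amidation calling) followed by physicochemical
characterisation and, where LC-MS data exist, confirmation of secretion by
theoretical m/z matching.

`fsapminer` implements that chain as composable, pipe-friendly functions over
data frames, plus a seeded synthetic-transcriptome generator so every stage
can be validated against known ground truth.

## The processing model

For each contig, ORFs are ATG-initiated, stop-terminated spans whose
nucleotide length (stop codon included) strictly exceeds a cutoff; both
strands are scanned because contig orientation after de novo assembly is not
guaranteed, and by default only the longest ORF per (strand, frame, stop) is
kept so downstream annotation is not flooded with nested fragments.

A translated ORF becomes a precursor candidate when it carries a signal
peptide. The built-in detector is a transparent hydropathy heuristic: the
8-residue window with maximal mean Kyte-Doolittle hydropathy among window
starts 1–35 must reach 2.0, and cleavage is placed at the first small residue
(A/G/S/C) after that window within positions 10–40 (fallback: window end + 5,
capped at 40). This is intentionally simple — it formalises the one property
all cleavable signal peptides share, a hydrophobic core followed by a small
residue at the processing site — and it is pluggable: a table of external
predictions (e.g. from a dedicated neural predictor) always overrides it.

Cleavage motifs are scanned as KR, RR and RXXR (X = any residue except Arg,
so nested RRs are not double-counted) and resolved leftmost-first with
priority RXXR > KR > RR at equal starts. Cleavage is placed C-terminal to the
motif and the motif residues are excised, belonging to neither flank; the
alternative convention (dibasic retained on the upstream fragment) is
available behind the `keep_dibasic` flag. The segments left between motifs
are classified as acidic spacer versus peptide candidate, and a Gly
immediately preceding a motif (or closing the C-terminus) is read as an
amidation donor: the peptide is flagged amidated and the Gly removed —
standard prohormone biochemistry, since the reported peptide tables mark
amidation but not its genomic trace. Fragments shorter than 4 residues after
processing are dropped (the shortest reported mature peptide in this family
has 6). A precursor with a signal but no motif yields one low-confidence
whole-region peptide; the pipeline excludes low-confidence calls from the
mature-peptide table unless asked.

### Spacer classification thresholds

A segment is a spacer when its D+E fraction reaches `de_spacer` (default
0.30). A second, configurable arm (`de_acidic`) can additionally call
segments with side-chain formal charge at most −2 and a lower D+E fraction;
its default equals 0.30, making it inert. The reason is empirical within
this family: genuinely secreted anionic peptides reach charge −4 at D+E
fractions of 0.28–0.29, so any acidic-charge arm below 0.30 would reclassify
real peptides as spacers. Users working on families whose spacers are less
concentrated in D/E can lower `de_acidic` deliberately.

## The property panel

The per-peptide panel mirrors the columns a peptidomics report prints:

* **Average mass** ("MW", Da): ExPASy-standard average residue masses plus
  one water (18.01524 Da); amidation shifts the mass by −0.98476 Da
  (−OH → −NH2). This is the mass to compare with printed MW columns. Three
  of the 19 published reference peptides sit at round-half boundaries where
  mass tables differing in the third decimal flip the final printed digit,
  so agreement is assessed within 0.1 Da (one printed unit); all 19 agree
  at that resolution.
* **Monoisotopic mass** (Da): kept separately for MS matching (water
  18.010565, amidation −0.98402).
* **Net charge at pH 7**: integer formal counting (+1 K/R, −1 D/E, His 0,
  free termini cancel; an amidated C-terminus removes the carboxylate, so
  the termini net +1). Printed tables show integers, which is what formal
  counting produces; a Henderson–Hasselbalch model would not. His = 0 is
  unconstrained by the reference panel (no His occurs there) and documented
  here as the package's choice.
* **GRAVY**: mean Kyte-Doolittle hydropathy. One published reference row
  prints 0.84 where the scale computes 0.827 → 0.83; the package reports the
  computed value and treats the printed one as a rounding/tool artefact.
* **Helicity (%)**: the fraction of H states in a per-residue H/E/C string
  from an external secondary-structure predictor; only the conversion is in
  scope.

All values are carried at full precision; rounding happens only in reports.

For LC-MS confirmation the theoretical [M + zH]^z+ ladder uses a proton mass
of 1.00728 Da and the ESI+ scan window 100–3000 m/z. A peptide is confirmed
when any ladder entry matches an observed peak within the tolerance
(default 0.5 m/z); each observed peak is assigned to at most one
(peptide, z) by smallest |Δm/z|, ties to the lower charge state — a
deterministic stand-in for manual spectrum inspection.

## The synthetic transcriptome: what it emulates, and what not

`generate_transcriptome()` emits Trinity-style contigs, a TPM table, and
ground-truth sidecars. Its defaults encode the study conditions the package
is validated under:

* precursors of 44–110 residues (the range reported for this family), with
  1–3 tandem peptides of 6–18 residues, spacer D+E fraction at least 0.5,
  amidation probability 0.3, and an optional inter-peptide spacer
  (probability 0.25);
* signal peptides of 15–25 residues whose central core is strongly
  hydrophobic (mean Kyte-Doolittle of the central 8-mer ≥ 2.0);
* decoys cycling through random non-coding sequence, ORFs without signal
  peptides, and signal-bearing ORFs without cleavage motifs;
* TPM drawn log-normally and renormalised to sum to 10^6 ("transcripts per
  million" by construction), with the spread solved analytically so that the
  expected fraction of contigs above 100 TPM matches a configured tail
  probability (default 0.004, the order observed in real skin libraries);
  where two spreads satisfy the constraint the lighter-tailed one is used;
* uniform random synonymous codons in reverse translation, an in-frame stop
  codon guarding each true ATG so assembled flanks cannot extend the reading
  frame, and i.i.d. uniform ACGT decoy composition.

Deliberate idealisations, which bound what green tests prove about real
data: generated mature peptides avoid K/R in their three edge residues and
contain no internal cleavage motifs, so the true segmentation is always
recoverable; spacers contain no K/R at all; non-amidated peptides never end
in Gly. Real precursors can violate all of these (a mature peptide may end
in Arg), in which case motif-based segmentation is genuinely ambiguous and
no text-based rule could recover the intended peptide — the generator
measures the pipeline's correctness, not biology's cooperativeness. The
generator also does not model sequencing error, isoforms, assembly chimeras
or GC bias (the decoy composition choice is documented precisely so
GC-sensitive extensions can replace it).

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; conversion to 1-based
  happens only in display.
* The ORF cutoff is strict ("> 150 nt"), measured including the stop codon;
  both interpretations differ only at the boundary and the choice is a
  documented convention, configurable via `min_nt`. The *pipeline* default
  is `min_nt = 132`: precursors of this superfamily run as short as 44
  residues (135 nt with stop), which a 150-nt cutoff would silently
  discard; 150 remains the default of standalone `find_orfs()`, matching
  its use for building text-search libraries.
* `tpm_sdlog_for_tail()` solves σ²/2 − z₁₋ₚσ + ln(thr·n/10⁶) = 0; an
  infeasible tail (negative discriminant) is an error rather than a silent
  approximation.
* Variant libraries de-duplicate sequences shared between originals but
  record every (origin, position, substitution) in a provenance table; the
  Σ(1 + 19L) size formula therefore holds exactly for non-overlapping
  originals and is property-tested.
* MIC with a skipped well (growth above a no-growth well) is flagged and
  resolved conservatively from the contiguous no-growth run that starts at
  the top concentration. Growth at the top concentration reports an
  above-range marker (e.g. "> 512 uM") rather than a number.
* The cytotoxicity formula 100 × (OD_obs − OD_0)/(OD_100 − OD_0) is applied
  exactly as written and unclamped (neutral-red OD falls as cells die, so
  OD_100 < OD_0 and noisy wells can legitimately leave [0, 100]); a clamped
  companion column is provided for plotting.
* All randomness is seeded through a single `seed` argument per generator;
  seeded runs are byte-reproducible on disk.

## Validation scales

The test suite validates the ORF finder against a six-frame regex oracle on
1000 random contigs; exact peptide-list recovery with oracle signal
positions on 500 seeded precursors (observed: 100%); end-to-end recovery
with the built-in heuristic on 500 precursors embedded among 250 decoys,
scored as peptide-level F1 (observed ≈ 0.97, with false positives arising
from chance ORFs in decoy sequence and flanks, and no false negatives); and
the expression tail on a 20,000-contig synthetic library. These sizes keep
the whole suite to a few minutes on a single CPU while leaving the binomial
and recovery bounds well-powered.

## Worked example

```{r example, eval = FALSE}
tx <- generate_transcriptome(n_precursors = 4, n_decoys = 8, seed = 6)
run <- run_pipeline(tx$contigs, annotation = tx$annotation)
glance(run)
tidy(run)

# LC-MS confirmation against a simulated peak list
pl <- generate_peak_list(run$peptides, charges = 1:3,
                         mz_noise_sd = 0.05, n_decoy_peaks = 30, seed = 1)
run_ms <- run_pipeline(tx$contigs, peaks = pl$peaks,
                       annotation = tx$annotation)
run_ms$ms$summary

# the published reference panel, recomputed from sequence alone
peptide_properties(phrynomantin_table())
```

## Known limitations

* The built-in signal-peptide heuristic is a documented approximation, not
  a replacement for a trained predictor; on real data, supply external
  calls via the `signal` table and the heuristic is bypassed.
* Segment classification is compositional; a spacer-like mature peptide
  (D+E ≥ 0.30) would be dropped. No such peptide occurs in the reference
  family.
* Homology annotation (protein families for the expression report) is an
  input, never computed here.
* MS matching is MS1-only: no isotope envelopes, retention-time modelling
  or fragment spectra.
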