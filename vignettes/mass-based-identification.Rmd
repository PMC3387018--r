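---
title: "Mass-based metabolite identification across record sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-based metabolite identification across record sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzident)
```

## The method

Untargeted LC-MS produces peaks characterised by an m/z value and a
retention time. The first identification step is mass-based: every
metabolite record whose neutral monoisotopic mass lies within a relative
tolerance of the query's implied neutral mass is a putative identification.
`mzident` implements this step against any number of tabular record
sources, with three refinements that matter in practice:

* **Ion annotation.** A molecular species rarely appears only as its
  protonated ion. Sodium/potassium adducts, in-source water loss,
  isotopologues and doubly charged ions all derive from the same neutral.
  When annotation output (CAMERA-style) is available, ions attributed to
  one compound are pooled into an *annotation group* and a single neutral
  mass is searched for the group, instead of treating, say, a sodiated ion
  as if it were protonated (which would shift the queried mass by ~22 Da
  and produce confidently wrong candidates).
* **Cross-referencing.** Sources differ in the chemical identifiers they
  carry; notably, a Metlin-style source provides neither InChI strings nor
  InChIKeys. Missing identifiers are filled from an index of identifier
  bundles built by transitive closure over shared identifiers of all loaded
  records plus an optional explicit mapping table.
* **Skeleton merging.** Hits from all sources are partitioned by the first
  14 characters of the InChIKey, which encode molecular connectivity.
  Stereochemistry annotations in databases are often incomplete and
  stereoisomers are indistinguishable by mass, so entries differing only in
  the key's later blocks are merged into one identification; the number of
  distinct full keys is reported as the possible stereoisomer count.
  Structural isomers have different skeletons and remain separate entries.

## Mass arithmetic and its constants

For an annotation with adduct shift Δ per charge-carrier event, charge z
and isotope order n,

$$ mz = \frac{M + z\,\Delta + n\,\Delta_{iso}}{z}, \qquad
   M = z\,mz - z\,\Delta - n\,\Delta_{iso}. $$

The constants are fixed for reproducibility: proton 1.00727646688 Da,
Na⁺ +22.98921822, K⁺ +38.96315791, H₂O 18.01056468, and
Δiso = 1.00335484 (the ¹³C–¹²C spacing). The sodium and potassium shifts
follow the adduct table printed by CAMERA itself (cation mass, i.e. atom
minus one electron), so the neutral-mass estimates embedded in its output
round-trip through `neutral_mass()` exactly; the test suite verifies every
shift against an independent element-mass summation to 1e-5 Da. Whether an
annotation tool means the pure ¹³C spacing or an averaged isotope spacing
is rarely stated; adopting the ¹³C value is a deliberate choice of this
package, not a claim about any upstream tool. Only five ion species are
supported (`[M+H]+`, `[M+Na]+`, `[M+K]+`, `[M+H-H2O]+`, `[M-H]-`), doubly
charged ions are interpreted as `[M+2H]2+`, and negative mode admits only
the deprotonated ion — a deliberately small grammar; anything else in an
annotation cell is warned about and the peak falls back to unannotated
rather than being guessed at.

The tolerance is applied in neutral-mass space with the *record* mass as
the reference: `|q − m| / m ≤ tol·1e−6`, reported as a signed error
`(q − m)/m · 1e6` ppm. Searching by molecular weight (rather than in m/z
space) keeps one query per annotation group regardless of which ion forms
the group contains. The default of 10 ppm matches Q-TOF-class mass
accuracy; it is a parameter everywhere (`tol_ppm`).

## Annotation groups

`parse_camera()` accepts TSV/CSV (sniffed) or xlsx tables with at least an
`mz` column. An adduct cell may hold several hypotheses
(`"[M+H]+ 180.0634 [M+Na]+ 158.0"`); a `pcgroup` cell may hold several
`;`-separated labels aligned with those hypotheses. CAMERA itself prints a
single group per row; the extended grammar exists because the
split-then-recombine contract needs per-hypothesis group labels, and a
single label simply applies to all hypotheses. Isotope cells follow the
`"[cluster][M+n]z+"` style and imply the protonated series.

A group's neutral mass is the **median** of its members' implied masses.
How to reconcile disagreeing members is genuinely open; the median is
robust to a single mis-annotated or conflicting member while equalling the
obvious value when members agree, whereas a mean is corrupted by any
outlier. Note that the median of *two* values is their mean, so a group
with one real member plus one wrong hypothesis is not protected — relevant
when interpreting results on sparse groups. Peaks with no usable
annotation become singleton groups under the monoisotopic (de)protonated
z = 1 assumption, which is also how bare m/z lists enter the engine; the
two entry points are exactly equivalent on unannotated input (a tested
invariant).

A peak carrying k conflicting (annotation, group) hypotheses is searched k
times, once per group, and `recombine()` then restores one output row per
input peak with the deduplicated union of all its groups' identifications
(ties on the same merged entry keep the smaller |ppm error|). Peak count
is conserved by construction, and hitless peaks keep an (empty) row.

## Cross-referencing semantics

Identifier bundles are built from every loaded record and every mapping
row, then closed by repeatedly merging bundles that share an identifier.
Two bundles that share a key but disagree on a single-valued field (KEGG
id, PubChem CID/SID, InChI, or the InChIKey *skeleton*) are never merged:
both are kept and the conflict is recorded, because no principled
precedence exists between sources and a silent overwrite would poison the
merge stage downstream. Since refusing merges makes the outcome depend on
merge order, the closure is made canonical: within each key-sharing
component, the first compatible pair in sorted-serialization order is
merged until a fixed point — the result is invariant under permutation of
the input records (tested against an independent brute-force oracle).

When filling a hit, a field offered with different values by different
reachable bundles is left missing and logged — with one domain-motivated
exception: candidate InChIKeys that differ only in the stereo suffix while
sharing the skeleton resolve to the lexicographically smallest key. The
downstream merge consumes only the skeleton, so stereoisomer-level
ambiguity is not a reason to withhold a structure code; withholding it
would wrongly demote the hit to a source-local entry. Hits that remain
keyless after cross-referencing are never merged across sources (their
fallback key is `SOURCE:native_id`): without a structure code,
cross-source identity cannot be asserted.

## Merging and deterministic output

Hits are canonically ordered (ascending |ppm error|, ties by native id,
then source, under C collation) before merging; every union is computed
over that order. Multi-valued unions (names, HMDB accessions) are
`;`-joined in **first-encounter order**, stable-deduplicated — matching
how integrated multi-source results render identifier unions in practice
(the accession contributed by the best-ordered hit leads the cell), while
remaining permutation-invariant because of the canonical pre-sort.
Single-valued identifiers take the union of distinct values with
disagreements flagged in an `id_conflicts` column rather than resolved.
The representative full key of an entry is the lexicographically smallest
among its members — an arbitrary but deterministic choice. Reports are
byte-stable: fixed column order, fixed numeric formats (masses to 5
decimals, ppm to 2), rows ordered by query, then |best ppm error|, then
merge key.

The search index is a binary search over a mass-sorted vector with a
±tol·1e−6·q window followed by the exact relative test; the suite checks
it against a linear scan, exactly, over thousands of random queries.

## The synthetic-data generators

Real multi-source searches depend on live database content, which is
neither stable nor redistributable; the package therefore ships seeded
generators that emulate the *structure* of the problem with known ground
truth:

* `generate_databases()`: metabolite masses uniform in 50–1000 Da (the
  usual small-molecule LC-MS range); 60% of metabolites present in 2–4
  sources; stereoisomer clusters (shared skeleton, distinct suffixes) at a
  10% rate; per-source identifier missingness following each source
  profile (the Metlin-style profile always withholds InChI data, the
  others lose identifiers at stated partial rates); and a mapping table
  that resolves 80% of the key-withheld records, keyed by native id.
  InChIKeys are structurally valid random strings — the merge logic
  consumes only string structure, and deriving real keys would add heavy
  chemistry dependencies for no additional coverage of the logic under
  test. Mass collisions are deliberately *not* removed, so ambiguous-hit
  behaviour is exercised.
* `generate_camera_file()`: groups drawn from the generated metabolites
  with ~1.5 ions per compound (sizes 1–4 with probabilities
  0.55/0.25/0.12/0.08, echoing the peaks-to-groups ratio typical of
  annotated LC-MS data); species drawn from a mix of the four positive
  adducts plus `[M+2H]2+` (0.45/0.2/0.1/0.1/0.15); protonated members
  escalate to isotope order 1–4 with probability 0.25; m/z jittered by up
  to 2 ppm (instrument-level accuracy, comfortably inside the 10 ppm
  search window); 10% of peaks receive a second, conflicting annotation
  and 10% are written unannotated. Two guards keep the ground truth
  meaningful: a peak is stripped of its annotation only if it is a
  (de)protonated monoisotopic ion or its group keeps another annotated
  member, and at most one conflicting annotation points into any target
  group, which must retain at least two genuine members — otherwise a
  group's median would be corrupted *by construction* and recovery
  failures would no longer isolate mass collisions, the one failure mode
  the truth table is meant to expose.

What the generators do **not** emulate: chromatography and co-elution
structure, intensity correlation (the evidence CAMERA actually uses),
realistic mass spectra of isotope clusters, heterogeneous per-source mass
accuracy, or chemically meaningful InChIKeys. Passing tests therefore
demonstrate the correctness of the arithmetic, grouping, search, fill and
merge logic — not the biological plausibility of annotations on real data.

## Problem sizes and verification

The test suite verifies, at full scale: a 10,000-ion mass round trip below
1e−9 Da; exact search/linear-scan agreement for 1,000 queries against
5,000 records at 5/10/20 ppm with tolerance monotonicity; merge
partitioning and stereoisomer counts on planted skeleton clusters with
order-invariance; exact 80%/20% merge-versus-source-local behaviour for a
key-less source rescued by a mapping table (for that fixture the
Metlin-style profile withholds *all* shared identifiers, so the mapping
table is provably the only resolution route); ≥99% ground-truth group
recovery on a 100-metabolite, 60-group annotated fixture at 2 ppm jitter,
with the bare-m/z run strictly worse; the four-source identifier-union
worked example shipped in `inst/extdata/worked_example/` (synthetic keys,
real published identifiers); and the conflicting-annotation
search-twice/report-once contract.

## Limitations

* Only the five ion species above; no `[2M+H]+`, ammonium, or general
  adduct grammar.
* No candidate scoring beyond the ppm error, and no retention-time or
  MS/MS evidence — results are putative by definition.
* Name-based matching of keyless entries across sources is deliberately
  not attempted.
* Spreadsheet export requires an optional writer package (`writexl`);
  TSV is the canonical output and is byte-reproducible.
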