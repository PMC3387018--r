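# mzident

Mass-based metabolite identification for untargeted LC-MS metabolomics,
searching one or more metabolite record sources at once and merging the
results into a single non-redundant table.

## The problem

Putative metabolite identification usually starts by looking up an observed
mass-to-charge ratio in a metabolite database: every record whose neutral
monoisotopic mass `M` satisfies

```
|M_query − M_record| / M_record ≤ tol · 1e−6        (tol in ppm, default 10)
```

is a candidate, pending downstream MS/MS and retention-time confirmation.
No single database covers the metabolome, so practitioners search several
(HMDB-, MMCD-, Metlin- and LIPID MAPS-style sources) and must then combine
the hit lists — a chore when hundreds of peaks are involved, and error-prone
because each source carries a different, incomplete subset of chemical
identifiers (KEGG id, PubChem CID/SID, HMDB ids, InChI string, InChIKey).

`mzident` automates the whole chain, offline, against tabular snapshots of
the sources:

1. **Mass arithmetic.** An observed m/z is converted to a neutral mass under
   its ion annotation: `M = z·mz − z·Δ(adduct) − n·Δiso`, with adducts
   `[M+H]+`, `[M+Na]+`, `[M+K]+`, the in-source water loss `[M+H−H2O]+`,
   `[M−H]−` in negative mode, charge z ≤ 2 (`[M+2H]2+`), and isotope order
   n ≤ 4 (Δiso = 1.00335484 Da).
2. **Annotation groups.** A CAMERA-style annotated peak table is parsed and
   ions deriving from one compound (adducts, isotopologues, fragments in the
   same `pcgroup`) are pooled; the group's neutral mass is the median of the
   member-implied masses and a single monoisotopic (de)protonated query m/z
   is searched per group. A peak with conflicting annotations joins every
   group that claims it and is recombined into one output row afterwards.
   Bare m/z lists are handled by treating every value as the (de)protonated
   ion.
3. **Search, cross-reference, merge.** Each source is searched over a
   mass-sorted index; missing identifiers are filled by cross-referencing
   bundles built by transitive closure over shared identifiers (conflicts
   are reported, never silently overwritten); finally hits are merged on the
   first 14 characters of the InChIKey — the connectivity skeleton — so the
   same compound and its stereoisomers collapse into one entry (with a
   stereoisomer count) while structural isomers stay separate.

## Worked example

A negative-mode ion at m/z 624.3401 (a bile-acid glucuronide) searched
against four bundled example sources with their typical identifier gaps
(the Metlin-style file has no InChI data at all and is rescued by the
cross-reference table):

```r
library(mzident)

dir <- system.file("extdata", "worked_example", package = "mzident")
files <- c(HMDB = "hmdb.tsv", MMCD = "mmcd.tsv",
           METLIN = "metlin.tsv", LIPIDMAPS = "lipidmaps.tsv")
sources <- purrr::imap(files, \(f, p) load_backend(file.path(dir, f), p))
xref <- build_crossref(dplyr::bind_rows(sources),
                       extra = file.path(dir, "xref.tsv"))

res <- run_mz_list(624.3401, "negative", sources, tol_ppm = 10, xref = xref)
res
#> <mz_id> mz_list run, negative mode, 10 ppm
#>   sources: HMDB, MMCD, METLIN, LIPIDMAPS
#>   1 query
#>   1 merged identification(s); 1/1 with at least one hit
tidy(res)[, c("kegg_id", "pubchem_sid", "hmdb_ids", "stereoisomer_count")]
#> kegg_id  pubchem_sid  hmdb_ids             stereoisomer_count
#> C03033   85300921     HMDB02618;HMDB02579  2
```

All four sources hit the query (best signed error −0.006 ppm), and although
each one alone reports at most two identifiers, the merged entry carries the
full union: the KEGG id contributed by the HMDB-style row, the PubChem SID
contributed by the LIPID MAPS-style row, a CID resolved from the mapping
table, and both HMDB accessions. The two full keys sharing the skeleton are
counted as 2 possible stereoisomers. `write_report(res, "out.tsv")` exports
the flat table; `autoplot(res)` plots per-source contributions and the
ppm-error distribution.

The same pipeline runs from a shell via the thin CLI in `exec/`:

```sh
mzident --mz-list peaks.txt --mode negative --tol-ppm 10 \
        --db hmdb.tsv:HMDB --db metlin.tsv:METLIN \
        --xref xref.tsv --out results.tsv
```

CAMERA-style annotated tables go through `run_camera()` / `--camera`;
`generate_databases()` and `generate_camera_file()` produce seeded synthetic
sources and peak tables with ground truth for testing and benchmarking.

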