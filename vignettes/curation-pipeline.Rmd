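---
title: "A reversible-lens curation pipeline for multi-source occurrence catalogues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reversible-lens curation pipeline for multi-source occurrence catalogues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The procedure

`dwclens` curates species-occurrence data drawn from several independent
sources into a single auditable checklist. One pass of the pipeline is:

1. **Map** each source's columns onto a Darwin Core field subset
   (`map_columns()`), assign a dataset ID, and **merge** into a master
   catalogue (`merge_catalogues()`).
2. **Resolve** reported names through the taxon-resolution lens
   (`apply_taxon_resolution()`): typos, synonyms, concept changes and
   misidentifications map to preferred names, transitively, without ever
   touching the as-reported string.
3. **Filter to taxa of interest** (`filter_taxa_of_interest()`): marine
   fauna by default, excluding a record only when the taxonomic backbone
   affirmatively places it out of scope.
4. **Georeference**: promote private/obscured coordinates
   (`promote_private_coordinates()`), apply the reversible patch lens
   (`apply_geo_patches()`), and partition by the project-area polygon
   (`filter_by_area()`).
5. **Summarise** one row per distinct taxon (`summarize_taxa()`), **split**
   into per-phylum expert sheets (`split_by_phylum()`), collect expert
   edits, **re-integrate** (`reintegrate_sheets()`) and **diff** against the
   pre-curation summaries (`diff_summaries()`).
6. Fold accepted name edits into the resolution table and repeat until a
   pass produces an empty diff (`run_to_fixed_point()`).

The central assumption is that all corrections are *data*, not edits:
because the two lens files (taxon swaps, geo patches) are stored separately
from the sources and are idempotent and — for coordinates — exactly
invertible, the same curation can be replayed mechanically when a source is
refreshed, and the full history is reconstructible from each catalogue's
append-only modification log.

## Name identity

Grouping and matching operate on a canonical key: lowercase, diacritics
stripped (Unicode transliteration applied to keys only, never to stored
strings), whitespace collapsed, authority and subgenus omitted.
Identification qualifiers are *retained* in the key as a suffix token
(`"nereis zonata?cf"`), because a hedged identification is a distinct
checklist entry from the unhedged binomial; the same holds for `aff.`,
`s. lat.`, `sp.` and `complex` forms. Provisional designators key as
`"myxicola?sp-a"`; this convention for informal names is a package choice,
flagged rather than asserted as community practice. Authority strings never
participate in identity — they are validated against the backbone
(`match_authority()`: exact / normalized / mismatch / missing) and reported
for curator action.

Resolution rules match the verbatim reported string first and fall back to
the canonical key only when no verbatim rule fires: typo rules are
inherently string-level, while concept-change rules should catch
spelling-level variants of the same name. A rule may carry a dataset ID, in
which case it fires only for that source — a misidentification in one
catalogue is not evidence against another catalogue's usage.

## Numerical and procedural choices

* **Polygon test.** Planar even–odd ray crossing on raw WGS84 degrees,
  boundary points inside. At the intended scale (a single island's waters,
  well away from the poles) the planar approximation alters no
  classification that a geodesic test would make differently except within
  metres of the boundary; boundary inclusion is chosen because excluding
  shoreline records from a coastal project would be perverse. Degenerate
  rings (< 3 distinct vertices) are rejected at load. Holes are handled
  implicitly by the even–odd rule.
* **Rounding.** All reported percentages and ratios round half away from
  zero (`round_half_away()`); this is the convention that makes a halfway
  ratio such as 852/13 = 65.5 print as 66.
* **Chain bounds.** Resolution chains longer than `max_chain` (default 20)
  are treated as data errors, and cycles are rejected at table load with
  the offending path printed.
* **Records without coordinates** go to a `noCoordinates` review bucket and
  records outside the area to an `outside` bucket; neither is silently
  dropped, and the three-way partition always conserves the input.
* **Convergence semantics.** Two summary sets are equal iff their diff is
  empty; the diff compares by canonical key, ignores row order and computed
  columns, and pairs a removed/added key with an identical record signature
  (reporting datasets, count, date span) as a single rename. Re-integrated
  summaries *show* proposed renames (as well as emitting them as proposal
  rows) so that a pending rename registers as a discrepancy rather than
  falsely converging; on the next pass the grown resolution table produces
  the renamed summary directly and the loop closes.
* **Cycle policing in the loop.** The resolution table only grows across
  iterations; a curation proposal whose addition would create a cycle
  (an editor renaming A→B one pass and B→A the next) is refused with a loud
  warning, never silently applied or silently dropped — the loop then fails
  at `max_iter` with the residual diff, which is the correct diagnosis of
  an oscillating editor.
* **Column matching is case-sensitive and exact**; schema drift in a
  refreshed source should fail the run, not be papered over. Unmapped
  columns are carried along verbatim.

## The synthetic-data generator

No real occurrence data ships with the package; `generate_fixture()` builds
a five-source dataset whose defaults emulate, at one-tenth scale, the
structure of a community-integrated marine checklist in which a systematic
dive survey dominates record volume while collections dominate novelty
efficiency: exclusive taxon targets (24, 8, 1, 1, 7) for the pmls,
collection, ecological, literature and crowd categories, 26 shared taxa
(67 in all), and per-category record targets (1615, 27, 84, 3, 275),
roughly 2,000 records. Each (source, taxon) pair receives at least one
record, so a source's record count is never below its taxon count (the
literature target is set to 3 for this reason). Injection rates — typos 5 %
of records (single-character edits, one typo form per taxon, so verbatim
rules are unambiguous), coordinate errors 2 %, out-of-area records 2 %,
missing coordinates 2 %, obscured coordinates on 30 % of crowd records —
are fixed generator conditions, chosen once as plausible for moderately
dirty multi-source data. Names come from a Latin-like CV-syllable grammar;
the project area is a synthetic island-scale hexagon. Points are placed
uniformly inside the polygon by rejection from its bounding box;
out-of-area points are pushed beyond a bounding-box edge.

Ground truth — the true taxon list, the exact domains of the two lens
tables, the expected area partition and the expected contribution
statistics — is recorded at generation time by direct enumeration
(`oracle_stats()`), independent of every pipeline code path. What the
generator does *not* emulate: realistic species-abundance distributions,
spatial or temporal clustering of effort, multi-error records, or ambiguous
typos. Passing the end-to-end recovery test therefore demonstrates the
pipeline's bookkeeping is exact under controlled corruption, not that real
catalogues are this well behaved.

## Test problem sizes

The property suites run at: patch reversibility, 100 random patches on a
500-record catalogue across 20 seeds; resolution vs a brute-force
chain-walking oracle on random acyclic tables of up to 200 rules; polygon
membership vs an independently coded winding-number oracle on 10,000 random
points over random 12-vertex star-shaped polygons (boundary cases excluded
by construction of the random draw); and the end-to-end recovery fixture at
the default ~2,000-record scale. These sizes exercise every code path many
times over while keeping the whole suite under a minute.

## Known limitations

* Polygon membership is planar; no geodesic option, no coordinate-
  uncertainty buffering, no reprojection.
* Fuzzy name matching is out of scope by design: resolution rules are
  explicit and human-authored, and the only automatic normalisation is the
  canonical key (case, diacritics, whitespace, authority, subgenus).
* The expert round-trip is modelled as a pluggable function over CSV
  sheets; live spreadsheet synchronisation is a transport concern outside
  the package.
* Conflicting expert edits to the same taxon cannot arise because a taxon
  appears in exactly one phylum sheet; the package enforces this partition
  rather than implementing multi-curator merge resolution.
* The backbone is a supplied local table; there are no live registry
  lookups, so its coverage bounds what the taxa filter and validation can
  decide — names absent from it are kept and flagged, never dropped.
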