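---
title: "Methods: modelling the rare-disease therapeutic ecosystem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the rare-disease therapeutic ecosystem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orphanscape)
```

## The problem and the data model

Treatments for rare diseases are developed by a small, tightly
interconnected set of sponsors. Because each indication affects few
patients, the loss of a single company can eliminate an entire therapeutic
axis for a disease, and market concentration is of direct public-health
interest. `orphanscape` quantifies this ecosystem from portfolio and
financial tables: who develops what, against which disease, with which
mechanism of action (MoA), with whom, and with what revenue.

The atomic unit is the *intervention record*: one development program of
one sponsor against one indication, carrying its MoA, modality (therapy
area), development phase (`early_clinical`, `late_clinical`, `approved`),
orphan-drug-designation (ODD) status, approval year and revenue (million
USD) for approved assets, collaborators, and affected organ systems. A drug
marketed for several indications appears as several records sharing a drug
name; uniqueness counts deduplicate on the name. Records are the common
currency of every module, so all analyses stay consistent with each other
by construction.

Real-world portfolio tables are messy. The reader is therefore deliberately
forgiving: malformed rows never abort a run — they are skipped, counted and
reported with row numbers — and missing-value tokens (`n/a`, `-`, blank) are
parsed as absence, not as errors. One validity rule is asymmetric by
design: an approval year on a non-approved record is a contradiction and
rejects the row, while an approved record *without* a year is accepted and
later counted in the timeline's unknown-year bucket, because published
financial sources frequently omit dates.

Entity names vary across sources ("Hoffmann-La Roche AG", "roche"). Alias
resolution folds case, whitespace and punctuation before lookup, and the
alias table must be idempotent (canonical names map to themselves).
Mergers are handled as an explicit, reversible roll-up: a subsidiary
sponsor is replaced by its (transitive) parent while the original name is
retained in `sponsor_original`, so portfolios can be reported both
including and excluding an acquisition.

## The tripartite network and the knockout simulation

Development activity is modelled as a three-layer directed multigraph:
sponsors (layer 1), collaborators (layer 2), diseases (layer 3). A solo
program contributes one direct sponsor→disease edge; a collaborative
program contributes sponsor→collaborator and collaborator→disease edges
and *no* direct edge. Every edge is annotated with its originating asset,
sponsor and MoA, and parallel programs are kept as parallel edges
(multigraph semantics), so program counts survive round-trips through the
graph; per-disease queries deduplicate at query time.

`disease_activity()` reports, per disease, the number of companies with at
least one program reaching it and the number of distinct MoAs among those
programs. MoA identity is exact string equality on canonical labels — no
mechanism ontology is assumed, so "BTK inhibitor" and "Bruton kinase
inhibitor" are distinct unless the alias table unifies them.

`knockout()` simulates a company leaving the space: its program edges and
sponsor node are deleted, and any collaborator left without incident edges
is pruned. A removed company's *collaborator-role* node survives while
other sponsors still route programs through it: those programs are other
companies' assets and their reach is unaffected by the sponsor's exit.
This makes the simulation exactly equivalent to rebuilding the network
from the record table minus the company's sponsored rows — an equivalence
the test suite checks against an igraph-free brute-force recount on
hundreds of random ecosystems. The impact table reports, per pre-removal
disease, companies and unique MoAs remaining and the respective losses;
deltas are non-negative and only diseases the company develops can change
(monotonicity and locality, both under test).

## Competitive and innovative indexes

Each pipeline asset is classified on two independent axes:

* **disease axis** — `shared_disease` if at least one other company runs a
  program against the same indication, else `single_development`;
* **MoA axis** — `unique_moa` if no other company uses the asset's
  mechanism, else `shared_moa`.

Company-level scores are the asset-weighted fractions of these flags:
the *competitive index (disease)* is the fraction of a company's assets on
contested indications; the *competitive index (MoA)* the fraction with
shared mechanisms; the *innovative index* the fraction with
company-exclusive mechanisms. The published narrative describes these
scores only qualitatively ("close to 1", "close to 0.5"); fractions are
the simplest graded statistic consistent with the four asset flags, they
are bounded in [0, 1], and they make the complementarity
`innovative + competitive_moa = 1` an algebraic identity — a property the
tests assert for every company on every generated ecosystem. By default
the scores are computed on pipeline (non-approved) assets, where the
competitive positioning of *development* is assessed; `scope = "all"`
includes approved assets. Sharing is assessed after merger roll-up when
the caller rolls up, so an acquired portfolio counts as one player; the
flag exists precisely because both views are legitimate.

## Market analytics

`market_shares()` turns per-asset revenues into percentage shares by
company, disease, or organ system. The denominator is always the grand
total of the supplied table and is reported alongside (`grand_total`
attribute): published share tables often leave their universe implicit,
and an explicit denominator is the only way to make percentages
comparable. Organ-system labels are combination strings
("liver/heart/lung") treated as atomic categories; an asset's revenue is
counted once under its full label, never split, because overlapping organ
assignments come with no defensible apportionment rule.

Tier classification uses the published share bands — market leaders,
upcoming major players, challengers — with lower band edges at 6% and
2.5%. The bands are printed without open/closed notation; this package
takes each band to include its lower edge (6.0% is a leader, 2.5% an
upcoming player) and exposes both boundaries as arguments.
`top_asset_profile()` reports each company's revenue concentration (top
asset over total) and the Pearson correlation between total and top-asset
revenue across companies — the signal used to stratify market leadership.
The correlation requires at least three companies and non-zero variance;
degenerate inputs return `NA` with an explanatory note rather than an
error.

The ODD segmentation splits approved drugs by designation status and
reports group counts and percentages, per-group therapy-area percentage
breakdowns, indication frequencies, top companies, and the indications
served by drugs of both statuses. Percentages are computed over
known-status approvals; unknown-status records are counted separately
rather than silently folded into either group.

## The chemical network

`read_stitch_links()` parses chemical-protein link tables in either score
dialect — integers on 0–1000 or reals on 0–1 — detecting the dialect per
file (recorded in an attribute) and normalizing to [0, 1]. Mixed dialects
in one file are an error; individual scores outside both ranges reject the
row. `build_chem_network()` keeps links at or above a confidence
threshold; the default 0.4 is the customary medium-confidence cutoff for
combined interaction scores, and the threshold used is always recorded in
the resulting object.

Two structural choices matter for interpretation:

* **Fixed node universe.** The network's nodes are all listed drugs plus
  every protein the *source table* links to them, regardless of threshold;
  only edges are filtered. With a threshold-dependent node set, density
  and mean degree would not be monotone in the threshold (removing a
  low-confidence protein shrinks the denominator), and metric sweeps would
  be incomparable. With a fixed universe, edge count, density, mean degree
  and shared-protein pairs all fall monotonically as the threshold rises —
  a property the tests sweep explicitly.
* **Shared targets are a relation, not edges.** Drug pairs linked to a
  common protein are counted (`shared_protein_pairs`) but not materialized
  as drug-drug edges; explicit chemical-chemical links alone become
  drug-drug edges. This keeps the two published readings of drug-drug
  connectivity — explicit chemical links versus shared-target inference —
  separately reportable.

`compare_groups()` contrasts two metric sets computed at the same
threshold and takes a 4-metric connectivity vote (density and mean degree:
higher is denser; component count and isolated-drug fraction: lower is
denser). The validation suite generates equal-sized ODD-like and
non-ODD-like drug groups whose link tables differ only in the
target-sharing probability (0.05 vs 0.5) and checks that the high-sharing
group wins at least 3 of 4 votes in every one of 20 seeded replicates —
the repositioning signature: repurposed drugs carry their original target
spectra with them and therefore form denser, more connected networks.

## The synthetic ecosystem generator

No public dataset accompanies the analyses this package supports, so
validation rests on a generator with planted ground truth. The defaults
describe a realistic EU-scale rare-disease ecosystem:

| parameter | default | rationale |
|---|---|---|
| `n_companies` | 43 | leading sponsors active in the space |
| `n_diseases` | 295 | indications with active development |
| `mean_assets_per_company` | 14 | ≈ 600 programs in total |
| `disease_popularity_exponent` | 1 | Zipf-like crowding: a few indications (multiple myeloma, cystic fibrosis) attract many developers |
| `approved_fraction` | 0.35 | ≈ 1 in 3 assets approved |
| `odd_fraction` | 0.35 | ODD share of approvals |
| `unique_moa_fraction` | 0.3 | exclusive-mechanism rate |
| `n_moas` | 60 | shared mechanism pool; small enough that shared MoAs are genuinely shared |
| `revenue_log_mean`, `revenue_log_sd` | 5.5, 1.5 | log-normal per-asset revenue, mean ≈ 750 M USD — a heavy tail where a blockbuster dwarfs the median asset, summing to a market on the 10^5 M USD scale |
| `year_range` | 1995–2021 | approval window |
| `collaboration_prob` | 0.3 | share of co-developed programs |

Each emitted table consumes its own random stream derived from the master
seed, so requesting an additional table never perturbs the others.
Disease assignment samples indication ranks with probability ∝
rank^(−exponent). An asset's MoA is a fresh company-namespaced label with
probability `unique_moa_fraction` (exclusive by construction), else a draw
from the shared pool. Revenues attach only to approved assets; pipeline
assets carry neither revenue nor ODD status.

The `ground_truth` component (per-company planted exclusive-MoA fraction,
per-disease developer counts, per-company revenue) is recounted from the
emitted tables in the tests — exact equality, not approximation — and the
downstream innovative index recovers the planted realization exactly; its
deviation from the *nominal* rate is pure binomial sampling noise, which
the recovery checks bound at three standard errors.

What the generator does **not** emulate: real entity-name noise (aliases
and subsidiaries must be exercised with hand fixtures), multi-indication
drugs (each generated asset has one indication), correlated structure
between revenue and indication crowding, and fiscal-year semantics.
Passing the synthetic suites therefore validates the *mechanics* of the
pipeline, not any empirical claim about the actual market.

## Numerical conventions and degenerate inputs

* All ordered tables break ties deterministically (descending count or
  revenue, then alphabetical), so outputs are reproducible to the byte.
* Density is `2E / (n(n−1))` for `n ≥ 2` and 0 otherwise; a non-empty
  graph has at least one component; the empty record table yields empty
  tables, not errors, everywhere except where a non-empty input is a
  stated precondition (`market_shares()`, `build_chem_network()`).
* Percentages are reported at full precision and formatted to one decimal
  only in print methods.
* Seeds are kept inside the 32-bit integer range; the pipeline's
  `run_pipeline()` is deterministic given its configuration, and the
  echoed configuration plus seed in each bundle's provenance re-derives
  every number in it.

## Problem sizes used in validation

The shipped test and acceptance suites run on: 100 random small ecosystems
(2–8 companies) for the knockout-versus-rebuild equivalence; 5 replicate
ecosystems of 50 companies × mean 12 assets for index recovery at planted
exclusive-MoA rates 0.2/0.5/0.8; 1,000 random revenue tables for share
normalization; and 20 seeded replicates of the 20-drug-per-group chemical
network contrast. These sizes give stable statistics (recovery standard
errors near 0.01) while keeping a full run in well under a minute per
suite.

## Known limitations

* MoA identity is string equality; without an alias table, mechanism
  granularity follows the source's vocabulary.
* Shares depend on the supplied revenue universe; the package reports its
  denominator but cannot detect revenues missing from the input.
* The knockout simulation removes whole companies; partial divestments or
  asset transfers are out of scope.
* Pathway support is a membership join against a user-supplied
  protein→pathway table; no enrichment statistic is computed.
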