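---
title: "Presence/absence interactor calling for AP-MS pull-downs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence/absence interactor calling for AP-MS pull-downs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmscall)
```

## The problem

Affinity purification followed by mass spectrometry (AP-MS, or IP-MS when
the purification is an immunoprecipitation) identifies the proteins that
co-purify with a tagged or antibody-captured bait. Two failure modes
dominate: *nonspecific binders* that stick to the beads or the antibody
isotype rather than to the bait, and *stochastic detection* — a genuinely
present protein can drop out of any single run near the instrument's
sensitivity limit. The classical remedy, implemented here, is a
presence/absence design: run the bait pull-down in biological triplicate
alongside an isotype-control (IgG) pull-down in triplicate for every
condition, and accept a protein as a candidate interactor only when it is

1. identified confidently (q-value strictly below 0.01),
2. not a decoy (reversed-sequence) or common-contaminant entry,
3. absent from **every** isotype-control replicate of that condition, and
4. detected in **all** bait replicates of that condition.

`call_candidates()` applies exactly these four rules. Everything downstream
is set algebra over the per-condition candidate sets: which interactors are
shared by all conditions (the common core), which belong exclusively to a
group of conditions (e.g. cancer cell lines but not a non-cancer line),
how the sets overlap reference interactomes, which annotation terms are
overrepresented, and whether the replicates were concordant enough to trust
any of it.

## The calling model, precisely

Let $I_{gs} \ge 0$ be the reported intensity of protein group $g$ in sample
$s$ (0 encodes "not detected" in MaxQuant-style output). Detection is
binarized as $D_{gs} = [I_{gs} > 0]$. For condition $c$ with bait samples
$B_c$ and control samples $C_c$, after the q-value and decoy/contaminant
filters,

$$\text{candidate}(g, c) \iff \Big(\textstyle\sum_{s \in B_c} D_{gs} = |B_c|\Big)
\wedge \Big(\textstyle\sum_{s \in C_c} D_{gs} = 0\Big).$$

Both clauses are configurable (`calling_params()`): the bait clause can be
relaxed to "at least $k$ of $n$ replicates", and the control clause can be
switched from the default *any-replicate* subtraction to *all-replicates*
(subtract only proteins seen in every control), a variant worth having
because control-complete detection is also how nonspecific-binder
inventories are usually tabulated. Two behaviours are deliberate and
order-sensitive:

* **Filters precede binarization.** A decoy or low-confidence row detected
  in a control cannot mask a real protein with the same accession pattern,
  because it is removed before the detection matrix is built.
* **Controls are per-condition.** Subtraction uses only the *respective*
  condition's controls, never a pool across conditions; bead/antibody
  stickiness can be condition-dependent.

The q-value comparison is strict (`q < q_max`): a row at exactly 0.01 is
excluded. The bait is treated like any other protein — it passes because it
is present in all bait IPs and no control, not by special-casing.

### Identifier semantics

Protein groups are matched across tables by their **leading (first
majority) accession**; the gene name is carried as a reporting attribute
and falls back to the leading accession when blank. Published AP-MS
interactor tables list single accessions per row, which is what this
convention reproduces; whether an upstream study matched by accession, gene
symbol, or group-overlap logic is generally not recoverable from its text,
so the convention is documented rather than guessed at per input. Mapping
tables (two-column TSV) can be applied by the caller before comparison when
two inputs use different namespaces; no identifier-mapping service is built
in.

## Set comparison

`compare_conditions()` partitions the union of the candidate sets by exact
membership signature — the regions of an $n$-set Venn diagram — and reports
all $2^n - 1$ regions, including empty ones, so output shape is
deterministic. `unique_to(sets, group)` is
$\bigcap_{c \in \text{group}} S_c \setminus \bigcup_{c \notin \text{group}} S_c$.
When exactly one condition lies outside the group, the group core must
split exactly into the common-to-all core plus the group-unique set;
`consistency_check()` verifies this identity and lists any discrepancy.
This is the arithmetic behind tallies like "38 common-to-all + 18
cancer-unique = 56 common to the three cancer lines" in the karyopherin
beta-1 (Kpn-beta-1) pull-down study whose printed tables ship with the
package (`kpnb1_common_core()`, `kpnb1_cancer_unique()`).

A note on those tables: the study's narrative counts 38 common binding
partners, while its printed common-core table lists 39 rows — the bait
itself (Q14974, KPNB1) plus the 38 partners. The package keeps the printed
table verbatim and treats "common core" as bait + 38 partners; the
38 + 18 = 56 identity holds on the partner sets. By default the bait is
*kept* in all sets and region counts (pull-down studies typically include
it in their Venn tallies); drop it explicitly with
`setdiff(sets$X, bait_id)` if partner-only counts are wanted, and both
conventions are one `setdiff()` apart.

`overlap_stats()` reports intersection count, the percentage of each side
covered, and the Jaccard index for comparisons against reference
interactome exports (BioGRID, BioPlex, STRING or any one-ID-per-line
list read by `read_id_list()`). Percentages against an empty side are
returned as 0 with a `degenerate` flag rather than NaN.

## Overrepresentation testing

`fisher_overrepresentation(k, n, K, N)` is the one-sided Fisher's exact
(hypergeometric upper-tail) probability of at least $k$ term members in a
query of size $n$ drawn from a background of $N$ genes of which $K$ carry
the term:

$$p = \sum_{i=k}^{\min(n, K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.$$

It is evaluated in log space through the hypergeometric distribution
function, so large backgrounds (e.g. all annotated human genes) are safe;
the test suite verifies it against a direct $\binom{\cdot}{\cdot}$
enumeration for every configuration with $N \le 40$ and against the
one-sided 2x2 `fisher.test()`. Only overrepresentation is tested —
depletion is out of scope. Design choices a user should know:

* **The background is always explicit.** The query's own union is never
  silently substituted; the intended background is the full annotation
  universe (for gene-ontology work, all genes of the organism in the
  annotation release used).
* **Correction is per ontology category.** Benjamini–Hochberg (default) or
  Bonferroni is applied within biological process, cellular component and
  molecular function separately, mirroring how gene-ontology tools report
  per-category rankings; `"none"` copies raw p into the fdr column.
* **Terms are flat sets.** GMT input (`read_gmt()`); no GO-DAG propagation,
  no protein-class hierarchy. Gene identity is case-sensitive exact match.
* **Ranking** (`top_terms()`) sorts ascending by p with ties broken by
  term id, and returns fewer than `n` when the category has fewer tested
  terms.

## Replicate QC

Correlation QC works on $\log_2$ intensities with zeros treated as
missing — no pseudocount, because $\log_2 0$ is undefined and imputing a
floor would manufacture correlation between sparse columns. Pearson r is
computed per sample pair over the proteins quantified in both
(pairwise-complete); pairs sharing fewer than 3 proteins are reported as
undefined together with their count rather than dropped. `qc_report()`
summarizes within-condition replicate pairs separately for bait IPs and
isotype controls and flags bait pairs below a threshold — 0.93 by default,
the concordance bar the accompanying study applied to its pull-down
replicates. Control replicates are *expected* to correlate less: their
shared content is the stochastic nonspecific background.

## The synthetic generator: what it emulates, and what it does not

`sim_params()` states a world; `generate_truth()` plants labels;
`simulate_protein_groups()` applies the detection and intensity model. The
default preset mirrors the accompanying study's design: 4 conditions (one
non-cancer, three cancer cell lines), 3 bait + 3 control replicates each,
38 planted common interactors, 18 planted cancer-group-unique interactors,
100 nonspecific binders, 10 contaminants, 10 decoys.

Detection: the bait is present in every bait IP and no control; a true
interactor is detected in each bait replicate of its conditions
independently with probability `p_det_true` (default 0.9, a realistic
per-run dropout for mid-abundance interactors) and never in controls;
nonspecific binders appear in bait samples with `p_det_bg_bait` (0.4) and
in controls with `p_det_bg_ctrl` (0.8). With these defaults about
$100 \times 0.8^3 \approx 51$ background proteins are seen in all three
controls of a condition, inside the 37–90 range the study reported for its
isotype controls. Independence across replicates is a deliberate modelling
choice: it makes the all-of-$n$ rule's recall exactly
$p_{\text{det}}^{\,n}$ (`expected_recall()`) and the background
false-positive rate exactly
$p_\text{bait}^{\,n}(1-p_\text{ctrl})^{\,n}$
(`expected_background_fp_rate()`), both of which the test suite verifies by
simulation against the closed forms.

Intensities: a detected cell gets
$\log_2 I = m_g + e_s + \varepsilon$, with protein means
$m_g \sim N(25, 4^2)$ (MaxQuant-scale intensities spanning roughly
$2^{13}$–$2^{37}$), a shared per-sample loading effect
$e_s \sim N(0, 0.3^2)$, and residual noise
$\varepsilon \sim N(0, 0.25^2)$ for specific interactions but
$N(0, 1^2)$ for nonspecific rows — stochastic bead binding is noisier
than a stoichiometric interaction. These four numbers were fixed once, at
design time, from the variance ratio
$r \approx \sigma_\text{protein}^2 / (\sigma_\text{protein}^2 + \sigma_\varepsilon^2)$:
they put bait-replicate Pearson r near 0.98 (comfortably above the 0.93
bar) and control-replicate r near 0.94 — below bait, reproducing the
study's qualitative QC observation. The separate background residual is an
extension beyond a single global noise term; without it, control and bait
replicates would be equally concordant, which real isotype controls are
not.

What a green synthetic test does **not** establish: the generator has no
peptide-level structure (no shared peptides, so no nontrivial protein
groups), no intensity-dependent dropout (detection is independent of
abundance, unlike real electrospray data), no correlated dropout across
replicates, no condition-specific background shifts, and decoys/
contaminants are simply flagged rows rather than artefacts of a search
engine. It validates the *pipeline logic* — filtering, subtraction,
replicate rules, set algebra, statistics — not MaxQuant's identification
behaviour.

Reproducibility: `generate_truth()` seeds the RNG with `seed` and
`simulate_protein_groups()` with `seed + 1`; the same seed yields a
byte-identical protein-group file.

## Numerical and degenerate-input choices

* q-values and intensities are parsed as plain decimals (UTF-8, no locale
  dependence); blank intensity cells are 0, blank q-values are an error.
* Empty candidate sets, empty Venn regions and empty overlap sides are
  legal results, reported with explicit zero counts or degenerate flags.
* Correlation cells with fewer than 3 shared proteins are `NA` with the
  count attached; the diagonal is 1 only where at least 2 observations
  exist.
* Fisher p-values are clamped to $[0, 1]$ against floating-point overshoot;
  `k = 0` gives exactly 1 (the full tail), `K = N` forces 1.
* Ties in enrichment ranking break by term id, making `top_terms()`
  deterministic.
* `venn_export()` writes all regions as TSV always; figures are drawn for
  2–4 sets (circles / the classic four-ellipse layout) and skipped with a
  warning above that.

## Known limitations

* Presence/absence calling ignores quantitative enrichment; a protein
  abundant in bait IPs but faintly detected in one control is discarded.
  Probabilistic scorers (SAINT, CompPASS) address this and are deliberately
  out of scope; their *output lists* can still be compared via
  `overlap_stats()`.
* Whether an upstream table's detections came from MS/MS identification or
  match-between-runs transfer is invisible here; intensity > 0 is the
  operative proxy for "identified in that sample".
* Only the protein-group table of a MaxQuant-style output is consumed;
  evidence/peptide tables, raw spectra and search parameters are not.
* Gene-ontology term membership counts depend on the annotation release
  supplied by the user; the package ships no annotation database.
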