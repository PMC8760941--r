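---
title: "Inferring convergent gene-family loss across independent lineage pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring convergent gene-family loss across independent lineage pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

When several parasitic lineages evolve independently from related
non-parasitic ancestors, do they lose the *same* genes? `convloss` answers
this for gene families scattered over large gene trees — the motivating case
being chemoreceptor (odorant/gustatory receptor) repertoires in socially
parasitic ants, with three independent parasite–host species pairs and a
reference outgroup species anchoring orthology.

The inference chain is:

1. **Orthologous clusters.** Each gene tree (built upstream with tools such
   as MAFFT + FastTree, rooted on a universal outgroup gene such as the
   odorant receptor co-receptor) is scanned for *maximal clades consisting
   only of focal-species genes*. Maximality forces at least one
   reference-species gene immediately outside the clade, so every cluster is
   anchored by reference genes; those anchors also carry ancestral-subfamily
   labels. Weakly supported branches (support < 0.7 by default) are first
   contracted into multifurcations so that orthology is not read off
   unreliable splits.
2. **In-paralog collapsing and calls.** Within a cluster, every maximal
   single-species clade is collapsed to one representative; at
   multifurcations, same-species sibling subtrees are merged likewise. A
   collapse marks a *gain* (species-specific expansion) for that species.
   For each parasite–host pair, the count difference
   `delta = parasite − host` over post-collapse counts defines the calls:
   `delta < 0` is a parasite loss, `delta > 0` a host loss. Each parasite is
   compared only against its own paired host.
3. **Convergence test.** Let `m_s` be the fraction of the `n` clusters with
   loss in parasite `s` (the marginal loss probability). If losses strike
   lineages independently, a given cluster is lost in *all* parasites with
   probability `p0 = prod(m_s)`. The observed number `x` of convergently
   lost clusters is compared with `Binomial(n, p0)` by a two-sided exact
   test; the observed probability `x/n` gets a Clopper–Pearson interval,
   and the test's power at the observed effect size is reported.
4. **Post-processing.** Per-subfamily enrichment of convergent loss against
   the family-wide `p0` (Benjamini–Hochberg across subfamilies), and
   ingestion of externally computed selection-intensity results (RELAX-style
   `k` per cluster) with FDR control, convergent-relaxation flags
   (`k < 1`, FDR < 0.05) and rank-sum comparisons of `k` across loss
   categories (no loss / loss in one / loss in more than one parasite).

## Numerical conventions

Several conventions are fixed here because they silently differ between
statistical environments:

* **Two-sided exact binomial p-value** — the point-probability ("minlike")
  convention: the p-value sums `Binomial(j; n, p0)` over every outcome `j`
  whose point probability is at most that of `x`, with a relative tolerance
  of `1e-7` absorbing floating-point ties. At the degenerate nulls `p0 = 0`
  (or 1), the p-value is 1 when `x` sits at the corresponding boundary and 0
  otherwise.
* **Clopper–Pearson bounds** — the beta-quantile form,
  `qbeta(alpha/2, x, n-x+1)` and `qbeta(1-alpha/2, x+1, n-x)`, with the
  conventional 0 and 1 at `x = 0` and `x = n`.
* **Power** — the default is exact enumeration of the two-sided rejection
  region `{j : p(j) <= alpha}` followed by summation of `Binomial(j; n, p1)`
  over it; a simulation estimator is provided as a cross-check. Published
  power figures for this kind of analysis often come from unstated
  conventions (one-sided regions, normal approximations); the package
  therefore reports exact and simulated power side by side rather than
  matching any particular printed figure. At the odorant-receptor effect
  size (`n = 307`, `p0 = 0.0164`, `p1 = 0.0586`) the exact rejection-region
  power is ≈ 0.99; at the gustatory effect size projected to `n = 307`
  (`p0 = 0.1457`, `p1 = 0.1806`) it is ≈ 0.37.
* **Support dialects** — FastTree writes local supports in [0,1], most
  bootstrap pipelines write 0–100. Any support value above 1 switches the
  whole tree to the 0–100 reading and rescales, so the 0.7 threshold means
  the same thing for every input. The comparison is strict (`< 0.7`
  collapses; 0.7 exactly is kept), and nodes *without* a support value are
  retained — absence of a label is not evidence of a weak branch.
* **Ties in subfamily assignment** — majority vote among a cluster's
  anchors; ties break by the anchor topologically closest to the cluster,
  then lexicographically. Collapsing representatives are the
  lexicographically smallest gene id, purely for determinism.
* **Both counts zero** — a cluster absent from both members of a pair
  yields no call for that lineage but still counts in `n`, matching the
  convention that `n` is the full cluster count of the family.

## Design choices where the procedure was genuinely open

* **Cluster definition.** "A clade whose outgroup contains a reference gene"
  is formalized as *maximal focal-only clade*. This is the only
  parameter-free reading: maximality itself supplies the reference
  outgroup, mixed clades are never clusters, and every focal gene lands in
  exactly one cluster (a partition the tests assert).
* **Manual curation.** Published cluster sets are typically hand-curated.
  Here curation is an explicit override table (gene → cluster) applied by
  `apply_curation()`: auditable and replayable. A moved gene keeps its
  representative status; a species left without a representative in a
  cluster has its smallest gene promoted, which makes cluster merges
  additive in collapsed counts.
* **Nonhost species** are focal (they occupy clusters and can show gains)
  but generate no loss calls unless an explicit pairing is supplied;
  host-versus-nonhost turnover comparisons reuse the same call machinery
  through the `lineages` override of `build_call_table()`.
* **Subfamily enrichment null.** Each subfamily is tested against the
  family-wide `p0` (the same null as the headline test), which is how a
  shared "all clusters" row and per-subfamily rows can carry a common
  expectation; a subfamily-specific `p0` can be passed instead.
* **Multiple testing.** Wherever an FDR is required (enrichment, selection
  LRTs) the Benjamini–Hochberg step-up is used.
* **Selection records.** One record per cluster (test branches = all
  parasite branches). Per-lineage records can be represented by suffixing
  the cluster id; "convergent relaxation" then means all of a cluster's
  records pass.

## What the simulator emulates — and what it does not

`sim_config()` / `generate_dataset()` produce gene families evolving by a
linear birth–death process along a fixed species tree: one ancestral copy
per family, duplication at `lambda_dup` and loss at `mu_loss` per copy per
unit branch length, with loss accelerated by `parasite_multiplier` on
parasite terminal branches and switched off on the reference terminal so
every family keeps an anchor. A fraction `convergent_fraction` of families
are *convergent targets* whose parasite terminal loss rate is multiplied by
`convergent_multiplier`, emulating genes whose loss is favoured in every
parasite. Internal-node supports are fixed at 1.0 or drawn from a
Beta(a, b); gene-tree error is modelled only through support noise and the
downstream collapsing — topologies are never scrambled, since the method
consumes supports, not alternative topologies (a topology-noise hook would
be the natural extension).

Default conditions (chosen once, as the study conditions the package is
calibrated against): a unit-depth ultrametric species tree with three
parasite–host pairs (terminal branches 0.2), two nonhosts and one reference
splitting at the root; `lambda_dup = 0.1`, `mu_loss = 0.15`,
`parasite_multiplier = 10` — giving parasite marginal cluster-loss
probabilities around 0.3 and host marginals of a few percent, the regime
reported for odorant receptors — `convergent_fraction = 0.1`, and
`convergent_multiplier = 100`, which makes a target's copy loss on each
parasite terminal nearly certain (rate × length = 3). Truth tables record
both raw tip counts and *ortholog-unit* counts (maximal single-species
clades of the true genealogy, computed by an independent recursion): loss
calls are defined on post-collapse counts, so the unit counts are the
quantity a correct pipeline must recover, and on clean data (supports 1.0)
the full emit → parse → root → cluster → collapse route reproduces them
cell for cell — an equality asserted by the test suite, which is also why
large calibration loops may run from `truth_call_table()` directly.

Passing these tests shows the chain is internally consistent and correctly
calibrated under the generative model; it does not certify performance on
real data, where annotation error, assembly gaps and alignment artefacts
add structure the simulator does not emulate.

## Calibration results the tests compute

With the default conditions (`n = 300` families, 10% targets), the
convergence test rejects at `alpha = 0.05` in ≥ 95% of 200 seeded
replicates; with no targets (losses still elevated but independent across
lineages) the rejection rate over 500 replicates stays at a few percent,
within the ≤ 7% band expected for a plug-in null. With
`parasite_multiplier = 1` the p-value distribution is super-uniform —
checked by a one-sided Kolmogorov–Smirnov test (CDF above the diagonal),
the appropriate direction for a discrete, conservative exact test whose
two-sided KS distance is dominated by the modal point probability. That
property run uses 150 families per replicate over 500 seeds; the
branching-process sanity check (mean tip count `e^{(lambda-mu)T}`) uses
5,000 families.

## Degenerate inputs and edge behaviour

Star trees (everything collapsed) are valid; a tree with no reference leaf
is a configuration error while one with no focal leaf yields an empty
cluster set with a warning; `p0 = 0` (a marginal of zero) gives p-value 1
at `x = 0` and 0 otherwise; clusters whose anchors are absent from the
anchor table stay unassigned and are ignored by the enrichment; selection
records with any branch dN/dS > 10 are excluded before FDR.

## Known limitations

* Gene-tree error beyond support noise (wrong topologies with confident
  supports) is not modelled and will not be caught by support collapsing.
* The plug-in null (`p0` estimated from the same table) makes the test only
  asymptotically calibrated; the measured small-sample inflation at
  `n = 300` is a percentage point or two above nominal.
* Tree-reconciliation-based gain/loss inference is intentionally out of
  scope; the cluster-based calls are the conservative choice for closely
  related species.
* The Wilcoxon exact path requires tie-free data; with ties it switches to
  the tie-corrected normal approximation, as standard.
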