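# sccgh

Single-cell BAC array CGH simulation and cell-cycle-aware detection of
segmental chromosomal imbalances.

## The problem

In preimplantation genetic diagnosis (PGD) for carriers of balanced
translocations, single blastomeres are profiled by BAC array CGH and
embryos carrying unbalanced segments are deselected. Standard practice
ignores the cell-cycle phase of the biopsied cell. That matters: in S
phase the genome is replicated progressively from stochastically firing
origins organised in replication-timing domains, so a single S-phase cell
carries an effective copy number of 2, 3 or 4 at a diploid locus depending
on whether zero, one or both copies have replicated. The resulting
megabase-scale oscillation of log2 intensity ratios can mask a genuine
segmental gain or loss — a false negative that, in the clinic, means
transferring an unbalanced embryo.

`sccgh` is for anyone who wants to study this failure mode
quantitatively: it packages the per-cell detection counts observed in
three carrier cell lines, the detection rule and group statistics used to
analyse them, and a mechanistic simulator that reproduces the phenomenon
from first principles.

## What the package computes

**Detection rule.** Per probe, a gain is called when the normalized log2
ratio L_p exceeds +0.3 and a loss when it falls below -0.3. A region of
interest is *accurately* detected when at least half of its probes pass
(k >= ceil(n/2)), *reliably* detected when additionally at least 10
consecutive probes pass, a *no-call* when at most a quarter pass, and
*underestimated* in between. A cell is a false negative when any of its
constitutive imbalances is not accurate.

**Preprocessing.** Probes with signal-to-noise < 2 are excluded; ratios
are normalized so that the ratio of the channel means equals 1
(`L_p = log2(test_p/ref_p) - log2(mean(test)/mean(ref))`, autosomes only
by default since the reference DNA is of the opposite sex).

**Generative model.** A locus with replication timing `t` (0 = earliest)
in a cell at S-phase progression `s` has been replicated with probability
`plogis((s - t)/tau)`; each of its `c` constitutive copies replicates with
domain-level coordination, giving effective copies `c + Binomial(c, p)`.
Two-channel intensities add probe affinity (shared between channels),
log-normal WGA representation bias, hybridization noise and a background
floor.

**Phase attribution.** S-like profiles are recognised by their
replication-domain oscillation: early-domain ratios exceed late-domain
ratios (rank-sum test), and L_p correlates with replication earliness
(Spearman r_t). Statistics and thresholds live in `early_late_statistics()`
/ `classify_phase()`.

**Group statistics.** `rank_sum_test()` (Mann-Whitney U, mid-rank ties,
tie-corrected normal approximation, exact enumeration for combined n <= 12)
and `chi_square_2x2()` (Pearson, df 1, no continuity correction).

## Worked example

```r
library(sccgh)

pm     <- paper_probe_map(seed = 1)          # array-matched probe layout
preset <- paper_presets()$der18_t9_18        # 24 Mb dup(9p) + 8 Mb del(18p)
coh    <- simulate_cohort(n_s = 10, n_g0g1 = 8, preset = preset,
                          probe_map = pm, seed = 42)
res    <- analyze_cohort(coh, preset)
print(res$table1b)
```

```
Per-phase false-negative summary
  S     underestimation  1 | no call  0 | false negative  1 / 10 cells
  G0G1  underestimation  0 | no call  0 | false negative  0 /  8 cells
```

One of ten simulated S-phase cells underestimates an imbalance that every
G0/G1 cell detects; at larger cohort sizes the S deficit concentrates in
the duplications (see the vignette for why deletions resist masking).
The packaged study table is reproduced by:

```r
print(reproduce_table1())
```

```
Per-phase false-negative summary
  S     underestimation 14 | no call  3 | false negative 17 / 26 cells
  G0G1  underestimation  3 | no call  1 | false negative  4 / 22 cells
Chi-square (accurate vs false negative x phase): p = 0.001
Mann-Whitney, passing fractions, all regions:    p = 0.326
Mann-Whitney, passing fractions, regions > 9 Mb: p = 0.025
```

17/26 S-phase versus 4/22 G0/G1 cells are false negatives — the accurate
detection rate is significantly phase-dependent (chi-square p = 0.001) —
and the per-region probe-passing fractions differ significantly between
phases for the regions above 9 Mb.

A thin command-line front end is installed with the package
(`system.file("scripts", "sccgh", package = "sccgh")`) with subcommands
`simulate`, `analyze` and `reproduce-table1`.

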