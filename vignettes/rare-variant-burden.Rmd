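---
title: "Rare-variant gene-set burden analysis in small case-control exome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant gene-set burden analysis in small case-control exome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The analysis

`rvburden` implements the downstream half of a small case-control exome
study: starting from an annotated multi-sample VCF, it asks whether
patients carry more rare variants than controls within curated gene sets,
whether particular rare variants are shared by patients but absent in
controls, and whether a resulting candidate list is functionally coherent.

The statistical core is deliberately plain, because with arms of five or
six individuals nothing more elaborate is estimable:

* **Burden comparison.** For a gene group $G$, zygosity state $z$ and
  filter $F$, each individual $i$ gets a count
  $x_i = \#\{v \in F : \mathrm{gene}(v) \in G,\ \mathrm{call}(i,v) = z\}$.
  The two per-individual count vectors (controls first) are compared with
  the Welch unequal-variance $t$ statistic
  $t = (\bar x_1 - \bar x_2)\, /\, \sqrt{s_1^2/n_1 + s_2^2/n_2}$ with
  Welch–Satterthwaite degrees of freedom and a two-sided p-value.
  Per-individual counts are treated as exchangeable units; no covariate
  adjustment is attempted, and no multiple-testing correction is applied
  across gene groups (the groups are few and pre-specified).
* **Shared-variant criterion.** A variant is flagged when at least $k$
  patients (default 3, half the patient arm) and at most $c_{\max}$
  controls (default 0) carry it, where a carrier is any heterozygous,
  homozygous-alternate or hemizygous-alternate call — presence, not
  dosage.
* **Over-representation.** For a candidate list of $n$ genes in a
  universe of $N$, a term annotating $K$ universe genes and $k$ query
  genes scores $P[X \ge k]$ under the hypergeometric distribution,
  computed in log space from `lchoose` sums; Benjamini–Hochberg step-up
  adjustment is applied across terms, and the report keeps terms with
  $p \le 0.05$ and adjusted $p \le 0.2$, ranked by adjusted then raw
  p-value (ties left in annotation order), at most ten rows.

## The frequency dialect

The "MAF" used for filtering is the **maximum** alternate-allele
frequency across up to six population databases (1000 Genomes, ExAC, ESP,
gnomAD v2 exomes, gnomAD v2 genomes, gnomAD v3), stored per variant as
separate INFO keys. Three consequences of this definition matter:

* a variant passes a threshold $\tau$ only when its maximum reported
  frequency is **strictly** below $\tau$ ("low-frequency" means `< 5%`,
  and `< 1%` for the exome-wide scenarios);
* a variant with **no** frequency in any database passes by default — it
  cannot be filtered against; `missing_af = "fail"` is available when a
  conservative run is wanted;
* a reported frequency of exactly 0 is a real value (the variant is known
  but unobserved in that database) and passes any positive threshold.

Filter scenarios mirror the whole-exome sweeps: `a` applies quality gates
only; `b` keeps MAF `< 0.01` variants whose consequence is a coding
change (synonymous or non-synonymous); `c` keeps MAF `< 0.01` variants
with any non-intronic consequence; `group` is the gene-set analysis
filter at MAF `< 0.05`. Survivor sets nest (`b` ⊆ `c` ⊆ `a`), which the
test suite checks on random cohorts.

Consequence terms collapse onto four location classes: `R` (regulatory:
UTRs, up/downstream, promoter/regulatory region, non-coding exon), `SC`
(synonymous coding), `NSC` (non-synonymous coding) and `intronic`;
anything unrecognized maps to `other`. Splice donor/acceptor/region terms
count as `NSC` by default — they alter the protein product even though
the nucleotide sits outside a codon — with `splice_as_nsc = FALSE`
available to reroute them. Which terms count as "regulatory" is a
package convention, not a property of any annotation platform.

## Gene catalog and SLC nomenclature

Four curated groups ship with the package: 17 detoxification / oxidative
stress genes (A), 29 TRP-channel genes (B), and 11 risk + 8 protective
GWAS genes (D). Group C — the solute carrier (SLC) superfamily — is
defined *operationally* rather than by a member list: a symbol belongs to
C when it resolves to one of the 66 SLC families, either as a typical
`SLC<family><subfamily><member>` symbol or through the alias table for
atypically named members (`SLCO→21`, `UCP`/`MTCH→25`, `RHAG`/`RHBG`/
`RHCG→42`, `FLVCR→49`, `XPR1→53`, `MPC→54`, `LETM→55`, `SFXN→56`,
`NIPA→57`, `MAGT→58`, `MFSD2→59`, `MFSD3→60`, `MFSD4`/`MFSD5→61`,
`ANKH→62`, `SPNS→63`, `NPC→65`, `CTNS`/`MPDU1→66`). Two rules guard
against false positives: alias matching is whole-prefix with a
digit/letter boundary (so `CAT` and `MFSD20` never match), and the
`TMEM → 64` mapping applies only to an explicit member list (`TMEM165`),
because TMEM is otherwise a huge unrelated symbol space. The published
alias prose maps four MFSD prefixes onto three families ("MFSD2 to
MFSD5, SLC59 to SLC61 respectively"); the catalog records the only
consistent completion — `MFSD4` and `MFSD5` both to 61 — rather than
inventing a fourth family. The restricted list C comprises the 12
families tied to neurotransmitter synthesis, release and clearance
({1, 4, 5, 6, 7, 8, 10, 16, 17, 18, 22, 38}); membership in it is
decided by family number, so it is always a subset of C. A symbol may
sit in several groups (`SLC25A38` is both an SLC gene and a GWAS risk
gene) and is counted independently in each group's table.

```{r}
parse_slc_family(c("SLC6A1", "SLCO1A2", "MTCH2", "TRPM2"))
assign_groups("SLC25A38")
```

## Zygosity and the hemizygote policy

Calls are one of `hom_ref`, `het`, `hom_alt`, `hemi_ref`, `hemi_alt`,
`missing`; phase separators are ignored and multi-allelic records are
split into biallelic variants with the genotype recoded per alternate
allele. Hemizygous-alternate calls (X-chromosome variants in males) count
as **homozygous** in burden tables by default: a single-copy variant is
functionally equivalent to two-copy dosage, and the X-linked genes on the
catalog (`SLC6A14`, `SLC9A7`) make the policy consequential. Set
`hemi_as_hom = FALSE` in `filter_config()` to count them with the
heterozygotes instead. Carrier counting for the shared-variant report is
presence-based and unaffected by the policy.

## The synthetic cohort generator

Real cohort data for a study like this is protected, so the package
ships a generator that reproduces the *statistical structure* the
analysis assumes, not any real genome:

* **Cohort layout.** Six cases and five controls by default, with the
  study's sex composition (5F + 1M cases, 2F + 3M controls) and age
  ranges (52–70 and 48–68).
* **Background variation.** Per individual and gene pool, a
  Poisson-distributed number of rare heterozygous singleton variants.
  Default per-individual rates come from the control-arm column totals of
  the group analyses — A: 3.0, B: 7.6, C: 48, D: 4.8 — with an
  exome-wide remainder of 40 (a free parameter: no per-individual
  exome-wide distribution is published to calibrate it against, and the
  simulated "exome" is deliberately three orders of magnitude smaller
  than a real one so the whole pipeline runs in milliseconds).
* **Planted signal.** Cases receive homozygous rare variants in a target
  gene set at a configured mean (default 4/3 per case, vs 0.2 per
  control). The planted count is a *fixed dose* — the integer part of
  the rate to every individual, the fractional part as a Bernoulli
  extra — not Poisson. This is the designed structure of the signal the
  analysis is meant to detect: at rate 4/3 every case carries at least
  one planted variant and a third carry two, exactly the observed
  pattern, whereas Poisson planting would leave roughly a quarter of
  cases carrier-free and make the imbalance undetectable in half of the
  replicates of a cohort this small. The configured mean is recovered in
  expectation either way, which the test suite verifies over 500 seeded
  replicates.
* **Frequencies.** True MAFs are uniform on `maf_range`
  (default (0.0005, 0.049]); each variant reports 1–6 database values,
  the true MAF jittered by up to ±20 % relative and kept inside the
  range, or none at all with probability `p_missing_af` (default 0.05)
  to exercise the missing-frequency pass-through. Planted homozygous
  variants cap their true MAF at 0.04 so no jitter can push them over
  the 0.05 filter.
* **X linkage.** Catalog-flagged X-linked genes yield haploid calls in
  males, so hemizygosity handling is always exercised.
* **Determinism.** The generator is a pure function of the
  configuration: identical config and seed give byte-identical VCF and
  sample-sheet files. The caller's RNG state is saved and restored.

What the generator does **not** emulate: linkage disequilibrium,
population structure, variant sharing in the background (every background
variant is a singleton; shared patterns are constructed explicitly with
`plant_signal()`), realistic gene lengths or exome-wide variant volumes,
genotype quality metrics, and real GO annotations (the packaged
annotation table is labelled synthetic and exists to test the machinery,
not to interpret genes). Consequently, passing tests demonstrate that the
pipeline counts, filters and tests correctly under its stated model —
not that the model captures every property of real exomes.

## Numerical choices

* Welch's statistic is computed from the explicit formulas rather than
  delegated, so the degenerate case of two zero-variance arms is defined:
  equal means give $t = 0$, $p = 1$; unequal means a signed infinite
  statistic with $p = 0$, flagged `degenerate`. Against `stats::t.test`
  the implementation agrees to machine precision on non-degenerate input,
  and it collapses to the pooled two-sample $t$ when arms have equal size
  and variance.
* The hypergeometric tail accumulates point masses in log space and is
  checked exhaustively against enumeration for every consistent
  configuration with $N \le 12$.
* The BH adjustment is the exact step-up formula
  $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, capped at 1; the adjusted
  value is used directly as the q-value (no Storey-type null-proportion
  estimation — the cutoff semantics follow the stated adjustment).
* Significance marks follow the usual convention: `*` $p<0.05$,
  `**` $p<0.01$, `***` $p<0.001$.
* Report cells are written at full precision; rounding (integer
  percentages, one-decimal statistics) happens only in rendered
  displays.

Two arithmetic inconsistencies in the published group tables are worth
recording: the TRP-group and SLC-group control means (7.2 and 46.4) do
not equal their own column totals divided by the arm size (38/5 = 7.6,
192/5 = 38.4). The package always computes means as total/n from the
per-individual vectors, and its checks rely only on internally consistent
cells. Likewise the printed whole-exome t statistics are not reproducible
from the printed means and SEMs under either the Welch or the pooled
formula; the scenario machinery is implemented and tested on counts it
can recompute, and those printed values are not asserted anywhere.

## Problem sizes in the test suite

The suite verifies distributional claims by simulation at sizes chosen to
keep the default run around a minute on one core while leaving the checks
sharp: 500 seeded replicates for planted-dose recovery, 200 for the
Poisson goodness-of-fit, null calibration and power checks (the null
rejection rate is required not to exceed 5 % beyond three binomial
standard errors; power at the default effect must exceed 50 % — it is
about 70 %), and 1000 random mini-cohorts for the carrier/burden
grid-scan oracle.

## A worked run

```{r, eval = FALSE}
out <- tempfile()
res <- run_pipeline(out, sim = sim_config(seed = 1),
                    annotation = system.file("extdata",
                                             "synthetic_go_annotation.tsv",
                                             package = "rvburden"))
print(res$burdens$C_hom)
print(res$shared)
```

## Known limitations

Arms of five and six individuals put hard limits on what any statistic
can say: the Welch test on discrete counts at this size is conservative
(observed null rejection ~1–2 % at nominal 5 %), per-gene comparisons are
hopeless, and a single individual moves every mean by 15–20 %. The
package reports exact counts alongside every test so that readers can
weigh the arithmetic themselves, and nothing in it corrects for the
multiplicity of gene groups — the groups are treated as four
pre-registered questions, as in the study design it supports.
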