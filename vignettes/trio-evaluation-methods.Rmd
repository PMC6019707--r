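---
title: "Pedigree-based evaluation of HLA typing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based evaluation of HLA typing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HLAtrio)
```

## The problem

Computational HLA typers are usually benchmarked against curated
gold-standard genotypes, but such panels overlap heavily between studies
and say little about performance on cohorts with a different genetic
background. When whole families are sequenced, Mendelian inheritance
offers a gold-standard-free alternative: in a father--mother--child trio,
each of the child's two alleles at a locus must be present in a different
parent. HLAtrio implements this evaluation strategy — nomenclature
handling, trio consistency, cross-method agreement and population
statistics — together with a synthetic trio simulator, so that every
statistic can be validated on cohorts with known ground truth even when
real family cohorts are access-restricted.

## Allele identifiers and resolution

An HLA allele identifier consists of a gene symbol and up to four numeric
fields separated by colons, e.g. `A*02:01:01:02`, optionally followed by
an expression suffix letter (`N`, `L`, `S`, `C`, `A`, `Q`). The number of
fields sets the *resolution*: 2-digit identifiers name the serological
allele group, 4-digit the distinct protein, 6-digit synonymous coding
variants, and 8-digit non-coding variants. Fields are stored as digit
strings (2--4 characters) because leading zeros are significant and
modern group numbers exceed two digits (e.g. `A*02:101`).

*Allele reduction* truncates an identifier to a coarser resolution by
dropping trailing fields (and the suffix): `A*02:01:01:02` reduces to
`A*02:01` at 4 digits. Reduction is idempotent and never pads: an
identifier already at or below the target is returned unchanged. All
comparisons in the package operate at an explicit working resolution
after reduction; expression suffixes are ignored by default (a strict
flag exists) since they do not affect typing comparisons.

Two text dialects are supported: the standard colon dialect (optionally
prefixed `HLA-`) and the underscore dialect used in Polysolver winners
files (`hla_a_02_01_01_02`). G- and P-group ambiguity identifiers are
rejected with an error rather than silently truncated, because their
semantics (sets of alleles) differ from single-allele identifiers.

## Descent Accuracy

For a child genotype $\{c_1, c_2\}$ and parental genotypes $M$ and $F$ at
one locus, the number of *explained* child alleles $N_{eq}$ is the
maximum, over assignments of the two child alleles to the two distinct
parents, of the count of child alleles equal (at the working resolution)
to an allele of their assigned parent. The Descent Accuracy of a method is

$$DA = \frac{N_{eq}}{N_{children} \times 2 \times |loci|}.$$

Design choices worth recording:

* **One allele per parent.** A child inherits one allele from each
  progenitor, so the two child alleles must be explained by *different*
  parents; a homozygous child is fully explained only when both parents
  carry the allele. The laxer "present in either parent" rule is
  available behind `requireDistinctParents = FALSE` for sensitivity
  analysis.
* **Ambiguity.** Two maximal assignments count as the same configuration
  when they induce the same set of (parent, allele) transmissions; only
  genuinely different maximal configurations (e.g. child `02:01/03:01`
  with a `02:01/03:01` mother) set the `ambiguous` flag. Ties are broken
  by a fixed canonical enumeration order.
* **Exclusions are per locus and never silent.** A complete family
  missing one member's call at one locus is dropped from that locus only;
  the report lists every exclusion. With complete data the denominator
  identity $N_{alleles} = N_{children} \times 2 \times |loci|$ holds
  exactly.

Because reduction can only merge alleles, a match at 8 digits is also a
match at 4, so DA at a coarser resolution is never smaller — the
qualitative behaviour expected when comparing a full-resolution typer
with its reduced calls.

## Method Agreement and the transmitted/non-transmitted split

Method Agreement between two typers is the fraction of identically typed
alleles,

$$MA = \frac{N_{agree}}{N_{population} \times 2 \times |loci|},$$

where per sample and locus the agreement is the size of the *multiset*
intersection of the two unordered pairs after reduction — a homozygous
call against a heterozygous call sharing one allele contributes 1, not 2.
Only individuals typed at every locus by both methods enter the
denominator (excluded samples are listed), so the identity above is
exact.

MA is split by transmission status: child alleles are inherited by
definition and count as transmitted; parental slots are classified by
mapping the maximal trio assignment back onto the parent's two allele
slots (a homozygous parent transmits slot 1 by tie-break, flagged).
Parents at ambiguous or inconsistent loci are unresolved, and unresolved
slots are excluded from both MA_T and MA_NT numerators *and*
denominators, with their count reported — the denominators of the split
are not fixed by the defining ratio, and this restriction keeps
MA_T = MA_NT = MA = 1 exactly when both methods agree everywhere. Phase
is computed under a single configurable reference method (default: the
first method) because two methods may phase a family differently.

## Population statistics

Homozygosity rate per locus is $HR = N_{H\ell} / N_{population}$,
computed on parents by default: parental genotypes are unconstrained
draws from the population, whereas a child's alleles are a subset of its
parents'. Homozygosity is evaluated *after* reduction, so an 8-digit
heterozygote whose alleles share a protein is homozygous at 4 digits —
HR can only rise as resolution coarsens. The overall HR pools counts
across loci; the unweighted per-locus mean is reported alongside, since
either convention is defensible.

Allele frequencies use direct counting: each occurrence counts once
(homozygotes twice) over $2N$ chromosomes, so per-locus frequencies sum
to 1 exactly. Top-$k$ ranking breaks exact ties lexicographically on the
canonical allele string, making reports deterministic. Reference
comparison matches alleles at 4-digit resolution and marks absences with
an explicit `NA`. CWD classification labels an observed allele
common/well-documented when its 4-digit reduction is catalogued; the
frequency-threshold definition (frequency > 0.001 in a reference
population of at least 1500 individuals) is applied only when *building*
a catalogue from reference tables, since published catalogues are
consumed as-is.

## The synthetic cohort simulator

The simulator generates what the analysis assumes and nothing more:

* **Founders** are drawn i.i.d. per locus from a configured frequency
  vector (Hardy--Weinberg equilibrium), so parental homozygosity has the
  closed-form expectation $\sum_i p_i^2$ and direct counting is unbiased.
* **Transmission** gives each child one uniformly chosen allele from each
  parent, making truth cohorts Mendelian-consistent by construction
  (DA = 1 at every resolution).
* **Typer errors** mirror the failure modes reported for real typers:
  homozygote inflation (a heterozygous call collapsed onto one of its
  alleles with probability $\eta$), then per-slot miscalls with
  probability $\varepsilon$, of which a fraction $\sigma$ stay within
  the 2-digit serotype group (falling back to any other pool allele when
  the group offers no alternative), then truncation to the method's
  output resolution. The order (inflation before miscalls) is fixed and
  documented. The defaults $\varepsilon = 0.05$, $\sigma = 0.5$,
  $\eta = 0.02$ are illustrative: no quantitative error rates are
  established for real typers, so these are chosen once as plausible
  magnitudes and are not calibrated to any benchmark outcome.
* **Novel replacements** (`replacement = "novel"`) substitute
  identifiers outside the pool, so a miscalled child allele can never be
  explained by inheritance; with children-only miscalls at rate
  $\varepsilon$ the expected DA is exactly $1 - \varepsilon$, which makes
  DA recovery testable as a binomial quantity.

The default pool holds 12 eight-digit alleles per locus — two 4-digit
proteins per 2-digit serotype group, so serotype-preserving replacements
always exist and differ at 4 digits — with frequencies from a symmetric
Dirichlet(1) draw; the default cohort size of 50 families matches the
scale of published trio cohorts. Determinism is per-call: every random
decision is seeded by a hash of (seed, stream, sample, locus), so
identical configurations reproduce byte-identical files regardless of
iteration order.

What the simulator does **not** emulate: linkage disequilibrium between
loci (independence is assumed), read-level artefacts, database
incompleteness, and method biases correlated within a family. Passing
tests therefore demonstrate the correctness of the statistics and the
qualitative response to the modelled error processes — not the accuracy
of any real typer on real data, where family-correlated biases can
inflate DA without improving agreement between methods.

One bookkeeping subtlety: a serotype-preserving 8-digit miscall can be
invisible after reduction to a 4-digit output. Provenance therefore
records every operator that fired together with a `changed_call` flag;
every observed call that differs from the reduced truth is guaranteed to
have provenance.

## Numerical and scale choices

Frequency-vector validation uses a 1e-8 tolerance on the sum; per-locus
frequency sums are exact to 1e-9 by construction. Statistical checks in
the test suite use 3-standard-error bands around closed-form
expectations (binomial for DA, HR and miscall counts), with cohort sizes
chosen so that expected effects exceed the bands comfortably: 500
families (3,000 child alleles) for DA recovery, 1,000 parents for
Hardy--Weinberg and frequency recovery, 50-replicate means of 30-family
cohorts for the monotone response of MA to the miscall rate, and 100
random 12-family cohorts for resolution monotonicity, which is a
deterministic property and must hold in every single case.

## Limitations

* The toolkit evaluates *consistency*, not correctness: a typer that is
  systematically wrong in the same way across a family scores a perfect
  DA. MA between independent methods is the designed counterweight.
* The transmitted/non-transmitted split depends on the phase reference
  method and excludes unresolved slots, so MA_T/MA_NT denominators vary
  with the cohort's ambiguity structure; the reports expose all counts.
* G/P ambiguity groups and database lookups are out of scope; identifiers
  are treated as opaque structured names.
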