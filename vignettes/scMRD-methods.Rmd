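---
title: "Single-cell-guided MRD target selection and monitoring: models and methods"
author: "scMRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell-guided MRD target selection and monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMRD)
```

# The problem

Roughly half of acute myeloid leukemia (AML) patients lack a validated
molecular marker for measurable residual disease (MRD) monitoring,
because their mutations sit in genes also mutated in clonal
hematopoiesis (CH) or myelodysplasia: tracking such a variant in bulk
material risks tracing a premalignant clone rather than the leukemia.
Single-cell DNA + surface-protein multi-omics resolves the subclonal
architecture — which variants co-occur in which cells, with which
immunophenotypes — and thereby lets one pick variants that belong only
to the leukemic compartment. scMRD implements that workflow end to end:
germline-SNP demultiplexing of multiplexed runs, genotype QC, clonal
reconstruction with loss-of-heterozygosity (LOH) detection, centered
log-ratio (CLR) immunophenotyping, a five-criterion target-selection
engine, and the downstream monitoring machinery (ddPCR positivity and
relapse rules, an error-corrected NGS caller). A fully labeled
synthetic-cohort generator stands in for patient data, which for this
application cannot be public.

# Data model

The central container, `CellGenotypeMatrix`, extends
`SingleCellExperiment`: rows are panel loci (germline SNPs used for
demultiplexing plus candidate somatic variants), columns are cell
barcodes, and four assays hold the per-entry genotype code (0 WT / 1 HET
/ 2 HOM / `NA` missing), read depth, genotype quality and cell-level
allele fraction. Antibody-tag counts live in `altExp(x, "antibody")`.
Downstream results use dedicated S4 classes (`CloneSet`, `CloneGraph`,
`MrdSeries`, `MrdCall`, `EcngsBackground`) with validity checks.

# Demultiplexing model

Patients are multiplexed into one run and separated afterwards by their
germline SNPs. `buildProfileDatabase()` stores one expected
alt-allele-dosage vector per patient and one per unordered pair (the
doublet profile: the mean of the two dosages, so a het + hom pair
expects 1.5). Scoring uses a per-locus categorical observation model
with a symmetric genotyping-error rate $\varepsilon$ (default 0.01):
an observed genotype matching the expected dosage has probability
$1-\varepsilon$; for half-integer doublet dosages the two adjacent
genotypes share $1-\varepsilon$; everything else absorbs the error
mass. Missing loci contribute nothing. The published pipeline names
only "a likelihood-based method"; this per-locus error model is the
minimal faithful choice and is config-exposed.

Cell removal follows the published thresholds: genotyped in under 30%
of database SNPs, 10 or more genotype discrepancies against the best
patient, or a discrepancy fraction of 30% or more. The source text is
grammatically ambiguous about whether these rules conjoin; the stricter
OR reading (any violation removes) is the default, and
`demux$rule_combine = "and"` selects the other reading. Likelihood ties
are removed as "ambiguous" — conservative, in keeping with the
removal-heavy QC stance of the original pipeline. Doublet-profile
matches are removed as doublets; note that doublet *sensitivity* is
bounded by the number of opposite-homozygote loci between the two
patients, so some doublets of genetically similar patients are
unavoidably retained under some patient's label. The acceptance
property is therefore framed on retained true singlets, which the
likelihood model assigns essentially perfectly given ~50 SNPs.

# Genotype and variant filtering

A cell-level call requires depth ≥ 10 and genotype quality ≥ 30
(otherwise missing); a covered cell is mutated when its allele fraction
reaches 35% (homozygous at 90%, a boundary the source never defines and
which is config-exposed). The 35% threshold is read as a *cell-level*
gate — a pseudobulk reading would contradict remission VAFs far below
1% — and `filter$min_cell_af` exposes it.

Variant-level filters then run as independent predicates, every
decision recorded: mutated in ≥ 3 cells; not synonymous; not
homopolymer-adjacent (a precomputed annotation flag, not recomputed
from a reference); no second variant within 300 bp (both members of an
offending pair are removed — the source does not say which member, so
the symmetric choice is made — unless the pair co-occurs); mutated in
≥ 6 cells unless co-occurring; at least one homozygous cell (allelic
dropout guarantees apparent homozygotes for any real variant, so their
absence flags an artifact); and not germline (gnomAD-style population
allele frequency ≥ 0.1% or a user germline flag). "Co-occurring" is
operationalized as pairs mutated together in ≥ 3 cells plus any
user-declared pairs. Because the filters are independent predicates,
the surviving set is order-invariant; the proximity filter is pairwise
but symmetric, preserving the invariance.

The zygosity-aware pseudobulk VAF is
$100\,(n_{HET} + 2 n_{HOM}) / (2 n_{informative})$ over cells passing
the quality gates. Panel uniformity is the fraction of amplicons with
mean coverage at least 0.2× the panel mean (the standard vendor
definition; the source uses the number without defining it); runs under
80% raise a force-call advisory, and `forceCall()` bypasses the
variant-level cascade (never the cell-level gates) for variants known
from bulk sequencing.

# Clonal reconstruction

Cells with complete genotype vectors over the surviving variants are
grouped by identical genotype. Two mechanisms separate real subclones
from allelic-dropout (ADO) artifacts, since the published pipeline does
not describe its clustering:

* a group differing from a larger clone only by HET→HOM is an ADO
  artifact when its share of the combined population is below
  `clones$ado_hom_threshold` (default 0.3) — above it, it is treated as
  a genuine ref-loss LOH subclone. The threshold is exposed and tested
  in both directions because a real LOH subclone must *not* be
  absorbed;
* a group reachable from accepted clones by HET→WT/HOM drops is
  absorbed when its size is within `clones$artifact_fold` (3×) of the
  dropout inflow expected under `clones$assumed_ado` (default 0.05 per
  allele).

Remaining groups of ≥ `min_clone_size` cells (default 6, echoing the
6-cell variant filter) become clones. Every cell is then assigned by
maximum posterior under a per-allele ADO observation model with
clone-size priors (HET observes HET with $(1-a)^2$, apparent HOM or WT
with $a(1-a)$ each; WT and HOM cannot gain or lose the alternate
allele). Cells with missing entries are assigned only when consistent
with exactly one clone at their observed loci. The fully wildtype
population is reported separately and never counted as a subclone.

The clone graph orders clones by developmental precedence: the parent
of C is the clone whose mutated set is the maximal LOH-aware proper
subset of C's. A parent HET site may be wildtype (alt lost) or
homozygous (ref lost) in the child; when two clones could each descend
from the other, the direction needing fewer LOH events wins (gains are
free), and an LOH-mediated edge additionally requires at least one
shared mutated variant — a clone sharing no mutation is an independent
branch, not an ancestor whose every mutation was lost. Ambiguous
maximal parentage records all candidate edges and flags the graph
non-tree. `detectLOH()` reports HET→WT as loss of the alternate allele
and HET→HOM as loss of the reference allele.

# Immunophenotyping

Antibody counts are CLR-transformed per cell
($CLR_i = \log(c_i + 1) - \overline{\log(c + 1)}$; pseudocount 1, the
source being silent). A clone's immunophenotype is its per-marker mean
CLR; marker positivity is mean CLR ≥ a configurable cutoff (default
1.0, chosen so that the generator's high/low mean counts separate
cleanly; real data should calibrate per panel). Clone-level calls are
means, so a minority subpopulation does not flip them — consistent with
the observed within-clone heterogeneity of CD34/CD117 expression.

Aberrancy follows a different-from-normal (DfN) approach integrated
with diagnostic LAIP rules: immature means CD34+ and/or CD117+;
aberrant fires on cross-lineage marker positivity (CD3/CD7/CD19/CD56
defaults), on any declarative LAIP rule (required-positive /
required-negative marker lists), or on any marker mean outside the DfN
reference range, which the pipeline derives from the run's own
wildtype cells (2.5–97.5% quantiles). All gates are configuration: the
source gives no numeric definition of "distinct, immature, aberrant",
so recovery tests rely on generator-known truth rather than clinical
gates.

# The five selection criteria

For each candidate variant: (1) diagnosis pseudobulk VAF ≥ 10% — the
clause "present in a large clone (target VAF ≥ 10% across clones)" is
read as the aggregate VAF pooled over clones, since one mutated allele
at the 20% diagnostic blast minimum gives exactly 10%; a
largest-single-clone mode is config-selectable. (2) Remission VAF < 1%;
a variant absent from the remission output but covered by the panel
counts as 0, an uncovered locus is not assessable and the variant is
ineligible with that reason. (3) Every variant-carrying diagnosis clone
is immature and aberrant (strict ALL mode default; ANY mode available
because the published wording admits both). (4) No descendant clone has
lost the variant — wildtype or alt-loss LOH fails; ref-loss LOH to
homozygosity retains the target. (5) The gene is not on the blacklist
of genes reported to disappear at relapse (NRAS/KRAS/FLT3 default,
editable). Eligibility is the strict conjunction. Ranking prefers
ascending user-supplied assay LoD (prioritizing assay sensitivity, as
the study did when two targets qualified) and otherwise descending
diagnosis VAF.

# ddPCR monitoring

The assay limit of detection comes from wildtype-well validation:
$LoD = \bar{x}_{WT} + 3.08\,\sigma_{WT}$ (z = 3.08, one-tailed
α = 0.001), with the sample standard deviation (n−1; unspecified in
the source). When DNA input, not chemistry, limits sensitivity, the
rule of three sets the floor: with zero events among $n$ assessable
allele observations the 95% bound on the rate is ≈ 3/n, so
$RoT = 300/n$ percent; the denominator counts allele observations by
default (`mrd$rot_unit` offers genome equivalents). A sample is MRD
positive when its VAF reaches the LoD, or the larger of LoD and RoT
when DNA-limited; a VAF exactly at threshold is positive (the
positivity clause reads "VAF ≥ LoD"; the negativity clause overlaps at
equality, resolved in favor of positivity with a config flag).

Relapse calling merges tissues chronologically and fires on (a)
conversion — a negative-to-positive transition confirmed by any later
positive sample (no time window, none being specified) — or (b) a
≥ 10-fold VAF rise between consecutive positive samples (consecutive
within the merged series by default; a same-tissue mode exists because
the source does not specify). The first sample indicating relapse
dates it. This reproduces the boundary behaviour of the published
patient 6 series: 0.0029% → 0.0135% against an LoD of 0.00242% is two
positives with a 4.7-fold rise and no conversion — no ELN relapse
despite the rising VAF. Lead times are signed day differences (ddPCR
minus comparator) per method and relapse event, negative meaning
earlier molecular detection.

# Error-corrected NGS caller

The caller is a simplified strand-aware beta-binomial formulation in
the spirit of Shearwater-type deep-sequencing callers: reads either
support the variant or do not (which is what makes insertions and
phased variants tractable), counted per strand. A background
beta-binomial (mean $\mu$, overdispersion $\rho$; $\rho \to 0$ is
binomial) is fitted per site and strand from reference samples by
method of moments, the mean floored at $10^{-6}$ to avoid degenerate
zero-error sites; optional trimming robustifies the mean against
contaminated references while leaving dispersion on the full data. The
"posterior error probability" of an observation is the probability
under the background of counts at least as supportive, evaluated per
strand and combined as the maximum — each strand must independently be
inconsistent with background, suppressing strand-biased artifacts. A
variant is called when this probability is below 1% *and* it has at
least 3 unique alternative observations (UAO; distinct consensus
families, which the generator equates with supporting reads). The
exact formulation of the published modified-Shearwater posterior is
not public; this tail formulation is a declared stand-in, isolated
behind `posteriorError()` so an alternative is swappable, and
validated against brute-force enumeration of the beta-binomial tail
rather than against the original code.

`sensitivityProbe()` reproduces the published sensitivity assay in
silico: holding per-strand totals fixed, it finds by bisection (valid
by monotonicity of the tail in the supporting counts) the minimal
total supporting count at which the caller fires. With a fixed
background *rate*, the absolute minimum grows with depth because
expected error counts grow too; the scientifically meaningful
quantity, the minimal detectable VAF $k_{min}/n$, is non-increasing in
depth and is the property the tests assert.

# The synthetic generator

`simulateMultiplexRun()` emulates the statistical structure the
analysis assumes: shared germline-SNP loci (per-locus allele
frequencies 0.1–0.5, Hardy–Weinberg per patient), per-patient clone
trees with stage-specific fractions (diagnosis vs remission, the
remainder being normal cells), per-allele allelic dropout (a het site
can appear HOM-alt or WT; both alleles dropping gives a missing
entry), independent per-entry missingness, doublets that sum the
allele observations of two component cells before genotype calling,
and negative-binomial antibody counts around per-clone marker means
over a 17-marker AML panel. The default single-patient
target-selection cohort plants exactly the confounders the selection
criteria exist to reject: a leukemia-specific founder variant (cleared
at remission, carried only by immature aberrant clones, homozygous in
a ref-loss LOH subclone), a persistent CH variant in a
normal-phenotype clone, and a passenger lost by alt-loss LOH in the
advanced subclone, plus a subclonal second leukemic variant. The
default multiplex cohort replicates that patient three times with
distinct germline profiles, 5% doublets and 5% ADO.

What the generator does *not* emulate: read-level errors and genotype
quality as derived quantities (GQ is emitted as a constant for covered
entries; the QC gates are exercised through depth and allele
fraction), amplicon dropout correlated across loci, ambient antibody
background and cell-type-specific ADO. Passing recovery tests
therefore demonstrate the pipeline's logic under the stated noise
model, not performance on any real Tapestri run.

Numerical and scale choices: simulations are sized to keep the full
suite a few minutes long (10,000-barcode demultiplex runs; 50 cohorts
of 1,200 + 400 cells for selection recovery; 200 stable trajectories;
10,000 null EC-NGS sites) — large enough for the rates being tested to
be well resolved, small enough to iterate on. ddPCR wells use 10,000
genome copies per well and duplicate wells by default, matching
routine ~200 ng inputs. The EC-NGS generator's default overdispersion
is $\rho = 10^{-5}$: at error rates around $10^{-4}$ a large $\rho$
collapses the beta into a spike-and-tail shape no consensus-read error
profile resembles. All randomness flows from a single integer seed;
identical seeds give identical cohorts.

# Known limitations

Clone discovery is exact-genotype grouping with model-based artifact
absorption, not probabilistic phylogeny inference; very small true
subclones below `min_clone_size`, or subclones distinguished only by a
pattern reachable by dropout from a much larger clone, are absorbed by
design. A clone that lost *all* of an ancestor's mutations by LOH is
indistinguishable from an independent branch and is rooted at
wildtype. Doublet detection depends on opposite-homozygote germline
loci between the multiplexed patients. Immunophenotype gates are
synthetic-calibrated defaults, not clinical gates. The EC-NGS caller
is a tail-probability formulation, not the original Bayes-factor
machinery, and UAO counting assumes one consensus family per
supporting read.
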