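---
title: "Mapping a recessive mutation by cosegregation and pooled sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive mutation by cosegregation and pooled sequencing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmap)
library(dplyr)
```

`fgmap` implements the analysis chain used to identify the causal gene of a
monogenic recessive plant mutant from an F2 cross -- the strategy behind
bulked-segregant "mapping-by-sequencing" studies such as the tomato seedless
(parthenocarpic) mutants. Every stage consumes and produces tidy tables, and
a seeded synthetic-data module generates all inputs, so the entire chain is
validated by parameter recovery: plant a known causal mutation, run the
analysis blind to the truth labels, and check that it comes back.

This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

## The genetic model

An F2 population descends from a cross between a mutagenised line (the
"mutant parent") and a wild-type accession. Each F2 plant receives two
independent F1 gametes; a gamete is a mosaic of mutant-parent and
WT-parent chromosome segments. Recombination follows the **Haldane model**:
crossover counts per chromosome are Poisson with mean equal to the map
length in Morgans, breakpoint positions are uniform, and there is no
interference. This is the standard minimal model and is sufficient for
interval-scale behaviour; interference would only sharpen the already-rare
double crossovers inside candidate intervals.

The genetic map is uniform at **1 cM per 750 kb** (`cm_per_bp`), a
tomato-like average; the source study gives no map, so a constant density
is the neutral choice.

A plant shows the mutant phenotype iff it is homozygous for the
mutant-parent haplotype at the causal position (recessive, fully penetrant).
Phenotype fractions therefore segregate 3:1, which the `segregation` stage
tests with Pearson's chi-square, **without Yates continuity correction** --
the uncorrected statistic is what classical segregation tables report (for
(76, 33) against 3:1 it equals 1.62, for (143, 43) it equals 0.35), and at
F2 sample sizes the uncorrected test is close to nominal (a property test
checks the rejection rate under a true 3:1).

## Cosegregation interval mapping

Mutant-phenotype F2 plants are genotyped on an array panel. A marker
*cosegregates* when every mutant plant is homozygous for the mutant-parent
allele there. The candidate interval is the maximal run of consecutive
cosegregating markers; its flanks are the **first non-cosegregating markers
on each side** (the outer bound). The outer bound is deliberate: it is the
smallest region guaranteed to contain the causal locus, and it is how
flanking markers are conventionally reported. Ties between equally long
runs break by physical span, then by position.

Two rules handle imperfect data:

* **missing calls are ignored** (uninformative), never imputed;
* a **heterozygous call in a mutant plant breaks cosegregation** at that
  marker and the plant is listed in a per-individual diagnostic attribute,
  because a heterozygous mutant usually means a phenotyping or genotyping
  error that the analyst should see, not silently absorb.

`narrow_interval()` refines the interval with an extra marker genotyped
inside it. A single failing marker cannot by itself reveal which side of
the causal locus it is on -- that information lives in which flank each
recombinant haplotype extends from. The default `side = "auto"` replaces
the **nearer flank**, which is the usual situation when markers are chosen
to split the longer arm of a region, and reproduces the published
tomInf4732 narrowing; `side = "left"`/`"right"` overrides it when the
recombinants have been inspected.

Gene content uses closed-interval, any-overlap counting, so a gene abutting
a flank is included and the causal gene can never be lost to a boundary
convention.

## SNP/Indel-index mapping on the pooled bulk

Twenty mutant-phenotype plants (equal DNA amounts) are pooled and
sequenced. For each variant the **SNP/Indel index** is the fraction of
reads carrying the mutant allele. At the causal locus every pooled
haplotype is mutant, so the index is ~1; at unlinked loci the selected bulk
still segregates and the index fluctuates around 0.5.

The read model: depth per variant is Poisson(`depth_mean`, default 30);
mutant-read counts are binomial with success probability
$f(1-e) + (1-f)e$, where $f$ is the bulk allele frequency and $e$ the
per-read allele-flip error (default 0.5%). The symmetric flip is the
simplest error model that makes the depth filter meaningful.

Three filters follow, each tallied separately: depth >= 10 ("reliable read
numbers"), index >= `min_index`, and position inside the candidate
interval. The published analysis states only a "high" index cutoff;
**0.9 is the default** because at the depth floor of 10 a bulk that is
truly homozygous still passes with one erroneous read (9/10), while
heterozygous regions (expected index 0.5) essentially never do. The
threshold is exposed.

**Intra-cultivar subtraction.** Cultivars that are not fully inbred carry
variants segregating among wild-type individuals, and reference-genome
mismatches behave the same way; both appear as high-index variants
genome-wide. They are removed by exact identity --
(chromosome, position, ref, alt) after left-anchoring -- against a
background set from WT resequencing. Position-only near-matches are kept
with a warning so that distinct overlapping indels are never silently
discarded. Exact-match subtraction is idempotent by construction.

Variants are assigned to genes only through **CDS overlap** (the
coding-region rule of the original analysis); intronic and intergenic
variants drop out of the candidate list.

## Variant effect and truncation calls

Gene models use 1-based inclusive coordinates (GFF3), and the **CDS
excludes the stop codon** -- under this convention a 2871-bp CDS encodes
exactly 957 amino acids. Files in the wild differ on this point, so the
convention is stated prominently wherever it matters.

Effects are called by re-translation rather than by rule tables: the
variant is applied to the sequence, the gene model is lifted across the
edit, and the mutated CDS is re-translated. Coding SNPs are
synonymous/missense/nonsense by protein comparison. Indels with net length
change divisible by 3 are in-frame (checked for premature stops against
the *shifted* expected length); all other coding indels are frameshifts.
For truncating calls the first stop codon of the mutated frame is reported
as a **1-based codon position in the mutated reading frame**, and the
truncated protein length is that position minus one -- a stop at codon 494
means a 493-residue product. Translation **scans past the annotated CDS
end into the downstream transcript** when the shift removes the native
stop; if no stop appears at or before the wild-type length the call is a
stop-lost extension, not a truncation. User-supplied protein domains are
reported as lost when they lie entirely beyond the truncation point (a
493-residue truncation loses a transmembrane span at 505-524); the module
reports domain loss but never predicts domains.

One known simplification: an indel whose reference span crosses an
exon-intron boundary is labelled by its net genomic length change, although
the spliced CDS may lose a different number of bases. The reported stop
position and truncated length still come from actual re-translation, so
they are correct; only the in-frame/frameshift label can be simplistic in
this rare case. Splice-site effect prediction is out of scope.

The worked construction behind `truncation_example()` is deterministic: a
CDS of ATG followed by GCT repeats, a TAA written at the frame-shifted
position of the target codon, and a 2-bp deletion of CDS bases 4-5. In the
shifted frame the gene reads TGC (Cys) until the planted stop, while the
wild-type frame stays stop-free, which realises the published
957/494/493-aa contract exactly and is verified against an independent
full-re-translation oracle in the test suite.

## RNA-seq differential expression

Expression is quantified as **RPKM** (count / (gene length in kb x library
size in millions)), genes are *expressed* when mean RPKM >= 1 in **at
least one group** (the source protocol does not state the group rule;
either-group keeps genes switched on only in the mutant testable), and
per-gene two-sample t-tests run on log2(RPKM + 1) -- the transformation and
pseudocount are unstated upstream, so the most common choice is used and
both are parameters.

Two decisions deserve emphasis:

* **Pooled-variance (Student) t rather than Welch.** With three replicates
  per group, Welch's Satterthwaite df collapses toward 2 whenever the
  sample variances differ, and a t statistic of 20 at df 2 still has
  p ~ 2.5e-3 -- after multiplicity adjustment across thousands of genes
  nothing passes, not even a 16-fold change. The pooled test keeps df = 4
  and restores the intended power; `test = "welch"` remains available.
* **Benjamini-Hochberg q values.** The upstream description mixes
  "Bonferroni" with "false discovery rate"; the two are incompatible, and
  the reported use of q values indicates FDR. BH is the default and
  Bonferroni an option.

Calls are up/down at |log2 fold change| >= 1 and q < 0.05, computed on the
ratio of group mean RPKM (pseudocount-stabilised). The expressed filter is
applied **before** testing, so the adjustment runs over expressed genes
only. `overlap_with_list()` compares the calls with an external
direction-annotated list (e.g. hormone-responsive genes) by set
intersection.

## What the synthetic-data generator emulates -- and what it does not

Defaults mirror the study conditions: F2 of 186 (109 for the second
cross), bulk of 20, depth 30x, 7600 array markers of which 1956 are
informative, three RNA-seq replicates per group, 25 planted DE genes (13
up, one of them >10-fold; 12 down), and a gene density of 1.03e-4 per bp
(267 genes per 2.6 Mbp).

Values the study does not state were fixed once, as follows:

* **Genome: 3 chromosomes x 8 Mb.** Cosegregation interval sizes are set
  by breakpoint density per bp -- about one per 451 kb of flank with 43
  mutant plants at 1 cM/750 kb -- not by genome size, so a scaled genome
  with study-scale marker counts and map density reproduces few-Mbp
  intervals while keeping a full simulated study cheap enough to repeat
  across many seeds (the recovery experiment runs 50 studies; the DE
  calibration 100).
* **Mutagen density 3e-6 per bp**, ~10% of it small indels: the scale of
  gamma-ray mutagenesis reported for irradiated tomato lines (hundreds to
  a few thousand variants genome-wide). The much higher within-interval
  variant counts printed in mapping studies include cultivar-vs-reference
  differences, which here belong to the subtracted class.
* **Intra-cultivar rate 5e-5 per bp** with per-variant carrier frequency
  U(0.5, 1): Micro-Tom-like cultivars are not fully inbred, and the upper
  end of that range emulates near-fixed differences from the reference
  genome -- exactly the variants that make background subtraction
  indispensable, since they pass every index filter.
* **RNA-seq dispersion 0.005** (replicate CV ~7%): each replicate pools
  15-17 ovaries, which averages single-organ biological noise down to a
  few percent; planted genes draw baseline means >= 100 so that the
  Poisson term does not dominate.
* **Sequencing error 0.5%**, Illumina scale.

The generator does **not** emulate: read-level artefacts (no FASTQ,
alignment, or base-quality model), crossover interference, segregation
distortion, DNA-quantity variation between pooled plants (the protocol
equalised DNA amounts), the mutation spectrum of gamma irradiation (variant
positions are uniform), or count-level DE structure beyond the negative
binomial. Passing recovery tests therefore demonstrate that the analysis
logic is sound under the stated statistical model -- they do not certify
performance on real sequencing artefacts, which enter upstream of this
package's inputs.

## Candidate ranking and confirmation

Surviving candidates are ranked by effect severity (frameshift, nonsense,
and stop-lost extension first, then missense, then the rest), then by an
independent-cohort cosegregation check that emulates the follow-up linkage
populations: 83 mutant-phenotype and 80 WT plants are simulated fresh, and
a candidate *cosegregates* when every mutant is homozygous for it and no
WT plant is; candidates are ordered by discordant-plant count, then by
SNP index and depth. Expression-weighted ranking was considered (the
original prioritisation also used expression) but kept out of the default:
the DE stage measures a different tissue contrast and would entangle two
evidence types; the run object retains both so users can re-rank.

A candidate tightly linked to the causal gene (within ~100 kb) can pass
every one of these filters -- exactly as in real studies, where the final
discrimination required transgenic validation. This is why end-to-end
recovery is asserted as a rate across seeded replicates (>= 90% top-ranked)
rather than per-run certainty.

## Numerical and degenerate-input choices

* Zero-depth pooled records are flagged `defined = FALSE` with `NA` index;
  no division by zero ever occurs.
* Zero library size in RPKM is an input error; an all-zero gene in a
  nonzero library has RPKM 0.
* Genes with zero within-group variance in both groups get `NA` p values
  and a `zero_variance` note, never a fabricated call.
* Interval ties break deterministically (marker count, span, position), so
  fixed seeds give byte-identical run reports.
* All simulators draw from R's global RNG; `run_pipeline(config, seed)`
  seeds once at entry, which makes every stage reproducible as a unit.

## Limitations

Beyond the generator's non-goals above: the cosegregation scan assumes a
single causal locus (no heterogeneity), the confirmation cohort simulates
F2-like segregation rather than true backcross pedigrees, left-anchoring
is assumed rather than enforced by a full left-alignment normaliser, and
the DE stage is a t-test on transformed RPKM, not a count-model GLM --
deliberate, because it mirrors the published protocol it reproduces.
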