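---
title: "isotrx: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isotrx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`isotrx` implements the analytical core of a long-read (Iso-Seq-style)
tumour transcriptome study: structural classification of full-length
transcript models against a reference annotation, an artifact-filter
cascade, differential transcript/gene expression with the
transcript-versus-gene overlap decomposition, tumour- and
metastasis-specific transcript (SRT) calling, isoform-switch detection, and
a random-forest panel-evaluation harness. Raw-read processing (CCS
generation, demultiplexing, clustering, alignment, quantification) is
upstream of this package and out of scope: inputs are transcript models
(GTF), a genome (FASTA), short-read junction-support tables (TSV) and TPM
matrices with sample-group labels.

# Structural classification

Every query transcript is reduced to its **junction chain** — the ordered
list of intron intervals — and compared with the reference by exact
coordinate matching (0-based half-open internally; GTF conversion happens
only at I/O boundaries). Multi-exon categories, evaluated in order:

1. **FSM** (full-splice match): the chain equals a reference transcript's
   chain on the same sequence and strand. Terminal exon *ends* are ignored
   entirely: the FSM/ISM split is junction-based and end variation is the
   filter cascade's concern.
2. **ISM** (incomplete-splice match): the chain is a *contiguous* window of
   some reference chain. Non-contiguous subsets (exon skipping) are novel
   combinations, not incomplete observations, and fall through to NIC/NNC.
3. **NIC** (novel in catalogue): every splice site is catalogued on that
   sequence and strand, but the combination is not.
4. **NNC** (novel not in catalogue): at least one uncatalogued splice site,
   with same-strand gene overlap.
5. **antisense**: opposite-strand gene overlap only.
6. **intergenic**: no gene overlap.

Splice-site matching is exact (0 bp tolerance): no wobble window is part of
the category definitions, exactness keeps the brute-force test oracle
trivial, and the bundled generator places novel sites at least 10 bp from
every catalogued site so no tolerance choice could change a label.

Mono-exon queries have no junctions, so chain logic cannot apply. The rules
used here mirror the common structural-category convention: exact interval
equality with a mono-exon reference transcript is FSM; containment within a
same-strand reference exon is ISM; other same-strand gene-span overlap
(at least 1 bp) is `other_genic`; otherwise antisense or intergenic.
Same-strand evidence takes precedence over antisense overlap wherever both
exist; this resolution is a design choice, as is reporting the best
opposite-strand gene on antisense calls. Gene assignment prefers the
same-strand gene sharing the most junctions, breaking ties by exonic
overlap and then lexicographic gene id, which makes every call
deterministic.

# Filter cascade

Order: classification → junction support → intrapriming → ISM 3'-end →
cross-sample merge → replicate filter. Per-sample evidence filters run
before merging so occurrence counts reflect surviving observations.

* **Junction support**: every junction of a multi-exon transcript must have
  pooled short-read support of at least `min_junction_reads` (default 1 —
  "observed at all"; the rule itself sets no count threshold, so the
  default is the weakest reading and the knob is exposed). Mono-exon
  transcripts pass vacuously.
* **Intrapriming**: oligo-dT can prime on genomic adenine tracts, creating
  false 3' ends. Non-FSM transcripts fail when the 20 bp genomically
  downstream of the TTS contain ≥ 16 adenines on the transcript strand
  (minus-strand windows are read reverse-complemented, so genomic T counts).
  FSM transcripts are exempt. Windows truncated by a sequence end are
  counted as-is and flagged.
* **ISM 3'-end**: ISMs whose missing region is at the 3' end only are
  dropped by default — the canonical RNA-degradation artifact. Several readings
  of "end incompleteness" are defensible; dropping the 3'-truncated class
  is the one adopted here, controlled by `filter_ism_ends`.
* **Merge**: multi-exon transcripts merge on exact chain identity with
  outermost observed ends (the longest-transcript convention of
  chain-collapse tools); mono-exon transcripts merge by single linkage at
  ≥ 50% reciprocal overlap.
* **Replicates**: merged transcripts must occur in ≥ 2 distinct samples.

All thresholds are monotone: tightening any of them can only shrink the
pass set, a property the test suite asserts over randomized datasets.

# Differential expression, SRTs, switches

Two-group comparisons use the unpaired Wilcoxon rank-sum test (exact for
small samples without ties, normal approximation with tie and continuity
correction otherwise) with Benjamini–Hochberg correction across all
features tested at that level; significance is |log2FC| > 1 and FDR < 0.05.
The unpaired test is the default even for paired tissue designs (the
weaker assumption); a paired flag is provided. Fold changes use
group means with pseudocount ε = 0.01 (means-vs-medians and the pseudocount
are unstated in the source; means are the common convention and ε keeps
zero-expression features finite); the choice of means and of ε = 0.01 is
the package's own. Gene expression is the sum of member
transcript TPM; ISM transcripts are removed before testing when
classification is available, since degradation artifacts would distort
isoform-level statistics. The overlap decomposition marks a gene
DET-positive when any member transcript is significant and partitions genes
into transcript-only / gene-only / shared signal.

Tumour SRT criteria are implemented with their operators taken
literally: (i) median tumour
TPM **at least** 10× the **maximum** TPM across all normals — inclusive
`≥`, with a `median > 0` guard so the degenerate all-zero case (10 × 0 = 0)
is never called; (ii) TPM > 0.5 in **more than** 5% of tumour samples
(strict `>`). Metastasis-specific transcripts use a median-ratio fold
change with pseudocount, strict `> 10`, and the same prevalence
criterion, kept for symmetry across the two callers and the
optional "barely expressed in normals" criterion is off by default.

A gene switches when at least one transcript is significantly up and
another significantly down in the same comparison — the DET thresholds
verbatim, with no additional switch statistic and no major-isoform
dominance requirement (dominance is deliberately not required). The isoform-fraction matrix
(transcript TPM / gene TPM, undefined where the gene is silent) is exported
as the concrete reading of a "switch ratio"; clustering it is out of scope.

# Panel evaluation

`evaluate_panel()` follows the standard biomarker-evaluation protocol: a
stratified
4:1 train/test split, 5-fold cross-validation on the training set, a
random forest (500 trees) on log2(TPM + 1) features, and AUC by the
rank-statistic (Mann–Whitney) formulation, which equals trapezoidal
integration of the ROC step curve; ties count one half. The classifier is
specified behaviourally — any bagged-tree ensemble satisfies the contract —
and the `randomForest` package provides it. A fixed seed pins split
membership, fold assignment and ensemble output exactly.

# The synthetic cohort generator

`simulate_dataset()` emits a complete toy study from one seed: a random
ACGT genome (2 × 500 kb), a 24-gene annotation with 2–3 transcripts per
gene built from shared exon slots, ~200 query transcripts constructed *per
intended category* (FSM with jittered ends, 5'- and 3'-truncated ISMs, NIC
recombinations, NNC with a site shifted ≥ 10 bp from any catalogued site,
antisense copies, intergenic models ≥ 10 kb from any gene), planted
adenine tracts downstream of selected TTSs, junction-support tables,
and log-normal TPM cohorts (baseline meanlog 3, sdlog 1; multiplicative
noise sdlog 0.4) for tumour/normal (10/10) and metastasis/primary (6/6)
arms. Planted SRTs draw tumour values from baseline × 50 with normals
uniform on [0, 0.05], making criterion (i) satisfiable by construction;
planted switch genes carry a reciprocal 4× pair with the gene sum conserved
exactly in expectation. Those cohort sizes and effect levels are the
package's fixed study conditions, chosen to mirror a paired-cohort design
at desk scale.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: sequencing error and truncation noise on
splice sites (real data needs junction-wobble handling upstream), batch
effects, library-size and GC biases, correlated expression between
isoforms, realistic intron/exon length distributions, and paired-sample
correlation. Recovery rates of 1.0 on planted effects are a correctness
check of the implementations under their own assumptions, not a
performance claim.

# Numerical and engineering choices

* Internal coordinates are 0-based half-open everywhere; GTF converts at
  the boundary. Junction identity is the intron interval; exon ends never
  participate.
* Unknown (`.`) strand on a query transcript is rejected rather than
  guessed — classification is strand-dependent. Unstranded junction-support
  rows match either strand.
* GTF parsing uses `rtracklayer`; writing uses a minimal deterministic
  formatter so that identically configured runs produce byte-identical
  artifacts (a determinism contract the pipeline tests assert).
* The pipeline derives a per-stage sub-seed from the global seed by a fixed
  integer hash of the stage name, so stages can be re-run independently yet
  reproducibly; all derived seeds stay within 32-bit range.
* Ties in merging and gene assignment are broken lexicographically —
  deterministic rather than order-dependent.
* Problem sizes in the test suite (1,000 random classifier instances,
  2,000-feature null cohorts, 20-seed replicate loops, full enumeration of
  rank-sum configurations up to 8 per group) were chosen so the whole suite
  completes in a few minutes on one CPU while still exercising every
  contract at meaningful scale.
* The package's interface is its R functions plus `scripts/acceptance.R`;
  no shell entry point is shipped, since the intended users drive analyses
  from R.

# Known limitations

Exact splice-site matching means real long-read data should be
junction-corrected upstream. The ISM 3'-end rule is one defensible
formalisation of "end incompleteness" among several. The brute-force classification oracle
and the generator's guarantees only cover annotations where genes do not
overlap; overlapping-gene precedence follows the documented tie-breaks but
has no independent oracle. Fusion/readthrough transcripts, RT-switching
artifacts, and end-support scoring (CAGE / poly(A) motifs) are not
detected.
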