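# methaplo

Epi-allelic haplotype reconstruction from bisulfite sequencing reads.

## The problem

Standard WGBS (whole-genome bisulfite sequencing) callers report a
methylation percentage per CpG site, averaging over all reads.  That
average hides *epi-allelic* structure: in imprinted regions, in
allele-specific methylation (ASM), and in heterogeneous cell
populations, the two DNA copies (or distinct subclones) carry different
methylation patterns that individual reads can still resolve.  methaplo
clusters reads into **haplotype chains** — groups of reads inferred to
come from DNA fragments sharing one epigenetic haplotype — and
annotates each chain with its own CpG methylation profile, SNP/SNV
genotype, and (for NOMe-seq data) GpC chromatin accessibility with
inferred nucleosome/protein-protected intervals.

It is aimed at analysts working with coordinate-sorted bisulfite
alignments (BSMAP-style, SAM/BAM) who want read-level epi-allele
resolution in regions of interest rather than genome-wide position-wise
averages.

## The model

The epigenotype of a position is one of six states
{A, C, G, T, meC, meG}, where meG denotes a G whose complementary
reverse-strand C is methylated.  A read from fragment strand
*r* ∈ {fwd, rev} observes base *D* at a position with epigenotype *g*
through two noise stages:

1. **Bisulfite conversion + PCR**, P(Z | g, r): an unmethylated C on the
   read's own strand converts to T unless conversion fails (rate
   α_fail = 1 − conversion rate, default 0.05); a methylated C is
   protected except for inappropriate conversion (rate β, default
   0.05); the complementary strand sees the partner base unperturbed.
2. **Sequencing error**, P(D = d | g, r) = (1 − 4ε/3) P(Z = d | g, r) + ε/3,
   with ε from the Phred quality of the base; an N is
   likelihood-neutral.

Reads are partitioned into chains B with strand assignment R, and each
chain *b* carries an epigenotype sequence g_b over its range, subject
to strand compatibility (a CpG is either CG or meC–meG; in NOMe mode a
GpC may be meG–meC).  The fit maximizes the posterior

Λ(B, G, R) = π₀(B) · π₁(G | B) · ∏ᵢ ∏ⱼ P(D = d_ij | g_{(s_i+j) b_i}, r_i)

where π₀(B) ∝ ∏ᵢ √L_{b_i} (Σ_{j∈I_{b_i}} l_j)² favors thick, long
chains and π₁ weights each chain position by q (default 0.9999) when
its nucleotide projection matches the reference (or a known variant)
and 1 − q otherwise.  A read may join a chain only when their overlap
spans at least K₀ bp and contains at least K₁ CpGs, K₂ isolated CpGs,
and K₃ isolated GpCs (mode-dependent defaults).  Optimization is
coordinate ascent over single-read moves with chain-level merge and
tail-swap moves at stalls; per-chain optimal epigenotype sequences are
computed exactly by a constrained Viterbi dynamic program.  After
fitting, minor chains are removed by the noise filter
`a ≤ chain length + b × depth fraction`.

## Worked example

Simulate an allele-specific methylated region — two epi-alleles at
equal frequency over a 3 kb window with a central CpG island, one
allele fully methylated, the other unmethylated and carrying an A>T
SNV — then fit and filter:

```r
library(methaplo)

sim <- sim_asm_scenario(seed = 11)
fit <- methaplo(sim$reads, sim$window, methaplo_config("wgbs-paired"))
fit <- filter_chains(fit)
summary(fit)
#> <methaplo_fit> wgbs-paired mode: 300 reads in 149 chain(s) (2 kept) on chr:1-3000
#>   log posterior 2072.08 after 3 pass(es)
#>   154 accepted move(s)
#>
#> Chains:
#>  chain start  end length n_reads depth_fraction mean_methylation  kept
#>  ...
#>     72   683 2286   1604      74          0.365                0  TRUE
#>     73   724 2320   1597      79          0.393                1  TRUE
#>   ... and 139 more chain(s) (139 read(s) in total, all filtered out)
```

The two kept chains are the two epi-alleles: one fully methylated
(`mean_methylation` 1) and one fully unmethylated (0); the remaining
chains are low-support singletons removed by the noise filter.
Position-wise methylation levels show the intermediate consensus
characteristic of ASM (about half the covering reads are methylated at
every island CpG):

```r
head(methylation_calls(fit), 3)
#>   chrom pos context     level coverage
#> 1   chr 850    HCGD 0.4000000       15
#> 2   chr 895     CpG 0.4166667       12
#> 3   chr 940     CpG 0.6111111       18
```

and the distinguishing SNV is called heterozygous from the two chains'
fit-ratio-qualified genotypes:

```r
combined_genotype(fit, attr(sim, "snv_pos"))$genotype
#> [1] "AT"
```

File-based runs go through `run_pipeline()` (BAM/SAM + FASTA + optional
VCF in; TSV/BED/bedGraph/JSON out), or the thin command-line front end
in `inst/cli/methaplo.R` with subcommands `simulate`, `fit`, `filter`,
and `call`.

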