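# stressdiv

Genetic architecture of the ER stress transcriptional response: induction
calling across inbred mouse strains and cis/trans classification of
regulatory divergence from F1 allele-specific RNA-seq counts.

`stressdiv` is for quantitative geneticists and genomicists who want to ask,
gene by gene, whether strain differences in a stress response are encoded in
the responding gene itself (*cis*) or in the diffusible regulatory
environment (*trans*). It implements the classical parent/hybrid comparison:
in an F1 both parental alleles share one set of trans factors, so the
allelic read ratio isolates cis effects, and a parental expression ratio
that disagrees with the F1 allelic ratio implicates trans. The package
covers the full path from raw count tables to calls — and, because public
data for this design are scarce, ships a synthetic-data generator with a
known regulatory architecture so every stage is validated by parameter
recovery.

## The statistics at the core

For a gene with pooled parental counts $(a, b)$ (library-size standardized
to the F1 allelic depth) and pooled F1 allelic counts $(m, p)$, per
condition:

1. **Parental divergence:** exact binomial test of $a$ vs $a+b$ against 0.5.
   **F1 allelic imbalance:** exact binomial test of $m$ vs $m+p$ against
   0.5. BH correction within each family, FDR 0.1%.
2. **Trans test** (step-1 significant genes only): Fisher's exact test on
   $\begin{pmatrix} a & b \\ m & p \end{pmatrix}$, BH within the tested
   subset, FDR 0.1%. A significant ratio difference is a trans signal.

Categories follow the standard decision table — *cis*, *trans*,
*cis+trans*, *cis×trans*, *compensatory*, *conserved*, *ambiguous* — with
magnitudes $\mathrm{cis} = |\log_2(m/p)|$,
$\mathrm{trans} = |\log_2(a/b) - \log_2(m/p)|$ and
$\%\mathrm{cis} = \mathrm{cis}/(\mathrm{cis}+\mathrm{trans})$.

Around this core: TMM normalization and a common-dispersion NB exact test
call tunicamycin-induced genes per strain (fold ≥ 1.5, FDR 1%); one-way
ANOVA on $\log_2(\mathrm{TM}/\widetilde{\mathrm{control}})$ tests strain
effects on induction; Fisher's exact test on control-vs-TM allele counts
detects stress-induced ASE changes; and a K×2 χ² tests strain effects on
the magnitude of differences shared across crosses.

## Worked example

The analysis is organised as numbered drivers over the package functions:

```sh
Rscript analysis/01_simulate.R 1   # generate the default synthetic study
Rscript analysis/02_induction.R    # QC, normalization, induction calling
Rscript analysis/03_cistrans.R     # two-step cis/trans classification
Rscript analysis/04_ase.R          # stress-induced ASE changes
Rscript analysis/05_shared.R       # sharing across F1 crosses
Rscript analysis/06_report.R       # aggregate report + recovery scoring
```

Stage 3 prints, per cross and condition, lines such as

```
xCAST control: 1585 informative; cis 34, trans 25 (58% cis); median |cis| 1.35, median |trans| 1.02
  cis effects by condition: both=27, control-only=7, TM-only=12
```

i.e. of the 1,585 genes with ≥ 2 discriminating SNPs and > 20 pooled
allelic reads in that cross, 34 were classified cis and 25 trans at FDR
0.1%, with the median cis magnitude (|log2 allelic ratio|) of 1.35; twelve
cis effects were detectable only under ER stress. Stage 6 scores the calls
against the generative truth and wrote, for the run above,

```
category recovery (called = true): cis 0.648, trans 0.721, conserved 0.954
induction: sensitivity 1.000 at true fold >= 3; empirical FDR 0.0029
```

— the cis/trans recovery at this realistic replicate dispersion (0.05)
visibly trails the low-dispersion benchmark regime (see the methods
vignette's discussion of the overdispersion caveat of exact count tests).

A deterministic building block, usable on its own, reconstructs a gene's
post-stress allelic state from its control allelic proportion and
allele-specific fold changes:

```r
library(stressdiv)
allelic_response_reconstruction(0.40, 1.7, 4.3)
#>   total_fold   prop_tm
#> 1       3.26 0.2085890
```

A gene whose maternal allele is at 40% under control and responds 1.7-fold
while the paternal allele responds 4.3-fold ends up ~3.3-fold induced
overall with the maternal allele reduced to ~21% — the signature of an
allele-specific stress response.

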