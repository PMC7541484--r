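# paleoproteo

Authentication and phylogenetics of ancient bone and dentine proteomes.

Ancient-protein studies of Pleistocene fossils face two linked problems
before any evolutionary inference is possible: deciding whether a bone still
contains enough endogenous protein to be worth destructive sampling, and
proving that the peptides recovered are ancient rather than modern
contamination. `paleoproteo` implements the full analysis chain a
palaeoproteomics lab runs around those questions, from infrared prescreening
of raw bone powder to a bootstrapped maximum-parsimony tree built from
authenticated consensus sequences.

## What the package computes

**Diagenetic prescreening.** From an ATR-FTIR spectrum of bone powder the
package computes the infrared splitting factor
IRSF = (h₆₀₅ + h₅₆₅) / h₅₉₀ (baseline-corrected heights of the phosphate ν₄
doublet over their valley; values above 4.0 indicate an extremely
degraded/burnt bone) and the amide-to-phosphate ratio Am/P = h₁₆₄₀ / h₁₀₁₀
(residual collagen relative to mineral; above 0.07 soluble collagen is
likely extractable). From whole-bone elemental data it computes the atomic
ratio C:N = (C wt%/12.011)/(N wt%/14.007); samples with N wt% > 3.0 and
3.0 ≤ C:N ≤ 3.9 are flagged as good radiocarbon-dating candidates.

**ZooMS deamidation (α-value).** Glutamine deamidation (+0.98402 Da)
accumulates over archaeological time. For the collagen marker peptide at
m/z 1105 (GVQGPPGPAGPR with one hydroxyproline), the observed isotope
envelope is modelled as α·T + (1−α)·T⁺, where T is the theoretical isotope
distribution of the undeamidated peptide and T⁺ the same distribution
shifted by the deamidation increment. Non-negative least squares on the
overlapping envelopes yields α ∈ [0, 1] (1 = pristine, 0 = fully
deamidated), combined over MALDI replicates by an intensity-weighted mean.

**Endogeneity classification.** Per protein, the deamidation frequency is
the intensity-pooled fraction Σ(deamidated Q/N intensity)/Σ(total Q/N
intensity) over sites covered by peptide-spectrum matches (PSMs). Proteins
with more than two covered Q/N positions enter a two-component univariate
Gaussian mixture fitted by EM; the higher-mean component is the endogenous
(ancient, heavily deamidated) class, the lower one collects keratins and
laboratory enzymes.

**Consensus sequence calling.** Per reference position, a substitution is
accepted only with ≥ 2 supporting PSMs, both b- and y-ion series, and —
for the isobaric hydroxyproline–alanine vs proline–serine pair — a
supporting hydroxyl localization; anything uncertain is called `X`.
Leucines become isoleucines (isobaric under low-energy CID). Sequences are
concatenated on fixed mature-chain coordinates: dataset 1 is type I
collagen (COL1A1 1–1057, COL1A2 1058–2098), dataset 2 adds eight
non-collagenous bone proteins for 5003 positions.

**Parsimony phylogenetics.** Fitch small-parsimony scoring with `X`/`-` as
fully missing, exact tree search (full enumeration or branch-and-bound,
provably identical results), nonparametric bootstrap with fractional credit
for tied trees, and strict majority-rule consensus with split supports.

A synthetic-data module generates FTIR spectra, MALDI isotope envelopes,
two-class PSM tables and alignments evolved on a known tree, so every
estimator in the package is validated by round-trip against ground truth.

## Worked example

```r
library(paleoproteo)

# the ZooMS marker at nominal m/z 1105
p1105 <- peptide("GVQGPPGPAGPR",
                 modifications = data.frame(type = "hydroxylation_PK",
                                            position = 6))
monoisotopic_mh(p1105)
#> [1] 1105.5749

# alpha-value from three simulated MALDI replicates (true alpha 0.75)
reps <- gen_maldi_replicates(p1105, alpha_true = 0.75, n_replicates = 3,
                             noise_sd = 0.01, seed = 2)
sample_alpha(reps, p1105)
#> <alpha_estimate> alpha = 0.750 (3 replicates)

# prescreening indices of a well-preserved synthetic bone spectrum
sc <- fixture_scenario(endo_mean = 0.8, contam_mean = 0.06,
                       n_proteins_per_class = 10, seed = 3)
compute_irsf(gen_ftir_spectrum(sc$ftir_band_heights, noise_sd = 1e-3, seed = 3))
#> [1] 3.63      # below the 4.0 degradation threshold
cn_atomic_ratio(10.53, 3.37)
#> [1] 3.64      # inside the 3.0-3.9 dating window

# endogenous vs contaminant proteins from a simulated PSM table
endogeneity_analysis(gen_psm_table(sc), seed = 3)$result
#> <endogeneity_result> 10 endogenous (mean 0.83), 10 contaminant (mean 0.05)
```

The interpretation: an α of 0.75 and an IRSF of 3.6 describe a
well-preserved bone; the mixture cleanly separates the heavily deamidated
(ancient) proteins near 83% deamidation from the essentially undeamidated
contaminants near 5%.

The end-to-end pipeline (simulate → prescreen → zooms → endogeneity →
consensus → phylo) runs from one config and writes per-stage TSV/FASTA/
NEXUS/Newick reports, byte-identically for a fixed seed:

```r
run_pipeline(out_dir = "demo_run")
```

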