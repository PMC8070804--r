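# flimetry

Optical metabolic imaging (OMI) analysis of drug response in patient-derived
tumor organoids, from raw fluorescence-lifetime photon counts to per-patient
response calls and single-cell heterogeneity measures.

## The problem

Slow-growing tumors — gastroenteropancreatic neuroendocrine tumors are the
motivating case — defeat the standard readouts of organoid drug screens:
diameter growth and proliferation staining barely move. Two-photon
fluorescence lifetime imaging (FLIM) of the endogenous metabolic co-enzymes
NAD(P)H and FAD offers a label-free, non-destructive alternative: drug
response shows up as a metabolic shift within days, cell by cell.

`flimetry` implements the full analysis chain for such experiments:

1. **Decay fitting** (`fitBiexponential`, `fitImage`). Each pixel's
   time-correlated single-photon-counting (TCSPC) histogram is fit by
   iterative reconvolution with the instrument response function (IRF) to
   the two-component model

   *I(t) = A [ α₁ e^(−t/τ₁) + α₂ e^(−t/τ₂) ] ⊛ IRF + C*,

   with α₁ + α₂ = 1, short/long lifetimes τ₁ < τ₂ (free vs protein-bound
   co-enzyme), and background C. The mean lifetime is
   τₘ = α₁τ₁ + α₂τ₂. Least squares uses Poisson deviance residuals
   (maximum likelihood) by default. Utilities cover the IRF FWHM,
   microsphere lifetime standards, pixel binning and intensity maps.
2. **Segmentation** (`segmentCells`). Nuclei are the mid-intensity band of
   a three-class Otsu threshold on the NAD(P)H intensity image (dark
   background, mid nuclei, bright cytoplasm), split by distance-transform
   watershed and filtered for area and roundness; whole cells grow from the
   nuclear seeds by intensity-guided propagation gated on a global Otsu
   foreground; cytoplasm = cell − nucleus. `percentPositive` scores
   object/marker colocalization for immunofluorescence counts.
3. **Per-cell OMI variables** (`aggregateCells`, `normalizeToControl`,
   `omiIndex`). Cytoplasm means of τₘ, τ₁, τ₂, α₁ and intensity per
   channel, the optical redox ratio I(NAD(P)H)/I(FAD), and — after dividing
   the redox ratio and both τₘ by the patient-matched control means — the
   composite **OMI index** = redox ratio + NAD(P)H τₘ − FAD τₘ
   (coefficients 1, 1, −1). A decrease indicates metabolic drug response.
4. **Response calling** (`callResponse`). Per patient and treatment:
   one-way ANOVA of control vs treatment (p < 0.05) and Glass's
   Δ = (mean control − mean treated)/SD(control) with cutoff 0.75; an OMI
   increase is reported "n.a." (non-response) rather than a negative Δ.
5. **Subpopulations** (`selectModel`, `whIndex`). For groups with more than
   100 cells, Gaussian mixtures (K = 1–3) are fitted by EM; the
   fit-and-AIC-select step is repeated 100 times from random starts and the
   majority selection wins. Heterogeneity is summarized by the weighted
   heterogeneity index **wH = Σᵢ (1 − pᵢ ln(pᵢ+1)) (σᵢ + dᵢ)**, where dᵢ is
   the distance from subpopulation i's median to the overall median.
6. **Synthetic data** (`cohort`, `renderScene`, `simulateDecay`,
   `growthGenerator`). Photon-realistic generators with known ground truth:
   Poisson decay histograms, two-channel organoid scenes, a 7-patient ×
   4-condition treatment cohort, microsphere standards and organoid-growth
   tables. These power the test suite end to end.

## Worked example

```r
library(flimetry)

irf <- defaultIrf()                      # Gaussian IRF, 220 ps FWHM
ms  <- microsphereStandard(seed = 1)     # 7 daily-standard decays
mean(sapply(ms, fitMonoexponential, irf = irf))
#> daily standard: 2.1 ns (n = 7)

tb    <- normalizeToControl(cohort(seed = 11))   # 7-patient synthetic cohort
calls <- callResponse(tb)
calls[calls$condition == "combination", ]
#>    patient_id   condition mean_control mean_treated f_statistic  p_value glass_delta   responder
#> 3          P1 combination            1        0.815      218.67 2.14e-42        1.18   responder
#> 6          P2 combination            1        0.822       52.64 8.88e-12        1.06   responder
#> 9          P3 combination            1        0.804       88.20 1.46e-17        1.38   responder
#> 12         P4 combination            1        1.041        3.90 4.96e-02          NA na_increase
#> 15         P5 combination            1        0.823       62.71 1.69e-13        1.13   responder
#> 18         P6 combination            1        1.040        1.86 1.73e-01          NA na_increase
#> 21         P7 combination            1        0.891      228.44 6.00e-44        1.23   responder
countResponders(calls, "combination")    #> 5  (everolimus: 4, ABT263: 4)
```

Five of the seven lines respond to the drug combination: their OMI index
drops by more than 0.75 control SDs (Δ ≈ 1.1–1.4) with p ≪ 0.05, while P4
and P6 show the OMI increase that marks non-response. Subpopulation
analysis on the eligible (>100 cells/group) patients:

```r
x6 <- tb$omi_index[tb$patient_id == "P6" & tb$condition == "control"]
(m6 <- selectModel(x6, seed = 1))
#> MixtureModel: K=2, n=300, logLik=-77.91, AIC=165.83
#>        p     mu  sigma
#> 1 0.5313 0.6936 0.1800
#> 2 0.4687 1.3474 0.1532
whIndex(m6, x6)$wh_index                 #> 0.789
```

Patient 6's control cells split into two balanced metabolic subpopulations
(wH ≈ 0.79); patient 7 is a single narrow population (K = 1, wH ≈ 0.03) —
high baseline heterogeneity co-occurring with non-response, low
heterogeneity with response.

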