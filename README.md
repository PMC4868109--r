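# petqc

Quality assessment of long-range chromatin-interaction assays (Hi-C, in situ
Hi-C, ChIA-PET) by random sub-sampling of mapped paired-end tags (PETs).

Proximity-ligation experiments report millions of PETs, but there is no
obvious readout for how reliable the reconstructed interaction map is: a map
built from too few PETs looks plausible yet its individual windows are
dominated by counting noise. `petqc` quantifies this. The working hypothesis
is that, at sequencing saturation, a contact map rebuilt from a random subset
of the data reproduces the original map; deviations from proportional
recovery measure how far a library is from that ideal. The package is aimed
at anyone generating or reusing Hi-C/ChIA-PET libraries who wants a single,
comparable number for library quality, plus per-window reliability maps.

## Method

Starting from mapped PETs (BEDPE or 4DN `.pairs` text):

1. **Filtering.** Clonal (PCR-duplicate) PETs are collapsed; only unique
   intra-chromosomal PETs spanning more than 10 kb (configurable) are kept —
   the *filtered PETs*. Short-range contacts dominate the matrix diagonal
   and would bias the assessment.
2. **Sub-sampling and binning.** The filtered PETs are randomly sub-sampled
   at densities *samd* = 90, 70 and 50 % (s90/s70/s50), and contact matrices
   are rebuilt in 5 kb or 25 kb windows (2-D bin pairs).
3. **Local indicator.** Per window,

   ```
   recPETcounts = (samPETcounts / oPETcounts) * 100
   ∂PETcounts   = samd − recPETcounts
   ```

   where `oPETcounts` / `samPETcounts` are the window's counts in the
   original and sub-sampled matrix. `∂PETcounts` (dispersion) is 0 when the
   window lost exactly the expected proportion of its PETs.
4. **Global indicators.** `denQC.samd` is the fraction of assessable windows
   with `|∂PETcounts| ≤ 10 %` (threshold configurable);
   `simQC.90/50 = denQC.90 / denQC.50` and likewise for 70/50 (both 1 at
   saturation); and

   ```
   QCscore_raw = (denQC.50 / simQC.90/50) * (denQC.50 / simQC.70/50)
   QCscore     = 10 * log10(QCscore_raw)
   ```

   so a perfect, saturated library scores 0 and noisier/shallower libraries
   score increasingly negative.

A seeded synthetic PET generator (TAD-block model with power-law distance
decay, inter-chromosomal noise and clonal duplicates) supports calibration
experiments without any external download.

## Worked example

```r
library(petqc)

cfg  <- synthetic_config(n_pets = 200000, seed = 42)  # two 2 Mb chromosomes
pets <- generate_pets(cfg)
library_stats(pets)
#> <library_stats>
#>   total PETs:    210098
#>   unique PETs:   200000 (95.2%)
#>   intra / inter: 180131 / 19869
#>   filtered PETs: 128794 (span > 10000 bp)

res <- run_qc(pets, qc_config(resolution_bp = 5000),
              sampling_plan(replicates = 5, master_seed = 42))
res
#> <qc_result> 5 replicate(s), 128794 filtered PETs, 5000 bp windows
#> <qc_summary>
#>   denqc_90 = 0.8515
#>   denqc_70 = 0.1842
#>   denqc_50 = 0.2149
#>   simqc_90_50 = 3.9619
#>   simqc_70_50 = 0.8569
#>   QCscore = -18.66 (raw 0.01361), 38594 windows
#>   mean QCscore = -18.72, CV = 0.59%
```

Reading: 85 % of windows are stable under a mild 10 % down-sampling
(denQC.90), but only 21 % survive halving the library (denQC.50) — this
synthetic library is far from saturation, and the QCscore of −18.7 places it
accordingly; the score varies by less than 1 % across independent
sub-sampling replicates. `res$maps` holds the per-window dispersion maps
([export_dispersion_map()] writes them as TSV for genome-browser-style
display).

The same pipeline is available from the shell via the installed script
(`system.file("exec", "petqc", package = "petqc")` after install, or
`exec/petqc` in the source tree):

```sh
petqc simulate --n-pets 200000 --seed 42 --outdir sim
petqc score --input sim/synthetic.bedpe --chrom-sizes sim/synthetic.chrom.sizes \
            --seed 42 --replicates 5 --outdir qc
petqc map --input sim/synthetic.bedpe --chrom-sizes sim/synthetic.chrom.sizes \
          --region chrS1:0-500000 --mode dispersion --out disp.tsv
petqc calibrate --depths 20000,50000,100000 --seed 1 --out ladder.tsv
```

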