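# riverindic

Bacterial bioindicator discovery for biological status classification along
longitudinally sampled rivers.

Macroinvertebrate-based indices (such as the Saprobic Index) are the
reference for river biological status but are slow and costly to survey.
Bacterioplankton communities respond rapidly to the same gradients and
drift downstream with the water mass, so upstream 16S amplicon data carry
information about downstream status. `riverindic` implements, as a tested R
package plus a numbered analysis workflow, the full chain for mining that
information from an ASV table, a taxonomy table and station metadata:

* **Prevalence/CV screening** — candidate bioindicator taxa are those both
  widely detected and highly variable: prevalence vs. coefficient of
  variation of relative abundances, ranked by Pareto front and the product
  of min–max standardized coordinates.
* **Constrained ordination** — Bray–Curtis dissimilarity of
  Hellinger-transformed profiles (`sqrt(x_ij / rowsum_i)`), PMM imputation
  of missing metadata, iterative VIF filtering (threshold 5), permutation
  -tested forward selection, and distance-based redundancy analysis (dbRDA)
  with a global permutation test.
* **Beta-diversity threshold surface** — boosted regression of pairwise
  dissimilarity d_ij on the chlorophyll *a* values (g_i, g_j) of each site
  pair; ridges of the spanning score S(c) (mean predicted dissimilarity
  between sites below c − band and above c + band) mark concentrations
  where community composition shifts faster than average.
* **Spatio-temporal ASV screening** — the core method. Within each
  transect, an ASV enters the model as a windowed-standardized lagged
  feature `z_i = (x_{i−ℓ} − mean_w) / sd_w`; a random-forest prefilter
  ranks candidates by %IncMSE; a greedy builder grid-searches (w, ℓ) per
  candidate and accepts strict improvements of the held-out metric on an
  ordered 0.85/0.15 upstream/downstream split; a randomized ensemble
  repeats this with shuffled candidate order and sampled boosting
  hyperparameters.
* **Network analysis** — perfect-accuracy models form a presence/absence
  table; co-occurrence and co-exclusion graphs over the most frequent ASVs
  expose informational redundancy; minimal perfect models reveal
  hub-and-partner indicator pairs; a taxonomy rank-distance dendrogram
  links redundancy to relatedness.

A seeded synthetic river-microbiome generator (60 stations × 3 transects,
environmental gradients, compositional background, planted lagged indicator
groups with known redundancy) makes every stage testable without any
external download.

## Worked example

The numbered scripts under `analysis/` run the whole study on the synthetic
river and write tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_prevalence_screen.R
Rscript analysis/03_ordination.R
Rscript analysis/04_threshold_surface.R
Rscript analysis/05_screening_ensemble.R
Rscript analysis/06_networks.R
```

Output of a full run (seed 7):

```
180 samples x 206 taxa; status classes: class1=95, class2=85
Phylum level: 6 groups screened; top candidates: Proteobacteria, Bacteroidota, ...
Genus level: 50 groups screened; top candidates: Genus_31, Genus_ind2, Genus_ind1, ...
VIF filter retained: pH, chl_a_mg_L, log_total_coliforms, log_ecoli
Forward selection admitted (in order): pH, chl_a_mg_L, log_total_coliforms
dbRDA: 40.1% of variance constrained (permutation p = 0.002)
surface over 16110 site pairs; held-out R^2 = 0.27; baseline beta-diversity = 0.21
detected thresholds (mg/L): 1.8
60 runs; 60 reached 100% held-out accuracy
simplest perfect models use 2 ASVs; hubs: ASV_ind1_a, ASV_ind1_c, ASV_ind2_a, ...
```

Reading: both planted indicator genera (`Genus_ind1`, `Genus_ind2`) surface
among the prevalence/CV candidates; the ordination attributes community
turnover to the pH / chlorophyll / fecal-indicator gradients; the threshold
surface flags a chlorophyll *a* concentration where composition shifts
abruptly; the screening ensemble recovers models that classify downstream
biological status perfectly from as few as two upstream ASVs — one member
of each planted redundancy group, the hub-and-partner structure the network
stage then makes explicit.

The same pipeline runs from a single YAML configuration
(`inst/extdata/pipeline_synthetic.yaml`) via `run_pipeline()`, which writes
a digest manifest for reproducibility. Real data enter through
`load_dataset(asv_tsv, taxonomy_tsv, metadata_tsv)` (BIOM supported for the
abundance table via the `biomformat` package).

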