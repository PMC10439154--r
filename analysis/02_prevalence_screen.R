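#!/usr/bin/env Rscript
# Stage 2: prevalence / coefficient-of-variation candidate screening.
#
# Taxa that are both widely present and highly variable across sites are
# candidate bioindicators. We aggregate the ASV table to phylum and genus
# level, compute prevalence and CV of relative abundances, and flag the top
# candidates (6 at phylum level, 15 at genus level) by Pareto front and the
# product of min-max standardized prevalence and CV.

suppressMessages(library(riverindic))

ds <- load_dataset("results/data/asv_table.tsv", "results/data/taxonomy.tsv",
                   "results/data/metadata.tsv")

for (spec in list(list(rank = "Phylum", n_top = 6),
                  list(rank = "Genus", n_top = 15))) {
  agg <- aggregate_taxa(ds$abundance, ds$taxonomy, spec$rank)
  screen <- select_candidates(prevalence_cv(agg), n_top = spec$n_top)
  out <- sprintf("results/prevalence_%s.tsv", tolower(spec$rank))
  write.table(screen, out, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s level: %d groups screened; top candidates: %s\n",
              spec$rank, nrow(screen),
              paste(head(screen$taxon[screen$candidate], 6), collapse = ", ")))
}
cat("Wrote results/prevalence_phylum.tsv and results/prevalence_genus.tsv\n")
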