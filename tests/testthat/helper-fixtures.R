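# Small synthetic fixtures shared across test files. Everything is generated
# in code under fixed seeds; no data files are read.

tiny_design <- function(n_stations = 12) {
  river_design(n_stations = n_stations)
}

tiny_dataset <- function(seed = 11, n_stations = 12, n_noise_taxa = 15,
                         library_size = 4000) {
  simulate_dataset(
    design = river_design(n_stations = n_stations),
    signal = planted_signal(n_groups = 1, clones_per_group = 2, true_lag = 1),
    n_noise_taxa = n_noise_taxa, library_size = library_size, seed = seed
  )
}

# mid-sized dataset with a single planted redundancy group; used by the
# screening and redundancy tests
midi_dataset <- function(seed, n_stations = 40, n_noise_taxa = 40,
                         library_size = 50000, n_groups = 1,
                         clones_per_group = 2, true_lag = 1) {
  simulate_dataset(
    design = river_design(n_stations = n_stations),
    signal = planted_signal(n_groups = n_groups,
                            clones_per_group = clones_per_group,
                            true_lag = true_lag),
    n_noise_taxa = n_noise_taxa, library_size = library_size, seed = seed
  )
}

# ordered-split pieces used by several screening tests
split_pieces <- function(ds) {
  ord <- order_by_flow(ds$metadata)
  meta <- ds$metadata[ord, , drop = FALSE]
  hmat <- hellinger_transform(ds$abundance)[ord, , drop = FALSE]
  n <- nrow(meta)
  n_train <- floor(0.85 * n)
  list(meta = meta, hmat = hmat, design = base_design(meta),
       train = seq_len(n_train), test = seq(n_train + 1, n))
}

toy_taxonomy <- function() {
  data.frame(
    asv_id = c("a1", "a2", "a3", "a4"),
    Kingdom = c("Bacteria", "Bacteria", "Bacteria", "Archaea"),
    Phylum = c("P1", "P1", "P1", "PX"),
    Class = c("C1", "C1", "C1", "CX"),
    Order = c("O1", "O1", "O1", "OX"),
    Family = c("F1", "F1", "F2", "FX"),
    Genus = c("G1", "G2", "G3", "GX"),
    stringsAsFactors = FALSE
  )
}
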