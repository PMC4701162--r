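# Shared fixture builders: everything is generated in code at test time.

# Raw side-A/side-B record table in the default CSV dialect.
raw_battles <- function(years = c(1650, 1705, 1800, 1870),
                        size_a = c(15000, 12000, 30000, 40000),
                        size_b = c(10000, 14000, 25000, 38000),
                        cas_a = c(3000, 1200, 6000, 4000),
                        cas_b = c(1000, 2100, 2500, 7600)) {
  data.frame(id = paste0("b", seq_along(years)), year = years,
             size_a = size_a, size_b = size_b,
             casualties_a = cas_a, casualties_b = cas_b,
             stringsAsFactors = FALSE)
}

# Canonical single battle for worked examples (sizes 15000 vs 10000).
one_battle <- function(cas_blue = 150, cas_red = 100) {
  battle_dataset(raw_battles(years = 1705, size_a = 15000, size_b = 10000,
                             cas_a = cas_blue, cas_b = cas_red))
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Small synthetic dataset reused by engine tests (kept small for speed).
small_synth <- function(n = 10, seed = 7, model = "fatigue") {
  generate_dataset(synth_config(true_model = model, n_battles = n,
                                seed = seed))$dataset
}
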