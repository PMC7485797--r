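# Shared fixtures: the pooled published life table used as the desk-scale
# worked example, and a small records builder.

table1_aq <- c(0.619, 0.478, 0.554, 0.169, 0.1368)
table1_al <- c(1, 0.381, 0.199, 0.089, 0.074, 0.064)
table1_ad <- c(0.619, 0.182, 0.110, 0.015, 0.010)
table1_l <- c(8968, 18447, 17254, 1546, 1499, 1291)

# per-stage unconditional cause decrements ad_ix, rows in stage order,
# columns in cause order (parasitism, plant defense, cannibalism, unknown,
# pathogens)
table1_decrements <- matrix(c(
  0,     0,     0.619, 0,     0,
  0,     0.102, 0.072, 0.008, 0,
  0.010, 0.063, 0.009, 0.027, 0,
  0.002, 0,     0,     0.012, 0.0007,
  0.002, 0,     0,     0.006, 0.0013
), nrow = 5, byrow = TRUE,
dimnames = list(setdiff(stage_levels(), "adult"), mortality_causes()))

# the printed cause totals (carry small rounding artifacts relative to the
# stage entries; plant defense and pathogens sum exactly)
table1_totals <- c(parasitism = 0.015, plant_defense = 0.165,
                   cannibalism = 0.701, unknown = 0.054, pathogens = 0.002)

# one dissection record with overridable fields
make_record <- function(site = "A", year = 2016, cultivar = "Hockett",
                        block = "B1", plot = "B1_Hoc", sample_kind = "stem",
                        week = 3, stub_phase = NA, unit_id = "s1",
                        n_eggs = 0, n_live_larvae = 0, dead_evidence = "",
                        emerged = FALSE) {
  data.frame(site = site, year = year, cultivar = cultivar, block = block,
             plot = plot, sample_kind = sample_kind, week = week,
             stub_phase = stub_phase, unit_id = unit_id, n_eggs = n_eggs,
             n_live_larvae = n_live_larvae, dead_evidence = dead_evidence,
             emerged = emerged, stringsAsFactors = FALSE)
}

make_records <- function(...) {
  rows <- list(...)
  validate_records(do.call(rbind, lapply(rows, function(r) {
    r[] <- lapply(r, as.character)
    r
  })))
}

# a small simulation configuration for fast tests
small_config <- function(..., stems_per_plot = 150, n_sites = 1,
                         n_blocks = 1, seed = 99) {
  sim_config(n_sites = n_sites, n_blocks = n_blocks,
             stems_per_plot = stems_per_plot, seed = seed, ...)
}
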