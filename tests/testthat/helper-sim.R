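# shared fixtures: small, fast simulation configs built in code

small_config <- function(seed = 7, noise = noise_free(), ...) {
  defaults <- list(region_length_bp = 50000, n_plates = 6,
                   coverage_target = 10, insert_size_mean_bp = 30000,
                   insert_size_sd_bp = 3000, n_assays = 12,
                   noise = noise, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

small_world <- function(seed = 7, noise = noise_free(), ...) {
  cfg <- small_config(seed = seed, noise = noise, ...)
  pair <- simulate_progenitor_pair(cfg)
  amph <- derive_amphidiploid(pair)
  lib <- suppressMessages(simulate_bac_library(amph, cfg))
  design <- pooling_design(cfg$n_plates, cfg$rows_per_plate,
                           cfg$cols_per_plate)
  panel <- simulate_assay_panel(amph, lib, cfg)
  list(cfg = cfg, pair = pair, amph = amph, lib = lib, design = design,
       panel = panel)
}

# evidence fixture transcribed from the published assignment table
table3_evidence <- function() {
  path <- system.file("extdata", "table3_evidence.tsv",
                      package = "snpcontig")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
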