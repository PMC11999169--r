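# Shared fixtures built in code: a miniature substrate map over an
# artificial 20-peptide universe, and a quick noise-controlled STK
# simulation helper.

tiny_universe <- function(n = 20) sprintf("pep%02d", seq_len(n))

tiny_map <- function() {
  u <- tiny_universe()
  sets <- list(FAM_A = u[1:10], FAM_B = u[8:14], FAM_C = u[15:20])
  attr(sets, "level") <- "family"
  attr(sets, "source_name") <- "tiny"
  class(sets) <- "kinase_map"
  sets
}

quick_sim <- function(seed = 1, noise_sd = 1, planted = numeric(0),
                      dead = 0, sat = 0, samples = 2L, chips = 2L) {
  cfg <- simulation_config(
    layout = array_layout("STK"),
    groups = c(sedentary = samples, exercise = samples),
    n_chips = chips, planted_effects = planted,
    dead_peptide_frac = dead, saturating_peptide_frac = sat,
    noise_sd = noise_sd, seed = seed)
  simulate_arrays(cfg)
}

# minimal kinetic read table built by hand
reads_from_series <- function(intensities,
                              exposures = c(10, 20, 50, 100, 200),
                              peptide = "p1", sample = "s1",
                              chip = "c1", group = "g1") {
  data.frame(chip_id = chip, sample_id = sample, group = group,
             peptide_id = peptide, exposure_ms = exposures,
             intensity = intensities, stringsAsFactors = FALSE)
}
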