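# Shared reduced-resolution configurations and cached scenario runs.
# Scenario-level tests all share one lattice resolution (1/4 of the cell
# model's native 60-um spacing, physical geometry unchanged) and seeds 1:3;
# runs are computed once per session and reused across test files.

fixture_scale <- 0.25
fixture_seeds <- 1:3

small_domain <- function(spacing_um = 600, ...) {
  build_domain(domain_config(cell_site_spacing = spacing_um,
                             fe_element_size_callus = 1.25,
                             fe_element_size_outer = 2.5,
                             bv_voxel_size = 0.25, ...))
}

# An open lattice for migration statistics: a domain whose callus region is
# broad, with helper to place isolated cells.
.sim_cache <- new.env(parent = emptyenv())

cached_run <- function(scenario, release = "sponge", seed = 1,
                       duration_days = 42, output_days = c(14, 28, 42)) {
  key <- paste(scenario, release, seed, duration_days,
               paste(output_days, collapse = "_"), sep = "|")
  if (is.null(.sim_cache[[key]])) {
    cfg <- generate_fixture(fixture_scale, scenario = scenario,
                            release = release, duration_days = duration_days,
                            output_days = output_days, seed = seed)
    .sim_cache[[key]] <- run_scenario(cfg)
  }
  .sim_cache[[key]]
}
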