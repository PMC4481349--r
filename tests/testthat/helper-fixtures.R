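# Shared synthetic fixtures, generated once per test run. The 20000-frame
# trajectory backs the recovery tests; smaller ones are built inline where a
# test needs special structure.

.fixture_cache <- new.env(parent = emptyenv())

big_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$cfg <- generator_config(seed = 101L, n_frames = 20000L)
    .fixture_cache$sim <- generate_trajectory(.fixture_cache$cfg)
  }
  list(cfg = .fixture_cache$cfg, sim = .fixture_cache$sim)
}

big_report <- function() {
  if (is.null(.fixture_cache$report)) {
    b <- big_sim()
    .fixture_cache$report <- run_pipeline(b$sim$trajectory,
                                          default_pipeline_config(0))
  }
  .fixture_cache$report
}
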