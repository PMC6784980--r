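# Shared, memoised model runs.  Unit tests use a coarse 30-cell column and
# short horizons; the acceptance tests use the package's default desk-scale
# configuration.  Everything is cached across test files within one session.

.test_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.test_env[[key]])) .test_env[[key]] <- force(expr)
  .test_env[[key]]
}

cfg_small <- function(...) solver_config(n_nodes = 30, stretch = 0.3, ...)

# Coarse full-history SQ run shared by the unit tests.
traj_small <- function() memo("traj_small", {
  run_scenario("SQ", cfg_small(), default_parameters(), end = 2050)
})

# Transport-only configuration: every reaction switched off.
params_inert <- function() {
  p <- default_parameters()
  for (nm in grep("^k_", names(p), value = TRUE))
    if (!grepl("^k_Eq", nm)) p[[nm]] <- 0
  p$f_dnra <- 0
  p
}

# Desk-scale runs for the acceptance tests (default configuration).
acc_cfg <- function() solver_config()

acc_traj <- function(scenario, seasonal = FALSE) {
  key <- paste0("acc_", scenario, if (seasonal) "_seas")
  memo(key, run_scenario(scenario, acc_cfg(), default_parameters(),
                         seasonal = seasonal,
                         end = if (seasonal) 2016 else 2050))
}
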