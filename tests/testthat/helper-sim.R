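# Shared fixtures. Heavy artifacts (the desk-scale end-to-end run) are
# built once per session and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a schedule whose four phases share identical targets: stationary conditions
flat_schedule <- function(duration_s, sv = 85, hr = 80, svr = 850,
                          spread = 24, instability = 0) {
  phase_schedule(duration_s = duration_s,
                 sv_mean = rep(sv, 4), sv_spread = rep(spread, 4),
                 hr_mean = rep(hr, 4), svr_mean = rep(svr, 4),
                 instability = rep(instability, 4))
}

quick_case <- function(duration_s = 120, seed = 7, ...) {
  simulate_case(patient_profile("P001"), phase_schedule(duration_s),
                seed = seed, ...)
}

# the desk-scale end-to-end run used by the recovery and report tests
default_run <- function() {
  cached_fixture("default_run", {
    cfg <- default_config(work_dir = file.path(tempdir(), "svwave_accept"),
                          seed = 1L)
    run_pipeline(cfg)
  })
}
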