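# Shared fixtures: models at the published best-fit parameter values and a
# small synthetic-study configuration reused across tests.

wt_ls <- function() lifespan_model(lognormal_law(4.45, 0.307))           # wild-type LS
wt_dls <- function() lifespan_model(lognormal_from_moments(99.5, 26.1),
                                    r = 0.0038)                          # wild-type DLS
wt_dorn <- function() lifespan_model(delta_law(109.4), r = 0.0072)       # wild-type Dornhorst
bclx_dorn <- function() lifespan_model(delta_law(55.8), r = 0.0029)

study_law <- function() lognormal_from_moments(100, 25)

study_model <- function(f = 0.2) {
  law <- study_law()
  lifespan_model(law, r = r_from_f(law, f))
}

# quick fitting settings used throughout the tests: same algorithm as the
# defaults, smaller multi-start schedule and grid for runtime
quick_fit <- function(ds, kind, patience = 6L, grid = 500L, seed = NULL, ...) {
  fit_survival(ds, kind, starts_patience = patience, grid_points = grid,
               seed = seed, ...)
}
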