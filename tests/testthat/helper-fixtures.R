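# Shared fixtures, built once per test run. The default campaign is the
# study condition all soft-sensor tests run under: single batch, 240 h
# induction, 4 h offline assays, seeded sensor noise at instrument
# accuracies when noisy.

.fixture_cache <- new.env(parent = emptyenv())

default_campaign <- function(noisy = FALSE) {
  key <- if (noisy) "noisy" else "clean"
  if (is.null(.fixture_cache[[key]])) {
    cfg <- campaign_config(jitter_frac = 0)
    .fixture_cache[[key]] <- generate_campaign(cfg, seed = 1, noisy = noisy)
  }
  .fixture_cache[[key]]
}

tiny_campaign <- function() {
  if (is.null(.fixture_cache$tiny))
    .fixture_cache$tiny <- make_fixture("tiny", seed = 42)
  .fixture_cache$tiny
}

# operating point (state + feeds) at a given hour of the default campaign
operating_point <- function(t_h = 120) {
  camp <- default_campaign(noisy = FALSE)
  tr <- camp$trajectories[[1]]
  i <- which.min(abs(tr$t_h - t_h))
  list(state = trajectory_states(tr)[i, ],
       feeds = c(fC = tr$fC_Lh[i], fN = tr$fN_Lh[i],
                 fM = tr$fM_Lh[i], fA = tr$fA_Lh[i]),
       rates = default_rate_laws(camp$manifest$cfg$kinetics),
       config = camp$manifest$cfg$config)
}

# flatten network parameters / gradients into one vector (gradient checks)
flatten_params <- function(p) unlist(c(p$W, p$b), use.names = FALSE)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
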