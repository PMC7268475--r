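# Shared synthetic-field fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

small_spec <- function() field_spec(6, 5, plot_length_m = 2.5, seed = 31)

# a 30-plot field with noiseless yield, a 5 cm canopy reconstruction bias and
# known rigid perturbations, exercising every pipeline stage
small_field <- function() {
  fixture("small_field", function() {
    simulate_field(small_spec(), yield_sigma = 0, height_bias_m = 0.05,
                   perturb = list(list(yaw_deg = 0.8, t = c(0.2, 0.1, 0.03)),
                                  list(yaw_deg = -0.5, t = c(-0.1, 0.2, -0.02))))
  })
}

small_pipeline <- function() {
  fixture("small_pipeline", function() run_field_pipeline(small_field()))
}

# literal term-by-term biweight-midvariance oracle, independent of the
# vectorized implementation
bwmv_oracle <- function(x) {
  m <- median(x)
  madv <- median(abs(x - m))
  num <- 0; den <- 0
  for (xi in x) {
    U <- (xi - m) / (9 * madv)
    a <- if (abs(U) < 1) 1 else 0
    num <- num + a * (xi - m)^2 * (1 - U^2)^4
    den <- den + a * (1 - U^2) * (1 - 5 * U^2)
  }
  sqrt(length(x) * num / den^2)
}
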