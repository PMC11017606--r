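# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

fx_config <- function() synth_config(seed = 7)

fx_censuses <- function() memo("censuses", generate_censuses(fx_config()))
fx_u5mr <- function() memo("u5mr", generate_u5mr(fx_config()))
fx_coefs <- function() memo("coefs", read_logquad_coefs())
fx_dcmd <- function() memo(
  "dcmd", dcmd_estimate(fx_censuses()$censuses, fx_u5mr(), fx_coefs()))
fx_pipeline <- function() memo(
  "pipeline", run_pipeline(fx_config(), n_sims = 300))

# a small well-behaved abridged life table for toy checks
fx_toy_table <- function() {
  mx <- c(0.02, 0.004, 0.0012, 0.0009, 0.0011, 0.0014, 0.0016, 0.0019,
          0.0024, 0.0032, 0.0044, 0.0063, 0.0092, 0.014, 0.021, 0.033,
          0.052, 0.082, 0.13, 0.20, 0.30, 0.45)
  lifetable(mx, age_grid_abridged(100), sex = "female", year = 2000)
}

# invert qx back to mx under the table's ax (closed intervals)
qx_to_mx <- function(qx, n, ax) qx / (n - (n - ax) * qx)
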