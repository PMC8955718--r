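# Shared fixtures: synthetic runs are generated once and reused across
# test files (they are deterministic given the seed).

iou_interval <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  union <- max(a1, b1) - min(a0, b0)
  inter / union
}

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .run_cache)) assign(key, maker(), envir = .run_cache)
  get(key, envir = .run_cache)
}

noiseless_run <- function()
  cached("noiseless", function()
    generate_run(synth_config(sigma_px = 0, dropout = 0, outlier_frac = 0),
                 seed = 2))

default_run <- function()
  cached("default", function() generate_run(synth_config(), seed = 1))

default_analysis <- function()
  cached("default_sr", function() analyze_run(default_run()))

noiseless_analysis <- function()
  cached("noiseless_sr", function() analyze_run(noiseless_run()))

# dwell truth of one limb as a data.frame aligned with detected contacts
limb_truth <- function(run, limb) {
  d <- run$truth$dwell_intervals
  d[d$limb == limb, , drop = FALSE]
}
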