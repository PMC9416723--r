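# Shared fixtures: the packaged registry and exposure table are cheap to
# load, but doing it once keeps individual tests focused.
reg <- default_registry()
exposure <- default_exposure()

# distributions reconstructed from the Belgian children 3-PBA percentiles
# and the pooled excretion-fraction data
belgian_exposure_dist <- dist_loglogistic(2.025207, 1.687245)
fue_weibull <- dist_weibull(2.4009431, 0.3465461)

# published Tier-I ratio matrix (substance-specific biomarkers), cell values
# at their printed precision; the Germany/permethrin cell is excluded where
# noted because it contradicts its own printed p95 (see package notes)
published_rcr_cells <- tibble::tribble(
  ~country, ~population, ~substance, ~printed, ~digits,
  "Israel",      "children", "lambda-cyhalothrin", 0.085, 3,
  "Netherlands", "children", "lambda-cyhalothrin", 0.142, 3,
  "Belgium",     "children", "lambda-cyhalothrin", 0.086, 3,
  "Cyprus",      "children", "lambda-cyhalothrin", 0.029, 3,
  "Israel",      "children", "bifenthrin",         0.013, 3,
  "Netherlands", "children", "bifenthrin",         0.021, 3,
  "Belgium",     "children", "bifenthrin",         0.013, 3,
  "Cyprus",      "children", "bifenthrin",         0.004, 3,
  "Israel",      "children", "deltamethrin",       0.011, 3,
  "Netherlands", "children", "deltamethrin",       0.042, 3,
  "Belgium",     "children", "deltamethrin",       0.034, 3,
  "Cyprus",      "children", "deltamethrin",       0.044, 3,
  "France",      "children", "deltamethrin",       0.059, 3,
  "Israel",      "children", "cypermethrin",       0.17,  2,
  "Netherlands", "children", "cypermethrin",       0.15,  2,
  "Belgium",     "children", "cypermethrin",       0.25,  2,
  "Cyprus",      "children", "cypermethrin",       0.20,  2,
  "France",      "children", "cypermethrin",       0.108, 3,
  "Israel",      "children", "permethrin",         0.016, 3,
  "Netherlands", "children", "permethrin",         0.014, 3,
  "Belgium",     "children", "permethrin",         0.02,  2,
  "Cyprus",      "children", "permethrin",         0.02,  2,
  "France",      "children", "permethrin",         0.01,  2,
  "Israel",      "children", "cyfluthrin",         0.013, 3,
  "France",      "children", "cyfluthrin",         0.004, 3,
  "Slovenia",    "children", "cyfluthrin",         0.018, 3,
  "Switzerland", "adults",   "lambda-cyhalothrin", 0.031, 3,
  "Germany",     "adults",   "lambda-cyhalothrin", 0.019, 3,
  "Israel",      "adults",   "lambda-cyhalothrin", 0.075, 3,
  "Switzerland", "adults",   "bifenthrin",         0.005, 3,
  "Germany",     "adults",   "bifenthrin",         0.003, 3,
  "Israel",      "adults",   "bifenthrin",         0.012, 3,
  "Switzerland", "adults",   "deltamethrin",       0.0068, 4,
  "Germany",     "adults",   "deltamethrin",       0.0041, 4,
  "Israel",      "adults",   "deltamethrin",       0.0032, 4,
  "France",      "adults",   "deltamethrin",       0.041, 3,
  "Switzerland", "adults",   "cypermethrin",       0.036, 3,
  "Germany",     "adults",   "cypermethrin",       0.019, 3,
  "Israel",      "adults",   "cypermethrin",       0.068, 3,
  "France",      "adults",   "cypermethrin",       0.053, 3,
  "Switzerland", "adults",   "permethrin",         0.003, 3,
  "Israel",      "adults",   "permethrin",         0.006, 3,
  "France",      "adults",   "permethrin",         0.005, 3,
  "France",      "adults",   "cyfluthrin",         0.003, 3
)
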