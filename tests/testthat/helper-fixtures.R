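# Lazily-built fixtures shared across test files (built once per run).
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# one noise-free, debris-free specimen
clean_specimen <- function() cached("clean", function()
  generate_specimen(synthetic_spec(seed = 42, noise_sigma = 0,
                                   debris_count = 0)))

# one specimen at default noise and debris
noisy_specimen <- function() cached("noisy", function()
  generate_specimen(synthetic_spec(seed = 1)))

# 52-specimen default cohort: 40 training + 12 held-out for the learned
# segmenter
model_cohort <- function() cached("model_cohort", function()
  generate_cohort(52, "default", seed = 99))

# the trained pixel-classifier model (40 pairs, 10 epochs, seed 7)
trained_model <- function() cached("trained_model", function() {
  pairs <- lapply(model_cohort()[1:40], function(s)
    list(image = s$image, labels = s$truth$pore_mask))
  train_pore_model(pairs, epochs = 10L, seed = 7L)
})

# 50-specimen cohorts for segmentation-recovery checks
cohort_clean50 <- function() cached("cohort_clean50", function()
  generate_cohort(50, "default", seed = 2024,
                  base_spec = synthetic_spec(noise_sigma = 0,
                                             debris_count = 0)))

cohort_noisy50 <- function() cached("cohort_noisy50", function()
  generate_cohort(50, "default", seed = 2024))

# whole-test ROI (no window restriction) for measuring against ground truth
whole_test_roi <- function(g) {
  list(mask = g$truth$chamber_map$labels > 0, area = g$truth$test_area_um2)
}

# ground-truth pore table restricted to visible pores
visible_truth <- function(g) {
  tr <- g$truth$true_params$pores
  tr[!tr$occluded, ]
}
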