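# Small in-code fixtures shared across test files.

# Random-noise bag (no lesion structure) for shape/invariance checks.
noise_bag <- function(n_images = 3, size = 16, seed = 1, label = 1L) {
  set.seed(seed)
  image_bag(paste0("N", seed),
            lapply(seq_len(n_images), function(i) matrix(runif(size * size),
                                                         size, size)),
            label)
}

# A tiny simulated, preprocessed dataset: returns list(train, test).
tiny_split <- function(n_bags = 16, seed = 3, image_size = 32,
                       witness_rate = 0.5, lesion_contrast = 0.5) {
  bags <- generate_dataset(sim_config(
    n_bags = n_bags, bag_size_range = c(2L, 4L), witness_rate = witness_rate,
    image_size = image_size, lesion_contrast = lesion_contrast, seed = seed))
  pp <- preprocess_spec(target_size = image_size)
  sp <- split_by_patient(bags, seed = seed)
  list(train = preprocess_bags(sp$train, pp, rng_seed = seed),
       test = preprocess_bags(sp$test, pp, rng_seed = seed + 500L))
}

random_attention_params <- function(feature_dim = 512, hidden = 128,
                                    seed = 1) {
  set.seed(seed)
  attention_params(feature_dim, hidden)
}

pred_df_acc <- function(label, prob) {
  data.frame(patient_id = sprintf("P%03d", seq_along(label)), label = label,
             probability = prob)
}
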