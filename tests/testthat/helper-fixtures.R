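# shared fixtures built in code

# a quiet, exactly periodic recording: b = 1, no noise, no asymmetry
clean_recording <- function(period_samples = 20, duration = 60, b = 1,
                            seed = 1) {
  set.seed(seed)
  cfg <- gen_config(duration = duration, noise_sd = 0, asymmetry_gain = 0,
                    sensor_gain_sd = 0, width_sd = 0)
  generate_recording(b, cfg, stride_period = period_samples / 20)$recording
}

# standardized feature matrix with labels linear in a known feature subset;
# all other columns are independent noise
linear_cohort <- function(n = 131, d = 156, k_true = 10, noise_sd = 1,
                          seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  colnames(x) <- if (d == 156) feature_names() else sprintf("f%03d", seq_len(d))
  true_idx <- seq_len(k_true)
  beta <- seq(3, 1.2, length.out = k_true)
  y <- as.vector(x[, true_idx] %*% beta) + rnorm(n, 0, noise_sd)
  list(x = x, y = y, true_features = colnames(x)[true_idx], beta = beta)
}
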