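# Shared fixtures, built once per test run.

# small balanced clip table (5 per class) and its model-ready form
tiny_cfg <- synth_config(n_per_class = 5, cycle_duration_s = c(1, 2.5), seed = 101)
tiny_clips <- synth_dataset(tiny_cfg)
tiny_pp <- preprocess_config(seed = 101)
tiny_dm <- prepare_dataset(tiny_clips, tiny_pp)

# a small architecture usable for fast training tests
tiny_arch <- function(input_len = 64, n_classes = 4, dropout_rate = 0.1) {
  arch_spec(input_len, list(
    conv1d(4, 5), maxpool1d(2), dropout(dropout_rate),
    conv1d(8, 3), maxpool1d(2),
    flatten(),
    dense(16), dropout(dropout_rate),
    dense(n_classes, activation = "softmax")
  ))
}

# random dataset_matrix with rows drawn from class-specific Gaussians,
# linearly separable enough for quick sanity training
random_dm <- function(n_per_class = 8, len = 64, seed = 1, sdev = 0.3) {
  set.seed(seed)
  classes <- class_levels()
  X <- do.call(rbind, lapply(seq_along(classes), function(ci) {
    centre <- sin(2 * pi * ci * seq_len(len) / len)
    t(replicate(n_per_class, centre + rnorm(len, 0, sdev)))
  }))
  dataset_matrix(X, rep(classes, each = n_per_class))
}

# brute-force metric oracle: per-class precision/recall/F1 from first
# principles, one comparison pair at a time
oracle_metrics <- function(truth, pred, classes = class_levels()) {
  truth <- as.character(truth); pred <- as.character(pred)
  acc <- mean(truth == pred)
  per <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  })
  list(accuracy = acc, per_class = do.call(rbind, per))
}
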