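# Shared fixtures, built in code at test time.

fix_montage <- function(n = 19L, seed = 1L) generate_montage(n, seed)

fix_templates <- function(n = 19L, seed = 7L, K = 4L)
  generate_templates(K, fix_montage(n), seed = seed)

# K orthonormal zero-mean maps on n channels (exactly separable cluster truth)
orthogonal_maps <- function(n = 19L, K = 4L, seed = 42L) {
  set.seed(seed)
  m <- matrix(rnorm(n * (K + 1L)), n)
  m <- sweep(m, 2L, colMeans(m))       # zero-mean columns
  q <- qr.Q(qr(m))[, seq_len(K), drop = FALSE]
  apply(q, 2L, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
}

# quick spec for small simulations
fix_spec <- function(record_length = 20, n_subjects_per_group = 3L, ...) {
  sim_spec(n_subjects_per_group = n_subjects_per_group, n_channels = 16L,
           fs = 250, record_length = record_length, seed = 5L, ...)
}

with_seed_shuffle <- function(x, seed = 1234L) {
  set.seed(seed)
  sample(x)
}

# a label sequence from explicit class letters, single epoch
labels_from_chars <- function(chars, fs = 100, classes = c("A", "B", "C", "D"),
                              epoch = NULL) {
  label_sequence(match(chars, classes), fs, classes, epoch = epoch)
}
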