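# Shared fixtures built in code at test time.

# A small count matrix with lengths and known values.
tiny_counts <- function() {
  counts <- matrix(c(10, 0, 5,
                     100, 50, 25,
                     3, 3, 3,
                     0, 0, 0), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  count_matrix(counts, lengths = c(g1 = 1000, g2 = 500, g3 = 2000,
                                   g4 = 100))
}

# A compact synthetic configuration for fast module tests.
small_sim_config <- function(seed = 1, ...) {
  simulate_config(n_genes = 200, n_mirnas = 20, n_tfs = 8,
                  n_true_edges = 6, n_de_genes = 20, n_de_mirnas = 8,
                  n_stage_genes = 25, n_tf_modules = 2, tf_module_size = 4,
                  utr_len = 300, seed = seed, ...)
}

# Build a pair of expression "profiles" with an exact sample Pearson
# correlation r between them (unit-variance construction on n samples).
profiles_with_r <- function(r, n = 6) {
  x <- seq_len(n)
  zx <- (x - mean(x)) / stats::sd(x)
  w <- stats::rnorm(n)
  w <- stats::residuals(stats::lm(w ~ zx))
  zw <- (w - mean(w)) / stats::sd(w)
  y <- r * zx + sqrt(1 - r^2) * zw
  list(x = zx, y = y)
}
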