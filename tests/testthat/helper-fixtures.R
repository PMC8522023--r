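# Shared fixtures: tiny networks and datasets built in code.

# single isolated neuron biased at voltage V
one_neuron_weights <- function(V = 0) {
  network_weights(matrix(0, 1, 1), matrix(0, 1, 1), V,
                  matrix(0, 2, 1), c(0, 0), n_input = 1L)
}

# small random network with voltage-scale weights
small_net <- function(n_hidden = 2L, n_inputs = 1L, seed = 1L,
                      params = mems_params()) {
  init_network(n_hidden, n_inputs, seed = seed, params = params)
}

# labeled ternary toy dataset: n_pos dense-symbol windows vs sparse ones
toy_ternary_dataset <- function(n_pos = 10L, n_neg = 90L, O = 3L, l = 16L,
                                seed = 5L) {
  with_seed(seed, {
    n <- n_pos + n_neg
    w <- array(0L, dim = c(O, l, n))
    for (j in seq_len(n_pos))
      w[, , j] <- matrix(sample(c(-1L, 1L), O * l, TRUE), O, l)
    for (j in n_pos + seq_len(n_neg))
      w[, , j] <- matrix(sample(c(-1L, 0L, 0L, 0L, 1L), O * l, TRUE), O, l)
    windowed_dataset(w, labels = rep(c(1L, 0L), c(n_pos, n_neg)),
                     quantized = TRUE)
  })
}

with_seed <- memsctrnn:::with_seed

# equilibrium displacements of one neuron at voltage V: roots of
# z (d - z)^2 = c1 V^2 on (0, d)
equilibrium_roots <- function(params, V) {
  ph <- memsctrnn:::mems_derived(params)
  r <- polyroot(c(-ph$c1 * V^2, ph$d^2, -2 * ph$d, 1))
  r <- Re(r[abs(Im(r)) < 1e-9 * ph$d])
  sort(r[r > 0 & r < ph$d])
}
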