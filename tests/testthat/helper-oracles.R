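# Independent oracles and small shared fixtures.

# Airy single-film reflection/transmission from the summed multiple-
# reflection series (independent of the matrix code path)
airy_film <- function(n0, n1, n2, d_nm, wavelength_nm) {
  r01 <- (n0 - n1) / (n0 + n1); r12 <- (n1 - n2) / (n1 + n2)
  t01 <- 2 * n0 / (n0 + n1);    t12 <- 2 * n1 / (n1 + n2)
  delta <- 2 * pi * n1 * d_nm / wavelength_nm
  den <- 1 + r01 * r12 * exp(2i * delta)
  list(r = (r01 + r12 * exp(2i * delta)) / den,
       t = t01 * t12 * exp(1i * delta) / den)
}

const_mat <- function(n, k = 0, id = "m") {
  dispersion_table(id, c(1, 1e7), c(n, n), c(k, k))
}

single_film_stack <- function(n1, d_nm, n0 = 1, n2 = 1, k1 = 0) {
  optical_stack(list(layer(const_mat(Re(n1), k1, "film"), d_nm)),
                incident = const_mat(n0, 0, "inc"),
                substrate = const_mat(n2, 0, "sub"))
}

tiny_unet <- function(L = 64, seed = 1)
  build_unet(unet_config(channels = c(4, 8), bottleneck = 16, kernel = 5),
             input_length = L, seed = seed)

random_pair_set <- function(n, L, seed = 1, recipe = "A_times") {
  set.seed(seed)
  structure(list(axis = seq_len(L), clean = matrix(runif(n * L), n),
                 corrupted = matrix(runif(n * L), n),
                 design_id = rep(1L, n), recipe = recipe, seed = seed),
            class = "pair_set")
}
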