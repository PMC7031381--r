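# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache))
    assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A small but realistic energy matrix derived from synthetic helix
# structures; all 20 residue types occur, with imputation warnings
# suppressed (expected on fixtures this small).
fixture_energy <- function() memo("energy", {
  structs <- lapply(1:8, function(i) gen_structure_fixture(60, "helix",
                                                           seed = i))
  suppressWarnings(energy_matrix(count_contacts(structs, "calpha")))
})

fixture_hla_pool <- function() memo("pool", gen_hla_pool(2, "A", seed = 3))

fixture_hla <- function() memo("hla", {
  pool <- fixture_hla_pool()
  prepare_hla(pool$allele[1], pool$sequence[1])
})

# A dense random energy matrix for lookup-oracle tests.
fixture_random_energy <- function(seed = 7) {
  V <- withr::with_seed(seed, matrix(rnorm(400), 20, 20))
  as_energy_matrix((V + t(V)) / 2)
}

random_peptides <- function(n, P = 9, seed = 1) {
  withr::with_seed(seed, {
    apply(matrix(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                        n * P, replace = TRUE), n, P),
          1, paste, collapse = "")
  })
}

# A tiny CNN config that trains in well under a second.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_kernels1 = 4L, n_kernels2 = 3L, window = 3L,
                   n_hidden = 6L, batch_size = 20L, learning_rate = 3e-4,
                   momentum = 0.9, lambda1 = 1e-4, lambda2 = 1e-4,
                   lambda3 = 3, epochs = 2L, seed = 1L)
  do.call(model_config, utils::modifyList(defaults, args))
}
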