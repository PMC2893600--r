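# Small deterministic fixtures shared across tests.

# tiny balanced target-species sample sheet: 2 genotypes x 2 tissues x R
tiny_samples <- function(R = 3, species = "target") {
  g <- expand.grid(replicate = seq_len(R), tissue = c("ES", "PES"),
                   genotype = c("gA", "gB"), stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("s%02d", seq_len(nrow(g))),
    species = species, genotype = g$genotype, tissue = g$tissue,
    replicate = g$replicate
  )
}

# random positive probe matrix with rownames/colnames
tiny_matrix <- function(n_probes = 20, samples = tiny_samples(), seed = 1) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_probes * nrow(samples), 8, 1.5), n_probes,
              dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                              samples$sample_id))
  probe_matrix(m, "linear")
}

# probe map assigning consecutive probes to sets of size k
tiny_map <- function(probe_ids, k = 4) {
  n <- length(probe_ids)
  sets <- sprintf("set%03d", rep(seq_len(ceiling(n / k)), each = k))[seq_len(n)]
  data.frame(probe_id = probe_ids, probeset_id = sets,
             probe_index = ave(seq_len(n), sets, FUN = seq_along))
}

# small simulated dataset cached per test file run
small_sim <- function(seed = 42, n_probesets = 300, ...) {
  simulate_csh(sim_config(n_probesets = n_probesets, seed = seed, ...))
}
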