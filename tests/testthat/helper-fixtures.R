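# Shared synthetic fixtures, built once per test run.

sim_cache <- new.env()

default_sim <- function(seed = 7L) {
  key <- paste0("sim", seed)
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- simulate_family(family_sim_config(seed = seed))
  }
  sim_cache[[key]]
}

write_tmp_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  f
}
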