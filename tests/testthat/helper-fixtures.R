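# Shared fixtures built in code. The reference annotation layout ships with
# the package; synthetic genomes are generated once per session and reused.

ref_ann <- function() suppressMessages(reference_layout())

.sim_cache <- new.env(parent = emptyenv())

# one synthetic mitogenome reused across test files (fixed seed)
sim_bundle <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- generate_mitogenome(synthetic_genome_spec(), seed = seed)
  .sim_cache[[key]]
}

# small linear helper annotation from a compact spec
toy_ann <- function(starts, ends, classes = "PCG", strands = "F",
                    names = NULL, genome_length = NULL, circular = TRUE) {
  n <- length(starts)
  if (is.null(names)) names <- paste0("g", seq_len(n))
  suppressMessages(annotation_table(
    data.frame(name = names, class = rep_len(classes, n),
               strand = rep_len(strands, n), start = starts, end = ends,
               stringsAsFactors = FALSE),
    genome_length = genome_length, circular = circular))
}

random_dna <- function(n, freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}
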