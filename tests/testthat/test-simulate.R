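# Synthetic mitogenome generator: determinism, closure, layout replay,
# composition targets, sequence evolution.

test_that("generation is a pure function of (spec, seed)", {
  spec <- synthetic_genome_spec()
  g1 <- generate_mitogenome(spec, seed = 3)
  g2 <- generate_mitogenome(spec, seed = 3)
  expect_identical(g1$genome$seq, g2$genome$seq)
  expect_identical(as.data.frame(g1$annotation), as.data.frame(g2$annotation))
  g3 <- generate_mitogenome(spec, seed = 4)
  expect_false(identical(g1$genome$seq, g3$genome$seq))

  # byte-identical files from the same seed
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g1$genome, f1)
  write_genome_fasta(g2$genome, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(g1$annotation, t1)
  write_annotation_tsv(g2$annotation, t2)
  expect_identical(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))
})

test_that("inconsistent closure arithmetic is rejected before sampling", {
  genes <- data.frame(name = c("a", "b"), class = "PCG", strand = "F",
                      length = c(9L, 9L), gap_after = c(1L, 1L))
  expect_error(layout_from_gaps(genes, genome_length = 25L), "closure")
  ok <- suppressMessages(layout_from_gaps(genes, genome_length = 20L))
  expect_equal(ok$start, c(1L, 11L))
  expect_equal(ok$end, c(9L, 19L))
})

test_that("generated genomes replay the published layout exactly", {
  bundle <- sim_bundle()
  rep <- layout_summary(bundle$annotation, mode = "computed")
  expect_equal(rep$total_overlap_bp, 34)
  expect_equal(rep$max_overlap$bp, 8)
  expect_equal(rep$max_spacer$bp, 52)
  adj <- adjacency_distances(bundle$annotation)
  lens <- bundle$annotation$end - bundle$annotation$start + 1L
  expect_equal(sum(lens) + sum(adj$signed_gap), genome_length(bundle$annotation))
  expect_equal(nchar(bundle$genome$seq), 15376)
})

test_that("PCGs honor start codons and length-consistent stops", {
  bundle <- sim_bundle()
  df <- as.data.frame(bundle$annotation)
  pcg <- df[df$class == "PCG", ]
  for (i in seq_len(nrow(pcg))) {
    cds <- extract_gene_sequence(bundle$genome, pcg[i, ])
    call <- detect_start_stop(cds, pcg$name[i])
    expect_equal(call$start_codon, pcg$start_codon[i], info = pcg$name[i])
    expect_equal(call$stop_codon, pcg$stop_codon[i], info = pcg$name[i])
    expect_equal(call$stop_is_complete, nchar(pcg$stop_codon[i]) == 3L,
                 info = pcg$name[i])
    expect_false(call$stop_anomalous)
  }
  # the cox1 analogue keeps its published non-canonical CGA start
  expect_equal(pcg$start_codon[pcg$name == "cox1"], "CGA")
  expect_equal(pcg$stop_codon[pcg$name == "cox1"], "T")
})

test_that("realized composition tracks the mixture target across seeds", {
  spec <- synthetic_genome_spec()
  errs <- vapply(1:20, function(s) {
    g <- generate_mitogenome(spec, seed = 200 + s)
    abs(base_composition(g$genome)$at_content / 100 - spec$at_target)
  }, numeric(1))
  expect_lt(mean(errs), 0.01)
  expect_lt(max(errs), 0.02)  # every 15 kb genome within 2 points of target
})

test_that("codon bias planted in the profile shows up downstream", {
  prof <- default_codon_profile()
  prof[] <- prof / sum(prof)
  prof["AAT"] <- prof["AAT"] + 1  # strong Asn bias
  prof <- prof / sum(prof)
  spec <- synthetic_genome_spec(codon_profile = prof)
  g <- generate_mitogenome(spec, seed = 77)
  tab <- codon_usage(g$genome, g$annotation)
  expect_equal(rank_amino_acids(tab)[1], "Asn")
  expect_gt(suppressMessages(rscu(tab))["AAT"], 1)
})

test_that("evolution along a star tree of zero lengths is a no-op", {
  star <- ape::stree(5, type = "star", tip.label = paste0("t", 1:5))
  star$edge.length <- rep(0, nrow(star$edge))
  aln <- evolve_alignment(star, 200, seed = 8)
  expect_equal(nrow(unique(aln)), 1)
  p <- pairwise_distances(concatenate(list(g = aln)), "p")
  expect_true(all(p == 0))
})

test_that("two-taxon JC69 distances recover the generating branch length", {
  tr <- ape::read.tree(text = "(x:0.05,y:0.05);")
  aln <- evolve_alignment(tr, 10000, seed = 13)
  d <- pairwise_distances(concatenate(list(g = aln)), "JC69")["x", "y"]
  true_d <- 0.1
  p_true <- 0.75 * (1 - exp(-4 * true_d / 3))
  se <- sqrt(p_true * (1 - p_true) / 10000) / (1 - 4 * p_true / 3)
  expect_lt(abs(d - true_d), 3 * se)
})

test_that("a planted superfamily clade is recovered by NJ on simulated data", {
  demo <- demo_lepidoptera_tree()
  alns <- evolve_partitions(demo$tree,
                            stats::setNames(rep(150L, 13), paste0("pcg", 1:13)),
                            seed = 6)
  sm <- concatenate(alns)
  tree <- nj_tree(pairwise_distances(sm, "JC69"))
  expect_true(check_monophyly(tree, demo$noctuoidea, demo$outgroup))
})
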