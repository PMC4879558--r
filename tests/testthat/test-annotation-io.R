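# Annotation table / GenBank / FASTA IO and strand-aware sequence extraction.

test_that("the shipped annotation fixture loads with the published layout", {
  ann <- ref_ann()
  expect_s3_class(ann, "annotation_table")
  expect_equal(nrow(ann), 38)  # 13 PCGs + 22 tRNAs + 2 rRNAs + control region
  expect_equal(genome_length(ann), 15376)
  expect_equal(as.vector(table(ann$class)[c("PCG", "tRNA", "rRNA", "control_region")]),
               c(13L, 22L, 2L, 1L))
  trnM <- ann[ann$name == "trnM", ]
  expect_equal(trnM$end - trnM$start + 1, 67)
  expect_equal(trnM$anticodon, "CAT")
  cox1 <- ann[ann$name == "cox1", ]
  expect_equal(cox1$start_codon, "CGA")
  expect_equal(cox1$stop_codon, "T")
})

test_that("TSV reading validates rows and honors directives", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#genome_length=10",
               "Gene\tClass\tDirection\tStart\tEnd",
               "g1\tPCG\tF\t1\t3"), tf)
  ann <- suppressMessages(read_annotation_tsv(tf))
  expect_equal(nrow(ann), 1)
  expect_equal(ann$end - ann$start + 1, 3)
  expect_equal(genome_length(ann), 10)

  writeLines(c("Gene\tClass\tDirection\tStart\tEnd",
               "g1\tPCG\tF\t10\t5"), tf)
  expect_error(suppressMessages(read_annotation_tsv(tf)), "start > end")

  writeLines(c("Gene\tClass\tDirection\tStart\tEnd",
               "g1\tPCG\tF\t1\tx5"), tf)
  expect_error(suppressMessages(read_annotation_tsv(tf)), "non-integer")

  writeLines(c("Gene\tClass\tDirection\tStart\tEnd",
               "g1\tPCG\tF\t1\t6", "g1\tPCG\tF\t8\t12"), tf)
  expect_error(suppressMessages(read_annotation_tsv(tf)), "duplicate")

  writeLines(c("Gene\tClass\tDirection\tStart\tEnd\tSize",
               "g1\tPCG\tF\t1\t6\t7"), tf)
  expect_warning(suppressMessages(read_annotation_tsv(tf)), "Size")
})

test_that("TSV write-then-read round trips are field-identical", {
  ann <- ref_ann()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, tf)
  back <- suppressMessages(suppressWarnings(read_annotation_tsv(tf)))
  expect_identical(as.data.frame(back), as.data.frame(ann))
  expect_identical(genome_length(back), genome_length(ann))
  expect_identical(attr(back, "circular"), attr(ann, "circular"))
})

test_that("GenBank features map onto the annotation model", {
  gb <- c("LOCUS       test     200 bp  DNA  circular  INV",
          "FEATURES             Location/Qualifiers",
          "     source          1..200",
          "     CDS             1..9",
          "                     /gene=\"nad2\"",
          "     tRNA            complement(5..10)",
          "                     /gene=\"trnQ\"",
          "                     /anticodon=\"(pos:7..9,aa:Gln,seq:ttg)\"",
          "     misc_feature    150..200",
          "                     /note=\"A+T-rich region\"",
          "ORIGIN", "//")
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tf)
  ann <- suppressMessages(read_genbank_features(tf))
  expect_equal(nrow(ann), 3)
  expect_equal(ann$class, c("PCG", "tRNA", "control_region"))
  expect_equal(ann$strand[1:2], c("F", "R"))
  expect_equal(ann[2, c("start", "end")], data.frame(start = 5L, end = 10L),
               ignore_attr = TRUE)
  expect_equal(ann$anticodon[2], "TTG")
  expect_equal(genome_length(ann), 200)

  gb2 <- sub("1\\.\\.9", "join(190..200,1..9)", gb)
  writeLines(gb2, tf)
  expect_error(suppressMessages(read_genbank_features(tf)),
               "origin-spanning")
})

test_that("gene extraction is strand-aware and length-preserving", {
  g <- genome_sequence("toy", "AAACGTTT", circular = FALSE)
  expect_equal(extract_gene_sequence(g, list(strand = "F", start = 4, end = 6)), "CGT")
  expect_equal(extract_gene_sequence(g, list(strand = "R", start = 4, end = 6)), "ACG")
  expect_error(extract_gene_sequence(g, list(strand = "F", start = 5, end = 9)),
               "beyond")
  bundle <- sim_bundle()
  df <- as.data.frame(bundle$annotation)
  lens <- vapply(seq_len(nrow(df)), function(i)
    nchar(extract_gene_sequence(bundle$genome, df[i, ])), integer(1))
  expect_equal(lens, df$end - df$start + 1L)
  # reverse-complement involution: flipping an R-strand extraction recovers
  # the forward substring
  r <- df[df$strand == "R", ][1, ]
  fwd <- substr(bundle$genome$seq, r$start, r$end)
  rc <- extract_gene_sequence(bundle$genome, r)
  expect_identical(as.character(Biostrings::reverseComplement(Biostrings::DNAString(rc))),
                   fwd)
})

test_that("FASTA write-then-read round trips the genome", {
  bundle <- sim_bundle()
  tf <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(bundle$genome, tf)
  back <- read_genome_fasta(tf)
  expect_identical(back$seq, bundle$genome$seq)
})

test_that("invalid annotation tables are rejected", {
  expect_error(toy_ann(1, 5, classes = "gene"), "feature class")
  expect_error(suppressMessages(annotation_table(
    data.frame(name = "g1", class = "PCG", strand = "F", start = 1, end = 5,
               anticodon = "CAT"))), "anticodon")
  expect_error(toy_ann(c(1, 3), c(5, 9), genome_length = 7), "genome_length")
})
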