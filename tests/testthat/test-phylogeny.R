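# Supermatrix assembly, block selection, distances, NJ, bootstrap, monophyly.

aln4 <- function() {
  list(g1 = rbind(A = strsplit("AAAAAA", "")[[1]],
                  B = strsplit("AAAAAT", "")[[1]],
                  C = strsplit("AATTTT", "")[[1]],
                  D = strsplit("TTTTTT", "")[[1]]))
}

test_that("concatenation joins partitions and validates taxon sets", {
  m1 <- matrix("A", 4, 6, dimnames = list(c("A", "B", "C", "D"), NULL))
  m2 <- matrix("T", 4, 9, dimnames = list(c("D", "C", "B", "A"), NULL))
  sm <- concatenate(list(x = m1, y = m2))
  expect_equal(ncol(sm$mat), 15)
  expect_equal(sm$partitions$gene, c("x", "y"))
  expect_equal(sm$partitions$end, c(6L, 15L))
  expect_equal(rownames(sm$mat), c("A", "B", "C", "D"))

  one <- concatenate(list(solo = m1))
  expect_equal(dim(one$mat), dim(m1))

  m3 <- m2[1:3, ]
  expect_error(concatenate(list(x = m1, y = m3)), "taxon sets differ")
})

test_that("partition spans tile the generated supermatrix width", {
  demo <- demo_lepidoptera_tree()
  alns <- evolve_partitions(demo$tree, stats::setNames(rep(60L, 13), paste0("p", 1:13)),
                            seed = 2)
  sm <- concatenate(alns)
  expect_equal(nrow(sm$partitions), 13)
  expect_equal(sm$partitions$start[1], 1L)
  expect_equal(sm$partitions$end[13], ncol(sm$mat))
  expect_true(all(sm$partitions$start[-1] == utils::head(sm$partitions$end, -1) + 1L))
})

test_that("block selection keeps conserved gap-free runs of sufficient length", {
  m <- matrix("A", 4, 12, dimnames = list(letters[1:4], NULL))
  sm <- concatenate(list(g = m))
  expect_true(all(select_blocks(sm)))

  m2 <- m
  m2[1, 5] <- "-"  # one gap splits the run into 4 + 7: only the 7 survives
  sm2 <- concatenate(list(g = m2))
  expect_equal(select_blocks(sm2), c(rep(FALSE, 5), rep(TRUE, 7)))

  m3 <- rbind(a = rep("A", 8), b = rep("C", 8), c = rep("G", 8), d = rep("T", 8))
  sm3 <- concatenate(list(g = m3))
  expect_warning(mask <- select_blocks(sm3), "no column")
  expect_false(any(mask))

  masked <- apply_mask(sm2, select_blocks(sm2))
  expect_equal(ncol(masked$mat), 7)
  expect_equal(masked$partitions$end, 7L)
})

test_that("distance models follow their closed forms", {
  sm <- concatenate(aln4())
  p <- pairwise_distances(sm, "p")
  expect_true(isSymmetric(p))
  expect_equal(diag(p), stats::setNames(rep(0, 4), LETTERS[1:4]))
  expect_equal(p["A", "B"], 1 / 6)
  expect_equal(p["A", "D"], 1)

  m <- rbind(a = strsplit("AAAA", "")[[1]], b = strsplit("AAAT", "")[[1]])
  sm2 <- concatenate(list(g = rbind(m, c = strsplit("AAAA", "")[[1]])))
  p2 <- pairwise_distances(sm2, "p")
  expect_equal(p2["a", "b"], 0.25)
  jc <- pairwise_distances(sm2, "JC69")
  expect_equal(round(jc["a", "b"], 4), 0.3041)  # -0.75 log(2/3)
  expect_equal(jc["a", "c"], 0)

  expect_error(pairwise_distances(sm, "JC69"), "saturation")
})

test_that("distances agree with an independent implementation", {
  set.seed(10)
  m <- matrix(sample(c("A", "C", "G", "T"), 8 * 300, replace = TRUE), 8,
              dimnames = list(paste0("t", 1:8), NULL))
  # soften divergence so JC/K2P are defined: copy with sprinkled changes
  base <- m[1, ]
  for (i in 1:8) {
    row <- base
    mut <- sample(300, 30 + 5 * i)
    row[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
    m[i, ] <- row
  }
  sm <- concatenate(list(g = m))
  bin <- ape::as.DNAbin(matrix(tolower(m), nrow = nrow(m),
                               dimnames = dimnames(m)))
  for (pair in list(c("p", "raw"), c("JC69", "JC69"), c("K2P", "K80"))) {
    mine <- pairwise_distances(sm, pair[1])
    theirs <- as.matrix(ape::dist.dna(bin, model = pair[2],
                                      pairwise.deletion = TRUE))
    expect_equal(mine, theirs[rownames(mine), colnames(mine)],
                 tolerance = 1e-10, info = pair[1])
  }
})

test_that("gapped sites are dropped per pair (pairwise deletion)", {
  m <- rbind(a = strsplit("AA-ATT", "")[[1]],
             b = strsplit("AAAA-T", "")[[1]],
             c = strsplit("AAAATT", "")[[1]])
  p <- pairwise_distances(concatenate(list(g = m)), "p")
  expect_equal(p["a", "b"], 0)   # 4 comparable, all equal
  expect_equal(p["a", "c"], 0)
  expect_equal(p["b", "c"], 0)
  m2 <- rbind(a = strsplit("--AA", "")[[1]], b = strsplit("AA--", "")[[1]])
  expect_error(pairwise_distances(concatenate(list(g = m2)), "p"),
               "no comparable")
})

test_that("NJ recovers the topology of additive distances on all small shapes", {
  for (ntax in 4:5) {
    shapes <- phangorn::allTrees(ntax, rooted = FALSE,
                                 tip.label = letters[1:ntax])
    for (k in seq_along(shapes)) {
      tr <- shapes[[k]]
      set.seed(100 + k)
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.4)
      dm <- ape::cophenetic.phylo(tr)
      got <- nj_tree(dm)
      expect_equal(phangorn::RF.dist(got, tr), 0,
                   info = sprintf("ntax=%d shape=%d", ntax, k))
    }
  }
})

test_that("NJ is invariant to taxon input order and clamps negative edges", {
  demo <- demo_lepidoptera_tree()
  dm <- ape::cophenetic.phylo(demo$tree)
  t1 <- nj_tree(dm)
  perm <- sample(rownames(dm))
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(phangorn::RF.dist(t1, t2), 0)
  expect_true(all(t1$edge.length >= 0))
  expect_error(nj_tree(dm[1:2, 1:2]), "3 taxa")
})

test_that("bootstrap is seed-deterministic and supports clean signal", {
  set.seed(77)
  tr <- ape::read.tree(text = "((A:0.05,B:0.05):0.08,(C:0.05,D:0.05):0.08);")
  aln <- evolve_alignment(tr, 800, seed = 5)
  sm <- concatenate(list(g = aln))
  b1 <- bootstrap_support(sm, n_reps = 100, seed = 42)
  b2 <- bootstrap_support(sm, n_reps = 100, seed = 42)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  supp <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(any(supp >= 95, na.rm = TRUE))
  expect_true(all(supp >= 0 & supp <= 100, na.rm = TRUE))
})

test_that("identical sequences give a star tree with no supports", {
  m <- matrix("A", 4, 50, dimnames = list(LETTERS[1:4], NULL))
  sm <- concatenate(list(g = m))
  expect_message(st <- bootstrap_support(sm, n_reps = 5, seed = 1), "star")
  expect_equal(ape::Ntip(st), 4)
  expect_equal(st$Nnode, 1)  # fully unresolved
})

test_that("Newick round trips preserve topology, lengths and supports", {
  set.seed(3)
  tr <- ape::rtree(8)
  tr$node.label <- c("", as.character(seq_len(tr$Nnode - 1) * 10))
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tf)
  back <- read_newick(tf)
  expect_equal(phangorn::RF.dist(back, tr), 0)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-9)
  expect_identical(back$node.label, tr$node.label)
})

test_that("monophyly testing roots on the outgroup", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(check_monophyly(tr, c("A", "B"), "D"))
  expect_false(check_monophyly(tr, c("A", "C"), "D"))
  expect_error(check_monophyly(tr, c("A", "Z"), "D"), "unknown")
  expect_error(check_monophyly(tr, c("A", "B"), "A"), "overlap")
})
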