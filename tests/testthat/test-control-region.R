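# Control-region motif grammar and tandem-repeat detection.

test_that("the motif grammar is detected with exact tract parameters", {
  region <- paste0("CCGCG", "ATAGA", strrep("T", 19), "CAGCG",
                   "ATTTA", strrep("AT", 6), "GCGCC",
                   "CGC", strrep("A", 8))
  hits <- scan_motifs(region)
  expect_equal(nrow(hits), 3)
  h1 <- hits[hits$kind == "ATAGA_polyT", ]
  expect_equal(h1$tract_length, 19)
  expect_equal(h1$gap, 0)
  expect_equal(h1$start, 6)
  h2 <- hits[hits$kind == "ATTTA_microsat", ]
  expect_equal(h2$copies, 6)
  expect_equal(h2$unit, "AT")
  h3 <- hits[hits$kind == "polyA", ]
  expect_equal(h3$tract_length, 8)
  expect_equal(h3$end, nchar(region))
})

test_that("motif-to-tract gaps are tolerated up to the configured maximum", {
  region <- paste0("G", "ATAGA", "GC", strrep("T", 12), "GGGGGG")
  hits <- scan_motifs(region)
  expect_equal(hits$gap, 2)
  expect_equal(hits$tract_length, 12)
  none <- scan_motifs(paste0("G", "ATAGA", strrep("G", 7), strrep("T", 12)))
  expect_equal(nrow(none), 0)  # gap beyond the 5 nt tolerance
})

test_that("regions without qualifying tracts yield an empty hit list", {
  hits <- scan_motifs("ATAGACCCATTTAGGGCCC")
  expect_equal(nrow(hits), 0)
  expect_true(is.data.frame(hits))
})

test_that("simple tandem repeats are called with period, copies and identity", {
  tr <- find_tandem_repeats("ATATATATATAT")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$period, 2)
  expect_equal(tr$copies, 6)
  expect_equal(tr$identity, 1)
  expect_equal(c(tr$start, tr$end), c(1, 12))

  # a duplicated 25 bp element flanked by non-repetitive sequence
  unit <- "GCTTAATTAAGTCAATTGACTTAAG"
  s <- paste0("CCGGACGT", strrep(unit, 2), "TGCACGTA")
  tr2 <- find_tandem_repeats(s)
  big <- tr2[tr2$period == 25, ]
  expect_equal(nrow(big), 1)
  expect_equal(big$copies, 2)
  expect_equal(big$start, 9)
  expect_equal(big$end, 8 + 50)
})

test_that("hits stay inside the sequence and runs are reproducible", {
  set.seed(9)
  for (i in 1:10) {
    s <- random_dna(120, c(A = .4, C = .1, G = .1, T = .4))
    a <- find_tandem_repeats(s)
    b <- find_tandem_repeats(s)
    expect_identical(a, b)
    if (nrow(a)) {
      expect_true(all(a$start >= 1 & a$end <= nchar(s)))
      expect_true(all(a$end - a$start + 1 == a$period * a$copies))
    }
  }
})

test_that("exact-mode detection matches a brute-force oracle on short strings", {
  # oracle: enumerate maximal exact runs via the shift-match formulation,
  # then apply the same published collapse rule (score, leftmost, smallest
  # period)
  oracle <- function(s, max_p = 10) {
    v <- strsplit(s, "")[[1]]
    n <- length(v)
    cand <- list()
    for (p in 2:min(max_p, n %/% 2)) {
      m <- v[seq_len(n - p)] == v[seq_len(n - p) + p]
      r <- rle(m)
      pos <- cumsum(c(1, r$lengths))
      for (j in seq_along(r$values)) {
        if (!r$values[j]) next
        t <- r$lengths[j]
        if (t < p) next  # fewer than two full copies
        i0 <- pos[j]
        # every left-maximal phase of the run is a candidate
        for (st in i0:min(i0 + p - 1L, i0 + t - p)) {
          k <- 1L + (i0 + t - st) %/% p
          if (k < 2) next
          cand[[length(cand) + 1L]] <- data.frame(
            start = st, end = st + k * p - 1L, period = p, copies = k,
            score = (k - 1L) * p)
        }
      }
    }
    if (!length(cand)) return(data.frame(start = integer(), end = integer(),
                                         period = integer(), copies = integer()))
    df <- do.call(rbind, cand)
    df <- df[order(-df$score, df$start, df$period), ]
    sel <- integer()
    for (i in seq_len(nrow(df))) {
      if (!any(df$start[i] <= df$end[sel] & df$end[i] >= df$start[sel]))
        sel <- c(sel, i)
    }
    out <- df[sel, c("start", "end", "period", "copies")]
    out <- out[order(out$start), ]
    rownames(out) <- NULL
    out
  }
  set.seed(31)
  for (i in 1:40) {
    n <- sample(8:30, 1)
    s <- random_dna(n, c(A = .45, C = .05, G = .05, T = .45))
    got <- find_tandem_repeats(s, min_period = 2, max_period = 10,
                               min_copies = 2, min_identity = 1)
    expect_equal(got[, c("start", "end", "period", "copies")],
                 oracle(s), info = s)
  }
})

test_that("planted control-region grammar is recovered from generated genomes", {
  bundle <- sim_bundle()
  crf <- suppressMessages(control_region_features(bundle$genome, bundle$annotation))
  truth <- bundle$cr_truth
  for (i in which(truth$kind %in% c("ATAGA_polyT", "ATTTA_microsat", "polyA"))) {
    t <- truth[i, ]
    hit <- crf$motifs[crf$motifs$kind == t$kind & crf$motifs$start == t$start, ]
    expect_equal(nrow(hit), 1, info = t$kind)
    expect_equal(hit$end, t$end, info = t$kind)
    if (!is.na(t$copies)) expect_equal(hit$copies, t$copies)
    if (!is.na(t$tract_length)) expect_equal(hit$tract_length, t$tract_length)
  }
  rep_truth <- truth[truth$kind == "tandem_repeat", ]
  hit <- crf$repeats[crf$repeats$period == rep_truth$period, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, rep_truth$start)
  expect_equal(hit$copies, rep_truth$copies)
})
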