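# Constrained cloverleaf folding of tRNA genes.
#
# The cloverleaf topology is fixed (acceptor stem, D arm, anticodon arm,
# variable loop, T arm), so folding is an exhaustive search over arm
# boundaries rather than free-energy minimization: every admissible
# partition of the sequence into
#   [acc5][link1][D5][D-loop][D3][link2][AC5][AC-loop(7)][AC3]
#   [var-loop][T5][T-loop][T3][acc3]
# is scored as 2 per Watson-Crick pair, +1 per G-U wobble, -1 per mismatch,
# and the best-scoring partition wins. Ties are broken by more WC pairs,
# then by the lexicographically first layout in the enumeration order
# (acceptor size, link1, D stem, D loop, link2, AC stem, T stem, T loop),
# which makes folding fully deterministic.

#' Cloverleaf search constraints
#'
#' Admissible size ranges (in nt or bp) for each element of the cloverleaf.
#' Defaults reflect canonical tRNA architecture: acceptor stem 6-7 bp,
#' D stem 3-4 bp with a 4-11 nt loop, anticodon stem 4-5 bp with a loop of
#' exactly 7 nt, T stem 4-5 bp with a 3-9 nt loop, variable loop 3-23 nt,
#' and short linkers (0-3 nt after the acceptor stem, 0-2 nt before the
#' anticodon arm).
#'
#' @param acceptor,d_stem,d_loop,ac_stem,t_stem,t_loop,var_loop,link1,link2
#'   integer ranges.
#' @return named list of ranges.
#' @export
cloverleaf_constraints <- function(acceptor = 6:7, d_stem = 3:4, d_loop = 4:11,
                                   ac_stem = 4:5, t_stem = 4:5, t_loop = 3:9,
                                   var_loop = 3:23, link1 = 0:3, link2 = 0:2) {
  list(acceptor = acceptor, d_stem = d_stem, d_loop = d_loop,
       ac_stem = ac_stem, t_stem = t_stem, t_loop = t_loop,
       var_loop = var_loop, link1 = link1, link2 = link2)
}

# pair scores: rows/cols indexed by A,C,G,T,N (N never pairs)
.pair_score_matrix <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1L, 5, 5, dimnames = list(b, b))
  m["A", "T"] <- m["T", "A"] <- m["G", "C"] <- m["C", "G"] <- 2L
  m["G", "T"] <- m["T", "G"] <- 1L
  m
}

.encode_dna <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  i <- match(v, c("A", "C", "G", "T"))
  i[is.na(i)] <- 5L
  i
}

# score one stem given 5' and 3' position vectors; returns c(score, n_wc)
.stem_score <- function(enc, ps, i5, i3) {
  s <- ps[cbind(enc[i5], enc[i3])]
  c(sum(s), sum(s == 2L))
}

#' Fold a tRNA gene into a cloverleaf
#'
#' Exhaustive constrained search over arm boundaries (see file header for
#' the scoring model). `T` is treated as `U`; input may be DNA or RNA.
#'
#' @param seq tRNA gene sequence in gene sense, 55-80 nt.
#' @param constraints a [cloverleaf_constraints()] list.
#' @param min_score score floor below which no structure is reported.
#' @param allow_missing_d_arm also consider structures without a D stem
#'   (some mitochondrial trnS1 genes); off by default.
#' @return an object of class `cloverleaf_structure`: `layout` (named
#'   element sizes), `arms` (pair matrices with columns `pos5`, `pos3` for
#'   `acceptor_stem`, `d_arm`, `anticodon_arm`, `t_arm`), `loops` (spans),
#'   `anticodon_span` (3 positions), `score`, `n_wc`, `n_wobble`,
#'   `n_mismatch`, `seq`.
#' @export
fold_cloverleaf <- function(seq, constraints = cloverleaf_constraints(),
                            min_score = 10, allow_missing_d_arm = FALSE) {
  seq <- toupper(chartr("u", "t", chartr("U", "T", seq)))
  seq <- check_dna(seq, allow_n = TRUE, what = "tRNA sequence")
  n <- nchar(seq)
  if (n < 55 || n > 80)
    stopf("tRNA sequence length %d outside the supported 55-80 nt range", n)
  cs <- constraints
  if (allow_missing_d_arm) cs$d_stem <- sort(unique(c(0L, cs$d_stem)))

  cand <- expand.grid(a = cs$acceptor, l1 = cs$link1, d = cs$d_stem,
                      dl = cs$d_loop, l2 = cs$link2, c = cs$ac_stem,
                      t = cs$t_stem, tl = cs$t_loop,
                      KEEP.OUT.ATTRS = FALSE)
  cand$v <- n - (2L * cand$a + cand$l1 + 2L * cand$d + cand$dl + cand$l2 +
                   2L * cand$c + 7L + 2L * cand$t + cand$tl)
  cand <- cand[cand$v %in% cs$var_loop, , drop = FALSE]
  if (!nrow(cand)) stopf("no cloverleaf found: no admissible layout for %d nt", n)
  # deterministic enumeration order for tie-breaking
  cand <- cand[do.call(order, cand[c("a", "l1", "d", "dl", "l2", "c", "t", "tl")]), ,
               drop = FALSE]

  enc <- .encode_dna(seq)
  ps <- .pair_score_matrix()
  # each stem's score depends only on its start position and sizes, which is
  # a far smaller set than the full candidate grid: evaluate each distinct
  # (arm, position, sizes) tuple once, then assemble candidate totals
  eval_keys <- function(keys, fun) {
    uk <- unique(keys)
    sc <- matrix(0L, length(uk), 2L)
    for (i in seq_along(uk)) sc[i, ] <- fun(uk[i])
    sc[match(keys, uk), , drop = FALSE]
  }
  p1 <- cand$a + cand$l1 + 1L
  p2 <- p1 + 2L * cand$d + cand$dl + cand$l2
  p3 <- p2 + 2L * cand$c + 7L + cand$v
  acc <- eval_keys(cand$a, function(a)
    .stem_score(enc, ps, seq_len(a), n + 1L - seq_len(a)))
  dd <- eval_keys(p1 * 10000L + cand$d * 100L + cand$dl, function(k) {
    d <- (k %/% 100L) %% 100L
    if (d == 0L) return(c(0L, 0L))
    q1 <- k %/% 10000L
    dl <- k %% 100L
    .stem_score(enc, ps, q1 + seq_len(d) - 1L, q1 + 2L * d + dl - seq_len(d))
  })
  ac <- eval_keys(p2 * 100L + cand$c, function(k) {
    q2 <- k %/% 100L
    cc <- k %% 100L
    .stem_score(enc, ps, q2 + seq_len(cc) - 1L, q2 + 2L * cc + 7L - seq_len(cc))
  })
  tt <- eval_keys(p3 * 10000L + cand$t * 100L + cand$tl, function(k) {
    q3 <- k %/% 10000L
    t <- (k %/% 100L) %% 100L
    tl <- k %% 100L
    .stem_score(enc, ps, q3 + seq_len(t) - 1L, q3 + 2L * t + tl - seq_len(t))
  })
  score <- acc[, 1] + dd[, 1] + ac[, 1] + tt[, 1]
  nwc <- acc[, 2] + dd[, 2] + ac[, 2] + tt[, 2]
  best <- max(score)
  if (best < min_score)
    stopf("no cloverleaf found: best score %d below floor %s", best,
          format(min_score))
  idx <- which(score == best)
  idx <- idx[which.max(nwc[idx])]  # more WC wins; then first in enumeration
  z <- cand[idx, ]
  .build_cloverleaf(seq, n, z, score[idx])
}

.build_cloverleaf <- function(seq, n, z, score) {
  p1 <- z$a + z$l1 + 1L
  p2 <- p1 + 2L * z$d + z$dl + z$l2
  p3 <- p2 + 2L * z$c + 7L + z$v
  pairs <- function(p, k, width) if (k > 0)
    cbind(pos5 = p + seq_len(k) - 1L, pos3 = p + width - seq_len(k))
  else cbind(pos5 = integer(), pos3 = integer())
  arms <- list(
    acceptor_stem = cbind(pos5 = seq_len(z$a), pos3 = n + 1L - seq_len(z$a)),
    d_arm = pairs(p1, z$d, 2L * z$d + z$dl),
    anticodon_arm = pairs(p2, z$c, 2L * z$c + 7L),
    t_arm = pairs(p3, z$t, 2L * z$t + z$tl))
  loops <- list(
    d_loop = if (z$d > 0) c(p1 + z$d, p1 + z$d + z$dl - 1L) else
      c(p1, p1 + z$dl - 1L),
    ac_loop = c(p2 + z$c, p2 + z$c + 6L),
    var_loop = if (z$v > 0) c(p2 + 2L * z$c + 7L, p3 - 1L) else c(NA, NA),
    t_loop = c(p3 + z$t, p3 + z$t + z$tl - 1L))
  anticodon_span <- (p2 + z$c + 2L):(p2 + z$c + 4L)  # loop positions 3-5
  cls <- .classify_all(arms, seq)
  structure(list(
    seq = seq, length = n,
    layout = c(acceptor = z$a, link1 = z$l1, d_stem = z$d, d_loop = z$dl,
               link2 = z$l2, ac_stem = z$c, ac_loop = 7L, var_loop = z$v,
               t_stem = z$t, t_loop = z$tl),
    arms = arms, loops = loops, anticodon_span = anticodon_span,
    score = score, n_wc = cls$n_wc, n_wobble = cls$n_wobble,
    n_mismatch = cls$n_mismatch),
    class = "cloverleaf_structure")
}

#' @export
print.cloverleaf_structure <- function(x, ...) {
  cat(sprintf(
    "<cloverleaf_structure> %d nt | score %d | %d WC, %d wobble, %d mismatch | anticodon %s\n",
    x$length, x$score, x$n_wc, x$n_wobble, x$n_mismatch,
    locate_anticodon(x)))
  cat("  layout:", paste(names(x$layout), x$layout, sep = "=", collapse = " "), "\n")
  invisible(x)
}

.classify_one <- function(b5, b3) {
  wc <- c(A = "T", T = "A", G = "C", C = "G")
  if (!is.na(wc[b5]) && wc[[b5]] == b3) return("WC")
  if ((b5 == "G" && b3 == "T") || (b5 == "T" && b3 == "G")) return("wobble")
  "mismatch"
}

.classify_all <- function(arms, seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  allp <- do.call(rbind, arms)
  cls <- vapply(seq_len(nrow(allp)),
                function(i) .classify_one(v[allp[i, 1]], v[allp[i, 2]]),
                character(1))
  mm <- allp[cls == "mismatch", , drop = FALSE]
  lab <- vapply(seq_len(nrow(mm)), function(i) {
    pp <- sort(chartr("T", "U", c(v[mm[i, 1]], v[mm[i, 2]])))
    paste(pp, collapse = "-")
  }, character(1))
  list(n_wc = sum(cls == "WC"), n_wobble = sum(cls == "wobble"),
       n_mismatch = sum(cls == "mismatch"),
       mismatch_breakdown = if (length(lab)) table(lab) else
         table(factor(character(), levels = character())))
}

#' Classify the stem base pairs of a cloverleaf
#'
#' Labels every stem pair Watson-Crick (`A-U`, `G-C`), G-U wobble, or
#' mismatch, and tabulates mismatches by unordered base pair (RNA
#' alphabet, e.g. `A-A`, `U-U`).
#'
#' @param s a [fold_cloverleaf()] result.
#' @param seq optional sequence; defaults to the one stored in `s`.
#' @return object of class `pair_class_count`: `n_wc`, `n_wobble`,
#'   `n_mismatch`, `mismatch_breakdown` (named table), `total_pairs`.
#' @export
classify_pairs <- function(s, seq = s$seq) {
  seq <- toupper(chartr("U", "T", seq))
  if (max(vapply(s$arms, function(a) if (nrow(a)) max(a) else 0L, numeric(1))) >
      nchar(seq))
    stopf("structure positions exceed sequence length")
  cls <- .classify_all(s$arms, seq)
  structure(c(cls, list(total_pairs = cls$n_wc + cls$n_wobble + cls$n_mismatch)),
            class = "pair_class_count")
}

#' @export
print.pair_class_count <- function(x, ...) {
  cat(sprintf("<pair_class_count> %d pairs: %d WC, %d wobble, %d mismatch",
              x$total_pairs, x$n_wc, x$n_wobble, x$n_mismatch))
  if (x$n_mismatch > 0)
    cat(" (", paste(names(x$mismatch_breakdown), x$mismatch_breakdown,
                    sep = ":", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Anticodon of a folded tRNA
#'
#' The 3 nt at anticodon-loop positions 3-5, reported in the gene-sense DNA
#' alphabet.
#'
#' @param s a [fold_cloverleaf()] result.
#' @param seq optional sequence; defaults to the one stored in `s`.
#' @return 3-letter DNA string.
#' @export
locate_anticodon <- function(s, seq = s$seq) {
  seq <- toupper(chartr("U", "T", seq))
  paste(strsplit(seq, "", fixed = TRUE)[[1]][s$anticodon_span], collapse = "")
}

#' Dot-bracket string of a cloverleaf
#'
#' @param s a [fold_cloverleaf()] result.
#' @return dot-bracket notation of length `s$length`.
#' @export
dot_bracket <- function(s) {
  v <- rep(".", s$length)
  for (a in s$arms) if (nrow(a)) {
    v[a[, "pos5"]] <- "("
    v[a[, "pos3"]] <- ")"
  }
  paste(v, collapse = "")
}
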