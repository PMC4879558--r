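# A+T-rich (control) region analysis: conserved motif grammar and a
# tandem-repeat detector. Coordinates in all hits are local to the region
# (1-based inclusive); callers carry the genome offset as metadata.

#' Scan a control region for its conserved motif grammar
#'
#' Reports the three structural signals of the lepidopteran A+T-rich
#' region: the `ATAGA` motif followed (within a small gap) by a poly-T
#' stretch, the `ATTTA` motif followed by a microsatellite-like `(AT)n`
#' tract, and the terminal poly-A element adjacent to the downstream
#' `trnM` gene. Poly-T/microsatellite tract lengths are reported exclusive
#' of the preceding motif. Hits are returned in left-to-right order;
#' scanning is fully deterministic.
#'
#' @param region DNA string of the control region.
#' @param min_polyt minimum poly-T tract length (default 10).
#' @param max_gap maximum nt between motif and tract (default 5, i.e.
#'   gaps of 0-5 are accepted; the smallest qualifying gap is reported).
#' @param min_at_copies minimum `(AT)` copies after `ATTTA` (default 4).
#' @param min_polya minimum terminal poly-A length (default 6).
#' @return a `data.frame` of hits with columns `kind`
#'   (`ATAGA_polyT` / `ATTTA_microsat` / `polyA`), `start`, `end`, `gap`,
#'   `tract_length`, `unit`, `copies`. Zero rows is a valid result.
#' @export
scan_motifs <- function(region, min_polyt = 10, max_gap = 5,
                        min_at_copies = 4, min_polya = 6) {
  region <- check_dna(region, allow_n = TRUE, what = "control region")
  if (nchar(region) == 0L) stopf("empty control region")
  v <- strsplit(region, "", fixed = TRUE)[[1]]
  n <- length(v)
  hits <- list()
  run_len <- function(pos, base) {
    k <- 0L
    while (pos + k <= n && v[pos + k] == base) k <- k + 1L
    k
  }
  add <- function(kind, start, end, gap = NA, tract = NA, unit = NA, copies = NA) {
    hits[[length(hits) + 1L]] <<- data.frame(
      kind = kind, start = start, end = end, gap = gap,
      tract_length = tract, unit = unit, copies = copies,
      stringsAsFactors = FALSE)
  }

  for (m in .find_all(region, "ATAGA")) {
    for (g in 0:max_gap) {
      p <- m + 5L + g
      len <- run_len(p, "T")
      if (len >= min_polyt) {
        add("ATAGA_polyT", m, p + len - 1L, gap = g, tract = len)
        break
      }
    }
  }
  for (m in .find_all(region, "ATTTA")) {
    for (g in 0:max_gap) {
      p <- m + 5L + g
      copies <- 0L
      while (p + 2L * copies + 1L <= n &&
             v[p + 2L * copies] == "A" && v[p + 2L * copies + 1L] == "T")
        copies <- copies + 1L
      if (copies >= min_at_copies) {
        add("ATTTA_microsat", m, p + 2L * copies - 1L, gap = g,
            tract = 2L * copies, unit = "AT", copies = copies)
        break
      }
    }
  }
  tail_a <- 0L
  while (tail_a < n && v[n - tail_a] == "A") tail_a <- tail_a + 1L
  if (tail_a >= min_polya)
    add("polyA", n - tail_a + 1L, n, tract = tail_a)

  if (!length(hits))
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      gap = integer(), tract_length = integer(),
                      unit = character(), copies = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$start, out$kind), , drop = FALSE]
}

.find_all <- function(s, pat) {
  m <- gregexpr(pat, s, fixed = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

#' Detect tandem repeats
#'
#' An identity-threshold tandem-repeat detector: for every period `p`, runs
#' of consecutive copies of the leading unit are collected where each
#' subsequent copy matches the first copy at identity `>= min_identity`.
#' Only left-maximal runs with at least `min_copies` full copies are kept;
#' overlapping calls (across periods and phases) are collapsed to the
#' highest-scoring, where the score is the number of aligned matching
#' positions of copies 2..k against copy 1, with ties going to the leftmost
#' start and then the smallest period. The detector is deterministic. This
#' is intentionally simpler than the full Tandem Repeats Finder scoring
#' model: it establishes presence and extent of repeats, not alignment
#' scores.
#'
#' @param seq DNA string.
#' @param min_period,max_period period range searched (bp).
#' @param min_copies minimum number of full copies (default 2).
#' @param min_identity minimum per-copy identity to the leading unit
#'   (default 0.9; 1 gives exact-match detection).
#' @return a `data.frame` with columns `kind` (`tandem_repeat`), `start`,
#'   `end`, `period`, `copies`, `identity` (mean per-copy identity),
#'   `score`.
#' @export
find_tandem_repeats <- function(seq, min_period = 2, max_period = 200,
                                min_copies = 2, min_identity = 0.9) {
  seq <- check_dna(seq, allow_n = TRUE, what = "sequence")
  n <- nchar(seq)
  if (n < 2 * min_period)
    stopf("sequence (%d nt) shorter than two copies of min_period", n)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  ident <- function(a, b) mean(v[a] == v[b])
  cands <- list()
  for (p in seq(min_period, min(max_period, n %/% 2))) {
    for (s in seq_len(n - 2L * p + 1L)) {
      unit <- s:(s + p - 1L)
      # left-maximality: drop starts whose preceding chunk also matches
      if (s - p >= 1L && ident(unit, (s - p):(s - 1L)) >= min_identity) next
      k <- 1L
      idents <- numeric()
      repeat {
        nx <- s + k * p
        if (nx + p - 1L > n) break
        id <- ident(unit, nx:(nx + p - 1L))
        if (id < min_identity) break
        k <- k + 1L
        idents <- c(idents, id)
      }
      if (k >= min_copies)
        cands[[length(cands) + 1L]] <- data.frame(
          kind = "tandem_repeat", start = s, end = s + k * p - 1L,
          period = p, copies = k, identity = mean(idents),
          score = sum(idents) * p, stringsAsFactors = FALSE)
    }
  }
  if (!length(cands))
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      period = integer(), copies = integer(),
                      identity = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, cands)
  df <- df[order(-df$score, df$start, df$period), , drop = FALSE]
  sel <- integer()
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in sel)
      if (df$start[i] <= df$end[j] && df$end[i] >= df$start[j]) { ok <- FALSE; break }
    if (ok) sel <- c(sel, i)
  }
  out <- df[sel, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full control-region feature scan
#'
#' Convenience wrapper combining [scan_motifs()] and
#' [find_tandem_repeats()] for the control region of an annotated genome.
#'
#' @param genome a [genome_sequence()].
#' @param ann an [annotation_table()] with a `control_region` feature.
#' @param ... passed to [scan_motifs()].
#' @return list with `region` (sequence), `offset` (genome start of the
#'   region), `motifs`, `repeats`.
#' @export
control_region_features <- function(genome, ann, ...) {
  df <- as.data.frame(ann)
  cr <- df[df$class == "control_region", , drop = FALSE]
  if (!nrow(cr)) stopf("annotation contains no control_region feature")
  cr <- cr[1, ]
  region <- extract_gene_sequence(genome, cr)
  list(region = region, offset = cr$start,
       motifs = scan_motifs(region, ...),
       repeats = find_tandem_repeats(region))
}
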