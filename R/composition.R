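# Base composition and strand-asymmetry (skew) statistics.

#' Base composition of a DNA sequence
#'
#' Counts A/C/G/T (N is excluded from both the counts and the denominator)
#' and derives percentages, A+T content and the two skew statistics
#' `AT skew = (A - T)/(A + T)` and `GC skew = (G - C)/(G + C)`. All values
#' are kept at full precision; rounding happens only at display time
#' (2 decimals for percentages, 3 for skews, half-up).
#'
#' @param seq DNA string or [genome_sequence()].
#' @return an object of class `composition_stats`: counts `n_a`, `n_c`,
#'   `n_g`, `n_t`, `length` (countable bases), percentages `pct_a` ...
#'   `pct_t`, `at_content`, `at_skew`, `gc_skew`.
#' @export
base_composition <- function(seq) {
  if (inherits(seq, "genome_sequence")) seq <- seq$seq
  seq <- check_dna(seq, allow_n = TRUE, what = "sequence")
  if (nchar(seq) == 0L) stopf("empty sequence")
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  cnt <- vapply(DNA_BASES, function(b) sum(v == b), integer(1))
  len <- sum(cnt)
  if (len == 0L) stopf("sequence has no countable (non-N) bases")
  pct <- 100 * cnt / len
  structure(list(
    n_a = cnt[["A"]], n_c = cnt[["C"]], n_g = cnt[["G"]], n_t = cnt[["T"]],
    length = len,
    pct_a = pct[["A"]], pct_c = pct[["C"]],
    pct_g = pct[["G"]], pct_t = pct[["T"]],
    at_content = pct[["A"]] + pct[["T"]],
    # a class absent from the sequence leaves its skew undefined (NA);
    # the standalone skew functions keep the hard zero-denominator error
    at_skew = if (cnt[["A"]] + cnt[["T"]] > 0)
      at_skew(cnt[["A"]], cnt[["T"]]) else NA_real_,
    gc_skew = if (cnt[["G"]] + cnt[["C"]] > 0)
      gc_skew(cnt[["G"]], cnt[["C"]]) else NA_real_
  ), class = "composition_stats")
}

#' AT and GC skew
#'
#' `at_skew(a, t) = (a - t)/(a + t)` and `gc_skew(g, c) = (g - c)/(g + c)`.
#' Arguments may be counts or percentages (the ratio is scale-free). A zero
#' denominator is an error, never a silent 0.
#'
#' @param a,t,g,c base counts or percentages.
#' @return signed skew in `[-1, 1]`.
#' @export
at_skew <- function(a, t) {
  if (!is.finite(a) || !is.finite(t) || a + t <= 0)
    stopf("at_skew: A + T must be > 0")
  (a - t) / (a + t)
}

#' @rdname at_skew
#' @export
gc_skew <- function(g, c) {
  if (!is.finite(g) || !is.finite(c) || g + c <= 0)
    stopf("gc_skew: G + C must be > 0")
  (g - c) / (g + c)
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "<composition_stats> %d bp | A %.2f%% G %.2f%% T %.2f%% C %.2f%% | A+T %.2f%% | AT skew %.3f GC skew %.3f\n",
    x$length, round_half_up(x$pct_a, 2), round_half_up(x$pct_g, 2),
    round_half_up(x$pct_t, 2), round_half_up(x$pct_c, 2),
    round_half_up(x$at_content, 2), round_half_up(x$at_skew, 3),
    round_half_up(x$gc_skew, 3)))
  invisible(x)
}

#' Per-feature-class composition summary
#'
#' For each feature class present in the annotation, the member sequences
#' are concatenated as they appear on the published forward strand (no
#' reverse-complementing; published composition tables count this way) and
#' summarized with [base_composition()]; bases inside overlapping features
#' are counted once per containing feature. `whole_genome` is computed on
#' the full forward strand. Set `gene_sense = TRUE` to reverse-complement
#' R-strand features before counting instead.
#'
#' @param genome a [genome_sequence()].
#' @param ann an [annotation_table()].
#' @param gene_sense count R-strand features in gene sense (default FALSE).
#' @return an object of class `region_class_summary`: a named list of
#'   `composition_stats`, one per class present, plus `whole_genome`.
#' @export
summarize_regions <- function(genome, ann, gene_sense = FALSE) {
  if (max(ann$end) > nchar(genome$seq))
    stopf("annotation extends beyond the genome (%d > %d)",
          max(ann$end), nchar(genome$seq))
  df <- as.data.frame(ann)
  ov <- .overlapping_pairs(df)
  if (nrow(ov))
    message("summarize_regions: ", nrow(ov),
            " overlapping feature pair(s); shared bases counted in each feature")
  out <- list()
  for (cls in FEATURE_CLASSES) {
    rows <- df[df$class == cls, , drop = FALSE]
    if (!nrow(rows)) {
      if (cls %in% df$class) next
      message("summarize_regions: class ", cls, " absent, omitted")
      next
    }
    seqs <- vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (!gene_sense) r$strand <- "F"
      extract_gene_sequence(genome, r)
    }, character(1))
    out[[cls]] <- base_composition(paste(seqs, collapse = ""))
  }
  out$whole_genome <- base_composition(genome$seq)
  structure(out, class = "region_class_summary")
}

.overlapping_pairs <- function(df) {
  n <- nrow(df)
  if (n < 2) return(data.frame(i = integer(), j = integer()))
  idx <- which(df$start[-1] <= df$end[-n])
  data.frame(i = idx, j = idx + 1L)
}

#' Published composition table fixture
#'
#' The shipped composition-and-skewness table for seven lepidopteran
#' mitogenomes (per region: whole genome, PCGs, tRNAs, rRNAs, A+T-rich
#' region), as printed in the comparative literature. Percentages in this
#' table are display-rounded; skews recomputed from them with [at_skew()] /
#' [gc_skew()] reproduce the printed skew columns.
#'
#' @return a `data.frame` with columns `Region`, `Species`, `Size`, `A`,
#'   `G`, `T`, `C`, `AT`, `ATskew`, `GCskew`.
#' @export
reference_composition <- function() {
  path <- system.file("extdata", "lepidoptera_composition.tsv",
                      package = "mitocomp", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' Composition summary as a display table
#'
#' Formats a [summarize_regions()] result (or a named list of
#' `composition_stats`) like a published composition table: columns `Region`,
#' `Size`, `A%`, `G%`, `T%`, `C%`, `A+T%`, `ATskewness`, `GCskewness`, with
#' half-up rounding at 2 decimals for percentages and 3 for skews.
#'
#' @param x a `region_class_summary` or named list of `composition_stats`.
#' @return a `data.frame`.
#' @export
composition_table <- function(x) {
  rows <- lapply(names(x), function(nm) {
    s <- x[[nm]]
    data.frame(Region = nm, Size = s$length,
               `A%` = round_half_up(s$pct_a, 2),
               `G%` = round_half_up(s$pct_g, 2),
               `T%` = round_half_up(s$pct_t, 2),
               `C%` = round_half_up(s$pct_c, 2),
               `A+T%` = round_half_up(s$at_content, 2),
               ATskewness = round_half_up(s$at_skew, 3),
               GCskewness = round_half_up(s$gc_skew, 3),
               check.names = FALSE)
  })
  do.call(rbind, rows)
}
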