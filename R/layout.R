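# Gene layout on the circle: neighbor adjacencies (overlaps / spacers)
# and gene-order comparison.

#' Signed neighbor distances on the circular genome
#'
#' For consecutive records i, i+1 (sorted by start) the signed gap is
#' `start(i+1) - end(i) - 1`: negative values are overlaps of that many bp,
#' 0 means abutting genes and positive values are intergenic spacers. On a
#' circular genome the wrap pair (last feature back to the first) is
#' included with gap `start(first) + genome_length - end(last) - 1`.
#' Features fully nested inside another feature break the neighbor chain;
#' they are excluded from it and reported via the `nested` attribute.
#'
#' @param ann an [annotation_table()] sorted by start.
#' @return a `data.frame` (class `adjacency_list`) with columns `upstream`,
#'   `downstream`, `signed_gap`; attributes `genome_length`, `circular`,
#'   `nested` (names of excluded nested features).
#' @export
adjacency_distances <- function(ann) {
  df <- as.data.frame(ann)
  if (is.unsorted(df$start))
    stopf("records are not sorted by start; sort the annotation table first")
  nested <- character()
  if (nrow(df) > 1) {
    run_max_end <- cummax(df$end)
    is_nested <- c(FALSE, df$end[-1] <= run_max_end[-nrow(df)])
    nested <- df$name[is_nested]
    if (length(nested))
      message("adjacency_distances: nested feature(s) excluded from the chain: ",
              paste(nested, collapse = ", "))
    df <- df[!is_nested, , drop = FALSE]
  }
  n <- nrow(df)
  if (n < 2) stopf("need at least two non-nested features")
  gaps <- df$start[-1] - df$end[-n] - 1L
  up <- df$name[-n]
  down <- df$name[-1]
  if (isTRUE(attr(ann, "circular"))) {
    gaps <- c(gaps, df$start[1] + attr(ann, "genome_length") - df$end[n] - 1L)
    up <- c(up, df$name[n])
    down <- c(down, df$name[1])
  }
  structure(data.frame(upstream = up, downstream = down, signed_gap = gaps,
                       stringsAsFactors = FALSE),
            class = c("adjacency_list", "data.frame"),
            genome_length = attr(ann, "genome_length"),
            circular = attr(ann, "circular"), nested = nested)
}

#' Overlap / spacer summary of a gene layout
#'
#' Aggregates signed neighbor gaps into the totals reported for compact
#' mitogenomes: total overlapping bp and number of overlap positions, total
#' intergenic bp and number of spacer regions, plus the extreme pairs. Two
#' input modes exist because published annotation tables carry a declared
#' intergenic column that may disagree with the printed coordinates:
#' `mode = "computed"` derives gaps from coordinates via
#' [adjacency_distances()]; `mode = "declared"` aggregates the table's own
#' `declared_intergenic` column (value on row i = distance to the next
#' gene). Reports always carry the mode that produced them.
#'
#' @param x an [annotation_table()] or an `adjacency_list`.
#' @param mode `"computed"` or `"declared"` (annotation-table input only).
#' @return an object of class `layout_report`: list with `adjacencies`,
#'   `total_overlap_bp`, `n_overlaps`, `max_overlap`, `total_spacer_bp`,
#'   `n_spacers`, `max_spacer`, `mode`.
#' @export
layout_summary <- function(x, mode = c("computed", "declared")) {
  mode <- match.arg(mode)
  if (inherits(x, "adjacency_list")) {
    adjs <- x
    mode <- "computed"
  } else if (inherits(x, "annotation_table")) {
    if (mode == "computed") {
      adjs <- adjacency_distances(x)
    } else {
      df <- as.data.frame(x)
      keep <- which(!is.na(df$declared_intergenic))
      if (!length(keep)) stopf("no declared intergenic values in the table")
      nxt <- ifelse(keep < nrow(df), keep + 1L, 1L)
      adjs <- data.frame(upstream = df$name[keep], downstream = df$name[nxt],
                         signed_gap = df$declared_intergenic[keep],
                         stringsAsFactors = FALSE)
    }
  } else stopf("x must be an annotation_table or adjacency_list")
  if (!nrow(adjs)) stopf("empty adjacency list")

  g <- adjs$signed_gap
  ov <- which(g < 0)
  sp <- which(g > 0)
  pair <- function(i) if (length(i)) {
    # ties on the extreme broken by first occurrence in genome order
    j <- i[which.max(abs(g[i]))]
    list(pair = c(adjs$upstream[j], adjs$downstream[j]), bp = abs(g[j]))
  } else list(pair = c(NA_character_, NA_character_), bp = 0L)
  structure(list(adjacencies = adjs,
                 total_overlap_bp = sum(abs(g[ov])),
                 n_overlaps = length(ov),
                 max_overlap = pair(ov),
                 total_spacer_bp = sum(g[sp]),
                 n_spacers = length(sp),
                 max_spacer = pair(sp),
                 mode = mode),
            class = "layout_report")
}

#' @export
print.layout_report <- function(x, ...) {
  cat(sprintf("<layout_report> mode=%s\n", x$mode))
  cat(sprintf("  overlaps: %d bp in %d positions (max %d bp, %s-%s)\n",
              x$total_overlap_bp, x$n_overlaps, x$max_overlap$bp,
              x$max_overlap$pair[1], x$max_overlap$pair[2]))
  cat(sprintf("  spacers:  %d bp in %d regions (max %d bp, %s-%s)\n",
              x$total_spacer_bp, x$n_spacers, x$max_spacer$bp,
              x$max_spacer$pair[1], x$max_spacer$pair[2]))
  invisible(x)
}

#' Compare a circular gene order against a reference order
#'
#' Treats both inputs as circular sequences of gene names, checks they use
#' the same name set, and counts breakpoints: ordered adjacent pairs present
#' in the query order but absent from the reference (including the wrap
#' pair). When the three tRNA genes of the M/I/Q cluster are present, their
#' observed local order is reported, since the derived `trnM-trnI-trnQ`
#' arrangement versus the ancestral `trnI-trnQ-trnM` is the classic
#' lepidopteran rearrangement.
#'
#' @param ann an [annotation_table()] or character vector of names in order.
#' @param reference character vector of names in reference order.
#' @return list with `identical` (logical), `n_breakpoints`, `breakpoints`
#'   (data.frame of query-only adjacencies), and `miq_order` (observed order
#'   of the M/I/Q cluster genes, or NULL).
#' @export
compare_gene_order <- function(ann, reference) {
  order1 <- if (inherits(ann, "annotation_table")) ann$name else as.character(ann)
  reference <- as.character(reference)
  extra <- setdiff(order1, reference)
  missing <- setdiff(reference, order1)
  if (length(extra) || length(missing))
    stopf("name sets differ; only in query: [%s]; only in reference: [%s]",
          paste(extra, collapse = ", "), paste(missing, collapse = ", "))
  adj <- function(o) paste(o, c(o[-1], o[1]), sep = "\r")
  a1 <- adj(order1)
  a2 <- adj(reference)
  bp <- setdiff(a1, a2)
  parts <- strsplit(bp, "\r", fixed = TRUE)
  bp_df <- data.frame(upstream = vapply(parts, `[`, "", 1),
                      downstream = vapply(parts, `[`, "", 2),
                      stringsAsFactors = FALSE)
  miq <- grep("^trn[MIQ]$", order1, value = TRUE, ignore.case = TRUE)
  miq_order <- if (length(miq) == 3)
    paste(order1[sort(match(miq, order1))], collapse = "-") else NULL
  list(identical = length(bp) == 0L,
       n_breakpoints = length(bp),
       breakpoints = bp_df,
       miq_order = miq_order)
}
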