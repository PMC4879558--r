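# Distance-based phylogeny stage: supermatrix concatenation, conserved-block
# masking, pairwise distances (p / JC69 / K2P), neighbor joining and
# column-resampling bootstrap. This deliberately replaces heavyweight
# maximum-likelihood inference with a fully specified, deterministic
# distance pipeline that recovers the same grouping structure at desk scale.

GAP_CHARS <- c("-", "?", "N")

#' Read one aligned FASTA file as a character matrix
#'
#' @param path FASTA alignment.
#' @return character matrix, taxa in rows.
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  w <- unique(Biostrings::width(ss))
  if (length(w) != 1) stopf("%s: unequal aligned lengths", path)
  m <- do.call(rbind, strsplit(toupper(as.character(ss)), "", fixed = TRUE))
  rownames(m) <- names(ss)
  m
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' All alignments must cover the same taxon set; rows are reordered to the
#' taxon order of the first alignment and columns are joined in the order
#' the genes are given, with the partition map recorded.
#'
#' @param alignments named list of alignments (character matrices with taxon
#'   rownames, `DNAbin` matrices, or named equal-length character vectors).
#' @return an object of class `supermatrix`: `taxa`, `mat` (character
#'   matrix), `partitions` (data.frame `gene`, `start`, `end`).
#' @export
concatenate <- function(alignments) {
  if (!length(alignments)) stopf("no alignments given")
  if (is.null(names(alignments)))
    names(alignments) <- paste0("gene", seq_along(alignments))
  mats <- lapply(names(alignments), function(g) {
    m <- alignments[[g]]
    if (inherits(m, "DNAbin")) m <- toupper(as.character(as.matrix(m)))
    if (is.character(m) && !is.matrix(m)) {
      if (is.null(names(m))) stopf("%s: sequences must be named by taxon", g)
      w <- unique(nchar(m))
      if (length(w) != 1) stopf("%s: unequal row lengths within the gene", g)
      mm <- do.call(rbind, strsplit(toupper(m), "", fixed = TRUE))
      rownames(mm) <- names(m)
      m <- mm
    }
    if (!is.matrix(m)) stopf("%s: cannot interpret alignment input", g)
    toupper(m)
  })
  names(mats) <- names(alignments)
  taxa <- rownames(mats[[1]])
  for (g in names(mats)) {
    absent <- setdiff(taxa, rownames(mats[[g]]))
    extra <- setdiff(rownames(mats[[g]]), taxa)
    if (length(absent) || length(extra))
      stopf("taxon sets differ in %s; absent: [%s]; extra: [%s]", g,
            paste(absent, collapse = ", "), paste(extra, collapse = ", "))
    mats[[g]] <- mats[[g]][taxa, , drop = FALSE]
  }
  widths <- vapply(mats, ncol, integer(1))
  ends <- cumsum(widths)
  parts <- data.frame(gene = names(mats),
                      start = c(1L, utils::head(ends, -1) + 1L),
                      end = ends, stringsAsFactors = FALSE)
  structure(list(taxa = taxa, mat = do.call(cbind, mats), partitions = parts),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partition(s)\n",
              length(x$taxa), ncol(x$mat), nrow(x$partitions)))
  invisible(x)
}

#' Select conserved alignment blocks
#'
#' A simplified conserved-block filter in the spirit of Gblocks: a column
#' passes when its gap fraction is at most `max_gap_frac` and its
#' majority-character frequency (over non-gap rows, relative to all rows)
#' is at least `min_conserved_frac`; only maximal runs of at least
#' `min_block` contiguous passing columns are kept.
#'
#' @param sm a [concatenate()] result.
#' @param min_block minimum run length kept (default 5).
#' @param max_gap_frac maximum per-column gap fraction (default 0).
#' @param min_conserved_frac minimum majority-character frequency
#'   (default 0.5).
#' @return logical column mask of length `ncol(sm$mat)`.
#' @export
select_blocks <- function(sm, min_block = 5, max_gap_frac = 0,
                          min_conserved_frac = 0.5) {
  m <- sm$mat
  nr <- nrow(m)
  pass <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gaps <- col %in% GAP_CHARS
    if (mean(gaps) > max_gap_frac) return(FALSE)
    bases <- col[!gaps]
    if (!length(bases)) return(FALSE)
    max(table(bases)) / nr >= min_conserved_frac
  }, logical(1))
  r <- rle(pass)
  r$values[r$values & r$lengths < min_block] <- FALSE
  mask <- inverse.rle(r)
  if (!any(mask)) warnf("select_blocks: no column passed the filter")
  mask
}

#' Subset a supermatrix by a column mask
#'
#' Keeps the masked columns and recomputes partition spans from the number
#' of surviving columns per gene; partitions left empty are dropped.
#'
#' @param sm a `supermatrix`.
#' @param mask logical vector over columns.
#' @return a `supermatrix`.
#' @export
apply_mask <- function(sm, mask) {
  stopifnot(length(mask) == ncol(sm$mat))
  kept <- vapply(seq_len(nrow(sm$partitions)), function(i)
    sum(mask[sm$partitions$start[i]:sm$partitions$end[i]]), integer(1))
  keep <- kept > 0
  ends <- cumsum(kept[keep])
  parts <- data.frame(gene = sm$partitions$gene[keep],
                      start = c(1L, utils::head(ends, -1) + 1L), end = ends,
                      stringsAsFactors = FALSE)
  structure(list(taxa = sm$taxa, mat = sm$mat[, mask, drop = FALSE],
                 partitions = parts), class = "supermatrix")
}

#' Pairwise distances from a supermatrix
#'
#' Standard closed forms with pairwise deletion: for each pair, columns
#' holding a gap (`-`, `?`, `N`) in either taxon are skipped. Models:
#' `p` (mismatch fraction), `JC69` (`-3/4 log(1 - 4p/3)`), `K2P` (Kimura
#' 1980 from transition/transversion fractions). Saturated pairs (a
#' non-positive logarithm argument) raise an error naming the pair rather
#' than returning infinity.
#'
#' @param sm a `supermatrix` (already masked, if desired).
#' @param model `"p"`, `"JC69"` or `"K2P"`.
#' @return symmetric numeric matrix with zero diagonal and taxa dimnames.
#' @export
pairwise_distances <- function(sm, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  m <- sm$mat
  taxa <- sm$taxa
  nt <- length(taxa)
  d <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
  purine <- c("A", "G")
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    a <- m[i, ]
    b <- m[j, ]
    use <- !(a %in% GAP_CHARS) & !(b %in% GAP_CHARS)
    nn <- sum(use)
    if (nn == 0) stopf("no comparable sites between %s and %s", taxa[i], taxa[j])
    diff <- a[use] != b[use]
    p <- mean(diff)
    val <- switch(model,
      p = p,
      JC69 = {
        arg <- 1 - 4 * p / 3
        if (arg <= 0)
          stopf("saturation between %s and %s (p = %.3f)", taxa[i], taxa[j], p)
        -0.75 * log(arg)
      },
      K2P = {
        ts <- mean(diff & ((a[use] %in% purine) == (b[use] %in% purine)))
        tv <- p - ts
        a1 <- 1 - 2 * ts - tv
        a2 <- 1 - 2 * tv
        if (a1 <= 0 || a2 <= 0)
          stopf("saturation between %s and %s (P = %.3f, Q = %.3f)",
                taxa[i], taxa[j], ts, tv)
        -0.5 * log(a1) - 0.25 * log(a2)
      })
    d[i, j] <- d[j, i] <- val
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration (via \pkg{ape}). Taxa are sorted
#' alphabetically before clustering so the result is invariant to the
#' input order of the distance matrix; negative branch lengths are clamped
#' to zero with a warning.
#'
#' @param dm symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stopf("neighbor joining needs at least 3 taxa")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord, drop = FALSE]
  tr <- ape::nj(stats::as.dist(dm))
  if (any(tr$edge.length < 0)) {
    warnf("nj_tree: %d negative branch length(s) clamped to 0",
          sum(tr$edge.length < 0))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support for the NJ tree
#'
#' Whole-column resampling with replacement: per replicate the supermatrix
#' columns are resampled, distances recomputed and an NJ tree rebuilt;
#' support of each internal edge of the original tree is the percentage of
#' replicates containing the same bipartition. Replicates whose distance
#' computation saturates are skipped with a message and removed from the
#' denominator. All resampling is governed by one integer seed.
#'
#' @param sm a `supermatrix` (masked, if desired).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed for the resampling stream.
#' @param model distance model, see [pairwise_distances()].
#' @return the original NJ `phylo` tree with `node.label` holding supports
#'   in `[0, 100]` (root label empty) and attribute `n_effective`.
#' @export
bootstrap_support <- function(sm, n_reps = 100, seed = 1, model = "JC69") {
  stopifnot(n_reps >= 1)
  dm <- pairwise_distances(sm, model)
  if (all(dm == 0)) {
    # degenerate input: no signal at all, supports undefined
    message("bootstrap_support: all pairwise distances are zero; ",
            "returning a star tree without supports")
    star <- ape::stree(length(sm$taxa), type = "star",
                       tip.label = sort(sm$taxa))
    star$edge.length <- rep(0, nrow(star$edge))
    attr(star, "n_effective") <- 0L
    return(star)
  }
  ref <- nj_tree(dm)
  nc <- ncol(sm$mat)
  set.seed(as.integer(seed))
  boots <- list()
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    rep_sm <- structure(list(taxa = sm$taxa,
                             mat = sm$mat[, cols, drop = FALSE],
                             partitions = data.frame(gene = "resampled",
                                                     start = 1L, end = nc)),
                        class = "supermatrix")
    tr <- tryCatch(nj_tree(pairwise_distances(rep_sm, model)),
                   error = function(e) NULL)
    if (is.null(tr)) skipped <- skipped + 1L else boots[[length(boots) + 1L]] <- tr
  }
  if (skipped)
    message("bootstrap_support: ", skipped,
            " replicate(s) skipped (saturated distances)")
  n_eff <- length(boots)
  if (n_eff == 0) stopf("all bootstrap replicates failed")
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supp <- 100 * counts / n_eff
  ref$node.label <- as.character(round_half_up(supp, 1))
  ref$node.label[1] <- ""  # root of the unrooted representation
  attr(ref, "n_effective") <- n_eff
  ref
}

#' Test monophyly of a taxon group
#'
#' Roots the tree on the first outgroup taxon and checks whether the group
#' forms a complete clade.
#'
#' @param tree a `phylo` tree.
#' @param group character vector of ingroup taxa.
#' @param outgroup character vector of outgroup taxa (disjoint from
#'   `group`).
#' @return logical.
#' @export
check_monophyly <- function(tree, group, outgroup) {
  unknown <- setdiff(c(group, outgroup), tree$tip.label)
  if (length(unknown))
    stopf("unknown taxa: %s", paste(unknown, collapse = ", "))
  if (length(intersect(group, outgroup)))
    stopf("group and outgroup overlap")
  rooted <- ape::root(tree, outgroup = outgroup[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, group)
}

#' Write / read Newick trees
#'
#' Thin wrappers over \pkg{ape} kept for a stable package surface; node
#' labels (bootstrap supports) and branch lengths survive the round trip.
#'
#' @param tree a `phylo` tree.
#' @param path file path.
#' @return `write_newick`: `path` invisibly; `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
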