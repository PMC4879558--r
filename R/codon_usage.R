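# Codon extraction, start/stop identification, codon counts, CDspT and RSCU
# under the invertebrate mitochondrial genetic code (NCBI table 5), where
# ATA = Met, TGA = Trp and AGA/AGG = Ser, and where truncated genes end in a
# 1-2 nt incomplete stop ("T"/"TA") completed by polyadenylation.

#' Genetic code table
#'
#' @param code_id identifier passed to [Biostrings::getGeneticCode()];
#'   default `"5"`, the invertebrate mitochondrial code.
#' @return named character vector mapping the 64 codons to amino acids
#'   (`*` = stop).
#' @export
mito_genetic_code <- function(code_id = "5") {
  Biostrings::getGeneticCode(code_id)
}

# three-letter amino-acid names for ranking/reporting
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

#' Split a coding sequence into codons
#'
#' The sequence must already be in gene sense (strand-corrected). Codons are
#' consecutive non-overlapping triplets; any trailing 1-2 nt (`length mod 3`)
#' is returned separately as the incomplete stop fragment. When the length
#' is a multiple of 3 the final triplet is the stop-codon candidate and no
#' trailing fragment exists.
#'
#' @param cds gene-sense DNA string, length >= 6.
#' @return list with `codons` (character vector of triplets) and `trailing`
#'   (`""` or the 1-2 nt incomplete stop).
#' @export
extract_codons <- function(cds) {
  cds <- check_dna(cds, allow_n = TRUE, what = "CDS")
  n <- nchar(cds)
  if (n < 6L) stopf("CDS shorter than 6 nt (%d)", n)
  k <- n %/% 3L
  starts <- seq(1L, by = 3L, length.out = k)
  codons <- substring(cds, starts, starts + 2L)
  trailing <- if (n %% 3L) substr(cds, 3L * k + 1L, n) else ""
  list(codons = codons, trailing = trailing)
}

#' Identify start and stop codons of a coding sequence
#'
#' The start codon is the first triplet, classified canonical when it
#' matches `ATN` (the usual mitochondrial initiators); anything else (e.g.
#' the `CGA` start of lepidopteran *cox1*) is flagged non-canonical. The
#' stop is the trailing incomplete fragment when the length is not a
#' multiple of 3; otherwise the final triplet, flagged anomalous when it is
#' not a stop codon of the genetic code.
#'
#' @param cds gene-sense DNA string, length >= 6.
#' @param gene optional gene name carried into the result.
#' @param code_id genetic code identifier (default invertebrate
#'   mitochondrial).
#' @return list of class `start_stop_call`: `gene`, `start_codon`,
#'   `start_canonical`, `stop_codon`, `stop_is_complete`, `stop_anomalous`.
#' @export
detect_start_stop <- function(cds, gene = NA_character_, code_id = "5") {
  ec <- extract_codons(cds)
  gc <- mito_genetic_code(code_id)
  stops <- names(gc)[gc == "*"]
  start <- ec$codons[1]
  if (nzchar(ec$trailing)) {
    stop_codon <- ec$trailing
    complete <- FALSE
    anomalous <- FALSE
  } else {
    stop_codon <- ec$codons[length(ec$codons)]
    complete <- TRUE
    anomalous <- !(stop_codon %in% stops)
  }
  structure(list(gene = gene, start_codon = start,
                 start_canonical = grepl("^AT[ACGT]$", start),
                 stop_codon = stop_codon, stop_is_complete = complete,
                 stop_anomalous = anomalous),
            class = "start_stop_call")
}

#' Count codons across a set of coding sequences
#'
#' By default only sense codons are counted: the trailing incomplete stop
#' fragment is never counted, and a final complete stop triplet is excluded
#' unless `include_stops = TRUE`. Amino-acid totals are derived via the
#' genetic code.
#'
#' @param cds_list character vector or list of gene-sense DNA strings
#'   (optionally named by gene).
#' @param include_stops also count final complete stop triplets.
#' @param code_id genetic code identifier (default invertebrate
#'   mitochondrial).
#' @return object of class `codon_usage_table`: `counts` (named integer over
#'   the 64 codons), `total_codons`, `aa_counts`, `code_id`,
#'   `include_stops`.
#' @export
count_codons <- function(cds_list, include_stops = FALSE, code_id = "5") {
  gc <- mito_genetic_code(code_id)
  stops <- names(gc)[gc == "*"]
  counts <- stats::setNames(integer(64), names(gc))
  cds_list <- as.list(cds_list)
  for (i in seq_along(cds_list)) {
    ec <- tryCatch(extract_codons(cds_list[[i]]), error = function(e) {
      nm <- names(cds_list)[i]
      stopf("gene %s: %s", if (is.null(nm) || !nzchar(nm)) i else nm,
            conditionMessage(e))
    })
    cods <- ec$codons
    n <- length(cods)
    if (!include_stops && !nzchar(ec$trailing) && cods[n] %in% stops)
      cods <- cods[-n]
    cods <- cods[cods %in% names(counts)]  # drop N-containing triplets
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  aa <- tapply(counts, gc[names(counts)], sum)
  structure(list(counts = counts, total_codons = sum(counts),
                 aa_counts = aa[order(names(aa))], code_id = code_id,
                 include_stops = include_stops),
            class = "codon_usage_table")
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) / mean(counts over c's synonymous family)`, the
#' observed count relative to its expectation under uniform usage within the
#' family (Sharp & Li). Families are defined by the genetic code of the
#' table; stop codons form no family. A family with zero total usage gets
#' RSCU 0 for all members and is flagged via the `empty_families` attribute.
#'
#' @param table a [count_codons()] result.
#' @return named numeric over the sense codons, with attribute
#'   `empty_families`.
#' @export
rscu <- function(table) {
  gc <- mito_genetic_code(table$code_id)
  sense <- names(gc)[gc != "*"]
  fams <- split(sense, gc[sense])
  out <- stats::setNames(numeric(length(sense)), sense)
  empty <- character()
  for (aa in names(fams)) {
    cods <- fams[[aa]]
    tot <- sum(table$counts[cods])
    if (tot == 0) {
      out[cods] <- 0
      empty <- c(empty, aa)
    } else {
      out[cods] <- table$counts[cods] / (tot / length(cods))
    }
  }
  if (length(empty))
    message("rscu: amino acid(s) with zero usage: ", paste(empty, collapse = ", "))
  attr(out, "empty_families") <- empty
  out
}

#' Codons per thousand codons
#'
#' `CDspT(c) = 1000 * count(c) / total_codons`; sums to 1000 by
#' construction.
#'
#' @param table a [count_codons()] result.
#' @return named numeric over the 64 codons.
#' @export
cdspt <- function(table) {
  if (table$total_codons == 0) stopf("cdspt: no codons counted")
  1000 * table$counts / table$total_codons
}

#' Rank amino acids by usage
#'
#' Amino acids in decreasing order of total codon count; ties broken
#' alphabetically by three-letter name. Stops are excluded.
#'
#' @param table a [count_codons()] result.
#' @return character vector of three-letter amino-acid names.
#' @export
rank_amino_acids <- function(table) {
  aa <- table$aa_counts
  aa <- aa[names(aa) != "*"]
  nm3 <- AA3[names(aa)]
  unname(nm3[order(-aa, nm3)])
}

#' Codons absent from the usage table
#'
#' Codons with zero observed count among those eligible for counting (sense
#' codons; stop codons too when the table was built with
#' `include_stops = TRUE`).
#'
#' @param table a [count_codons()] result.
#' @return character vector of codons.
#' @export
absent_codons <- function(table) {
  gc <- mito_genetic_code(table$code_id)
  eligible <- if (table$include_stops) names(gc) else names(gc)[gc != "*"]
  eligible[table$counts[eligible] == 0]
}

#' Codon usage of the protein-coding genes of an annotated genome
#'
#' Convenience wrapper: extracts all `PCG` features in gene sense and runs
#' [count_codons()].
#'
#' @param genome a [genome_sequence()].
#' @param ann an [annotation_table()].
#' @inheritParams count_codons
#' @return a `codon_usage_table`.
#' @export
codon_usage <- function(genome, ann, include_stops = FALSE, code_id = "5") {
  df <- as.data.frame(ann)
  pcg <- df[df$class == "PCG", , drop = FALSE]
  if (!nrow(pcg)) stopf("annotation contains no PCG features")
  seqs <- stats::setNames(
    lapply(seq_len(nrow(pcg)), function(i) extract_gene_sequence(genome, pcg[i, ])),
    pcg$name)
  count_codons(seqs, include_stops = include_stops, code_id = code_id)
}

#' Codon usage as a display table
#'
#' One row per codon with amino-acid label, count, CDspT and RSCU.
#'
#' @param table a [count_codons()] result.
#' @return a `data.frame` with columns `Codon`, `AA`, `Count`, `CDspT`,
#'   `RSCU` (RSCU is NA for stop codons).
#' @export
codon_usage_table <- function(table) {
  gc <- mito_genetic_code(table$code_id)
  ct <- cdspt(table)
  rs <- rscu(table)
  data.frame(Codon = names(gc),
             AA = ifelse(gc == "*", "Stop", AA3[gc]),
             Count = as.integer(table$counts),
             CDspT = round_half_up(ct, 2),
             RSCU = round_half_up(unname(rs[names(gc)]), 2),
             stringsAsFactors = FALSE)
}
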