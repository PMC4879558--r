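# Annotation and sequence IO.
#
# Coordinate convention (used everywhere in the package): positions are
# 1-based and fully inclusive, so a feature spanning start..end has length
# end - start + 1. Features that would span the circular origin are rejected
# rather than wrapped; the canonical 37-gene layout places the control region
# flush against the origin so no wrapping is ever needed.

FEATURE_CLASSES <- c("PCG", "tRNA", "rRNA", "control_region")

# controlled vocabulary of mitochondrial gene names (case-insensitive);
# unknown names are allowed but flagged so typos surface in logs
KNOWN_NAME_RE <- paste0(
  "^(atp6|atp8|cox[123]|cob|nad[1-6]|nad4l|rrn[ls]|cr|",
  "trn[a-z](1|2)?(\\([a-z]{3}\\))?)$"  # (UUR)-style family suffixes use IUPAC codes
)

#' Construct a genome sequence object
#'
#' A light container for one circular (or linear) DNA molecule. The sequence
#' is upper-cased and restricted to the alphabet `{A,C,G,T,N}`.
#'
#' @param id sequence identifier.
#' @param seq DNA string.
#' @param circular logical, is the molecule circular?
#' @return an object of class `genome_sequence` with elements `id`, `seq`
#'   and `circular`.
#' @export
genome_sequence <- function(id, seq, circular = TRUE) {
  seq <- check_dna(seq, allow_n = TRUE, what = "genome sequence")
  if (nchar(seq) == 0L) stopf("genome sequence must be non-empty")
  structure(list(id = as.character(id), seq = seq,
                 circular = isTRUE(circular)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %d bp, %s\n", x$id, nchar(x$seq),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct an annotation table
#'
#' The ordered set of features of one mitogenome: name, feature class
#' (`PCG`, `tRNA`, `rRNA`, `control_region`), strand (`F`/`R`), 1-based
#' inclusive coordinates, and the optional anticodon / start codon / stop
#' codon / declared intergenic columns of a published annotation table.
#'
#' @param records a `data.frame` with columns `name`, `class`, `strand`,
#'   `start`, `end` and optionally `anticodon`, `start_codon`, `stop_codon`,
#'   `declared_intergenic`.
#' @param genome_length total genome size in bp; defaults to `max(end)`.
#' @param circular logical flag.
#' @return an object of class `annotation_table`: the records `data.frame`
#'   with attributes `genome_length` and `circular`.
#' @export
annotation_table <- function(records, genome_length = NULL, circular = TRUE) {
  req <- c("name", "class", "strand", "start", "end")
  miss <- setdiff(req, names(records))
  if (length(miss)) stopf("records lack column(s): %s", paste(miss, collapse = ", "))
  for (opt in c("anticodon", "start_codon", "stop_codon"))
    if (is.null(records[[opt]])) records[[opt]] <- NA_character_
  if (is.null(records[["declared_intergenic"]]))
    records[["declared_intergenic"]] <- NA_integer_
  records$name <- as.character(records$name)
  records$class <- as.character(records$class)
  records$strand <- as.character(records$strand)
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$declared_intergenic <- as.integer(records$declared_intergenic)

  n <- nrow(records)
  if (n == 0L) stopf("annotation table has no records")
  bad <- which(is.na(records$start) | is.na(records$end))
  if (length(bad)) stopf("row %d: non-integer coordinates", bad[1])
  bad <- which(records$start > records$end)
  if (length(bad))
    stopf("row %d (%s): start > end (origin-spanning features are not supported)",
          bad[1], records$name[bad[1]])
  bad <- which(records$start < 1L)
  if (length(bad)) stopf("row %d (%s): start < 1", bad[1], records$name[bad[1]])
  dup <- records$name[duplicated(records$name)]
  if (length(dup)) stopf("duplicate gene name(s): %s", paste(unique(dup), collapse = ", "))
  if (!all(records$strand %in% c("F", "R", NA_character_)))
    stopf("strand must be 'F' or 'R'")
  bad <- setdiff(unique(records$class), FEATURE_CLASSES)
  if (length(bad))
    stopf("unknown feature class(es): %s (expected %s)",
          paste(bad, collapse = ", "), paste(FEATURE_CLASSES, collapse = "/"))
  bad <- which(!is.na(records$anticodon) & records$class != "tRNA")
  if (length(bad))
    stopf("row %d (%s): anticodon given for a non-tRNA feature", bad[1],
          records$name[bad[1]])
  bad <- which(!is.na(records$stop_codon) &
                 !nchar(records$stop_codon) %in% 1:3)
  if (length(bad))
    stopf("row %d (%s): stop codon must be 1-3 nt", bad[1], records$name[bad[1]])

  unknown <- records$name[!grepl(KNOWN_NAME_RE, tolower(records$name))]
  if (length(unknown))
    message("annotation: gene name(s) outside the standard vocabulary: ",
            paste(unknown, collapse = ", "))

  if (is.null(genome_length)) genome_length <- max(records$end)
  genome_length <- as.integer(genome_length)
  if (genome_length < max(records$end))
    stopf("genome_length (%d) smaller than max feature end (%d)",
          genome_length, max(records$end))

  structure(records, class = c("annotation_table", "data.frame"),
            genome_length = genome_length, circular = isTRUE(circular))
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %d features on a %s genome of %d bp\n",
              nrow(x), if (attr(x, "circular")) "circular" else "linear",
              attr(x, "genome_length")))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("...", nrow(x) - 8, "more rows\n")
  invisible(x)
}

#' Genome length of an annotation table
#' @param ann an `annotation_table`.
#' @return integer genome length in bp.
#' @export
genome_length <- function(ann) attr(ann, "genome_length")

# absent-value markers accepted in annotation TSVs (hyphen, en dash, empty)
.absent <- function(x) {
  x <- trimws(x)
  is.na(x) | x %in% c("", "-", "–", "—", "NA")
}

#' Read an annotation table from TSV
#'
#' The dialect mirrors a published mitogenome annotation table: columns
#' `Gene`, `Class`, `Direction`, `Start`, `End`, optionally `Size`,
#' `Anticodon`, `StartCodon`, `StopCodon`, `Intergenic`. A dash or empty
#' field means absent. Comment lines starting with `#` are ignored except
#' for the optional directives `#genome_length=N` and `#circular=true/false`.
#' A `Size` column, when present, is cross-checked against
#' `End - Start + 1`; discrepancies are reported as warnings and never
#' auto-corrected.
#'
#' @param path path to the TSV file.
#' @return an [annotation_table()].
#' @export
read_annotation_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gl <- NULL
  circ <- TRUE
  for (l in grep("^#", lines, value = TRUE)) {
    m <- regmatches(l, regexec("^#\\s*genome_length\\s*=\\s*(\\d+)", l))[[1]]
    if (length(m)) gl <- as.integer(m[2])
    m <- regmatches(l, regexec("^#\\s*circular\\s*=\\s*(\\w+)", l))[[1]]
    if (length(m)) circ <- tolower(m[2]) %in% c("true", "yes", "1")
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stopf("%s: no data rows", path)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          colClasses = "character", check.names = FALSE)
  need <- c("Gene", "Class", "Direction", "Start", "End")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))

  to_int <- function(col, what) {
    out <- suppressWarnings(as.integer(col))
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!.absent(col) & (is.na(out) | num != out))
    if (length(bad)) stopf("row %d: non-integer %s '%s'", bad[1], what, col[bad[1]])
    out
  }
  start <- to_int(df$Start, "Start")
  end <- to_int(df$End, "End")
  bad <- which(start > end)
  if (length(bad)) stopf("row %d (%s): start > end", bad[1], df$Gene[bad[1]])
  opt <- function(col) {
    if (is.null(df[[col]])) return(rep(NA_character_, nrow(df)))
    ifelse(.absent(df[[col]]), NA_character_, toupper(trimws(df[[col]])))
  }
  ig <- if (is.null(df$Intergenic)) rep(NA_integer_, nrow(df)) else
    suppressWarnings(as.integer(ifelse(.absent(df$Intergenic), NA, df$Intergenic)))

  rec <- data.frame(name = trimws(df$Gene), class = trimws(df$Class),
                    strand = ifelse(.absent(df$Direction), NA, trimws(df$Direction)),
                    start = start, end = end,
                    anticodon = opt("Anticodon"),
                    start_codon = opt("StartCodon"),
                    stop_codon = opt("StopCodon"),
                    declared_intergenic = ig,
                    stringsAsFactors = FALSE)
  if (!is.null(df$Size)) {
    declared <- suppressWarnings(as.integer(df$Size))
    comp <- end - start + 1L
    off <- which(!is.na(declared) & declared != comp)
    for (i in off)
      warnf("%s: declared Size %d differs from coordinates (%d); table preserved",
            rec$name[i], declared[i], comp[i])
  }
  annotation_table(rec, genome_length = gl, circular = circ)
}

#' Write an annotation table to TSV
#'
#' Emits the same dialect [read_annotation_tsv()] reads, with a deterministic
#' column order and `#genome_length=`/`#circular=` directives, so that
#' write-then-read round trips are field-identical.
#'
#' @param ann an `annotation_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  df <- as.data.frame(ann)
  out <- data.frame(Gene = df$name, Class = df$class,
                    Direction = ifelse(is.na(df$strand), "", df$strand),
                    Start = df$start, End = df$end,
                    Size = df$end - df$start + 1L,
                    Anticodon = ifelse(is.na(df$anticodon), "", df$anticodon),
                    StartCodon = ifelse(is.na(df$start_codon), "", df$start_codon),
                    StopCodon = ifelse(is.na(df$stop_codon), "", df$stop_codon),
                    Intergenic = ifelse(is.na(df$declared_intergenic), "",
                                        df$declared_intergenic),
                    check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#genome_length=%d", attr(ann, "genome_length")), con)
  writeLines(sprintf("#circular=%s", tolower(attr(ann, "circular"))), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read features from a GenBank flat file
#'
#' A minimal reader for the FEATURES block of a GenBank record: `CDS`,
#' `tRNA`, `rRNA`, `D-loop` and `misc_feature` entries with simple
#' `a..b` / `complement(a..b)` locations are mapped onto the same model as
#' [read_annotation_tsv()]. `complement` locations become strand `R`;
#' `D-loop` entries and `misc_feature`s annotated as the A+T-rich region
#' become class `control_region`. Compound (`join`/`order`) locations,
#' including origin-spanning features, are rejected.
#'
#' @param path path to a GenBank flat file.
#' @return an [annotation_table()].
#' @export
read_genbank_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gl <- NULL
  loc <- grep("^LOCUS", lines, value = TRUE)
  if (length(loc)) {
    m <- regmatches(loc[1], regexec("(\\d+)\\s+bp", loc[1]))[[1]]
    if (length(m)) gl <- as.integer(m[2])
  }
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) stopf("%s: no FEATURES block", path)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(lines)
  block <- lines[(fstart[1] + 1L):fend]

  keymap <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
              "D-loop" = "control_region", misc_feature = "misc_feature")
  feats <- list()
  cur <- NULL
  flush <- function(cur, feats) {
    if (is.null(cur)) return(feats)
    feats[[length(feats) + 1L]] <- cur
    feats
  }
  for (l in block) {
    m <- regmatches(l, regexec("^ {2,10}(\\S+)\\s+(\\S.*)$", l))[[1]]
    is_key <- length(m) && !startsWith(m[2], "/")
    if (is_key) {
      feats <- flush(cur, feats)
      cur <- if (m[2] %in% names(keymap))
        list(key = m[2], loc = trimws(m[3]), quals = character()) else NULL
    } else if (!is.null(cur)) {
      q <- regmatches(l, regexec("^\\s+/(\\w+)=?\"?([^\"]*)\"?\\s*$", l))[[1]]
      if (length(q)) cur$quals[q[2]] <- q[3]
    }
  }
  feats <- flush(cur, feats)
  if (!length(feats)) stopf("%s: no supported features found", path)

  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    loc <- f$loc
    strand <- "F"
    if (grepl("^complement\\(", loc)) {
      strand <- "R"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("join|order|complement", loc))
      stopf("feature %d (%s): compound/origin-spanning location '%s' is not supported",
            i, f$key, f$loc)
    m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
    if (!length(m)) stopf("feature %d (%s): cannot parse location '%s'", i, f$key, f$loc)
    name <- f$quals["gene"]
    if (is.na(name)) name <- f$quals["product"]
    cls <- keymap[[f$key]]
    if (cls == "misc_feature") {
      txt <- tolower(paste(f$quals, collapse = " "))
      if (grepl("a\\+t-rich|at-rich|control region|d-loop", txt)) cls <- "control_region"
      else return(NULL)
    }
    if (cls == "control_region" && is.na(name)) name <- "CR"
    if (is.na(name)) name <- paste0(tolower(f$key), "_", i)
    anti <- NA_character_
    if (cls == "tRNA" && !is.na(f$quals["anticodon"])) {
      am <- regmatches(f$quals["anticodon"],
                       regexec("seq:([acgtuACGTU]{3})", f$quals["anticodon"]))[[1]]
      if (length(am)) anti <- toupper(chartr("Uu", "Tt", am[2]))
    }
    data.frame(name = unname(name), class = cls, strand = strand,
               start = as.integer(m[2]), end = as.integer(m[3]),
               anticodon = anti, start_codon = NA_character_,
               stop_codon = NA_character_,
               declared_intergenic = NA_integer_, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  rec <- do.call(rbind, rows)
  annotation_table(rec, genome_length = gl, circular = TRUE)
}

#' Read a genome from a FASTA file
#'
#' @param path FASTA file; the first record is used.
#' @param circular logical flag for the returned object.
#' @return a [genome_sequence()].
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stopf("%s: empty FASTA", path)
  genome_sequence(names(ss)[1], as.character(ss[[1]]), circular = circular)
}

#' Write a genome to a FASTA file
#' @param genome a [genome_sequence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Extract a gene sequence from the genome
#'
#' Returns the inclusive substring `start..end`; for strand `R` features the
#' reverse complement is returned, i.e. the gene-sense sequence.
#'
#' @param genome a [genome_sequence()] or plain DNA string.
#' @param rec one annotation record: a single-row `data.frame` or list with
#'   `strand`, `start`, `end`.
#' @return gene-sense DNA string of length `end - start + 1`.
#' @export
extract_gene_sequence <- function(genome, rec) {
  seq <- if (inherits(genome, "genome_sequence")) genome$seq else
    check_dna(genome, what = "genome")
  start <- as.integer(rec$start)
  end <- as.integer(rec$end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stopf("invalid coordinates %s..%s", rec$start, rec$end)
  if (end > nchar(seq))
    stopf("feature end %d beyond genome length %d", end, nchar(seq))
  s <- substr(seq, start, end)
  if (identical(rec$strand, "R")) s <- revcomp(s)
  s
}
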