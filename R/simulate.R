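# Synthetic mitogenome generator.
#
# Produces genomes + annotations, tRNA gene sequences with known cloverleaf
# ground truth, control regions realizing the conserved motif grammar, and
# tree-evolved alignments, so that every analysis module can be exercised
# and verified against planted parameters without any database access.
# All outputs are pure functions of (spec, seed).

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Default per-class base frequencies
#'
#' Class-specific A/C/G/T frequencies emulating a strongly A+T-biased
#' lepidopteran mitogenome (~81% A+T overall): protein-coding genes around
#' 78% A+T, tRNAs 82%, rRNAs 84.5%, and a control region around 96.5%,
#' with intergenic stretches at the whole-genome average.
#'
#' @return named list of frequency vectors (`A`,`C`,`G`,`T`, summing to 1)
#'   for `PCG`, `tRNA`, `rRNA`, `control_region`, `intergenic`.
#' @export
default_class_freqs <- function() {
  list(
    PCG = c(A = 0.4068, C = 0.1320, G = 0.0840, T = 0.3772),
    tRNA = c(A = 0.4152, C = 0.1000, G = 0.0800, T = 0.4048),
    rRNA = c(A = 0.4189, C = 0.1051, G = 0.0500, T = 0.4260),
    control_region = c(A = 0.4747, C = 0.0230, G = 0.0115, T = 0.4908),
    intergenic = c(A = 0.4078, C = 0.1133, G = 0.0768, T = 0.4021))
}

#' Codon sampling profile from base frequencies
#'
#' Weight of each non-stop codon is the product of its base frequencies
#' under the given composition, normalized to sum to 1 — the simplest
#' profile whose realized coding-strand composition matches the target.
#'
#' @param freqs named A/C/G/T frequency vector.
#' @param code_id genetic code identifier.
#' @return named numeric weights over the sense codons.
#' @export
default_codon_profile <- function(freqs = default_class_freqs()$PCG,
                                  code_id = "5") {
  gc <- mito_genetic_code(code_id)
  sense <- names(gc)[gc != "*"]
  w <- vapply(strsplit(sense, "", fixed = TRUE),
              function(b) prod(freqs[b]), numeric(1))
  stats::setNames(w / sum(w), sense)
}

#' Control-region grammar parameters
#'
#' The planted structural signals: `ATAGA` + poly-T stretch, `ATTTA` +
#' `(AT)n` microsatellite, a terminal poly-A element, and optionally a
#' tandemly duplicated repeat unit.
#'
#' @param polyt_len poly-T tract length (nt).
#' @param at_copies copies of the `AT` unit after `ATTTA`.
#' @param polya_len terminal poly-A length (nt).
#' @param repeat_unit_len length of the duplicated repeat unit (bp), or
#'   `NULL` for none.
#' @param repeat_copies copies of the repeat unit.
#' @return named list of parameters.
#' @export
cr_grammar <- function(polyt_len = 19, at_copies = 6, polya_len = 8,
                       repeat_unit_len = 25, repeat_copies = 2) {
  list(polyt_len = as.integer(polyt_len), at_copies = as.integer(at_copies),
       polya_len = as.integer(polya_len),
       repeat_unit_len = if (is.null(repeat_unit_len)) NULL else
         as.integer(repeat_unit_len),
       repeat_copies = as.integer(repeat_copies))
}

#' Reference 37-gene annotation layout
#'
#' The annotation table fixture shipped with the package: the published
#' 37-feature layout of the *Eligma narcissus* mitogenome (13 PCGs, 22
#' tRNAs, 2 rRNAs and the A+T-rich region on a 15,376 bp circle), used as
#' the default layout of the synthetic generator and as the in-package
#' acceptance surface for the layout statistics.
#'
#' @return an [annotation_table()].
#' @export
reference_layout <- function() {
  path <- system.file("extdata", "eligma_narcissus_annotation.tsv",
                      package = "mitocomp", mustWork = TRUE)
  suppressMessages(read_annotation_tsv(path))
}

#' Build a layout from gene order, lengths and signed gaps
#'
#' Alternative layout input for the generator: features are placed starting
#' at position 1 with the given signed gap after each one (the last gap is
#' the circular wrap back to position 1). The closure identity
#' `sum(lengths) + sum(gaps) == genome_length` is checked before anything
#' is sampled.
#'
#' @param genes data.frame with columns `name`, `class`, `strand`, `length`,
#'   `gap_after` (signed; last row = wrap gap).
#' @param genome_length total genome size.
#' @return an [annotation_table()].
#' @export
layout_from_gaps <- function(genes, genome_length) {
  tot <- sum(genes$length) + sum(genes$gap_after)
  if (tot != genome_length)
    stopf("inconsistent closure arithmetic: lengths + gaps = %d, genome_length = %d",
          tot, genome_length)
  start <- integer(nrow(genes))
  start[1] <- 1L
  for (i in seq_len(nrow(genes) - 1L))
    start[i + 1L] <- start[i] + genes$length[i] + genes$gap_after[i]
  rec <- data.frame(name = genes$name, class = genes$class,
                    strand = genes$strand, start = start,
                    end = start + genes$length - 1L,
                    stringsAsFactors = FALSE)
  annotation_table(rec, genome_length = genome_length, circular = TRUE)
}

#' Specification for a synthetic mitogenome
#'
#' @param layout an [annotation_table()] giving gene order, coordinates,
#'   strands, anticodons and start/stop codons; defaults to
#'   [reference_layout()].
#' @param class_freqs per-class base frequencies, see
#'   [default_class_freqs()].
#' @param codon_profile sampling weights over sense codons; default derived
#'   from the PCG frequencies.
#' @param grammar control-region grammar, see [cr_grammar()].
#' @param id genome identifier.
#' @return an object of class `synthetic_genome_spec`. Its `at_target`
#'   element is the length-weighted mixture of the class A+T targets, the
#'   value realized genomes are compared against.
#' @export
synthetic_genome_spec <- function(layout = reference_layout(),
                                  class_freqs = default_class_freqs(),
                                  codon_profile = NULL,
                                  grammar = cr_grammar(),
                                  id = "synthetic_mitogenome") {
  for (nm in names(class_freqs)) {
    f <- class_freqs[[nm]]
    if (abs(sum(f) - 1) > 1e-8)
      stopf("class_freqs$%s does not sum to 1", nm)
  }
  if (is.null(codon_profile))
    codon_profile <- default_codon_profile(class_freqs$PCG)
  df <- as.data.frame(layout)
  L <- attr(layout, "genome_length")
  covered <- logical(L)
  # PCG bodies are sampled codon-wise, so their A+T expectation is the
  # letter marginal of the codon profile, not the nominal class frequency
  pcg_at <- sum(codon_profile *
                  vapply(strsplit(names(codon_profile), "", fixed = TRUE),
                         function(b) sum(b %in% c("A", "T")) / 3, numeric(1)))
  at_of <- function(cls) {
    if (cls == "PCG") return(pcg_at)
    f <- class_freqs[[cls]]
    unname(f["A"] + f["T"])
  }
  at_num <- 0
  for (i in seq_len(nrow(df))) {
    idx <- df$start[i]:df$end[i]
    new <- idx[!covered[idx]]
    covered[new] <- TRUE
    at_num <- at_num + length(new) * at_of(df$class[i])
  }
  at_num <- at_num + sum(!covered) *
    unname(class_freqs$intergenic["A"] + class_freqs$intergenic["T"])
  structure(list(layout = layout, class_freqs = class_freqs,
                 codon_profile = codon_profile, grammar = grammar,
                 id = id, at_target = at_num / L),
            class = "synthetic_genome_spec")
}

.sample_bases <- function(n, freqs) {
  if (n <= 0) return(character())
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# realize the control-region grammar as a character vector + ground truth
.realize_cr <- function(len, grammar, freqs) {
  g <- grammar
  blocks <- list()
  truth <- list()
  pos <- 0L
  emit <- function(chars, kind = NULL, detail = NULL) {
    blocks[[length(blocks) + 1L]] <<- chars
    if (!is.null(kind))
      truth[[length(truth) + 1L]] <<- c(list(kind = kind, start = pos + 1L,
                                             end = pos + length(chars)), detail)
    pos <<- pos + length(chars)
  }
  filler <- function(n, no_lead = NULL, no_lead2 = NULL) {
    if (n <= 0) return(character())
    x <- .sample_bases(n, freqs)
    # guard the first filler bases so planted tracts are not extended
    if (!is.null(no_lead) && x[1] %in% no_lead)
      x[1] <- sample(setdiff(names(freqs), no_lead), 1)
    if (!is.null(no_lead2) && n >= 2 && length(no_lead2) == 2 &&
        x[1] == no_lead2[1] && x[2] == no_lead2[2])
      x[2] <- sample(setdiff(names(freqs), no_lead2[2]), 1)
    x
  }
  fixed_nt <- 10L + 5L + g$polyt_len + 5L + 2L * g$at_copies + 8L + 5L +
    (if (is.null(g$repeat_unit_len)) 0L else g$repeat_unit_len * g$repeat_copies) +
    g$polya_len
  slack <- len - fixed_nt
  if (slack < 12L)
    stopf("control region of %d nt too short for the grammar (needs >= %d)",
          len, fixed_nt + 12L)
  mid1 <- slack %/% 3L
  mid2 <- slack %/% 3L
  mid3 <- slack - mid1 - mid2

  emit(filler(10L))
  emit(c(strsplit("ATAGA", "")[[1]], rep("T", g$polyt_len)),
       kind = "ATAGA_polyT", detail = list(gap = 0L, tract_length = g$polyt_len))
  emit(filler(mid1, no_lead = "T"))
  emit(c(strsplit("ATTTA", "")[[1]], rep(c("A", "T"), g$at_copies)),
       kind = "ATTTA_microsat",
       detail = list(gap = 0L, copies = g$at_copies))
  emit(filler(8L, no_lead2 = c("A", "T")))
  if (!is.null(g$repeat_unit_len)) {
    unit <- .sample_bases(g$repeat_unit_len, c(A = .35, C = .12, G = .12, T = .41))
    # make the unit aperiodic enough that the duplication is called at its
    # own period rather than a divisor
    unit[1:2] <- c("G", "C")
    unit[g$repeat_unit_len] <- "G"
    emit(rep(unit, g$repeat_copies), kind = "tandem_repeat",
         detail = list(period = g$repeat_unit_len, copies = g$repeat_copies))
  }
  emit(filler(mid2 + 5L, no_lead = unlist(strsplit("G", ""))))
  emit(filler(mid3, no_lead = NULL))
  # ensure the base before the terminal poly-A is not A
  last <- blocks[[length(blocks)]]
  if (length(last) && last[length(last)] == "A") {
    last[length(last)] <- "T"
    blocks[[length(blocks)]] <- last
  }
  emit(rep("A", g$polya_len), kind = "polyA",
       detail = list(tract_length = g$polya_len))
  chars <- unlist(blocks)
  stopifnot(length(chars) == len)
  truth_df <- do.call(rbind, lapply(truth, function(t)
    data.frame(kind = t$kind, start = t$start, end = t$end,
               gap = if (is.null(t$gap)) NA_integer_ else t$gap,
               tract_length = if (is.null(t$tract_length)) NA_integer_ else t$tract_length,
               copies = if (is.null(t$copies)) NA_integer_ else t$copies,
               period = if (is.null(t$period)) NA_integer_ else t$period,
               stringsAsFactors = FALSE)))
  list(chars = chars, truth = truth_df)
}

# realized stop codon from length arithmetic: a 1-2 nt trailer when the
# length is not a multiple of 3, else the declared (or TAA) full stop
.realized_stop <- function(len, declared) {
  r <- len %% 3L
  if (r > 0L) substr("TAA", 1L, r)
  else if (!is.na(declared) && nchar(declared) == 3L) declared else "TAA"
}

#' Generate a synthetic mitogenome
#'
#' Realizes the spec's layout exactly: every feature keeps its coordinates
#' and strand; protein-coding genes get their declared start codon, a body
#' of codons sampled from the codon profile, and a stop consistent with
#' their length (full `TAA`/`TAG`, or the 1-2 nt incomplete trailer the
#' length arithmetic implies); the control region realizes the motif
#' grammar verbatim; tRNA/rRNA bodies and intergenic gaps are sampled
#' i.i.d. from the class frequencies. Start/stop codons and the control
#' region are written first as hard constraints with conflict detection, so
#' overlapping genes never corrupt them; remaining overlapping positions
#' are owned by the earlier feature in table order. Deterministic per seed.
#'
#' @param spec a [synthetic_genome_spec()].
#' @param seed integer seed.
#' @return list with `genome` (a [genome_sequence()]), `annotation` (an
#'   [annotation_table()] with realized start/stop codons), `cr_truth`
#'   (planted control-region features, local coordinates) and `at_target`.
#' @export
generate_mitogenome <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  df <- as.data.frame(spec$layout)
  L <- attr(spec$layout, "genome_length")
  set.seed(derive_seed(seed, 1L))
  geno <- rep(NA_character_, L)
  fixed <- logical(L)

  sense_to_genome <- function(sense, start, end, strand) {
    if (identical(strand, "R"))
      list(idx = end:start, vals = unname(COMPLEMENT[sense]))
    else list(idx = start:end, vals = sense)
  }
  place_hard <- function(sense, s_from, s_to, row) {
    l <- row$end - row$start + 1L
    if (identical(row$strand, "R")) {
      idx <- (row$end - s_from + 1L):(row$end - s_to + 1L)
      vals <- unname(COMPLEMENT[sense])
    } else {
      idx <- (row$start + s_from - 1L):(row$start + s_to - 1L)
      vals <- sense
    }
    clash <- fixed[idx] & geno[idx] != vals
    if (any(clash))
      stopf("constraint conflict at genome position %d (feature %s)",
            idx[which(clash)[1]], row$name)
    geno[idx] <<- vals
    fixed[idx] <<- TRUE
  }

  # pass 1: hard constraints
  realized_start <- realized_stop <- rep(NA_character_, nrow(df))
  cr_truth <- NULL
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    l <- row$end - row$start + 1L
    if (row$class == "PCG") {
      st <- if (!is.na(row$start_codon)) row$start_codon else "ATG"
      sp <- .realized_stop(l, row$stop_codon)
      realized_start[i] <- st
      realized_stop[i] <- sp
      place_hard(strsplit(st, "")[[1]], 1L, 3L, row)
      place_hard(strsplit(sp, "")[[1]], l - nchar(sp) + 1L, l, row)
    } else if (row$class == "control_region") {
      cr <- .realize_cr(l, spec$grammar, spec$class_freqs$control_region)
      cr_truth <- cr$truth
      place_hard(cr$chars, 1L, l, row)
    }
  }

  # pass 2: feature bodies, earlier features own shared positions
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    l <- row$end - row$start + 1L
    if (row$class == "control_region") next
    sense <- if (row$class == "PCG") {
      n_cod <- (l - 3L - nchar(realized_stop[i])) %/% 3L
      cods <- sample(names(spec$codon_profile), n_cod, replace = TRUE,
                     prob = spec$codon_profile)
      strsplit(paste0(realized_start[i], paste(cods, collapse = ""),
                      realized_stop[i]), "")[[1]]
    } else .sample_bases(l, spec$class_freqs[[row$class]])
    m <- sense_to_genome(sense, row$start, row$end, row$strand)
    free <- is.na(geno[m$idx])
    geno[m$idx[free]] <- m$vals[free]
  }
  free <- is.na(geno)
  geno[free] <- .sample_bases(sum(free), spec$class_freqs$intergenic)

  rec <- df
  rec$start_codon[rec$class == "PCG"] <- realized_start[rec$class == "PCG"]
  rec$stop_codon[rec$class == "PCG"] <- realized_stop[rec$class == "PCG"]
  ann <- annotation_table(rec, genome_length = L,
                          circular = attr(spec$layout, "circular"))
  list(genome = genome_sequence(spec$id, paste(geno, collapse = "")),
       annotation = ann, cr_truth = cr_truth, at_target = spec$at_target)
}

#' tRNA template specification
#'
#' @param anticodon 3 nt anticodon (DNA alphabet).
#' @param layout named element sizes (`acceptor`, `link1`, `d_stem`,
#'   `d_loop`, `link2`, `ac_stem`, `var_loop`, `t_stem`, `t_loop`); the
#'   anticodon loop is always 7 nt.
#' @param noncanonical data.frame of planted non-Watson-Crick stem pairs
#'   with columns `arm` (`acceptor_stem` / `d_arm` / `anticodon_arm` /
#'   `t_arm`), `pair` (1-based index within the stem, from the outside in)
#'   and `type` (`"wobble"`, `"A-A"`, `"U-U"`, ... in the RNA alphabet).
#' @return list of class `trna_template` with the total `length`.
#' @export
trna_template <- function(anticodon,
                          layout = c(acceptor = 7, link1 = 2, d_stem = 4,
                                     d_loop = 8, link2 = 1, ac_stem = 5,
                                     var_loop = 4, t_stem = 5, t_loop = 7),
                          noncanonical = NULL) {
  anticodon <- check_dna(anticodon, allow_n = FALSE, what = "anticodon")
  if (nchar(anticodon) != 3L) stopf("anticodon must be 3 nt")
  len <- 2L * layout[["acceptor"]] + layout[["link1"]] +
    2L * layout[["d_stem"]] + layout[["d_loop"]] + layout[["link2"]] +
    2L * layout[["ac_stem"]] + 7L + layout[["var_loop"]] +
    2L * layout[["t_stem"]] + layout[["t_loop"]]
  if (is.null(noncanonical))
    noncanonical <- data.frame(arm = character(), pair = integer(),
                               type = character(), stringsAsFactors = FALSE)
  structure(list(anticodon = anticodon, layout = layout,
                 noncanonical = noncanonical, length = len),
            class = "trna_template")
}

#' Generate a tRNA gene sequence with known structure
#'
#' Builds a sequence realizing the template: stem pairs are Watson-Crick
#' except for the planted non-canonical pairs, loops and linkers are
#' sampled from tRNA-like base frequencies, and the anticodon occupies loop
#' positions 3-5. The result is verified by [fold_cloverleaf()]: if the
#' recovered structure does not match the planted boundaries and pair
#' classes (a rare event for pathological loop draws, or inevitable when
#' too many planted mismatches make the fold non-optimal), the nucleotides
#' are resampled from a derived seed; after `max_attempts` failures the
#' template is rejected as unrealizable.
#'
#' @param template a [trna_template()].
#' @param seed integer seed.
#' @param constraints fold constraints used for verification.
#' @param max_attempts resampling budget.
#' @return list with `seq`, `structure` (the verified
#'   [fold_cloverleaf()] result), `template`.
#' @export
generate_trna <- function(template, seed = 1,
                          constraints = cloverleaf_constraints(),
                          max_attempts = 50) {
  stopifnot(inherits(template, "trna_template"))
  lay <- template$layout
  freqs <- c(A = 0.38, C = 0.12, G = 0.12, T = 0.38)
  arm_sizes <- c(acceptor_stem = lay[["acceptor"]], d_arm = lay[["d_stem"]],
                 anticodon_arm = lay[["ac_stem"]], t_arm = lay[["t_stem"]])
  nc <- template$noncanonical
  if (nrow(nc)) {
    bad <- which(!(nc$arm %in% names(arm_sizes)) | nc$pair < 1 |
                   nc$pair > arm_sizes[nc$arm])
    if (length(bad)) stopf("noncanonical pair %d outside its stem", bad[1])
  }
  planted_counts <- list(
    n_wobble = sum(nc$type == "wobble"),
    n_mismatch = sum(nc$type != "wobble"))

  sample_stem <- function(arm, k) {
    p5 <- character(k)
    p3 <- character(k)
    for (i in seq_len(k)) {
      t <- nc$type[nc$arm == arm & nc$pair == i]
      if (length(t) == 0) {
        b <- sample(names(freqs), 1, prob = freqs)
        p5[i] <- b
        p3[i] <- COMPLEMENT[[b]]
      } else if (t == "wobble") {
        gt <- sample(list(c("G", "T"), c("T", "G")), 1)[[1]]
        p5[i] <- gt[1]
        p3[i] <- gt[2]
      } else {
        bb <- chartr("U", "T", strsplit(t, "-", fixed = TRUE)[[1]])
        if (length(bb) != 2) stopf("bad noncanonical type '%s'", t)
        p5[i] <- bb[1]
        p3[i] <- bb[2]
      }
    }
    list(p5 = p5, p3 = p3)
  }

  can_pair <- function(x, y)
    paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  for (attempt in seq_len(max_attempts)) {
    set.seed(derive_seed(seed, attempt))
    acc <- sample_stem("acceptor_stem", lay[["acceptor"]])
    dd <- sample_stem("d_arm", lay[["d_stem"]])
    ac <- sample_stem("anticodon_arm", lay[["ac_stem"]])
    tt <- sample_stem("t_arm", lay[["t_stem"]])
    acl <- .sample_bases(7L, freqs)
    acl[3:5] <- strsplit(template$anticodon, "")[[1]]
    link1 <- .sample_bases(lay[["link1"]], freqs)
    dloop <- .sample_bases(lay[["d_loop"]], freqs)
    link2 <- .sample_bases(lay[["link2"]], freqs)
    vloop <- .sample_bases(lay[["var_loop"]], freqs)
    tloop <- .sample_bases(lay[["t_loop"]], freqs)
    # guard positions that could extend a planted stem by one opportunistic
    # pair (a same-base pair is always a mismatch): D stem into the linkers
    # or the D-loop ends, T stem into the T-loop ends, acceptor stem into
    # link1 / the T arm when only 6 bp are planted
    if (lay[["d_stem"]] < max(constraints$d_stem)) {
      if (length(link1) && length(link2) &&
          can_pair(link1[length(link1)], link2[1]))
        link1[length(link1)] <- link2[1]
      if (can_pair(dloop[1], dloop[length(dloop)]))
        dloop[length(dloop)] <- dloop[1]
    }
    if (lay[["t_stem"]] < max(constraints$t_stem) &&
        can_pair(tloop[1], tloop[length(tloop)]))
      tloop[length(tloop)] <- tloop[1]
    if (lay[["acceptor"]] < max(constraints$acceptor) && length(link1) &&
        can_pair(link1[1], tt$p3[1]))
      link1[1] <- tt$p3[1]
    seq <- paste(c(acc$p5, link1, dd$p5, dloop, rev(dd$p3), link2,
                   ac$p5, acl, rev(ac$p3), vloop,
                   tt$p5, tloop, rev(tt$p3), rev(acc$p3)), collapse = "")
    fold <- tryCatch(fold_cloverleaf(seq, constraints), error = function(e) NULL)
    if (is.null(fold)) next
    want <- c(acceptor = lay[["acceptor"]], link1 = lay[["link1"]],
              d_stem = lay[["d_stem"]], d_loop = lay[["d_loop"]],
              link2 = lay[["link2"]], ac_stem = lay[["ac_stem"]],
              ac_loop = 7, var_loop = lay[["var_loop"]],
              t_stem = lay[["t_stem"]], t_loop = lay[["t_loop"]])
    if (!identical(unname(fold$layout[names(want)]), unname(as.integer(want))))
      next
    if (fold$n_wobble != planted_counts$n_wobble ||
        fold$n_mismatch != planted_counts$n_mismatch) next
    return(list(seq = seq, structure = fold, template = template))
  }
  stopf("template not realizable as the optimal cloverleaf after %d attempts %s",
        max_attempts, "(planted mismatches may make the fold non-optimal)")
}

#' Template set emulating a 22-tRNA mitogenome
#'
#' One template per mitochondrial tRNA with its standard anticodon, with
#' lightly varied arm sizes (gene lengths 63-71 nt) and a planted aggregate
#' of 8 G-U wobble pairs, 1 A-A and 2 U-U mismatches distributed across the
#' set — the pair-class profile reported for lepidopteran mitogenomes.
#'
#' @return named list of [trna_template()] objects.
#' @export
trna_template_set <- function() {
  anticodons <- c(
    trnM = "CAT", trnI = "GAT", trnQ = "TTG", trnW = "TCA", trnC = "GCA",
    trnY = "GTA", trnL2 = "TAA", trnK = "CTT", trnD = "GTC", trnG = "TCC",
    trnA = "TGC", trnR = "TCG", trnN = "GTT", trnS1 = "GCT", trnE = "TTC",
    trnF = "GAA", trnH = "GTG", trnT = "TGT", trnP = "TGG", trnS2 = "TGA",
    trnL1 = "TAG", trnV = "TAC")
  layouts <- list(
    c(acceptor = 7, link1 = 2, d_stem = 4, d_loop = 8, link2 = 1, ac_stem = 5,
      var_loop = 4, t_stem = 5, t_loop = 7),
    c(acceptor = 7, link1 = 2, d_stem = 4, d_loop = 7, link2 = 1, ac_stem = 5,
      var_loop = 4, t_stem = 4, t_loop = 7),
    c(acceptor = 7, link1 = 2, d_stem = 3, d_loop = 7, link2 = 1, ac_stem = 5,
      var_loop = 4, t_stem = 4, t_loop = 6),
    c(acceptor = 6, link1 = 2, d_stem = 3, d_loop = 7, link2 = 1, ac_stem = 4,
      var_loop = 4, t_stem = 4, t_loop = 6))
  wobble_arms <- c("acceptor_stem", "t_arm", "anticodon_arm", "acceptor_stem",
                   "d_arm", "t_arm", "anticodon_arm", "acceptor_stem")
  out <- list()
  for (i in seq_along(anticodons)) {
    nm <- names(anticodons)[i]
    nc <- NULL
    if (i <= 8)  # one wobble pair each in the first eight tRNAs
      nc <- data.frame(arm = wobble_arms[i], pair = 2L + (i %% 2L),
                       type = "wobble", stringsAsFactors = FALSE)
    if (i == 9)
      nc <- data.frame(arm = "d_arm", pair = 2L, type = "A-A",
                       stringsAsFactors = FALSE)
    if (i %in% c(10, 11))
      nc <- data.frame(arm = "t_arm", pair = 2L, type = "U-U",
                       stringsAsFactors = FALSE)
    out[[nm]] <- trna_template(anticodons[[i]],
                               layout = layouts[[1L + (i - 1L) %% 4L]],
                               noncanonical = nc)
  }
  out
}

#' Evolve sequences along a tree
#'
#' Site-independent nucleotide evolution under JC69 (equal base frequencies
#' and exchange rates; branch lengths in expected substitutions per site),
#' delegated to \pkg{phangorn}'s sequence simulator under a fixed seed.
#' Zero-length branches yield identical child sequences.
#'
#' @param tree a `phylo` tree with branch lengths (>= 0).
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @param model substitution model; only `"JC69"` is supported.
#' @return character matrix (taxa x sites, uppercase).
#' @export
evolve_alignment <- function(tree, n_sites, seed = 1, model = "JC69") {
  model <- match.arg(model, "JC69")
  if (any(tree$edge.length < 0)) stopf("negative branch lengths")
  set.seed(derive_seed(seed, 1L))
  sim <- phangorn::simSeq(tree, l = n_sites, type = "DNA")
  m <- toupper(as.character(sim))
  m[, , drop = FALSE]
}

#' Evolve a set of gene partitions along one tree
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param lengths named integer vector of per-gene alignment lengths.
#' @param seed integer master seed; each gene uses a derived stream.
#' @param model see [evolve_alignment()].
#' @return named list of character matrices, ready for [concatenate()].
#' @export
evolve_partitions <- function(tree, lengths, seed = 1, model = "JC69") {
  if (is.null(names(lengths))) names(lengths) <- paste0("gene", seq_along(lengths))
  out <- lapply(seq_along(lengths), function(i)
    evolve_alignment(tree, lengths[[i]], seed = derive_seed(seed, i),
                     model = model))
  names(out) <- names(lengths)
  out
}

#' Demonstration tree shaped like the lepidopteran superfamily phylogeny
#'
#' A 21-taxon tree (19 lepidopterans in six superfamily clades plus two
#' dipteran outgroups) with low divergence, used to exercise the phylogeny
#' stage: the Noctuoidea clade is planted and should be recovered as
#' monophyletic.
#'
#' @return list with `tree` (a `phylo`), `noctuoidea` (tip names of the
#'   planted clade) and `outgroup` (tip names).
#' @export
demo_lepidoptera_tree <- function() {
  nwk <- paste0(
    "(((((((E_narcissus:0.02,A_ipsilon:0.02):0.01,(H_armigera:0.015,",
    "H_assulta:0.015):0.015):0.01,S_inferens:0.04):0.01,(H_cunea:0.03,",
    "(P_flavescens:0.025,L_dispar:0.025):0.005):0.02):0.03,",
    "((B_mori:0.02,A_selene:0.02):0.01,M_sexta:0.03):0.04):0.01,",
    "(((E_interruptalis:0.03,C_cephalonica:0.03):0.03,(A_fimbriana:0.02,",
    "A_orana:0.02):0.04):0.01,(P_suzukiella:0.05,(P_syfanius:0.02,",
    "(T_aureus:0.015,P_nepenthes:0.015):0.005):0.03):0.02):0.02):0.08,",
    "(D_incompta:0.05,A_gambiae:0.05):0.08);")
  tree <- ape::read.tree(text = nwk)
  list(tree = tree,
       noctuoidea = c("E_narcissus", "A_ipsilon", "H_armigera", "H_assulta",
                      "S_inferens", "H_cunea", "P_flavescens", "L_dispar"),
       outgroup = c("D_incompta", "A_gambiae"))
}
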