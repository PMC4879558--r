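# One-shot report orchestration: runs the analysis stages over one genome +
# annotation (and optionally a directory of per-gene alignments) and writes
# a reproducible bundle of TSVs plus a plain-text summary. Every number in
# the summary comes from the corresponding module output — the formatter
# recomputes nothing.

.config_defaults <- function() {
  list(fasta = NULL, annotation = NULL, alignments_dir = NULL,
       out_dir = "mitocomp_report", use_declared = FALSE, seed = 42L,
       bootstrap_reps = 100L, model = "JC69", outgroup = NULL,
       stage_composition = TRUE, stage_layout = TRUE, stage_codons = TRUE,
       stage_trna = TRUE, stage_control_region = TRUE,
       stage_phylogeny = NA)
}

#' Validate a run configuration
#'
#' @param config named list or path to a flat YAML file. Unknown keys are
#'   rejected.
#' @return the completed configuration list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || !length(config)) stopf("empty or invalid config")
  defs <- .config_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defs, config)
  if (is.null(out$fasta) || is.null(out$annotation))
    stopf("config must name 'fasta' and 'annotation' inputs")
  if (is.na(out$stage_phylogeny))
    out$stage_phylogeny <- !is.null(out$alignments_dir)
  out
}

#' Run the full characterization report
#'
#' Executes the configured stages — per-class composition, gene layout
#' (computed and, when a declared intergenic column exists, declared mode),
#' codon usage/RSCU, tRNA cloverleaf folding, control-region motif and
#' repeat scanning, and (when alignments are configured) the NJ + bootstrap
#' phylogeny — writing one TSV per stage, a Newick tree, a plain-text
#' summary and the configuration used. Any stage failure aborts the run
#' with the stage name and removes the partial bundle.
#'
#' @param config a list or YAML path accepted by [run_config()].
#' @return the output directory, invisibly.
#' @export
run_report <- function(config) {
  cfg <- run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  fail <- function(stage, e) {
    unlink(written)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  summary_lines <- character()
  say <- function(...) summary_lines <<- c(summary_lines, sprintf(...))

  genome <- tryCatch(read_genome_fasta(cfg$fasta), error = function(e) fail("input", e))
  ann <- tryCatch(suppressMessages(read_annotation_tsv(cfg$annotation)),
                  error = function(e) fail("input", e))
  say("Genome %s: %d bp, %d annotated features.", genome$id,
      nchar(genome$seq), nrow(ann))

  if (isTRUE(cfg$stage_composition)) tryCatch({
    cmp <- suppressMessages(summarize_regions(genome, ann))
    emit(composition_table(cmp), "composition.tsv")
    wg <- cmp$whole_genome
    say("Whole-genome A+T content %.2f%%; AT skew %.3f; GC skew %.3f.",
        round_half_up(wg$at_content, 2), round_half_up(wg$at_skew, 3),
        round_half_up(wg$gc_skew, 3))
  }, error = function(e) fail("composition", e))

  if (isTRUE(cfg$stage_layout)) tryCatch({
    rep_c <- layout_summary(ann, mode = "computed")
    emit(rep_c$adjacencies, "layout.tsv")
    say(paste0("Gene layout (computed): %d bp of overlap in %d positions ",
               "(max %d bp, %s-%s); %d bp of spacers in %d regions (max %d bp, %s-%s)."),
        rep_c$total_overlap_bp, rep_c$n_overlaps, rep_c$max_overlap$bp,
        rep_c$max_overlap$pair[1], rep_c$max_overlap$pair[2],
        rep_c$total_spacer_bp, rep_c$n_spacers, rep_c$max_spacer$bp,
        rep_c$max_spacer$pair[1], rep_c$max_spacer$pair[2])
    if (isTRUE(cfg$use_declared)) {
      rep_d <- layout_summary(ann, mode = "declared")
      emit(rep_d$adjacencies, "layout_declared.tsv")
      say("Gene layout (declared column): %d bp of overlap in %d positions; %d bp of spacers in %d regions.",
          rep_d$total_overlap_bp, rep_d$n_overlaps,
          rep_d$total_spacer_bp, rep_d$n_spacers)
    }
  }, error = function(e) fail("layout", e))

  if (isTRUE(cfg$stage_codons)) tryCatch({
    cu <- codon_usage(genome, ann)
    emit(suppressMessages(codon_usage_table(cu)), "codon_usage.tsv")
    top <- utils::head(rank_amino_acids(cu), 5)
    say("PCGs contain %d sense codons; most used amino acids: %s.",
        cu$total_codons, paste(top, collapse = ", "))
  }, error = function(e) fail("codon_usage", e))

  if (isTRUE(cfg$stage_trna)) tryCatch({
    df <- as.data.frame(ann)
    tr <- df[df$class == "tRNA", , drop = FALSE]
    rows <- lapply(seq_len(nrow(tr)), function(i) {
      s <- extract_gene_sequence(genome, tr[i, ])
      fold <- tryCatch(fold_cloverleaf(s), error = function(e) NULL)
      if (is.null(fold))
        return(data.frame(Gene = tr$name[i], Length = nchar(s), Score = NA,
                          WC = NA, Wobble = NA, Mismatch = NA,
                          Anticodon = NA, DotBracket = NA))
      data.frame(Gene = tr$name[i], Length = nchar(s), Score = fold$score,
                 WC = fold$n_wc, Wobble = fold$n_wobble,
                 Mismatch = fold$n_mismatch,
                 Anticodon = locate_anticodon(fold),
                 DotBracket = dot_bracket(fold))
    })
    tab <- do.call(rbind, rows)
    emit(tab, "trna_structures.tsv")
    say("tRNA folding: %d/%d genes fold into a cloverleaf.",
        sum(!is.na(tab$Score)), nrow(tab))
  }, error = function(e) fail("trna", e))

  if (isTRUE(cfg$stage_control_region)) tryCatch({
    crf <- control_region_features(genome, ann)
    both <- merge(crf$motifs, crf$repeats, all = TRUE, sort = FALSE)
    emit(both[order(both$start), ], "control_region.tsv")
    say("Control region (%d bp at offset %d): %d motif hit(s), %d tandem repeat(s).",
        nchar(crf$region), crf$offset, nrow(crf$motifs), nrow(crf$repeats))
  }, error = function(e) fail("control_region", e))

  if (isTRUE(cfg$stage_phylogeny)) tryCatch({
    files <- list.files(cfg$alignments_dir, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    if (!length(files)) stopf("no FASTA alignments in %s", cfg$alignments_dir)
    alns <- stats::setNames(lapply(files, read_alignment_fasta),
                            sub("\\.[^.]+$", "", basename(files)))
    sm <- concatenate(alns)
    mask <- select_blocks(sm)
    smk <- apply_mask(sm, mask)
    tree <- bootstrap_support(smk, n_reps = cfg$bootstrap_reps,
                              seed = cfg$seed, model = cfg$model)
    path <- file.path(out_dir, "tree.nwk")
    write_newick(tree, path)
    written <- c(written, path)
    say("Phylogeny: %d taxa, %d/%d columns kept, NJ + %d bootstrap replicates (%s distances).",
        length(smk$taxa), ncol(smk$mat), ncol(sm$mat),
        attr(tree, "n_effective"), cfg$model)
  }, error = function(e) fail("phylogeny", e))

  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  yaml::write_yaml(cfg, file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}
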