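#' Run the full analysis pipeline from a single configuration
#'
#' Ties the stages into one reproducible run: simulate a genome and detect
#' its repeat family, enumerate conformations and flanking pairs, quantify
#' read-pair support and test recombinational equilibrium, predict virtual
#' Southern bands, build the tRNA decoding table, run the RNA
#' structure-conservation test, and scan a planted alignment for conversion
#' tracts.  One global seed is split deterministically per stage, so a config
#' plus seed fully determines every number in the report.
#'
#' @param config a nested list, or the path of a YAML file with the same
#'   shape.  Top level: `seed` (integer), `stages` (character subset of
#'   `genome`, `repeats`, `conformations`, `support`, `southern`, `trna`,
#'   `rna`, `geneconv`), optional `outdir`, and one optional parameter block
#'   per stage (see Details in the vignette).  Stage dependencies
#'   (`repeats`/`support`/`southern` need `genome`) are validated before
#'   anything runs.
#' @return A `mitodyn_report` list with one entry per executed stage plus
#'   `headline` (the key numbers: conformation and flanking-pair counts,
#'   supported pairs, equilibrium p, band count, codons/amino acids decoded,
#'   conservation p, top conversion fragment p).  If `outdir` is set, stage
#'   outputs and a JSON report are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_mitodyn("config must be a list or a YAML file path")
  stages <- config$stages %||% c("genome", "repeats", "conformations",
                                 "support", "southern", "trna", "rna", "geneconv")
  known <- c("genome", "repeats", "conformations", "support", "southern",
             "trna", "rna", "geneconv")
  if (length(stages) == 0L) stop_mitodyn("empty stage selection")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_mitodyn("unknown stage(s): ", paste(bad, collapse = ", "))
  needs_genome <- intersect(stages, c("repeats", "support", "southern"))
  if (length(needs_genome) && !"genome" %in% stages)
    stop_mitodyn("stage(s) ", paste(needs_genome, collapse = ", "),
                 " require the genome stage")
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  report <- list(seed = seed, stages = stages,
                 package_version = as.character(utils::packageVersion("mitodyn")))
  headline <- list()
  gt <- NULL; pool <- NULL

  if ("genome" %in% stages) {
    gp <- config$genome %||% list()
    gp$seed <- split_seed(seed, 1L)
    spec <- do.call(genome_spec, gp)
    gt <- make_genome(spec)
    report$genome <- list(length = gt$genome$length,
                          n_repeats = gt$truth$n_repeats,
                          core_length = gt$truth$core_length)
    if (!is.null(outdir)) {
      write_genome_fasta(gt$genome, file.path(outdir, "genome.fasta"))
      write_truth_gff3(gt$truth, gt$genome, file.path(outdir, "genome.gff3"))
    }
  }

  if ("repeats" %in% stages) {
    rp <- config$repeats %||% list()
    fams <- find_repeat_families(gt$genome, min_length = rp$min_length %||% 50L)
    fam <- if (length(fams)) compute_extensions(gt$genome, fams[[1L]]) else NULL
    report$repeats <- list(
      n_families = length(fams),
      core_length = if (!is.null(fam)) fam$core_length else NA_integer_,
      n_copies = if (!is.null(fam)) fam$n_copies else NA_integer_)
  }

  n_rep <- if (!is.null(gt)) gt$truth$n_repeats else
    (config$conformations$n_repeats %||% 6L)

  if ("conformations" %in% stages) {
    report$conformations <- list(
      master_circles = count_master_circles(n_rep),
      flanking_pairs = nrow(enumerate_flanking_pairs(n_rep)),
      subgenomic_circles = if (n_rep >= 2L)
        count_subgenomic_circles(n_rep, n_rep - 1L) else 0)
    headline$master_circle_conformations <- report$conformations$master_circles
    headline$flanking_pairs <- report$conformations$flanking_pairs
  }

  if ("support" %in% stages || "southern" %in% stages)
    pool <- make_equilibrium_molecules(gt$genome, gt$truth)

  if ("support" %in% stages) {
    sp <- config$support %||% list()
    reads <- make_read_pairs(pool,
                             coverage = sp$coverage %||% 7,
                             insert_range = sp$insert_range %||% c(4000L, 6500L),
                             read_length = sp$read_length %||% 700L,
                             seed = split_seed(seed, 2L))
    fam <- family_from_truth(gt$truth)
    sup <- support_from_read_pairs(reads, gt$genome, fam,
                                   insert_bounds = sp$insert_range %||% c(4000L, 6500L))
    eq <- equilibrium_test(sup)
    report$support <- list(n_read_pairs = nrow(reads),
                           supported_pairs = supported_pairs(sup),
                           equilibrium_p = eq$p.value,
                           evenness = eq$evenness)
    headline$supported_flanking_pairs <- report$support$supported_pairs
    headline$equilibrium_p <- eq$p.value
    if (!is.null(outdir)) {
      utils::write.table(sup$counts, file.path(outdir, "support_counts.tsv"),
                         sep = "\t", quote = FALSE)
    }
  }

  if ("southern" %in% stages) {
    tp <- config$southern %||% list()
    probe <- tp$probe %||% default_probe(gt$truth)
    blot <- virtual_southern(pool, probe)
    report$southern <- list(probe = probe, n_bands = length(blot$bands),
                            bands = blot$bands)
    headline$southern_bands <- length(blot$bands)
    if (!is.null(outdir))
      utils::write.table(blot$fragments, file.path(outdir, "bands.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("trna" %in% stages) {
    np <- config$trna %||% list()
    trnas <- make_trna_set(np$preset %||% "silene_latifolia_table1")
    tab <- build_decoding_table(trnas,
                                include_pseudogenes = np$include_pseudogenes %||% TRUE)
    cap <- capacity_summary(tab)
    report$trna <- cap
    headline$codons_decoded <- cap$codons_decoded
    headline$amino_acids_covered <- cap$amino_acids_covered
    if (!is.null(outdir))
      utils::write.table(as.data.frame(tab), file.path(outdir, "decoding_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("rna" %in% stages) {
    rp <- config$rna %||% list()
    db <- rp$structure %||% example_5s_structure()
    st <- parse_structure(db)
    ref <- make_structured_rna(st$length, st, seed = split_seed(seed, 3L))
    k <- rp$k %||% 16L
    obs <- mutate_in_loops(ref, st, k, seed = split_seed(seed, 4L))
    ct <- conservation_test(ref, st, obs, N = rp$N %||% 1000L,
                            seed = split_seed(seed, 5L))
    report$rna <- list(k = ct$k, N = ct$N, observed_dg = ct$observed_dg,
                       p = ct$p.value)
    headline$conservation_p <- ct$p.value
  }

  if ("geneconv" %in% stages) {
    gp <- config$geneconv %||% list()
    aln <- make_conversion_alignment(
      recipient_len = gp$recipient_len %||% 650L,
      donor_divergence = gp$donor_divergence %||% 0.25,
      tract = gp$tract %||% c(300L, 50L),
      outgroup_divergence = gp$outgroup_divergence %||% 0.02,
      seed = split_seed(seed, 6L))
    prof <- condense_alignment(aln)
    frags <- conversion_pvalue(prof, mismatch_cost = gp$mismatch_cost %||% 1,
                               n_perm = gp$n_perm %||% 999L,
                               seed = split_seed(seed, 7L))
    top <- if (nrow(frags)) frags[1L, ] else NULL
    report$geneconv <- list(
      n_sites = length(prof$columns),
      top_score = if (!is.null(top)) top$score else NA_real_,
      top_interval = if (!is.null(top)) c(top$col_start, top$col_end) else NULL,
      top_p = if (!is.null(top)) top$p.value else NA_real_,
      true_tract = unname(aln$tract))
    headline$conversion_p <- report$geneconv$top_p
  }

  report$headline <- headline
  class(report) <- "mitodyn_report"
  if (!is.null(outdir))
    jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' Place k substitutions only at unpaired (loop) positions
#'
#' Companion to [mutate_k()]: the same substitution model, but positions are
#' drawn from the loop positions of a reference structure.  Because loop
#' penalties depend only on loop size, a loop-confined mutant has exactly the
#' reference's free energy under the reduced model — the idealised signature
#' of selection for structure conservation.
#'
#' @param sequence the reference sequence.
#' @param structure its `secondary_structure` or dot-bracket string.
#' @param k number of substitutions (at most the number of unpaired positions).
#' @param seed integer seed (`NULL` uses the ambient RNG stream).
#' @return The mutated sequence.
#' @export
mutate_in_loops <- function(sequence, structure, k, seed = NULL) {
  st <- if (inherits(structure, "secondary_structure")) structure
  else parse_structure(structure)
  unpaired <- setdiff(seq_len(st$length), as.vector(st$pairs))
  if (k > length(unpaired))
    stop_mitodyn("k exceeds the number of unpaired positions")
  alphabet <- if (grepl("U", sequence, fixed = TRUE)) RNA_BASES else DNA_BASES
  with_seed(seed, {
    v <- strsplit(sequence, "")[[1L]]
    pos <- sample(unpaired, k)
    v[pos] <- mutate_bases(v[pos], alphabet)
    paste(v, collapse = "")
  })
}

default_probe <- function(truth) {
  # a probe in the unique part of the "left" flank of copy 1: the last gap
  u <- truth$unique_intervals
  last <- nrow(u)
  end <- u$end[last] - 5L
  c(max(u$start[last], end - 500L), end)
}

#' @export
print.mitodyn_report <- function(x, ...) {
  cat("<mitodyn_report> stages:", paste(x$stages, collapse = ", "), "\n")
  for (nm in names(x$headline))
    cat(sprintf("  %-28s %s\n", nm, format(x$headline[[nm]])))
  invisible(x)
}
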