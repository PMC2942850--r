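#' Read and write genomes, alignments, structures and tRNA sets
#'
#' FASTA is handled through Biostrings.  Genome annotation (repeat cores,
#' extensions, single-copy regions, planted enzyme sites) is written as GFF3;
#' coordinates are converted from the package's 0-based half-open circular
#' convention to GFF3's 1-based inclusive one, and features crossing the
#' origin keep `end > sequence length` as permitted for circular landmarks.
#'
#' @param genome a `circular_genome`.
#' @param path output/input file path.
#' @return `read_genome_fasta()` returns a `circular_genome`; writers return
#'   the path invisibly.
#' @name mitodyn-io
NULL

#' @rdname mitodyn-io
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- paste0(genome$name, if (isTRUE(genome$circular)) " circular=true" else "")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname mitodyn-io
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) stop_mitodyn("expected a single-sequence FASTA")
  desc <- names(x)[1L]
  structure(list(name = sub("\\s.*$", "", desc),
                 seq = as.character(x[[1L]]),
                 length = Biostrings::width(x)[1L],
                 circular = grepl("circular=true", desc, fixed = TRUE)),
            class = "circular_genome")
}

#' @param truth a `genome_truth` (see [make_genome()]).
#' @rdname mitodyn-io
#' @export
write_truth_gff3 <- function(truth, genome, path) {
  ci <- truth$repeat_copy_intervals
  ei <- truth$extension_intervals
  si <- truth$singlecopy_intervals
  rows <- c(
    sprintf("%s\tmitodyn\trepeat_core\t%d\t%d\t.\t+\t.\tID=core_%d;copy=%d",
            genome$name, ci$start + 1L, ci$end, ci$copy, ci$copy),
    {
      e <- ei[ei$length > 0L, , drop = FALSE]
      if (nrow(e)) sprintf(
        "%s\tmitodyn\trepeat_extension\t%d\t%d\t.\t+\t.\tID=ext_%s_%d;copy=%d;side=%s",
        genome$name, e$start + 1L, e$end, e$side, e$copy, e$copy, e$side)
      else character(0)
    },
    sprintf("%s\tmitodyn\tsinglecopy_region\t%d\t%d\t.\t+\t.\tID=sc_%d",
            genome$name, si$start + 1L, si$end, si$id),
    if (length(truth$site_positions)) sprintf(
      "%s\tmitodyn\tenzyme_site\t%d\t%d\t.\t+\t.\tID=site_%d;site=%s",
      genome$name, truth$site_positions + 1L,
      truth$site_positions + nchar(truth$enzyme_site),
      seq_along(truth$site_positions), truth$enzyme_site)
    else character(0))
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", genome$name, genome$length),
               rows), path)
  invisible(path)
}

#' @rdname mitodyn-io
#' @export
read_features_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(seqid = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      attributes = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(seqid = vapply(f, `[`, "", 1L),
             type = vapply(f, `[`, "", 3L),
             start = as.integer(vapply(f, `[`, "", 4L)) - 1L,  # back to 0-based
             end = as.integer(vapply(f, `[`, "", 5L)),
             attributes = vapply(f, `[`, "", 9L),
             stringsAsFactors = FALSE)
}

#' @param pairs a `read_pairs` data frame.
#' @param prefix output path prefix; writes `<prefix>_1.fasta`,
#'   `<prefix>_2.fasta` and the ground-truth sidecar `<prefix>_truth.tsv`.
#' @rdname mitodyn-io
#' @export
write_read_pairs <- function(pairs, prefix) {
  ids <- sprintf("pair_%06d", seq_len(nrow(pairs)))
  r1 <- Biostrings::DNAStringSet(pairs$read1); names(r1) <- paste0(ids, "/1")
  r2 <- Biostrings::DNAStringSet(pairs$read2); names(r2) <- paste0(ids, "/2")
  Biostrings::writeXStringSet(r1, paste0(prefix, "_1.fasta"))
  Biostrings::writeXStringSet(r2, paste0(prefix, "_2.fasta"))
  truth <- pairs[, c("molecule", "left_id", "right_id", "start", "insert")]
  truth <- cbind(id = ids, truth)
  utils::write.table(truth, paste0(prefix, "_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @param sequences named character vector of aligned sequences.
#' @rdname mitodyn-io
#' @export
write_alignment_fasta <- function(sequences, path) {
  if (inherits(sequences, "conversion_alignment")) sequences <- sequences$sequences
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname mitodyn-io
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @param sequence,structure a sequence and its dot-bracket string.
#' @rdname mitodyn-io
#' @export
write_structure_file <- function(sequence, structure, path) {
  if (inherits(structure, "secondary_structure")) structure <- structure$dotbracket
  writeLines(c(sequence, structure), path)
  invisible(path)
}

#' @rdname mitodyn-io
#' @export
read_structure_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop_mitodyn("structure file needs two lines: sequence, dot-bracket")
  list(sequence = lines[1L], structure = parse_structure(lines[2L]))
}

#' @rdname mitodyn-io
#' @export
read_trna_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  make_trna_set(d)
}

#' @param trnas a `trna_set`.
#' @rdname mitodyn-io
#' @export
write_trna_tsv <- function(trnas, path) {
  utils::write.table(as.data.frame(trnas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
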