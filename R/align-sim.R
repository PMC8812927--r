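#' Exhaustively align reads to an assembly
#'
#' Reports, for each read and strand, every location where the read
#' aligns end-to-end with edit distance at most `max_edits`. Candidate
#' loci are found by pigeonhole k-mer seeding (complete for the given
#' edit budget) and verified with an infix dynamic program; overlapping
#' placements at one locus collapse to the best, mimicking the
#' one-hit-per-locus behaviour of real aligners. In mode `"all"` one hit
#' becomes the primary alignment (lowest edit distance, ties broken by a
#' seeded RNG) and the rest become secondaries; mode `"best_only"` keeps
#' the primary alone, emulating conventional best-hit alignment.
#'
#' @param reads A data.frame from [simulate_reads()] (`name`, `seq`,
#'   `segment`), or a character vector of sequences.
#' @param assembly A `DNAStringSet` or named character vector.
#' @param max_edits Maximum edit distance per alignment (small, <= 5).
#' @param mode `"all"` (all-alignments-per-read) or `"best_only"`.
#' @param seed Integer seed for primary-selection tie-breaks.
#' @return A `data.table` of alignments: `qname`, `segment`, `contig`
#'   (`NA` for unmapped reads), `ref_start` (0-based), `is_reverse`,
#'   `edit_distance`, `cigar`, `is_secondary`, `seq`
#'   (reference-forward orientation), `k` (alignment count of the read).
#' @export
exhaustive_align <- function(reads, assembly, max_edits = 5L,
                             mode = c("all", "best_only"), seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(reads))
    reads <- data.frame(name = sprintf("r%06d", seq_along(reads)),
                        seq = reads, segment = 0L, stringsAsFactors = FALSE)
  contigs <- as_contigs(assembly)
  seqs <- toupper(reads$seq)
  lmin <- min(nchar(seqs))
  k <- min(31L, lmin %/% (as.integer(max_edits) + 1L))
  if (k < 4L)
    stop("reads too short for seeded search at max_edits = ", max_edits)
  rc <- revcomp_chr(seqs)
  hits <- cpp_exhaustive_align(seqs, rc, unname(contigs),
                               as.integer(max_edits), k)
  dt <- data.table::as.data.table(hits)

  # primary selection per read: minimum distance, seeded tie-break
  aligned <- with_seed(seed, {
    if (nrow(dt) == 0) {
      dt[, is_secondary := logical(0)]
    } else {
      dt[, row_id := .I]
      prim <- dt[, {
        best <- which(edit_distance == min(edit_distance))
        chosen <- if (length(best) == 1) best else best[sample.int(length(best), 1L)]
        .(prim_row = row_id[chosen])
      }, by = read]
      dt[, is_secondary := TRUE]
      dt[prim$prim_row, is_secondary := FALSE]
      dt[, row_id := NULL]
    }
    dt
  })
  if (mode == "best_only") aligned <- aligned[is_secondary == FALSE]

  out <- data.table::data.table(
    qname = reads$name[aligned$read],
    segment = reads$segment[aligned$read],
    contig = names(contigs)[aligned$contig],
    ref_start = aligned$start,
    is_reverse = aligned$is_reverse,
    edit_distance = aligned$edit_distance,
    cigar = aligned$cigar,
    is_secondary = aligned$is_secondary,
    seq = ifelse(aligned$is_reverse, rc[aligned$read], seqs[aligned$read]))

  # unmapped reads
  unhit <- setdiff(seq_len(nrow(reads)), unique(aligned$read))
  if (length(unhit)) {
    out <- rbind(out, data.table::data.table(
      qname = reads$name[unhit], segment = reads$segment[unhit],
      contig = NA_character_, ref_start = NA_integer_, is_reverse = FALSE,
      edit_distance = NA_integer_, cigar = NA_character_,
      is_secondary = FALSE, seq = seqs[unhit]))
  }
  out[, k := sum(!is.na(ref_start)), by = .(qname, segment)]
  data.table::setorder(out, qname, segment, is_secondary, contig, ref_start,
                       na.last = TRUE)
  out[]
}

#' Write alignments to SAM
#'
#' Emits SAM 1.x text with a minimal header (`@HD`, `@SQ` lines).
#' Secondary records carry `*` in place of their sequence, matching the
#' dialect of real all-per-read aligner output (and exercising the
#' sequence resolution in [group_and_resolve()]). Mapped records carry an
#' `NM` tag with the alignment's edit distance.
#'
#' @param alignments A `data.table` from [exhaustive_align()].
#' @param assembly The assembly the alignments refer to.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, assembly, path) {
  contigs <- as_contigs(assembly)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
  a <- data.table::as.data.table(alignments)
  mapped <- !is.na(a$contig)
  flag <- integer(nrow(a))
  flag <- flag + ifelse(a$segment == 1L, 1L + 64L,
                        ifelse(a$segment == 2L, 1L + 128L, 0L))
  flag <- flag + ifelse(!mapped, 4L, 0L)
  flag <- flag + ifelse(mapped & a$is_reverse, 16L, 0L)
  flag <- flag + ifelse(mapped & a$is_secondary, 256L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                   a$qname, flag,
                   ifelse(mapped, a$contig, "*"),
                   ifelse(mapped, a$ref_start + 1L, 0L),
                   ifelse(mapped & !a$is_secondary, 60L, 0L),
                   ifelse(mapped, a$cigar, "*"),
                   ifelse(mapped & a$is_secondary, "*", a$seq),
                   ifelse(mapped, sprintf("\tNM:i:%d", a$edit_distance), ""))
  writeLines(c(header, lines), path)
  invisible(path)
}
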