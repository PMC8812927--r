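#' Global alignment of two sequences
#'
#' Unit-cost global (Needleman-Wunsch) alignment computed with an
#' expanding-band dynamic program, so bacterial-chromosome-scale pairs
#' with few edits align in seconds. Traceback tie-breaks prefer match >
#' substitution > deletion > insertion, giving deterministic column
#' labels. The distance is the number of non-match columns.
#'
#' @param query,ref Sequences (character or `XString`). `I` columns are
#'   query-only bases, `D` columns reference-only bases.
#' @param band_init Initial band half-width.
#' @param band_max Maximum band half-width before giving up (sequences
#'   more divergent than this are not meaningfully "the same genome").
#' @return An object of class `global_alignment`: `distance`, `identity`
#'   (matches / alignment columns), `cigar` (ops `=`, `X`, `I`, `D`),
#'   `matches`, `columns`.
#' @export
global_align <- function(query, ref, band_init = 32L, band_max = 65536L) {
  q <- toupper(as.character(query))
  r <- toupper(as.character(ref))
  stopifnot(length(q) == 1, length(r) == 1)
  res <- cpp_global_align(q, r, as.integer(band_init), as.integer(band_max))
  structure(list(distance = res$distance,
                 identity = if (res$columns > 0) res$matches / res$columns else 1,
                 cigar = res$cigar, matches = res$matches,
                 columns = res$columns),
            class = "global_alignment")
}

#' Expand a global alignment into labelled columns
#'
#' @param aln A [global_align()] result.
#' @return A data.frame with one row per alignment column: `op` (`=`,
#'   `X`, `I`, `D`) and `ref_pos`, the 0-based reference coordinate of
#'   the column; insertion columns are attributed to the reference
#'   position of their left-anchoring base (clamped to 0 for a leading
#'   insertion).
#' @export
alignment_columns <- function(aln) {
  co <- cigar_parse(aln$cigar)[[1]]
  op <- rep(co$op, co$len)
  consumes_ref <- op %in% c("=", "X", "D")
  n_before <- cumsum(consumes_ref)
  ref_pos <- integer(length(op))
  ref_pos[consumes_ref] <- n_before[consumes_ref] - 1L
  ins <- op == "I"
  ref_pos[ins] <- pmax(n_before[ins] - 1L, 0L)
  data.frame(op = op, ref_pos = ref_pos, stringsAsFactors = FALSE)
}

#' Assess an assembly against a reference
#'
#' Globally aligns the assembly to the reference and reports the error
#' count (non-matching alignment positions), identity (matching positions
#' over alignment length), the Phred-scaled Q-score
#' `Q = -10 log10(1 - identity)`, per-type error counts, and -- when a
#' repeat annotation is supplied -- how many errors fall inside repeat
#' regions. Substitution and deletion errors are attributed to their
#' reference position, insertions to their left-anchoring reference
#' position.
#'
#' @param assembly The assembly to assess (`DNAStringSet`, named
#'   character, or a single sequence). Multi-contig inputs are matched to
#'   the reference by contig name.
#' @param reference The truth sequence(s).
#' @param repeats Optional repeat annotation: data.frame of (`contig`,
#'   `start`, `end`), 0-based half-open.
#' @param qscore_cap Numeric Q-score reported for a perfect assembly
#'   (identity 1 has infinite Q; printed as `Q-inf`).
#' @return An object of class `assembly_assessment`: `error_count`,
#'   `identity`, `qscore`, `errors_by_type` (substitution / insertion /
#'   deletion), `errors_in_repeat`, `errors_outside_repeat`.
#' @export
assess <- function(assembly, reference, repeats = NULL, qscore_cap = 90) {
  asm <- assess_contigs(assembly)
  ref <- assess_contigs(reference)
  if (length(asm) > 1 || length(ref) > 1) {
    if (!setequal(names(asm), names(ref)))
      stop("assembly and reference contig names do not match")
    asm <- asm[names(ref)]
  } else {
    names(asm) <- names(ref)
  }
  total <- list(distance = 0L, matches = 0, columns = 0,
                by_type = c(substitution = 0L, insertion = 0L, deletion = 0L),
                in_rep = 0L, out_rep = 0L)
  for (nm in names(ref)) {
    aln <- global_align(asm[[nm]], ref[[nm]])
    cols <- alignment_columns(aln)
    err <- cols[cols$op != "=", , drop = FALSE]
    total$distance <- total$distance + aln$distance
    total$matches <- total$matches + aln$matches
    total$columns <- total$columns + aln$columns
    total$by_type <- total$by_type +
      c(substitution = sum(err$op == "X"),
        insertion = sum(err$op == "I"),
        deletion = sum(err$op == "D"))
    if (!is.null(repeats)) {
      rp <- repeats[repeats$contig == nm, , drop = FALSE]
      inr <- positions_in_intervals(err$ref_pos, rp$start, rp$end)
      total$in_rep <- total$in_rep + sum(inr)
      total$out_rep <- total$out_rep + sum(!inr)
    }
  }
  identity <- if (total$columns > 0) total$matches / total$columns else 1
  qscore <- if (identity >= 1) qscore_cap
            else min(qscore_cap, -10 * log10(1 - identity))
  structure(list(error_count = total$distance, identity = identity,
                 qscore = qscore, errors_by_type = total$by_type,
                 errors_in_repeat = if (is.null(repeats)) NA_integer_ else total$in_rep,
                 errors_outside_repeat = if (is.null(repeats)) NA_integer_ else total$out_rep),
            class = "assembly_assessment")
}

assess_contigs <- function(x) {
  if (is.character(x) && is.null(names(x)) && length(x) == 1) {
    stats::setNames(toupper(x), "seq")
  } else {
    as_contigs(x)
  }
}

#' @export
print.assembly_assessment <- function(x, ...) {
  qtxt <- if (x$identity >= 1) "Q-inf (capped)" else sprintf("Q%.1f", x$qscore)
  cat(sprintf("errors: %d  identity: %.6f  %s\n",
              x$error_count, x$identity, qtxt))
  cat(sprintf("  by type: %d substitution, %d insertion, %d deletion\n",
              x$errors_by_type[["substitution"]],
              x$errors_by_type[["insertion"]],
              x$errors_by_type[["deletion"]]))
  if (!is.na(x$errors_in_repeat))
    cat(sprintf("  in repeats: %d  outside: %d\n",
                x$errors_in_repeat, x$errors_outside_repeat))
  invisible(x)
}

#' Annotate repeat regions of a genome
#'
#' Repetitive regions are defined operationally, as in read-based repeat
#' detection: simulate deep error-free unpaired reads from the genome
#' (defaults 150 bp at 300x), align them in all-alignments-per-read mode,
#' and mark every position covered by any read that aligned to two or
#' more places; the marked positions are merged into intervals.
#'
#' @param reference A `DNAStringSet` or named character vector.
#' @param read_length Simulated read length.
#' @param depth Simulated depth.
#' @param max_edits Edit budget for cross-repeat alignment (controls how
#'   diverged two repeat copies may be and still count as a repeat).
#' @param seed Integer seed.
#' @return A data.frame of 0-based half-open intervals (`contig`,
#'   `start`, `end`).
#' @export
find_repeats <- function(reference, read_length = 150L, depth = 300,
                         max_edits = 2L, seed = 1L) {
  contigs <- as_contigs(reference)
  reads <- simulate_reads(contigs, read_length = read_length, depth = depth,
                          seed = seed)
  hits <- exhaustive_align(reads, contigs, max_edits = max_edits,
                           mode = "all", seed = seed)
  multi <- hits[!is.na(contig)][k >= 2L]
  if (nrow(multi) == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  multi[, span := cigar_ref_len(cigar)]
  out <- lapply(unique(multi$contig), function(nm) {
    m <- multi[contig == nm]
    ir <- IRanges::reduce(IRanges::IRanges(start = m$ref_start + 1L,
                                           end = m$ref_start + m$span))
    data.frame(contig = nm, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read a BED interval file (0-based half-open)
#'
#' @param intervals Data frame of (`contig`, `start`, `end`).
#' @param path File path.
#' @return `path` invisibly, or the intervals data.frame.
#' @export
write_bed <- function(intervals, path) {
  write.table(intervals[, c("contig", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "start", "end"),
                          stringsAsFactors = FALSE)
  df
}

# Project a query sequence onto reference coordinates: returns a character
# vector with one piece per reference position (matched/substituted base,
# "" for a reference base deleted from the query, insertions appended to
# their left-anchoring reference position).
project_to_reference <- function(query, reference) {
  aln <- global_align(query, reference)
  co <- cigar_parse(aln$cigar)[[1]]
  op <- rep(co$op, co$len)
  qchars <- strsplit(toupper(as.character(query)), "", fixed = TRUE)[[1]]
  rlen <- nchar(reference)
  consumes_q <- op %in% c("=", "X", "I")
  consumes_r <- op %in% c("=", "X", "D")
  qidx <- integer(length(op)); qidx[consumes_q] <- seq_len(sum(consumes_q))
  ridx <- cumsum(consumes_r)  # ref base count so far
  piece <- character(rlen)
  mr <- op %in% c("=", "X")
  piece[ridx[mr]] <- qchars[qidx[mr]]
  # deletions already ""; insertions appended to left anchor (clamped)
  for (j in which(op == "I")) {
    anchor <- max(ridx[j], 1L)
    piece[anchor] <- paste0(piece[anchor], qchars[qidx[j]])
  }
  piece
}

#' Confusion matrix of a polishing run
#'
#' Projects the unpolished and polished assemblies onto reference
#' coordinates via pairwise global alignment, then classifies every
#' reference position: an error in the unpolished sequence that the
#' polished sequence gets right is a true positive (fixed), a correct and
#' untouched base a true negative, a persisting error a false negative,
#' and a newly introduced error a false positive. Insertions are
#' attributed to their left-anchoring reference position.
#'
#' @param reference,unpolished,polished Comparable sequences
#'   (`DNAStringSet`, named character, or single sequences); multi-contig
#'   inputs are matched by name.
#' @return An object of class `confusion_matrix` with integer fields
#'   `tp`, `tn`, `fp`, `fn` (they sum to the reference length).
#' @export
confusion <- function(reference, unpolished, polished) {
  ref <- assess_contigs(reference)
  unp <- assess_contigs(unpolished)
  pol <- assess_contigs(polished)
  if (length(ref) > 1) {
    if (!setequal(names(ref), names(unp)) || !setequal(names(ref), names(pol)))
      stop("contig names do not match across the three sequences")
  } else {
    names(unp) <- names(ref); names(pol) <- names(ref)
  }
  tp <- tn <- fp <- fn <- 0L
  for (nm in names(ref)) {
    rchars <- strsplit(ref[[nm]], "", fixed = TRUE)[[1]]
    pu <- project_to_reference(unp[[nm]], ref[[nm]])
    pp <- project_to_reference(pol[[nm]], ref[[nm]])
    u_ok <- pu == rchars
    p_ok <- pp == rchars
    tp <- tp + sum(!u_ok & p_ok)
    tn <- tn + sum(u_ok & p_ok)
    fp <- fp + sum(u_ok & !p_ok)
    fn <- fn + sum(!u_ok & !p_ok)
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("TP %d (fixed)  TN %d (kept correct)  FP %d (introduced)  FN %d (missed)\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}
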