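#' Terminal trim length of an aligned sequence
#'
#' Alignment ends inside a homopolymer run cannot attest the run's full
#' length, so the pileup drops the end of every alignment: whatever base
#' is at the end of the read, however many times it repeats, plus one more
#' base. This returns `r + 1` where `r` is the length of the terminal run
#' of identical bases (so always at least 2), capped at the sequence
#' length.
#'
#' @param aligned_seq Non-empty aligned (clip-stripped) sequence in
#'   reference-forward orientation.
#' @param from_start Compute the mirrored leading-run trim length instead
#'   (used by `both_ends` trimming).
#' @return Integer number of read bases to trim.
#' @export
#' @examples
#' terminal_trim_length("ACGTT") # run of 2 T's + 1 = 3
#' terminal_trim_length("ACGT")  # minimum trim of 2
terminal_trim_length <- function(aligned_seq, from_start = FALSE) {
  stopifnot(length(aligned_seq) == 1)
  n <- nchar(aligned_seq)
  if (is.na(aligned_seq) || n == 0) stop("aligned_seq must be non-empty")
  ch <- strsplit(aligned_seq, "", fixed = TRUE)[[1]]
  if (from_start) ch <- rev(ch)
  run <- 1L
  while (run < n && ch[n - run] == ch[n]) run <- run + 1L
  min(run + 1L, n)
}

#' Expand one alignment into per-position read pieces
#'
#' Walks a CIGAR over the stored (reference-forward) sequence and emits
#' one piece per covered reference position: `M`/`=`/`X` give length-1
#' pieces, `I` appends its bases to the piece of the preceding reference
#' position (an insertion before the first reference-consuming op is
#' discarded), `D` gives empty pieces at the deleted positions, and
#' `S`/`H` clips contribute nothing.
#'
#' @param cigar CIGAR string.
#' @param seq Stored sequence (reference-forward; includes soft-clipped
#'   bases when the CIGAR has `S` ops).
#' @param ref_start 0-based reference start of the alignment.
#' @return A data.frame with one row per covered position: `pos` (0-based),
#'   `piece`, and `read_from`/`read_to`, the 0-based indices of the
#'   aligned-read bases the piece uses (`NA` for deletion pieces).
#' @export
walk_cigar <- function(cigar, seq, ref_start = 0L) {
  co <- cigar_parse(cigar)[[1]]
  if (any(co$op == "N")) stop("CIGAR op 'N' is not supported")
  if (any(!co$op %in% c("M", "=", "X", "I", "D", "S", "H")))
    stop("unknown CIGAR op in '", cigar, "'")
  # strip clips
  keep <- co$op %in% c("M", "=", "X", "I", "D")
  lead_clip <- if (length(co$op) && co$op[1] == "S") co$len[1] else 0L
  if (length(co$op) > 1 && co$op[1] == "H" && co$op[2] == "S") lead_clip <- co$len[2]
  aseq <- substr(seq, lead_clip + 1L,
                 lead_clip + sum(co$len[keep & co$op %in% c("M", "=", "X", "I")]))
  ops <- co$op[keep]
  lens <- co$len[keep]

  pos <- integer(0); piece <- character(0)
  read_from <- integer(0); read_to <- integer(0)
  rpos <- as.integer(ref_start); a <- 0L
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      idx <- seq_len(len)
      pos <- c(pos, rpos + idx - 1L)
      piece <- c(piece, substring(aseq, a + idx, a + idx))
      read_from <- c(read_from, a + idx - 1L)
      read_to <- c(read_to, a + idx - 1L)
      rpos <- rpos + len; a <- a + len
    } else if (op == "I") {
      if (length(pos)) {
        j <- length(pos)
        piece[j] <- paste0(piece[j], substr(aseq, a + 1L, a + len))
        if (is.na(read_from[j])) read_from[j] <- a
        read_to[j] <- a + len - 1L
      }
      a <- a + len
    } else if (op == "D") {
      idx <- seq_len(len)
      pos <- c(pos, rpos + idx - 1L)
      piece <- c(piece, rep("", len))
      read_from <- c(read_from, rep(NA_integer_, len))
      read_to <- c(read_to, rep(NA_integer_, len))
      rpos <- rpos + len
    }
  }
  data.frame(pos = pos, piece = piece, read_from = read_from,
             read_to = read_to, stringsAsFactors = FALSE)
}

#' Trim pieces at alignment ends
#'
#' Drops the pieces affected by homopolymer-aware end trimming: with the
#' last `trim_len` aligned read bases marked as trimmed, the first covered
#' position whose piece uses any trimmed base -- and every subsequent
#' position, including trailing deletion pieces -- is removed. In
#' `both_ends` mode the mirrored rule is applied at the alignment start
#' using `lead_trim_len` leading read bases.
#'
#' @param pieces Data frame from [walk_cigar()].
#' @param trim_len Number of terminal aligned read bases to trim (from
#'   [terminal_trim_length()]).
#' @param mode `"end_only"` (default) or `"both_ends"`.
#' @param lead_trim_len Leading trim length; required in `both_ends` mode.
#' @return The surviving rows of `pieces` (possibly none).
#' @export
trim_pieces <- function(pieces, trim_len, mode = c("end_only", "both_ends"),
                        lead_trim_len = NULL) {
  mode <- match.arg(mode)
  if (nrow(pieces) == 0) return(pieces)
  aligned_len <- suppressWarnings(max(pieces$read_to, na.rm = TRUE)) + 1L
  if (!is.finite(aligned_len)) return(pieces[0, ])
  cutoff <- aligned_len - trim_len
  hit <- which(!is.na(pieces$read_to) & pieces$read_to >= cutoff)
  keep_until <- if (length(hit)) hit[1] - 1L else nrow(pieces)
  if (cutoff <= 0) keep_until <- 0L
  drop_through <- 0L
  if (mode == "both_ends") {
    if (is.null(lead_trim_len))
      stop("both_ends trimming needs lead_trim_len")
    lead_hit <- which(!is.na(pieces$read_from) & pieces$read_from < lead_trim_len)
    if (length(lead_hit)) drop_through <- lead_hit[length(lead_hit)]
  }
  if (drop_through >= keep_until) return(pieces[0, ])
  pieces[seq.int(drop_through + 1L, keep_until), , drop = FALSE]
}

#' Build a pileup from resolved alignments
#'
#' For every assembly position, collects the read pieces of all retained
#' (post-trim) alignment positions as raw integer counts, and accumulates
#' fractional read depth: an alignment of a read with `k` alignments adds
#' `1/k` depth at each retained position. Counts are deliberately *not*
#' weighted by `1/k` -- inside a collapsed repeat the piece counts carry
#' the full evidence from every copy while depth approximates conventional
#' best-hit depth; this asymmetry is what lets the change rule operate
#' inside repeats.
#'
#' @param assembly A `DNAStringSet` or named character vector of contigs.
#' @param alignments Resolved alignments from [group_and_resolve()] (or
#'   from [exhaustive_align()] after resolution): needs columns `contig`,
#'   `ref_start`, `cigar`, `seq`, `k`.
#' @param params A [polish_params()] object (supplies the trim mode).
#' @return An object of class `pileup`: per contig the reference string, a
#'   numeric `depth` vector (one entry per position) and a `data.table` of
#'   observed piece counts (`pos` 0-based, `piece`, `count`; the empty
#'   string is a deletion piece). The per-alignment count of retained
#'   positions is attached as attribute `retained`.
#' @export
build_pileup <- function(assembly, alignments, params = polish_params()) {
  contigs <- as_contigs(assembly)
  aln <- data.table::as.data.table(alignments)
  needed <- c("contig", "ref_start", "cigar", "seq", "k")
  if (!all(needed %in% names(aln)))
    stop("alignments must have columns: ", paste(needed, collapse = ", "))
  ci <- match(aln$contig, names(contigs))
  if (anyNA(ci))
    stop("alignment references unknown contig '",
         aln$contig[which(is.na(ci))[1]], "'")
  res <- cpp_build_pileup(names(contigs), nchar(contigs),
                          as.integer(ci), as.integer(aln$ref_start),
                          aln$cigar, aln$seq, 1 / aln$k,
                          params$trim_mode == "both_ends")
  out <- lapply(seq_along(contigs), function(i) {
    r <- res[[i]]
    list(ref = contigs[[i]],
         depth = r$depth,
         counts = data.table::data.table(pos = r$pos, piece = r$piece,
                                         count = r$count))
  })
  names(out) <- names(contigs)
  structure(list(contigs = out, params = params,
                 n_alignments = nrow(aln)),
            class = "pileup",
            retained = attr(res, "retained"))
}

#' Extract one pileup column
#'
#' @param pileup A [build_pileup()] object.
#' @param contig Contig name.
#' @param pos 0-based position.
#' @return A list with `contig`, `pos`, `ref_base`, `depth`, and `counts`
#'   (a named integer vector of piece counts; `""` is the deletion piece).
#' @export
pileup_column <- function(pileup, contig, pos) {
  pc <- pileup$contigs[[contig]]
  if (is.null(pc)) stop("unknown contig '", contig, "'")
  sel <- pc$counts$pos == pos
  counts <- pc$counts$count[sel]
  names(counts) <- pc$counts$piece[sel]
  list(contig = contig, pos = pos,
       ref_base = substr(pc$ref, pos + 1L, pos + 1L),
       depth = pc$depth[pos + 1L],
       counts = counts)
}

#' @export
print.pileup <- function(x, ...) {
  cat("pileup over", length(x$contigs), "contig(s),",
      x$n_alignments, "alignments\n")
  for (nm in names(x$contigs)) {
    pc <- x$contigs[[nm]]
    cat(sprintf("  %s: %d bp, mean depth %.2f, %d piece records\n",
                nm, nchar(pc$ref), mean(pc$depth), nrow(pc$counts)))
  }
  invisible(x)
}

#' Write a per-position pileup debug TSV
#'
#' Columns: contig, pos (0-based), ref_base, depth (6 decimals), pieces
#' (semicolon-joined `piece:count` pairs, `-` denoting the deletion
#' piece), status (filled by the polishing engine: `changed`,
#' `dead_zone`, or empty).
#'
#' @param pileup A [build_pileup()] object.
#' @param path Output path.
#' @param status Optional `data.table` of (`contig`, `pos`, `status`).
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path, status = NULL) {
  rows <- lapply(names(pileup$contigs), function(nm) {
    pc <- pileup$contigs[[nm]]
    cnt <- data.table::copy(pc$counts)
    cnt[, lab := ifelse(piece == "", "-", piece)]
    pieces <- cnt[, .(pieces = paste0(lab, ":", count, collapse = ";")),
                  by = pos]
    dt <- data.table::data.table(
      contig = nm, pos = seq_len(nchar(pc$ref)) - 1L,
      ref_base = strsplit(pc$ref, "", fixed = TRUE)[[1]],
      depth = sprintf("%.6f", pc$depth))
    dt <- merge(dt, pieces, by = "pos", all.x = TRUE, sort = TRUE)
    dt[is.na(pieces), pieces := ""]
    data.table::setcolorder(dt, c("contig", "pos", "ref_base", "depth", "pieces"))
    dt
  })
  out <- data.table::rbindlist(rows)
  out[, status := ""]
  if (!is.null(status)) {
    st <- data.table::as.data.table(status)
    out[st, on = c("contig", "pos"), status := i.status]
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
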