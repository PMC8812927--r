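#' Parse a SAM file into alignment records
#'
#' Reads SAM 1.x text (the 11 mandatory columns; optional tags are ignored
#' except `NM`, which is captured for the optional alignment filter).
#' FLAG bits are decoded into logical fields, the 1-based `POS` column is
#' converted to a 0-based `ref_start`, and a SEQ of `*` is recorded as
#' missing (`NA`) for later dialect repair by [group_and_resolve()].
#'
#' @param path Path to a SAM file, or a character vector of paths whose
#'   records are concatenated (the usual case when R1 and R2 were aligned
#'   separately in all-alignments-per-read mode).
#' @return A `data.table` with one row per alignment line: `qname`,
#'   `segment` (0 = unpaired, 1 = first, 2 = second of a pair), `contig`,
#'   `ref_start` (0-based), `cigar`, `seq` (`NA` when absent),
#'   `is_reverse`, `is_secondary`, `is_supplementary`, `is_unmapped`,
#'   `nm` (NM tag value or `NA`).
#' @export
parse_sam <- function(path) {
  if (length(path) > 1) return(data.table::rbindlist(lapply(path, parse_sam)))
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  if (length(body_idx) == 0) {
    return(data.table::data.table(
      qname = character(), segment = integer(), contig = character(),
      ref_start = integer(), cigar = character(), seq = character(),
      is_reverse = logical(), is_secondary = logical(),
      is_supplementary = logical(), is_unmapped = logical(), nm = integer()))
  }
  body <- lines[body_idx]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("SAM line ", body_idx[which(nf < 11)[1]],
         ": fewer than 11 mandatory columns")
  col <- function(i) vapply(fields, `[[`, character(1), i)
  qname <- col(1)
  flag <- suppressWarnings(as.integer(col(2)))
  rname <- col(3)
  pos <- suppressWarnings(as.integer(col(4)))
  cigar <- col(6)
  seq <- col(10)
  if (anyNA(flag))
    stop("SAM line ", body_idx[which(is.na(flag))[1]], ": non-integer FLAG")
  if (anyNA(pos))
    stop("SAM line ", body_idx[which(is.na(pos))[1]], ": non-integer POS")

  is_unmapped <- bitwAnd(flag, 4L) > 0L
  recs <- data.table::data.table(
    qname = qname,
    segment = ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                     ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L)),
    contig = ifelse(rname == "*", NA_character_, rname),
    ref_start = pos - 1L,
    cigar = ifelse(cigar == "*", NA_character_, cigar),
    seq = ifelse(seq == "*", NA_character_, toupper(seq)),
    is_reverse = bitwAnd(flag, 16L) > 0L,
    is_secondary = bitwAnd(flag, 256L) > 0L,
    is_supplementary = bitwAnd(flag, 2048L) > 0L,
    is_unmapped = is_unmapped,
    nm = {
      m <- regexpr("\tNM:i:[0-9]+", body)
      v <- rep(NA_integer_, length(body))
      hit <- m > 0
      v[hit] <- as.integer(substring(body[hit], m[hit] + 6L,
                                     m[hit] + attr(m, "match.length")[hit] - 1L))
      v
    })

  # CIGAR validation for mapped records
  mapped <- !recs$is_unmapped & !is.na(recs$cigar)
  if (any(mapped)) {
    ops <- gsub("[0-9]+", "", recs$cigar[mapped])
    bad_op <- grepl("[^MIDSH=X]", ops)
    if (any(bad_op))
      stop("SAM line ", body_idx[mapped][which(bad_op)[1]],
           ": unsupported CIGAR operation in '",
           recs$cigar[mapped][which(bad_op)[1]], "'")
    has_seq <- mapped & !is.na(recs$seq)
    if (any(has_seq)) {
      rl <- cigar_read_len(recs$cigar[has_seq])
      mismatch <- rl != nchar(recs$seq[has_seq])
      if (any(mismatch))
        stop("SAM line ", body_idx[has_seq][which(mismatch)[1]],
             ": CIGAR read length does not match SEQ length")
    }
  }
  recs
}

#' Group alignment records per read segment and resolve missing sequences
#'
#' Discards unmapped (and, by default, supplementary) records, groups the
#' rest by `(qname, segment)`, and repairs the common all-per-read SAM
#' dialect in which secondary records carry `*` instead of a sequence:
#' such records receive the sequence of a same-group record that has one,
#' reverse-complemented when the strand flags differ. Each surviving
#' record is annotated with `k`, the number of alignments of its read
#' segment, which downstream fractional-depth computation relies on.
#'
#' @param records A `data.table` from [parse_sam()].
#' @param include_supplementary Keep supplementary (chimeric) records.
#' @return A `data.table` of resolved records with added columns `group`
#'   and `k`. Groups in which no record carries a sequence are dropped;
#'   their count is attached as attribute `n_dropped_groups` (records
#'   whose filled sequence is inconsistent with their CIGAR are dropped
#'   and tallied in `n_dropped_records`).
#' @export
group_and_resolve <- function(records, include_supplementary = FALSE) {
  recs <- data.table::as.data.table(records)
  recs <- recs[is_unmapped == FALSE & !is.na(contig) & !is.na(cigar)]
  if (!include_supplementary) recs <- recs[is_supplementary == FALSE]
  n_dropped_groups <- 0L
  n_dropped_records <- 0L
  if (nrow(recs) == 0) {
    out <- recs[, c("group", "k") := list(character(), integer())]
    data.table::setattr(out, "n_dropped_groups", 0L)
    data.table::setattr(out, "n_dropped_records", 0L)
    return(out)
  }
  recs[, group := paste0(qname, "/", segment)]

  # drop groups with no resolvable sequence
  recs[, any_seq := any(!is.na(seq)), by = group]
  n_dropped_groups <- recs[!(any_seq), data.table::uniqueN(group)]
  if (n_dropped_groups > 0)
    warning(n_dropped_groups,
            " read group(s) had no record with a sequence and were dropped")
  recs <- recs[any_seq == TRUE][, any_seq := NULL]

  # fill missing sequences from a same-group donor
  recs[, `:=`(donor_seq = seq[!is.na(seq)][1],
              donor_rev = is_reverse[!is.na(seq)][1]), by = group]
  need <- which(is.na(recs$seq))
  if (length(need)) {
    same <- recs$is_reverse[need] == recs$donor_rev[need]
    filled <- recs$donor_seq[need]
    if (any(!same)) filled[!same] <- revcomp_chr(filled[!same])
    recs[need, seq := filled]
  }
  recs[, c("donor_seq", "donor_rev") := NULL]

  # filled sequence must be consistent with the record's CIGAR
  rl <- cigar_read_len(recs$cigar)
  ok <- rl == nchar(recs$seq)
  n_dropped_records <- sum(!ok)
  if (n_dropped_records > 0) {
    warning(n_dropped_records,
            " record(s) dropped: resolved sequence inconsistent with CIGAR")
    recs <- recs[ok]
  }
  recs[, k := .N, by = group]
  data.table::setattr(recs, "n_dropped_groups", n_dropped_groups)
  data.table::setattr(recs, "n_dropped_records", n_dropped_records)
  recs[]
}

#' Filter alignment records by their NM edit distance
#'
#' Optional noise guard, disabled by default: drops alignments whose `NM`
#' tag exceeds `max_errors` (records with `NM <= max_errors` are kept).
#'
#' @param records A `data.table` from [parse_sam()].
#' @param max_errors Maximum NM value to keep, or `NULL` to disable.
#' @return The filtered records.
#' @export
filter_alignments <- function(records, max_errors = NULL) {
  if (is.null(max_errors)) return(records)
  recs <- data.table::as.data.table(records)
  mapped <- !recs$is_unmapped
  if (any(mapped & is.na(recs$nm)))
    stop("alignment filtering needs the NM tag on every mapped record; ",
         "re-run the aligner with NM tags enabled or disable max_errors")
  recs[is_unmapped | nm <= max_errors]
}
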