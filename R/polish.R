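#' Polishing parameters
#'
#' The three thresholds governing the conservative change rule, plus the
#' trim mode and optional alignment filter. At a column with fractional
#' depth `d`, a piece is *valid* when its count strictly exceeds
#' `max(min_depth, fraction_valid * d)` and *invalid* when its count is
#' strictly below `fraction_invalid * d`; counts between the two
#' thresholds fall in the dead zone and block any change at that column.
#'
#' @param fraction_valid Valid-threshold fraction of depth (default 0.5).
#' @param fraction_invalid Invalid-threshold fraction of depth (default 0.2).
#' @param min_depth Floor on the valid threshold (default 5).
#' @param trim_mode `"end_only"` (default; trims the alignment end) or
#'   `"both_ends"` (applies the mirrored rule at the alignment start too).
#' @param max_errors Optional NM-tag alignment filter; `NULL` disables.
#' @param seed Integer seed for any seeded steps (ambiguity replacement).
#' @return An object of class `polish_params`.
#' @export
polish_params <- function(fraction_valid = 0.5, fraction_invalid = 0.2,
                          min_depth = 5L,
                          trim_mode = c("end_only", "both_ends"),
                          max_errors = NULL, seed = 1L) {
  trim_mode <- match.arg(trim_mode)
  if (!(fraction_invalid > 0 && fraction_invalid <= fraction_valid &&
        fraction_valid <= 1))
    stop("need 0 < fraction_invalid <= fraction_valid <= 1")
  if (min_depth < 0) stop("min_depth must be >= 0")
  structure(list(fraction_valid = fraction_valid,
                 fraction_invalid = fraction_invalid,
                 min_depth = as.integer(min_depth),
                 trim_mode = trim_mode,
                 max_errors = max_errors,
                 seed = as.integer(seed)),
            class = "polish_params")
}

#' Classify the pieces of one pileup column
#'
#' @param column A column from [pileup_column()] (a list with `depth` and
#'   a named `counts` vector), or any list with those fields.
#' @param params A [polish_params()] object.
#' @return A list of piece values: `valid`, `invalid`, `neither`, plus the
#'   numeric thresholds `t_valid` and `t_invalid`.
#' @export
classify_column <- function(column, params = polish_params()) {
  t_valid <- max(params$min_depth, params$fraction_valid * column$depth)
  t_invalid <- params$fraction_invalid * column$depth
  counts <- column$counts
  v <- counts > t_valid
  i <- counts < t_invalid
  list(valid = names(counts)[v], invalid = names(counts)[i],
       neither = names(counts)[!v & !i],
       t_valid = t_valid, t_invalid = t_invalid)
}

#' Decide whether one column warrants a change
#'
#' A change is emitted iff the column has exactly one valid piece, that
#' piece differs from the current assembly base, and every other observed
#' piece is invalid. Any piece in the dead zone, multiple valid pieces,
#' no valid piece, or a valid piece equal to the current base all leave
#' the column unchanged.
#'
#' @inheritParams classify_column
#' @return `NULL`, or a one-row data.frame (`contig`, `pos`, `old`, `new`,
#'   `depth`, `count`, `class`).
#' @export
decide_change <- function(column, params = polish_params()) {
  cl <- classify_column(column, params)
  if (length(cl$valid) != 1 || length(cl$neither) > 0) return(NULL)
  new_piece <- cl$valid
  if (identical(new_piece, column$ref_base)) return(NULL)
  data.frame(contig = column$contig, pos = column$pos,
             old = column$ref_base, new = new_piece,
             depth = column$depth,
             count = unname(column$counts[new_piece]),
             class = change_class(new_piece),
             stringsAsFactors = FALSE)
}

change_class <- function(new_piece) {
  ifelse(nchar(new_piece) == 0, "deletion",
         ifelse(nchar(new_piece) == 1, "substitution", "insertion"))
}

#' Decide all changes for a pileup
#'
#' Vectorised application of [decide_change()] over every column with
#' observed pieces.
#'
#' @param pileup A [build_pileup()] object.
#' @param params A [polish_params()] object.
#' @return A list: `changes` (a `data.table` ordered by contig then
#'   position, with the [decide_change()] columns) and `dead_zone` (a
#'   `data.table` of (`contig`, `pos`) with at least one dead-zone piece).
#' @export
decide_changes <- function(pileup, params = pileup$params) {
  ch <- list(); dz <- list()
  for (nm in names(pileup$contigs)) {
    pc <- pileup$contigs[[nm]]
    if (nrow(pc$counts) == 0) next
    dt <- data.table::copy(pc$counts)
    dt[, depth := pc$depth[pos + 1L]]
    dt[, t_valid := pmax(params$min_depth, params$fraction_valid * depth)]
    dt[, `:=`(valid = count > t_valid,
              invalid = count < params$fraction_invalid * depth)]
    agg <- dt[, .(n_valid = sum(valid), n_neither = sum(!valid & !invalid),
                  new = if (sum(valid) == 1) piece[valid] else NA_character_,
                  cnt = if (sum(valid) == 1) count[valid] else NA_integer_,
                  depth = depth[1]),
              by = pos]
    ref_chars <- strsplit(pc$ref, "", fixed = TRUE)[[1]]
    agg[, old := ref_chars[pos + 1L]]
    sel <- agg[n_valid == 1L & n_neither == 0L & new != old]
    if (nrow(sel))
      ch[[nm]] <- data.table::data.table(
        contig = nm, pos = sel$pos, old = sel$old, new = sel$new,
        depth = sel$depth, count = sel$cnt, class = change_class(sel$new))
    dzp <- agg[n_neither > 0L, pos]
    if (length(dzp)) dz[[nm]] <- data.table::data.table(contig = nm, pos = dzp)
  }
  empty_ch <- data.table::data.table(
    contig = character(), pos = integer(), old = character(),
    new = character(), depth = numeric(), count = integer(),
    class = character())
  changes <- if (length(ch)) data.table::rbindlist(ch) else empty_ch
  data.table::setorder(changes, contig, pos)
  dead_zone <- if (length(dz)) data.table::rbindlist(dz)
               else data.table::data.table(contig = character(), pos = integer())
  list(changes = changes, dead_zone = dead_zone)
}

#' Apply changes to an assembly
#'
#' Rebuilds each contig as the concatenation, over pre-polish positions,
#' of the new piece where a change applies and the original base
#' elsewhere (zero-depth positions always keep their base because no
#' change can be decided there). Output length is input length minus
#' deletions plus inserted bases.
#'
#' @param assembly A `DNAStringSet` or named character vector.
#' @param changes A changes table from [decide_changes()].
#' @return The polished assembly as a `DNAStringSet`.
#' @export
apply_changes <- function(assembly, changes) {
  contigs <- as_contigs(assembly)
  if (nrow(changes)) {
    bad <- !(changes$contig %in% names(contigs))
    if (any(bad)) stop("change references unknown contig '",
                       changes$contig[bad][1], "'")
    for (nm in unique(changes$contig)) {
      ch <- changes[changes$contig == nm, ]
      chars <- strsplit(contigs[[nm]], "", fixed = TRUE)[[1]]
      if (any(ch$pos < 0 | ch$pos >= length(chars)))
        stop("change position outside contig '", nm, "'")
      chars[ch$pos + 1L] <- ch$new
      contigs[[nm]] <- paste0(chars, collapse = "")
    }
  }
  as_dnastringset(contigs)
}

#' Run one polishing round end-to-end
#'
#' Loads the assembly and SAM alignments, optionally filters by NM,
#' groups and resolves the records, builds the pileup, decides and
#' applies changes, and writes the polished FASTA plus change/debug
#' tables. Multiple rounds require realigning reads to each round's
#' output; this function performs exactly one round.
#'
#' @param assembly A FASTA path, `DNAStringSet`, or named character vector.
#' @param sam One or more SAM paths (concatenated before grouping), or a
#'   pre-parsed records `data.table`.
#' @param params A [polish_params()] object.
#' @param out_fasta,changes_tsv,debug_tsv Optional output paths (polished
#'   FASTA; change table with columns contig, pos, old, new, depth, count,
#'   class; per-position pileup debug table).
#' @return A list: `assembly` (polished `DNAStringSet`), `changes`,
#'   `dead_zone`, and `summary` (per-contig substitution / insertion /
#'   deletion counts and the number of dead-zone positions).
#' @export
polish_round <- function(assembly, sam, params = polish_params(),
                         out_fasta = NULL, changes_tsv = NULL,
                         debug_tsv = NULL) {
  asm <- if (is.character(assembly) && length(assembly) == 1 &&
             file.exists(assembly) && is.null(names(assembly)))
    load_assembly(assembly, seed = params$seed) else assembly
  contigs <- as_contigs(asm)

  recs <- if (is.character(sam)) parse_sam(sam) else data.table::as.data.table(sam)
  recs <- filter_alignments(recs, params$max_errors)
  groups <- group_and_resolve(recs)

  mapped_contigs <- unique(groups$contig)
  unknown <- setdiff(mapped_contigs, names(contigs))
  if (length(unknown))
    stop("SAM alignments reference contig(s) absent from the assembly: ",
         paste(unknown, collapse = ", "))
  if (nrow(groups) == 0)
    warning("no usable alignments; assembly returned unchanged")

  pile <- build_pileup(contigs, groups, params)
  dec <- decide_changes(pile, params)
  polished <- apply_changes(contigs, dec$changes)

  smry <- summarise_changes(dec$changes, names(contigs), nrow(dec$dead_zone))
  for (nm in names(contigs)) {
    s <- smry$per_contig[smry$per_contig$contig == nm, ]
    message(sprintf("%s: %d substitution(s), %d insertion(s), %d deletion(s)",
                    nm, s$substitutions, s$insertions, s$deletions))
  }

  if (!is.null(out_fasta)) write_assembly(polished, out_fasta)
  if (!is.null(changes_tsv))
    data.table::fwrite(dec$changes, changes_tsv, sep = "\t", quote = FALSE)
  if (!is.null(debug_tsv)) {
    status <- data.table::rbindlist(list(
      dec$changes[, .(contig, pos, status = "changed")],
      dec$dead_zone[, .(contig, pos, status = "dead_zone")]))
    write_pileup_tsv(pile, debug_tsv, status = status)
  }
  list(assembly = polished, changes = dec$changes,
       dead_zone = dec$dead_zone, summary = smry)
}

summarise_changes <- function(changes, contig_names, n_dead_zone) {
  per <- data.table::data.table(contig = contig_names)
  tab <- if (nrow(changes))
    data.table::dcast(changes[, .N, by = .(contig, class)],
                      contig ~ class, value.var = "N", fill = 0L)
  else data.table::data.table(contig = character())
  for (cl in c("substitution", "insertion", "deletion"))
    if (!cl %in% names(tab)) tab[, (cl) := 0L]
  per <- merge(per, tab, by = "contig", all.x = TRUE)
  for (cl in c("substitution", "insertion", "deletion"))
    per[is.na(get(cl)), (cl) := 0L]
  data.table::setnames(per, c("substitution", "insertion", "deletion"),
                       c("substitutions", "insertions", "deletions"))
  list(per_contig = per[], n_changes = nrow(changes),
       n_dead_zone = n_dead_zone)
}
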