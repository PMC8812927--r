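# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate expr with a private, seeded RNG stream; the caller's RNG state
# is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce to a named character vector of uppercase contig sequences.
as_contigs <- function(assembly) {
  if (is(assembly, "DNAStringSet") || is(assembly, "BStringSet")) {
    out <- as.character(assembly)
  } else if (is.character(assembly)) {
    out <- assembly
  } else {
    stop("assembly must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop("assembly contigs must be named")
  toupper(out)
}

as_dnastringset <- function(contigs) {
  Biostrings::DNAStringSet(contigs)
}

# Split CIGAR strings into per-record integer lengths and op characters.
cigar_parse <- function(cigar) {
  m <- gregexpr("[0-9]+[A-Z=]", cigar)
  toks <- regmatches(cigar, m)
  bad <- vapply(seq_along(cigar), function(i) {
    sum(nchar(toks[[i]])) != nchar(cigar[[i]])
  }, logical(1))
  if (any(bad)) stop("invalid CIGAR '", cigar[which(bad)[1]], "'")
  lapply(toks, function(tk) {
    list(len = as.integer(sub("[A-Z=]$", "", tk)),
         op = sub("^[0-9]+", "", tk))
  })
}

cigar_consumed <- function(cigar, ops_wanted) {
  vapply(cigar_parse(cigar), function(co) {
    sum(co$len[co$op %in% ops_wanted])
  }, integer(1))
}

# Read bases consumed by a CIGAR (including soft clips).
cigar_read_len <- function(cigar) cigar_consumed(cigar, c("M", "=", "X", "I", "S"))

# Reference bases consumed by a CIGAR.
cigar_ref_len <- function(cigar) cigar_consumed(cigar, c("M", "=", "X", "D", "N"))

# Membership of 0-based positions in a set of 0-based half-open intervals
# (single contig; intervals need not be pre-merged).
positions_in_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(pos)))
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  IRanges::overlapsAny(IRanges::IRanges(start = pos + 1L, width = 1L), ir)
}
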