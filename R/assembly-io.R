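#' Load an assembly from FASTA
#'
#' Reads a (multi-)FASTA file into a [Biostrings::DNAStringSet], normalises
#' sequences to uppercase and replaces any IUPAC ambiguity codes (for
#' example `N`) with random unambiguous bases drawn from a seeded RNG
#' stream, so that loads are reproducible. Record order is preserved and
#' contig names are taken as the first whitespace-delimited token of each
#' header.
#'
#' @param path Path to a FASTA file.
#' @param seed Integer seed for ambiguity-code replacement.
#' @return A `DNAStringSet` of uppercase contigs over A/C/G/T. The number
#'   of replaced bases is attached as attribute `n_ambiguous_replaced`.
#' @export
load_assembly <- function(path, seed = 1L) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("no FASTA records in '", path, "'")
  nm <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(nm))) stop("FASTA record with empty name in '", path, "'")
  if (anyDuplicated(nm))
    stop("duplicate contig name '", nm[duplicated(nm)][1], "' in '", path, "'")
  seqs <- toupper(as.character(raw))
  names(seqs) <- nm

  iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  n_replaced <- 0L
  seqs <- with_seed(seed, {
    vapply(seq_along(seqs), function(i) {
      ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
      bad <- !(ch %in% DNA_BASES)
      if (any(bad)) {
        if (!all(ch[bad] %in% iupac))
          stop("contig '", nm[i], "' contains non-nucleotide characters: ",
               paste(unique(ch[bad & !(ch %in% iupac)]), collapse = ", "))
        ch[bad] <- sample(DNA_BASES, sum(bad), replace = TRUE)
        n_replaced <<- n_replaced + sum(bad)
      }
      paste0(ch, collapse = "")
    }, character(1))
  })
  names(seqs) <- nm
  out <- as_dnastringset(seqs)
  attr(out, "n_ambiguous_replaced") <- n_replaced
  out
}

#' Write an assembly to FASTA
#'
#' @param assembly A `DNAStringSet` or named character vector of contigs.
#' @param path Output FASTA path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path, width = 70L) {
  contigs <- as_contigs(assembly)
  Biostrings::writeXStringSet(as_dnastringset(contigs), path, width = width)
  invisible(path)
}
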