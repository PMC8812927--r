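#' Error-injection profile
#'
#' Per-base rates for the four error classes injected into an assembly
#' copy: substitutions, homopolymer insertions, homopolymer deletions and
#' non-homopolymer indels. The defaults are 0.01% per class, the rate
#' used to degrade simulated long-read assemblies to roughly Q30.
#'
#' @param substitution,hp_insertion,hp_deletion,other_indel Per-base
#'   probabilities, each in \[0, 0.01\].
#' @param seed Integer seed.
#' @return An object of class `error_profile`.
#' @export
error_profile <- function(substitution = 1e-4, hp_insertion = 1e-4,
                          hp_deletion = 1e-4, other_indel = 1e-4,
                          seed = 1L) {
  rates <- c(substitution = substitution, hp_insertion = hp_insertion,
             hp_deletion = hp_deletion, other_indel = other_indel)
  if (any(rates < 0 | rates > 0.01))
    stop("each rate must be in [0, 0.01]")
  structure(c(as.list(rates), list(seed = as.integer(seed))),
            class = "error_profile")
}

#' Generate a random genome with planted exact repeats
#'
#' Draws an i.i.d. uniform random sequence and plants `repeat_copies`
#' character-identical copies of one random segment at non-overlapping
#' positions, recording their locations (0-based half-open).
#'
#' @param length Genome length in bp.
#' @param repeat_length Length of the repeated segment (0 for none).
#' @param repeat_copies Total number of identical copies (0 or >= 2).
#' @param seed Integer seed.
#' @param contig_name Name of the single contig.
#' @return A list: `assembly` (`DNAStringSet`) and `repeats` (data.frame
#'   `contig`, `start`, `end`, one row per planted copy).
#' @export
make_genome <- function(length, repeat_length = 0L, repeat_copies = 0L,
                        seed = 1L, contig_name = "chromosome") {
  length <- as.integer(length)
  repeat_length <- as.integer(repeat_length)
  repeat_copies <- as.integer(repeat_copies)
  if (repeat_copies > 0 && repeat_copies * repeat_length >= length)
    stop("cannot pack ", repeat_copies, " x ", repeat_length,
         " bp repeats into ", length, " bp")
  with_seed(seed, {
    chars <- sample(DNA_BASES, length, replace = TRUE)
    starts <- integer(0)
    if (repeat_copies > 0 && repeat_length > 0) {
      for (attempt in seq_len(10000L)) {
        starts <- sort(sample.int(length - repeat_length + 1L, repeat_copies) - 1L)
        if (repeat_copies == 1 || all(diff(starts) >= repeat_length)) break
        starts <- integer(0)
      }
      if (length(starts) == 0)
        stop("could not place ", repeat_copies,
             " non-overlapping repeat copies; reduce repeat_length or copies")
      template <- chars[(starts[1] + 1L):(starts[1] + repeat_length)]
      for (s in starts[-1]) chars[(s + 1L):(s + repeat_length)] <- template
    }
    genome <- paste0(chars, collapse = "")
    names(genome) <- contig_name
    repeats <- data.frame(contig = rep(contig_name, length(starts)),
                          start = starts, end = starts + repeat_length,
                          stringsAsFactors = FALSE)
    list(assembly = as_dnastringset(genome), repeats = repeats)
  })
}

# 0-based positions lying inside a homopolymer run of length >= 2
hp_positions <- function(chars) {
  n <- length(chars)
  if (n < 2) return(integer(0))
  same_prev <- c(FALSE, chars[-1] == chars[-n])
  same_next <- c(chars[-n] == chars[-1], FALSE)
  which(same_prev | same_next) - 1L
}

#' Inject errors into an assembly
#'
#' Plants substitutions, homopolymer insertions/deletions (which extend or
#' contract a run of >= 2 identical bases by one) and non-homopolymer
#' single-base indels. The number of errors per class is drawn
#' Binomial(genome length, class rate) -- or fixed via `counts` -- and the
#' positions are sampled uniformly from the class's eligible sites
#' (homopolymer interiors for the homopolymer classes, non-homopolymer
#' positions for other indels), avoiding already-edited positions and
#' their immediate neighbours so planted errors stay independent.
#'
#' @param assembly A `DNAStringSet` or named character vector (currently
#'   one contig).
#' @param profile An [error_profile()].
#' @param counts Optional named integer vector fixing the per-class error
#'   counts, e.g. `c(sub = 4, hp_ins = 2, hp_del = 2, other_ins = 1,
#'   other_del = 1)`; overrides the binomial draw.
#' @param exclude Optional data.frame of 0-based half-open intervals
#'   (`start`, `end`) where no error may be placed.
#' @param repeats Optional repeat intervals (as from [make_genome()]) used
#'   to set the `in_repeat` flag of the truth list.
#' @return A list: `assembly` (mutated `DNAStringSet`) and `errors` (the
#'   ground-truth data.frame sorted by position, with `contig`,
#'   `position` in reference coordinates, `type` in sub / hp_ins /
#'   hp_del / other_ins / other_del, `ref_allele`, `alt_allele`,
#'   `in_repeat`).
#' @export
inject_errors <- function(assembly, profile = error_profile(), counts = NULL,
                          exclude = NULL, repeats = NULL) {
  contigs <- as_contigs(assembly)
  if (length(contigs) != 1)
    stop("inject_errors currently handles a single contig")
  nm <- names(contigs)
  chars <- strsplit(contigs[[1]], "", fixed = TRUE)[[1]]
  L <- length(chars)

  with_seed(profile$seed, {
    n_class <- if (!is.null(counts)) {
      need <- c("sub", "hp_ins", "hp_del", "other_ins", "other_del")
      missing <- setdiff(need, names(counts))
      cnt <- c(counts, stats::setNames(rep(0L, length(missing)), missing))
      as.integer(cnt[need])
    } else {
      other <- rbinom(1L, L, profile$other_indel)
      other_ins <- rbinom(1L, other, 0.5)
      c(rbinom(1L, L, profile$substitution),
        rbinom(1L, L, profile$hp_insertion),
        rbinom(1L, L, profile$hp_deletion),
        other_ins, other - other_ins)
    }
    names(n_class) <- c("sub", "hp_ins", "hp_del", "other_ins", "other_del")

    excluded <- rep(FALSE, L)
    if (!is.null(exclude) && nrow(exclude))
      for (i in seq_len(nrow(exclude)))
        excluded[(exclude$start[i] + 1L):(exclude$end[i])] <- TRUE
    hp <- rep(FALSE, L)
    hp[hp_positions(chars) + 1L] <- TRUE

    used <- rep(FALSE, L)  # positions blocked by earlier picks (+- 1)
    pick <- function(eligible, n) {
      idx <- which(eligible & !excluded & !used)
      if (length(idx) < n)
        stop("not enough eligible positions for requested error count")
      got <- if (length(idx) == 1) idx else sample(idx, n)
      for (p in got) used[max(1, p - 1):min(L, p + 1)] <<- TRUE
      got - 1L  # 0-based
    }

    errs <- list()
    add <- function(pos0, type, ref, alt)
      errs[[length(errs) + 1L]] <<- data.frame(
        contig = nm, position = pos0, type = type,
        ref_allele = ref, alt_allele = alt, stringsAsFactors = FALSE)

    edits <- character(L)  # "" means untouched; else replacement piece
    touched <- rep(FALSE, L)

    if (n_class["sub"] > 0) {
      p <- pick(rep(TRUE, L), n_class["sub"])
      for (pos in p) {
        old <- chars[pos + 1L]
        new <- sample(setdiff(DNA_BASES, old), 1L)
        edits[pos + 1L] <- new; touched[pos + 1L] <- TRUE
        add(pos, "sub", old, new)
      }
    }
    if (n_class["hp_ins"] > 0) {
      p <- pick(hp, n_class["hp_ins"])
      for (pos in p) {
        b <- chars[pos + 1L]
        edits[pos + 1L] <- paste0(b, b); touched[pos + 1L] <- TRUE
        add(pos, "hp_ins", b, paste0(b, b))
      }
    }
    if (n_class["hp_del"] > 0) {
      p <- pick(hp, n_class["hp_del"])
      for (pos in p) {
        edits[pos + 1L] <- ""; touched[pos + 1L] <- TRUE
        add(pos, "hp_del", chars[pos + 1L], "")
      }
    }
    if (n_class["other_ins"] > 0) {
      p <- pick(!hp, n_class["other_ins"])
      for (pos in p) {
        b <- chars[pos + 1L]
        nxt <- if (pos + 2L <= L) chars[pos + 2L] else ""
        ins <- sample(setdiff(DNA_BASES, c(b, nxt)), 1L)
        edits[pos + 1L] <- paste0(b, ins); touched[pos + 1L] <- TRUE
        add(pos, "other_ins", b, paste0(b, ins))
      }
    }
    if (n_class["other_del"] > 0) {
      p <- pick(!hp, n_class["other_del"])
      for (pos in p) {
        edits[pos + 1L] <- ""; touched[pos + 1L] <- TRUE
        add(pos, "other_del", chars[pos + 1L], "")
      }
    }

    out_chars <- chars
    out_chars[touched] <- edits[touched]
    mutated <- paste0(out_chars, collapse = "")
    names(mutated) <- nm

    errors <- if (length(errs)) do.call(rbind, errs)
              else data.frame(contig = character(), position = integer(),
                              type = character(), ref_allele = character(),
                              alt_allele = character(), stringsAsFactors = FALSE)
    errors <- errors[order(errors$position), , drop = FALSE]
    rownames(errors) <- NULL
    errors$in_repeat <- if (!is.null(repeats) && nrow(repeats))
      positions_in_intervals(errors$position, repeats$start, repeats$end)
    else rep(FALSE, nrow(errors))
    list(assembly = as_dnastringset(mutated), errors = errors)
  })
}

#' Simulate error-free short reads tiling an assembly
#'
#' Draws reads of fixed length at uniform random positions and strands
#' until the target mean depth is reached. Reads are error-free copies of
#' the assembly (reverse-strand reads are reverse-complemented); names
#' encode the true origin for debugging.
#'
#' @param assembly A `DNAStringSet` or named character vector.
#' @param read_length Read length in bp (must not exceed the shortest
#'   contig).
#' @param depth Target mean depth.
#' @param seed Integer seed.
#' @param paired Emit read pairs from fixed-length fragments instead of
#'   single reads.
#' @param fragment_length Fragment length for paired simulation.
#' @return A data.frame of reads: `name`, `seq` (sequencing orientation),
#'   `segment` (0 unpaired; 1/2 for pairs).
#' @export
simulate_reads <- function(assembly, read_length = 150L, depth = 30,
                           seed = 1L, paired = FALSE,
                           fragment_length = 400L) {
  contigs <- as_contigs(assembly)
  read_length <- as.integer(read_length)
  if (read_length > min(nchar(contigs)))
    stop("read_length exceeds the shortest contig")
  if (paired && fragment_length > min(nchar(contigs)))
    stop("fragment_length exceeds the shortest contig")
  with_seed(seed, {
    out <- lapply(names(contigs), function(nm) {
      s <- contigs[[nm]]
      L <- nchar(s)
      if (!paired) {
        n <- as.integer(ceiling(depth * L / read_length))
        starts <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
        rev <- sample(c(FALSE, TRUE), n, replace = TRUE)
        seqs <- substring(s, starts + 1L, starts + read_length)
        seqs[rev] <- revcomp_chr(seqs[rev])
        data.frame(
          name = sprintf("r%06d_%s_%d_%s", seq_len(n), nm, starts,
                         ifelse(rev, "-", "+")),
          seq = seqs, segment = 0L, stringsAsFactors = FALSE)
      } else {
        n <- as.integer(ceiling(depth * L / (2L * read_length)))
        fstarts <- sample.int(L - fragment_length + 1L, n, replace = TRUE) - 1L
        r1 <- substring(s, fstarts + 1L, fstarts + read_length)
        r2 <- revcomp_chr(substring(s, fstarts + fragment_length - read_length + 1L,
                                    fstarts + fragment_length))
        nmv <- sprintf("p%06d_%s_%d", seq_len(n), nm, fstarts)
        data.frame(name = rep(nmv, 2L), seq = c(r1, r2),
                   segment = rep(c(1L, 2L), each = n),
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, out)
  })
}

#' Write reads to FASTQ
#'
#' Constant quality `I`; paired read sets are split by segment into
#' `path` and `path2`.
#'
#' @param reads A data.frame from [simulate_reads()].
#' @param path Output FASTQ path (segment 1 / unpaired reads).
#' @param path2 Output path for segment-2 reads (paired sets only).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, path2 = NULL) {
  emit <- function(df, p) {
    qual <- strrep("I", nchar(df$seq))
    writeLines(paste0("@", df$name, "\n", df$seq, "\n+\n", qual), p)
  }
  if (any(reads$segment == 2L)) {
    if (is.null(path2)) stop("paired reads need path2")
    emit(reads[reads$segment == 1L, ], path)
    emit(reads[reads$segment == 2L, ], path2)
  } else {
    emit(reads, path)
  }
  invisible(path)
}
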