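# Independent oracles, written from scratch against the stated semantics
# (not by calling the package's fast paths), used to cross-check pileup
# construction and the exhaustive aligner.

# Character-level re-derivation of the read-base <-> position
# correspondence for one alignment, with homopolymer end trimming.
# Returns a data.frame(pos, piece).
oracle_pieces <- function(cigar, seq, ref_start, trim_both = FALSE) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  lens <- as.integer(sub(".$", "", toks))
  ops <- substr(toks, nchar(toks), nchar(toks))
  # aligned sequence: drop soft-clipped bases
  sidx <- 1L
  aseq_chars <- character(0)
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "=", "X", "I")) {
      aseq_chars <- c(aseq_chars, substring(seq, sidx + seq_len(lens[i]) - 1L,
                                            sidx + seq_len(lens[i]) - 1L))
      sidx <- sidx + lens[i]
    } else if (ops[i] == "S") {
      sidx <- sidx + lens[i]
    }
  }
  A <- length(aseq_chars)
  # per-position pieces with the read indices (1-based here) they use
  pos <- integer(0); piece <- character(0); uses <- list()
  rpos <- ref_start; a <- 1L
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      for (j in seq_len(len)) {
        pos <- c(pos, rpos); piece <- c(piece, aseq_chars[a])
        uses[[length(uses) + 1L]] <- a
        rpos <- rpos + 1L; a <- a + 1L
      }
    } else if (op == "I") {
      if (length(pos) > 0) {
        piece[length(piece)] <- paste0(piece[length(piece)],
                                       paste0(aseq_chars[a + seq_len(len) - 1L],
                                              collapse = ""))
        uses[[length(uses)]] <- c(uses[[length(uses)]], a + seq_len(len) - 1L)
      }
      a <- a + len
    } else if (op == "D") {
      for (j in seq_len(len)) {
        pos <- c(pos, rpos); piece <- c(piece, "")
        uses[[length(uses) + 1L]] <- integer(0)
        rpos <- rpos + 1L
      }
    }
  }
  if (A == 0) return(data.frame(pos = integer(0), piece = character(0)))
  # end trim: terminal run + 1, capped
  run <- 1L
  while (run < A && aseq_chars[A - run] == aseq_chars[A]) run <- run + 1L
  t_end <- min(run + 1L, A)
  trimmed <- seq.int(A - t_end + 1L, A)  # 1-based trimmed read indices
  first_bad <- NA_integer_
  for (i in seq_along(pos)) {
    if (any(uses[[i]] %in% trimmed)) { first_bad <- i; break }
  }
  keep <- if (is.na(first_bad)) seq_along(pos) else seq_len(first_bad - 1L)
  if (trim_both && length(keep)) {
    run0 <- 1L
    while (run0 < A && aseq_chars[run0 + 1L] == aseq_chars[1L]) run0 <- run0 + 1L
    t0 <- min(run0 + 1L, A)
    lead <- seq_len(t0)
    last_bad <- 0L
    for (i in keep) if (any(uses[[i]] %in% lead)) last_bad <- i
    keep <- keep[keep > last_bad]
  }
  data.frame(pos = pos[keep], piece = piece[keep], stringsAsFactors = FALSE)
}

# Full pileup oracle: accumulates raw piece counts and 1/k depth over all
# alignments.
oracle_pileup <- function(alignments, contigs, trim_both = FALSE) {
  depth <- lapply(contigs, function(s) numeric(nchar(s)))
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(alignments))) {
    al <- alignments[i, ]
    pieces <- oracle_pieces(al$cigar, al$seq, al$ref_start, trim_both)
    if (nrow(pieces) == 0) next
    depth[[al$contig]][pieces$pos + 1L] <-
      depth[[al$contig]][pieces$pos + 1L] + 1 / al$k
    for (j in seq_len(nrow(pieces))) {
      key <- paste(al$contig, pieces$pos[j], pieces$piece[j], sep = "\r")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  dt <- data.table::data.table(
    contig = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    piece = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
    count = vapply(keys, function(k) counts[[k]], integer(1)))
  data.table::setorder(dt, contig, pos, piece)
  list(depth = depth, counts = dt[])
}

# Edit distance implied by a CIGAR: mismatching M columns plus indel
# lengths, re-walked against the reference.
oracle_cigar_distance <- function(cigar, seq, ref, start) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  lens <- as.integer(sub(".$", "", toks))
  ops <- substr(toks, nchar(toks), nchar(toks))
  d <- 0L; rpos <- start; a <- 1L
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "=", "X")) {
      for (j in seq_len(lens[i])) {
        if (substr(seq, a, a) != substr(ref, rpos + 1L, rpos + 1L)) d <- d + 1L
        a <- a + 1L; rpos <- rpos + 1L
      }
    } else if (ops[i] == "I") { d <- d + lens[i]; a <- a + lens[i] }
    else if (ops[i] == "D") { d <- d + lens[i]; rpos <- rpos + lens[i] }
    else if (ops[i] == "S") { a <- a + lens[i] }
  }
  d
}

# Best end-to-end edit distance of a read at every reference window,
# via utils::adist (an independent alignment engine): returns the
# minimum distance over windows whose start lies in [at - slack, at + slack].
oracle_best_distance_near <- function(read, ref, at, slack = 5L) {
  L <- nchar(read)
  best <- Inf
  for (s in max(0L, at - slack):(at + slack)) {
    for (w in (L - slack):(L + slack)) {
      if (s + w > nchar(ref)) next
      win <- substr(ref, s + 1L, s + w)
      best <- min(best, utils::adist(read, win))
    }
  }
  best
}

# Shared fixture: a small genome with a 2-copy exact repeat, an
# error-containing copy, error-free reads and all-per-read alignments.
make_polish_fixture <- function(genome_len = 20000, repeat_len = 1000,
                                depth = 40, seed = 5,
                                counts = c(sub = 3, hp_ins = 1, hp_del = 1,
                                           other_ins = 1, other_del = 1)) {
  g <- make_genome(genome_len, repeat_length = repeat_len, repeat_copies = 2,
                   seed = seed)
  ends <- data.frame(start = c(0L, genome_len - 200L),
                     end = c(200L, genome_len))
  pad <- data.frame(start = pmax(0L, g$repeats$start - 20L),
                    end = pmin(genome_len, g$repeats$end + 20L))
  inj <- inject_errors(g$assembly, error_profile(seed = seed + 1),
                       counts = counts,
                       exclude = rbind(ends, pad), repeats = g$repeats)
  reads <- simulate_reads(g$assembly, 150, depth = depth, seed = seed + 2)
  aln <- exhaustive_align(reads, inj$assembly, max_edits = 5, mode = "all",
                          seed = seed + 3)
  list(genome = g, inj = inj, reads = reads, aln = aln)
}
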