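test_that("genomes plant identical, recorded, non-overlapping repeat copies", {
  g <- make_genome(10000, repeat_length = 1000, repeat_copies = 2, seed = 1)
  s <- as.character(g$assembly[[1]])
  expect_equal(nchar(s), 10000)
  expect_equal(nrow(g$repeats), 2)
  r <- g$repeats
  expect_true(all(r$end - r$start == 1000))
  expect_true(r$start[2] >= r$end[1])
  expect_identical(substr(s, r$start[1] + 1, r$end[1]),
                   substr(s, r$start[2] + 1, r$end[2]))
  # no repeats requested -> none reported
  expect_equal(nrow(make_genome(1000, seed = 1)$repeats), 0)
  # seeded determinism
  expect_identical(as.character(make_genome(5000, 500, 2, seed = 9)$assembly),
                   as.character(make_genome(5000, 500, 2, seed = 9)$assembly))
  expect_error(make_genome(1000, 600, 2), "pack")
})

test_that("error injection honours rates, context and exclusions", {
  g <- make_genome(50000, seed = 2)
  # all rates zero: identity
  zero <- inject_errors(g$assembly, error_profile(0, 0, 0, 0, seed = 1))
  expect_identical(as.character(zero$assembly), as.character(g$assembly))
  expect_equal(nrow(zero$errors), 0)
  # seeded determinism
  a <- inject_errors(g$assembly, error_profile(seed = 4))
  b <- inject_errors(g$assembly, error_profile(seed = 4))
  expect_identical(as.character(a$assembly), as.character(b$assembly))
  expect_identical(a$errors, b$errors)

  inj <- inject_errors(g$assembly, error_profile(seed = 5),
                       counts = c(sub = 5, hp_ins = 3, hp_del = 3,
                                  other_ins = 2, other_del = 2),
                       exclude = data.frame(start = 0L, end = 25000L))
  expect_equal(nrow(inj$errors), 15)
  expect_true(all(inj$errors$position >= 25000))
  chars <- strsplit(as.character(g$assembly[[1]]), "")[[1]]
  for (i in seq_len(nrow(inj$errors))) {
    e <- inj$errors[i, ]
    p <- e$position + 1L
    expect_equal(chars[p], e$ref_allele)
    in_run <- (p > 1 && chars[p - 1] == chars[p]) ||
      (p < length(chars) && chars[p + 1] == chars[p])
    if (e$type %in% c("hp_ins", "hp_del")) expect_true(in_run)
    if (e$type %in% c("other_ins", "other_del")) expect_false(in_run)
    if (e$type == "sub") expect_true(e$alt_allele != e$ref_allele)
  }
  # the truth list accounts for the full edit distance
  aln <- global_align(inj$assembly[[1]], g$assembly[[1]])
  expect_equal(aln$distance, 15)
})

test_that("in_repeat flags come from the planted intervals", {
  g <- make_genome(20000, repeat_length = 2000, repeat_copies = 2, seed = 3)
  inside <- data.frame(start = c(0L, g$repeats$start[1] + 500L),
                       end = c(g$repeats$start[1] + 400L, 20000L))
  inj <- inject_errors(g$assembly, error_profile(seed = 6),
                       counts = c(sub = 3), exclude = inside,
                       repeats = g$repeats)
  expect_true(all(inj$errors$in_repeat))
})

test_that("read simulation hits the target depth and encodes origins", {
  g <- make_genome(10000, seed = 7)
  reads <- simulate_reads(g$assembly, 150, depth = 300, seed = 8)
  realized <- sum(nchar(reads$seq)) / 10000
  expect_lt(abs(realized - 300) / 300, 0.05)
  # spot-check: forward reads match the genome, reverse are complemented
  s <- as.character(g$assembly[[1]])
  info <- do.call(rbind, strsplit(reads$name[1:50], "_"))
  for (i in 1:50) {
    start <- as.integer(info[i, 3])
    sub <- substr(s, start + 1, start + 150)
    if (info[i, 4] == "+") expect_identical(reads$seq[i], sub)
    else expect_identical(
      reads$seq[i],
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub))))
  }
  expect_identical(simulate_reads(g$assembly, 150, 5, seed = 9)$seq,
                   simulate_reads(g$assembly, 150, 5, seed = 9)$seq)
  expect_error(simulate_reads(g$assembly, 20000, 5), "read_length")
})

test_that("FASTQ output carries names, sequences and constant quality", {
  g <- make_genome(2000, seed = 17)
  reads <- simulate_reads(g$assembly, 100, depth = 2, seed = 18)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  lines <- readLines(f)
  expect_equal(length(lines), 4 * nrow(reads))
  expect_identical(lines[seq(1, length(lines), 4)], paste0("@", reads$name))
  expect_identical(lines[seq(2, length(lines), 4)], reads$seq)
  expect_true(all(lines[seq(4, length(lines), 4)] == strrep("I", 100)))
})

test_that("the exhaustive aligner finds every placement within the edit budget", {
  g <- make_genome(6000, repeat_length = 600, repeat_copies = 2, seed = 10)
  s <- as.character(g$assembly[[1]])
  rs <- g$repeats$start

  # unique-region read: exactly one alignment at distance 0
  u <- substr(s, 3001, 3100)  # outside both repeat copies by construction?
  # pick a window guaranteed outside the repeats
  gap <- setdiff(0:5900, unlist(Map(seq, rs - 100, rs + 600)))
  at <- gap[gap > 100][1]
  u <- substr(s, at + 1, at + 100)
  h <- exhaustive_align(u, g$assembly, max_edits = 2, seed = 1)
  expect_equal(nrow(h), 1)
  expect_equal(h$ref_start, at)
  expect_equal(h$edit_distance, 0L)

  # repeat-interior read: one alignment per planted copy
  rr <- substr(s, rs[1] + 101, rs[1] + 200)
  h <- exhaustive_align(rr, g$assembly, max_edits = 2, seed = 1)
  expect_equal(nrow(h), 2)
  expect_setequal(h$ref_start, rs + 100)
  expect_equal(h$k, c(2L, 2L))
  expect_equal(sum(h$is_secondary), 1)

  # reverse-complement reads are found on the reverse strand
  rcu <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(u)))
  h <- exhaustive_align(rcu, g$assembly, max_edits = 2, seed = 1)
  expect_true(h$is_reverse)
  expect_equal(h$ref_start, at)

  # no hit within budget -> unmapped record
  h <- exhaustive_align(strrep("ACGTT", 20), g$assembly, max_edits = 1, seed = 1)
  expect_true(is.na(h$contig))
  expect_equal(h$k, 0L)
})

test_that("claimed edit distances survive a CIGAR re-walk", {
  fx <- make_polish_fixture(genome_len = 4000, repeat_len = 400, depth = 6,
                            seed = 81)
  grp <- fx$aln[!is.na(contig)]
  ref <- as.character(fx$inj$assembly[[1]])
  for (i in seq_len(nrow(grp))) {
    expect_equal(
      oracle_cigar_distance(grp$cigar[i], grp$seq[i], ref, grp$ref_start[i]),
      grp$edit_distance[i])
  }
})

test_that("best-only alignment starves the mutated repeat copy", {
  g <- make_genome(8000, repeat_length = 1000, repeat_copies = 2, seed = 12)
  s <- as.character(g$assembly[[1]])
  rs <- g$repeats$start
  # substitution in the middle of copy 2
  p <- rs[2] + 500L
  old <- substr(s, p + 1, p + 1)
  mut <- s
  substr(mut, p + 1, p + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
  mutated <- c(chromosome = mut)
  # a clean read overlapping the error offset, taken from copy 1
  read <- substr(s, rs[1] + 451, rs[1] + 550)
  h <- exhaustive_align(read, mutated, max_edits = 3, mode = "all", seed = 2)
  expect_equal(nrow(h), 2)
  expect_equal(sort(h$edit_distance), c(0L, 1L))
  expect_equal(h[h$edit_distance == 1L, ]$ref_start, rs[2] + 450L)
  # oracle: an independent alignment engine agrees on the distances
  expect_equal(oracle_best_distance_near(read, mut, rs[1] + 450L), 0)
  expect_equal(oracle_best_distance_near(read, mut, rs[2] + 450L), 1)
  # best-only placement prefers the error-free copy
  hb <- exhaustive_align(read, mutated, max_edits = 3, mode = "best_only",
                         seed = 2)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$ref_start, rs[1] + 450L)
  expect_equal(hb$edit_distance, 0L)
})

test_that("SAM output round-trips through the parser", {
  fx <- make_polish_fixture(genome_len = 3000, repeat_len = 300, depth = 4,
                            seed = 91, counts = c(sub = 2))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(fx$aln, fx$inj$assembly, f)
  recs <- parse_sam(f)
  mapped_in <- fx$aln[!is.na(contig)]
  mapped_out <- recs[recs$is_unmapped == FALSE, ]
  expect_equal(nrow(mapped_out), nrow(mapped_in))
  expect_equal(sum(recs$is_unmapped), sum(is.na(fx$aln$contig)))
  # secondary records have no stored sequence until resolution
  expect_true(all(is.na(mapped_out$seq[mapped_out$is_secondary])))
  grp <- group_and_resolve(recs)
  expect_equal(nrow(grp), nrow(mapped_in))
  data.table::setorder(grp, qname, ref_start)
  cmp <- data.table::copy(mapped_in)
  data.table::setorder(cmp, qname, ref_start)
  expect_equal(grp$ref_start, cmp$ref_start)
  expect_equal(grp$seq, cmp$seq)
  expect_equal(grp$k, cmp$k)
})

test_that("paired simulation yields proper segments and fragment geometry", {
  g <- make_genome(5000, seed = 13)
  reads <- simulate_reads(g$assembly, 100, depth = 4, seed = 14,
                          paired = TRUE, fragment_length = 400)
  expect_setequal(unique(reads$segment), c(1L, 2L))
  aln <- exhaustive_align(reads, g$assembly, max_edits = 1, seed = 15)
  m <- aln[!is.na(contig)]
  # the two segments of one pair are distinct groups 400 bp apart
  qn <- m$qname[1]
  pair <- m[qname == qn]
  expect_equal(nrow(pair), 2)
  expect_equal(abs(diff(pair$ref_start)), 300)
  expect_equal(sort(pair$segment), c(1L, 2L))
})
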