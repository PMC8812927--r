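col_fixture <- function(ref_base, depth, counts, contig = "c", pos = 0L) {
  list(contig = contig, pos = pos, ref_base = ref_base, depth = depth,
       counts = counts)
}

test_that("parameters are validated", {
  expect_error(polish_params(fraction_valid = 0.1, fraction_invalid = 0.2),
               "fraction_invalid <= fraction_valid")
  expect_error(polish_params(min_depth = -1), "min_depth")
  expect_equal(polish_params()$trim_mode, "end_only")
})

test_that("pieces are classified against strict valid/invalid thresholds", {
  p <- polish_params()
  cl <- classify_column(col_fixture("A", 20, c(A = 19L, C = 1L)), p)
  expect_equal(cl$t_valid, 10)
  expect_equal(cl$t_invalid, 4)
  expect_equal(cl$valid, "A")
  expect_equal(cl$invalid, "C")

  # strict inequality at the valid boundary: 5 > max(5, 5) is false
  cl <- classify_column(col_fixture("A", 10, c(A = 5L)), p)
  expect_equal(cl$neither, "A")

  # invalid boundary: 2 < 2 is false -> dead zone
  cl <- classify_column(col_fixture("A", 10, c(A = 8L, G = 2L)), p)
  expect_equal(cl$valid, "A")
  expect_equal(cl$neither, "G")

  # repeat column: 20 alignments at half weight, unanimous piece is valid
  cl <- classify_column(col_fixture("A", 10, c(T = 20L)), p)
  expect_equal(cl$t_valid, 5)
  expect_equal(cl$valid, "T")
})

test_that("a change needs a single valid alternative and no dead zone", {
  p <- polish_params()
  # unanimous deletion evidence
  ch <- decide_change(col_fixture("A", 12, stats::setNames(12L, "")), p)
  expect_equal(ch$class, "deletion")
  expect_equal(ch$new, "")
  # unanimous insertion evidence
  ch <- decide_change(col_fixture("G", 9, stats::setNames(9L, "AT")), p)
  expect_equal(ch$class, "insertion")
  expect_equal(ch$new, "AT")
  # any piece in the dead zone blocks the change
  expect_null(decide_change(col_fixture("A", 10, c(C = 6L, G = 3L)), p))
  # the single valid piece equals the current base: nothing to do
  expect_null(decide_change(col_fixture("A", 9, c(A = 9L)), p))
  # multiple valid pieces block
  expect_null(decide_change(col_fixture("A", 10, c(C = 6L, G = 6L)), p))
  # no valid piece blocks
  expect_null(decide_change(col_fixture("A", 30, c(C = 4L)), p))
})

test_that("vectorised change decisions agree with the per-column rule", {
  fx <- make_polish_fixture(genome_len = 4000, repeat_len = 400, depth = 25,
                            seed = 51)
  grp <- fx$aln[!is.na(contig)]
  pile <- build_pileup(fx$inj$assembly, grp)
  dec <- decide_changes(pile)
  p <- pile$params
  # every column with observed pieces, decided one at a time
  slow <- list()
  for (pos in unique(pile$contigs$chromosome$counts$pos)) {
    ch <- decide_change(pileup_column(pile, "chromosome", pos), p)
    if (!is.null(ch)) slow[[length(slow) + 1L]] <- ch
  }
  slow <- do.call(rbind, slow)
  expect_equal(nrow(dec$changes), nrow(slow))
  expect_equal(dec$changes$pos, slow$pos)
  expect_equal(dec$changes$new, slow$new)
  # conservativeness: every emitted change beats the thresholds strictly
  for (i in seq_len(nrow(dec$changes))) {
    ch <- dec$changes[i, ]
    col <- pileup_column(pile, ch$contig, ch$pos)
    t_v <- max(p$min_depth, p$fraction_valid * col$depth)
    t_i <- p$fraction_invalid * col$depth
    expect_gt(unname(col$counts[names(col$counts) == ch$new]), t_v)
    others <- col$counts[names(col$counts) != ch$new]
    if (length(others)) expect_true(all(others < t_i))
  }
})

test_that("applying changes does exact sequence surgery", {
  asm <- c(c1 = strrep("ACGT", 25))  # 100 bp
  none <- data.table::data.table(contig = character(), pos = integer(),
                                 old = character(), new = character(),
                                 depth = numeric(), count = integer(),
                                 class = character())
  expect_identical(as.character(apply_changes(asm, none)[[1]]), asm[["c1"]])

  one <- data.table::data.table(contig = "c1", pos = 5L, old = "C",
                                new = "T", depth = 10, count = 10L,
                                class = "substitution")
  out <- as.character(apply_changes(asm, one)[[1]])
  expect_equal(sum(strsplit(out, "")[[1]] != strsplit(asm[["c1"]], "")[[1]]), 1)
  expect_equal(substr(out, 6, 6), "T")

  # one deletion + one 2-base insertion: length 100 - 1 + 1 = 101
  two <- data.table::data.table(contig = "c1", pos = c(10L, 50L),
                                old = c("G", "G"), new = c("", "GAT"),
                                depth = 10, count = 10L,
                                class = c("deletion", "insertion"))
  expect_equal(nchar(as.character(apply_changes(asm, two)[[1]])), 101)
})

test_that("a polishing round fixes planted errors and reports them", {
  fx <- make_polish_fixture(genome_len = 8000, repeat_len = 800, depth = 40,
                            seed = 61)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(fx$aln, fx$inj$assembly, f)
  out_fa <- withr::local_tempfile(fileext = ".fasta")
  ch_tsv <- withr::local_tempfile(fileext = ".tsv")
  res <- suppressMessages(
    polish_round(fx$inj$assembly, f, out_fasta = out_fa, changes_tsv = ch_tsv))
  expect_equal(nrow(res$changes), nrow(fx$inj$errors))
  expect_identical(as.character(res$assembly[[1]]),
                   as.character(fx$genome$assembly[[1]]))
  # outputs round-trip
  expect_identical(as.character(load_assembly(out_fa)[[1]]),
                   as.character(res$assembly[[1]]))
  tsv <- data.table::fread(ch_tsv)
  expect_equal(tsv$pos, res$changes$pos)

  # determinism: identical inputs give byte-identical outputs
  out2 <- withr::local_tempfile(fileext = ".fasta")
  suppressMessages(polish_round(fx$inj$assembly, f, out_fasta = out2))
  expect_identical(readLines(out_fa), readLines(out2))
})

test_that("polishing an error-free assembly changes nothing", {
  g <- make_genome(6000, repeat_length = 500, repeat_copies = 2, seed = 71)
  reads <- simulate_reads(g$assembly, 100, depth = 20, seed = 72)
  aln <- exhaustive_align(reads, g$assembly, max_edits = 3, mode = "all",
                          seed = 73)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, g$assembly, f)
  res <- suppressMessages(polish_round(g$assembly, f))
  expect_equal(nrow(res$changes), 0)
  expect_identical(as.character(res$assembly[[1]]),
                   as.character(g$assembly[[1]]))
})

test_that("an empty SAM yields zero changes with a warning", {
  asm <- c(c1 = strrep("ACGT", 50))
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:c1\tLN:200"), f)
  expect_warning(res <- suppressMessages(polish_round(asm, f)),
                 "no usable alignments")
  expect_equal(nrow(res$changes), 0)
  expect_identical(as.character(res$assembly[[1]]), asm[["c1"]])
})

test_that("alignments to unknown contigs are fatal", {
  asm <- c(c1 = strrep("ACGT", 50))
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:c9\tLN:200",
               "r1\t0\tc9\t1\t60\t4M\t*\t0\t0\tACGT\t*"), f)
  expect_error(suppressMessages(polish_round(asm, f)), "c9")
})
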