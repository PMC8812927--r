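# Repeat-repair study fixture: a genome with a 2-copy exact repeat, one
# substitution and one homopolymer deletion planted inside the interior of
# the first repeat copy, ten assorted errors in unique sequence, and
# error-free reads simulated from the clean genome.
make_repeat_repair_fixture <- function(genome_len = 50000, repeat_len = 2000,
                                       depth = 50, read_len = 150, seed = 1) {
  g <- make_genome(genome_len, repeat_length = repeat_len, repeat_copies = 2,
                   seed = seed)
  L <- genome_len
  s1 <- g$repeats$start[1]; e1 <- g$repeats$end[1]

  # two errors confined to the interior of repeat copy 1 (further than a
  # read length from either repeat edge, so covering reads lie wholly
  # inside the repeat)
  inj1 <- inject_errors(
    g$assembly, error_profile(seed = seed + 10),
    counts = c(sub = 1, hp_del = 1),
    exclude = data.frame(start = c(0L, e1 - 200L), end = c(s1 + 200L, L)),
    repeats = g$repeats)

  # ten assorted errors in unique sequence, away from repeats and contig
  # ends (the hp_del above shifts downstream coordinates by one, hence the
  # padded exclusion)
  Lm <- nchar(as.character(inj1$assembly[[1]]))
  pad <- data.frame(start = pmax(0L, g$repeats$start - 25L),
                    end = pmin(Lm, g$repeats$end + 25L))
  ends <- data.frame(start = c(0L, Lm - 200L), end = c(200L, Lm))
  inj2 <- inject_errors(
    inj1$assembly, error_profile(seed = seed + 20),
    counts = c(sub = 4, hp_ins = 2, hp_del = 2, other_ins = 1, other_del = 1),
    exclude = rbind(pad, ends))

  reads <- simulate_reads(g$assembly, read_len, depth = depth,
                          seed = seed + 30)
  list(genome = g, mutated = inj2$assembly, reads = reads,
       repeat_errors = inj1$errors, unique_errors = inj2$errors)
}
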