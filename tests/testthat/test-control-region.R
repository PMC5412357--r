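test_that("homopolymer finder reports maximal runs with exact bounds", {
  s <- paste0("ACGC", strrep("T", 15), "GACA")
  hits <- find_homopolymer(s, "T", 10)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start0, 4)
  expect_equal(hits$length, 15)

  expect_equal(nrow(find_homopolymer("ACGTACGTTT", "T", 10)), 0)

  # run abutting the sequence end keeps the right-open bound
  s2 <- paste0("ACG", strrep("A", 12))
  h2 <- find_homopolymer(s2, "A", 10)
  expect_equal(h2$end0, nchar(s2))

  # appending unrelated sequence after the last run changes nothing
  h3 <- find_homopolymer(paste0(s, "GCGCGC"), "T", 10)
  expect_equal(h3[, c("start0", "end0")], hits[, c("start0", "end0")])
})

test_that("(TA)n finder reports whole-unit maximal stretches", {
  h <- find_ta_stretch("GGCTATATATACC", 3)
  expect_equal(nrow(h), 1)
  expect_equal(h$length, 8)       # TATATATA
  expect_equal(h$start0, 3)

  expect_equal(nrow(find_ta_stretch("TATG", 3)), 0)

  h2 <- find_ta_stretch("CCTATATACCATATATACC", 3)
  expect_equal(nrow(h2), 2)
  expect_true(all(diff(h2$start0) > 0))
  expect_true(all(h2$length %% 2 == 0))
  expect_true(all(h2$length >= 6))
})

test_that("macro-repeat finder recovers the planted 72/36 bp repeats", {
  set.seed(99)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE,
                                 prob = c(.4, .1, .1, .4)), collapse = "")
  long <- paste0("GTTAAATTCCCCTTAATTTAACAATTAATTTTCTTTTATTTATTGGT",
                 "AAGAAAACTTATCAATTAATCAATT")
  s <- paste0(bg(150), "C", long, "G", bg(300), "T", long, "A", bg(150))
  out <- find_macro_repeats(s, 30)
  expect_equal(out$repeats$length[1], 72)
  expect_equal(out$repeats$n_occ[1], 2)
  expect_equal(out$repeats$seq[1], long)
  starts <- as.integer(strsplit(out$repeats$starts0[1], ",")[[1]])
  expect_equal(diff(starts), 72 + 1 + 300 + 1)
})

test_that("macro-repeat finder agrees with the brute-force oracle", {
  for (seed in c(1, 2, 3)) {
    s <- random_dna(1500, seed)
    mine <- find_macro_repeats(s, 10)
    ref <- oracle_macro_repeats(s, 10)
    got <- sort(paste(mine$repeats$seq, mine$repeats$length))
    want <- sort(paste(ref$seq, ref$length))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("abutting copies are reported as tandem, not non-tandem", {
  unit <- "ACGTTGCAACGTGGTACCAT"  # 20-mer
  # insulating flank characters keep the planted copies flank-maximal
  s <- paste0(random_dna(60, 4), "G", unit, unit, "C", random_dna(60, 5))
  out <- find_macro_repeats(s, 10)
  expect_true(any(out$tandem$seq == unit))
  expect_false(any(out$repeats$seq == unit))

  # the same unit with a 1 nt gap qualifies as non-tandem
  s2 <- paste0(random_dna(60, 6), "G", unit, "C", unit, "T",
               random_dna(60, 7))
  out2 <- find_macro_repeats(s2, 10)
  expect_true(any(out2$repeats$seq == unit))
})

test_that("all occurrences of a reported repeat are character-identical", {
  s <- random_dna(1200, 8)
  out <- find_macro_repeats(s, 8)
  for (i in seq_len(nrow(out$repeats))) {
    st <- as.integer(strsplit(out$repeats$starts0[i], ",")[[1]])
    copies <- substring(s, st + 1, st + out$repeats$length[i])
    expect_equal(length(unique(copies)), 1)
  }
})

test_that("stem-loop finder detects a planted perfect hairpin", {
  stem <- "ACGTACGGTC"
  hp <- paste0(stem, "TTCTTC", revcomp(stem))
  s <- paste0(strrep("A", 40), hp, strrep("A", 40))
  hits <- find_stem_loops(s, min_stem = 6)
  expect_gte(nrow(hits), 1)
  expect_equal(hits$stem[1], 10)
  expect_equal(hits$loop[1], 6)
  expect_equal(hits$start0[1], 40)

  # no self-pairing in a homopolymer
  expect_equal(nrow(find_stem_loops(strrep("A", 200))), 0)
})

test_that("stem-loop finder agrees with the triple-enumeration oracle", {
  for (seed in c(11, 12)) {
    s <- random_dna(600, seed)
    mine <- find_stem_loops(s, min_stem = 5, loop_range = c(3, 20),
                            flank_motifs = FALSE)
    ref <- oracle_stem_loops(s, 5, c(3, 20))
    cols <- c("start0", "end0", "stem", "loop")
    m1 <- mine[do.call(order, mine[cols]), cols]
    m2 <- ref[do.call(order, ref[cols]), cols]
    rownames(m1) <- rownames(m2) <- NULL
    expect_equal(m1, m2, info = paste("seed", seed))
  }
})

test_that("the control-region report recovers all planted elements", {
  out <- generate_genome(generator_config(seed = 47))
  rep <- cr_report(out$genome)
  expect_true(all(rep$present))

  truth <- out$truth$cr$elements
  for (k in seq_len(nrow(truth))) {
    t <- truth[k, ]
    hit <- rep$elements[rep$elements$kind == t$kind &
                          rep$elements$start0 == t$start0 &
                          rep$elements$length == t$length, ]
    expect_equal(nrow(hit), 1, info = paste(t$kind, t$start0))
  }
  # both macro repeats present with their planted copies
  expect_equal(sort(rep$repeats$length), c(36, 72))

  # element output follows genomic position
  expect_true(!is.unsorted(rep$elements$start0))

  # a genome scanned with a stricter stem threshold loses only stem-loops
  rep2 <- cr_report(out$genome, min_stem = 15)
  expect_false(rep2$present[["stem_loop"]])
  expect_true(rep2$present[["polyT"]])
})

test_that("3'-end stem-loop flank motifs are reported per hairpin", {
  stem <- "GGATCCGTAC"
  hp <- paste0("TATAC", stem, "TTCTTC", revcomp(stem), "TGAAAT")
  s <- paste0(strrep("C", 30), hp, strrep("C", 30))
  hits <- find_stem_loops(s, min_stem = 8)
  expect_true(hits$tata_5p[1])
  expect_true(hits$gant_3p[1])
})
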