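toy_arm_map <- function() {
  data.frame(arm = "acceptor", stem_start5 = 1L, stem_end5 = 7L,
             stem_start3 = 11L, stem_end3 = 17L,
             loop_start = 8L, loop_end = 10L)
}

test_that("cloverleaf parsing assigns pairs to arms from the arm map", {
  # 7-pair hairpin with a 3-nt loop
  seqn <- "GGGAAACTTTGTTTCCC"
  struct <- "(((((((...)))))))"
  cl <- parse_cloverleaf(seqn, struct, toy_arm_map(), name = "toy")
  expect_equal(nrow(cl$arms$acceptor$stems), 7)
  expect_true(all(cl$arms$acceptor$stems$paired))

  # all-dot structure: zero paired positions, stems still tracked by map
  cl2 <- parse_cloverleaf(seqn, strrep(".", 17), toy_arm_map())
  expect_false(any(cl2$arms$acceptor$stems$paired))

  # errors: length mismatch and unbalanced brackets
  expect_error(parse_cloverleaf("ACGT", "(((", toy_arm_map()), "length")
  expect_error(parse_cloverleaf("ACGTA", "(((..", toy_arm_map()),
               "unbalanced")
})

test_that("the Ser(AGN) template has an empty DHU stem", {
  cl <- template_cloverleaf("trnS1")
  expect_equal(nrow(cl$arms$DHU$stems), 0)
  expect_equal(nrow(cl$arms$acceptor$stems), 7)
  expect_equal(cl$anticodon, "GCU")
  # all other templates have a 4-pair DHU stem
  cl2 <- template_cloverleaf("trnR")
  expect_equal(nrow(cl2$arms$DHU$stems), 4)
})

test_that("mismatch detection reports exactly the non-canonical stem pairs", {
  # planted U-U in the acceptor stem of tRNA-Arg (reference mismatch)
  g <- generate_genome(generator_config(seed = 41))
  tmpl <- trna_templates()
  i <- match("trnR", tmpl$name)
  seq_r <- extract_region(g$genome, "trnR")
  cl <- parse_cloverleaf(seq_r, tmpl$structure[i], read_arm_map("standard"),
                         name = "trnR")
  mm <- find_mismatches(cl)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$arm, "acceptor")
  expect_equal(mm$position, 2)
  expect_equal(mm$pair, "U-U")

  # an all-Watson-Crick cloverleaf has no mismatches
  expect_equal(nrow(find_mismatches(template_cloverleaf("trnK"))), 0)

  # two U-U pairs in one stem give two records
  seqn <- "GGGUAAACUUUGUUUCCC"
  cl3 <- parse_cloverleaf("GGGTAAACTTTGTTTCCC", strrep(".", 18),
                          data.frame(arm = "TPsiC", stem_start5 = 1L,
                                     stem_end5 = 7L, stem_start3 = 12L,
                                     stem_end3 = 18L, loop_start = 8L,
                                     loop_end = 11L))
  mm3 <- find_mismatches(cl3)
  expect_true(nrow(mm3) >= 2)
  expect_true(all(mm3$arm == "TPsiC"))
})

test_that("the five-pattern classifier reproduces the worked examples", {
  expect_equal(classify_pair_change("GC", "AU"), "cbc")
  expect_equal(classify_pair_change("GU", "AU"), "hemi_cbc")
  expect_equal(classify_pair_change("AA", "AU"), "rbc")
  expect_equal(classify_pair_change("AU", "UA"), "mbc")
  expect_equal(classify_pair_change("UU", "UC"), "nrbc")
  expect_equal(classify_pair_change("GC", "GC"), "identity")
  # T on input is accepted as U
  expect_equal(classify_pair_change("GT", "AT"), "hemi_cbc")
  expect_error(classify_pair_change("GX", "AU"), "base pair")
})

test_that("classification agrees with the oracle, is symmetric, and partitions", {
  bases <- c("A", "C", "G", "U")
  pairs <- as.vector(outer(bases, bases, paste0))
  cats <- c("identity", "cbc", "hemi_cbc", "rbc", "mbc", "nrbc")
  for (a in pairs) for (b in pairs) {
    got <- classify_pair_change(a, b)
    expect_equal(got, oracle_classify(a, b), info = paste(a, b))
    expect_equal(got, classify_pair_change(b, a), info = paste(a, b))
    expect_true(got %in% cats)
  }
})

test_that("pairwise cloverleaf comparison recovers planted changes", {
  pp <- pattern_panel()
  ref <- pp$cloverleaves$taxon1

  # identical cloverleaves: all identity
  self_cmp <- compare_trnas(ref$trnK, ref$trnK)
  expect_true(all(self_cmp$category == "identity"))

  # each plant is recovered at its planted arm/position with its category
  for (k in seq_len(nrow(pp$plants))) {
    p <- pp$plants[k, ]
    other <- pp$cloverleaves[[p$taxon]][[p$trna]]
    cmp <- compare_trnas(ref[[p$trna]], other)
    hit <- cmp[cmp$category != "identity", ]
    expect_equal(nrow(hit), 1, info = paste(p$trna, p$category))
    expect_equal(hit$arm, p$arm)
    expect_equal(hit$position, p$position)
    expect_equal(hit$category, p$category)
  }

  # the aggregated category histogram equals the planted one
  changes <- unlist(lapply(2:5, function(t) {
    per_trna <- lapply(names(ref), function(nm)
      compare_trnas(ref[[nm]], pp$cloverleaves[[t]][[nm]]))
    cat_ <- unlist(lapply(per_trna, `[[`, "category"))
    cat_[cat_ != "identity"]
  }))
  expect_equal(as.list(table(changes)),
               list(cbc = 3L, hemi_cbc = 2L, mbc = 1L, nrbc = 1L, rbc = 1L))

  # comparing different tRNAs is an identity error
  expect_error(compare_trnas(ref$trnK, ref$trnD), "identity mismatch")
})

test_that("unequal stem depths are compared over the shared depth", {
  am5 <- data.frame(arm = "acceptor", stem_start5 = 1L, stem_end5 = 5L,
                    stem_start3 = 9L, stem_end3 = 13L,
                    loop_start = 6L, loop_end = 8L)
  am4 <- data.frame(arm = "acceptor", stem_start5 = 1L, stem_end5 = 4L,
                    stem_start3 = 8L, stem_end3 = 11L,
                    loop_start = 5L, loop_end = 7L)
  a <- parse_cloverleaf("GGGGGAAACCCCC", "(((((...)))))", am5, "t")
  b <- parse_cloverleaf("GGGGAAACCCC", "((((...))))", am4, "t")
  cmp <- compare_trnas(a, b)
  expect_equal(sum(cmp$category == "unaligned"), 1)
  expect_equal(nrow(cmp), 5)
})

test_that("rbc annotation says which taxon holds the canonical state", {
  pp <- pattern_panel()
  p <- pp$plants[pp$plants$category == "rbc", ][1, ]
  cmp <- compare_trnas(pp$cloverleaves$taxon1[[p$trna]],
                       pp$cloverleaves[[p$taxon]][[p$trna]])
  hit <- cmp[cmp$category == "rbc", ]
  expect_equal(hit$canonical_in, "other")  # reference holds A-A, taxon A-U
})
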