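test_that("GenBank round trip preserves the feature table and sequence", {
  g <- generate_genome(generator_config(seed = 11))$genome
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  expect_no_warning(g2 <- read_genbank(path))
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features[, c("name", "type", "strand", "start0", "end0")],
                   g$features[, c("name", "type", "strand", "start0", "end0")])
  expect_equal(nchar(g2$sequence), nchar(g$sequence))
})

test_that("strand census matches the ancestral 23 J / 14 N split", {
  g <- generate_genome(generator_config(seed = 3))$genome
  cen <- strand_census(g)
  expect_equal(cen$J, 23)
  expect_equal(cen$N, 14)
  expect_length(cen$missing, 0)

  # all features flipped to J
  g_allJ <- g
  g_allJ$features$strand <- "J"
  cen2 <- strand_census(g_allJ)
  expect_equal(cen2$J, 37)
  expect_equal(cen2$N, 0)

  # drop three tRNAs: counts sum to 34 and the genes are listed missing
  drop <- c("trnW", "trnC", "trnY")
  g_part <- g
  g_part$features <- g$features[!g$features$name %in% drop, ]
  cen3 <- strand_census(g_part)
  expect_equal(cen3$J + cen3$N, 34)
  expect_setequal(cen3$missing, drop)
})

test_that("gene order signature is rotation-invariant and localizes swaps", {
  g <- generate_genome(generator_config(seed = 5))$genome
  sig <- gene_order_signature(g)
  expect_true(compare_gene_order(sig)$equal)

  # rotate the genome by ~5000 nt at a feature boundary: same signature
  L <- nchar(g$sequence)
  rot <- g$features$start0[which.min(abs(g$features$start0 - 5000L))]
  seq_rot <- paste0(substr(g$sequence, rot + 1, L), substr(g$sequence, 1, rot))
  f <- g$features
  f$start0 <- (f$start0 - rot) %% L
  f$end0 <- ((f$end0 - rot - 1L) %% L) + 1L
  g_rot <- annotated_genome(g$id, seq_rot, f, "circular")
  expect_true(compare_gene_order(gene_order_signature(g_rot))$equal)

  # swap two tRNAs: unequal, divergence at the first swapped slot
  f2 <- g$features
  i <- which(f2$name == "trnW"); j <- which(f2$name == "trnC")
  f2$name[c(i, j)] <- f2$name[c(j, i)]
  f2$strand[c(i, j)] <- f2$strand[c(j, i)]
  g_swap <- annotated_genome(g$id, g$sequence, f2, "circular")
  cmp <- compare_gene_order(gene_order_signature(g_swap))
  expect_false(cmp$equal)
  expect_equal(cmp$first_divergence,
               which(ancestral_gene_order()$name == "trnW"))
})

test_that("duplicated canonical genes are rejected", {
  g <- generate_genome(generator_config(seed = 5))$genome
  f <- g$features
  f <- rbind(f, f[f$name == "trnW", ])
  expect_error(annotated_genome(g$id, g$sequence, f), "duplicated")
})

test_that("extract_region honors strand and origin wrapping", {
  s <- paste0("AAAACGTAAA", strrep("G", 30))
  f_j <- data.frame(name = "x", type = "spacer", strand = "J",
                    start0 = 10L, end0 = 13L)
  g <- annotated_genome("toy", s, f_j)
  expect_equal(extract_region(g, g$features[1, ]), "GGG")

  # N-strand feature over the J-strand "CAT" reads "ATG" in coding orientation
  s2 <- paste0("AACATAA", strrep("T", 20))
  f_n <- data.frame(name = "y", type = "spacer", strand = "N",
                    start0 = 2L, end0 = 5L)
  g2 <- annotated_genome("toy2", s2, f_n)
  expect_equal(extract_region(g2, g2$features[1, ]), "ATG")

  # wrapping span [L-2, L) + [0, 2)
  s3 <- paste0("GT", strrep("A", 20), "AC")
  L <- nchar(s3)
  f_w <- data.frame(name = "z", type = "spacer", strand = "J",
                    start0 = L - 2L, end0 = L, wrap_end0 = 2L)
  g3 <- annotated_genome("toy3", s3, f_w)
  expect_equal(extract_region(g3, g3$features[1, ]), "ACGT")

  # reverse-complementing an N-strand extraction twice is the identity
  x <- extract_region(g2, g2$features[1, ])
  expect_equal(revcomp(revcomp(x)), x)
})

test_that("feature lengths plus intergaps tile a gap-free genome exactly", {
  out <- generate_genome(generator_config(seed = 13))
  g <- out$genome
  f <- g$features[order(g$features$start0), ]
  covered <- sum(f$end0 - f$start0)
  spacer_len <- sum(out$truth$spacers$end0 - out$truth$spacers$start0)
  expect_equal(covered + spacer_len, nchar(g$sequence))
})

test_that("gene names are normalized through the synonym table", {
  expect_equal(normalize_gene_name(c("COX1", "COI", "NAD2", "12S rRNA")),
               c("CO1", "CO1", "ND2", "srRNA"))
  expect_equal(normalize_gene_name("tRNA-Ser(UCN)"), "trnS2")
  expect_warning(out <- normalize_gene_name("mystery9"), "unknown")
  expect_equal(out, "mystery9")
})

test_that("a missing control region is inferred between srRNA and trnI", {
  g <- generate_genome(generator_config(seed = 17))$genome
  f <- g$features[g$features$type != "control_region", ]
  g_nocr <- annotated_genome(g$id, g$sequence, f, "circular")
  g_inf <- infer_control_region(g_nocr)
  cr <- g_inf$features[g_inf$features$type == "control_region", ]
  cr_true <- g$features[g$features$type == "control_region", ]
  expect_equal(cr$start0, cr_true$start0)
  expect_true(cr$inferred)
})

test_that("feature table text round trip preserves coordinates", {
  g <- generate_genome(generator_config(seed = 19))$genome
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(g, path)
  f2 <- read_feature_table(path, nchar(g$sequence))
  expect_equal(f2$start0, g$features$start0)
  expect_equal(f2$end0, g$features$end0)
})
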