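mk_block <- function(gene, type, ncol, taxa = paste0("t", 1:3), frame = 1L,
                     seed = 1L) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), length(taxa) * ncol, TRUE),
              length(taxa), ncol, dimnames = list(taxa, NULL))
  gene_block(gene, type, m, frame = if (type == "PCG") frame else NA_integer_)
}

test_that("concatenation appends columns and records the block map", {
  b1 <- mk_block("g1", "PCG", 6)
  b2 <- mk_block("g2", "PCG", 9, seed = 2)
  cc <- concatenate_blocks(list(b1, b2))
  expect_equal(ncol(cc$matrix), 15)
  expect_equal(cc$column_map$from, c(1, 7))
  expect_equal(cc$column_map$to, c(6, 15))
  # single block: identity
  cc1 <- concatenate_blocks(list(b1))
  expect_identical(cc1$matrix, b1$alignment)
  # taxon order follows the first block
  b3 <- mk_block("g3", "PCG", 6, taxa = c("t3", "t1", "t2"), seed = 3)
  cc2 <- concatenate_blocks(list(b1, b3))
  expect_equal(rownames(cc2$matrix), rownames(b1$alignment))
  # taxon mismatch errors with the offending names
  b4 <- mk_block("g4", "PCG", 6, taxa = c("t1", "t2", "tX"), seed = 4)
  expect_error(concatenate_blocks(list(b1, b4)), "tX")
})

test_that("third-position exclusion removes one column in three", {
  b <- mk_block("g", "PCG", 9)
  b2 <- exclude_third_positions(b)
  expect_equal(ncol(b2$alignment), 6)
  expect_identical(b2$alignment[, 1:2], b$alignment[, 1:2])
  expect_identical(b2$alignment[, 3:4], b$alignment[, 4:5])

  # frame-complete superblock arithmetic: 10,977 -> 7,318
  wide <- mk_block("all", "PCG", 10977, seed = 5)
  expect_equal(ncol(exclude_third_positions(wide)$alignment), 7318)

  # applying it twice removes phase-3 of the renumbered columns
  b3 <- exclude_third_positions(b2)
  expect_equal(ncol(b3$alignment), 4)

  expect_error(exclude_third_positions(mk_block("r", "rRNA", 9)), "PCG")
})

test_that("dataset assembly reproduces the four matrix sizes and partitions", {
  blocks <- supermatrix_blocks(n_taxa = 5, seed = 9)
  sizes <- c(P123 = 10977, P123R = 13903, P12 = 7318, P12R = 10244)
  parts <- c(P123 = 39, P123R = 60, P12 = 26, P12R = 47)
  for (d in names(sizes)) {
    sm <- build_dataset(blocks, d)
    expect_equal(ncol(sm$matrix), unname(sizes[d]), info = d)
    expect_equal(nrow(sm$partitions), unname(parts[d]), info = d)
  }
})

test_that("P12 columns are exactly two thirds of P123 columns", {
  blocks <- supermatrix_blocks(n_taxa = 4, seed = 10)
  p123 <- build_dataset(blocks, "P123")
  p12 <- build_dataset(blocks, "P12")
  p123r <- build_dataset(blocks, "P123R")
  p12r <- build_dataset(blocks, "P12R")
  expect_equal(ncol(p12$matrix), 2 / 3 * ncol(p123$matrix))
  expect_equal(ncol(p12r$matrix),
               ncol(p123r$matrix) - ncol(p123$matrix) / 3)
})

test_that("partitions tile every dataset exactly", {
  blocks <- supermatrix_blocks(n_taxa = 3, seed = 11)
  for (d in c("P123", "P123R", "P12", "P12R")) {
    sm <- build_dataset(blocks, d)
    cols <- unname(unlist(partition_columns(sm)))
    expect_equal(sort(cols), seq_len(ncol(sm$matrix)), info = d)
    expect_false(any(duplicated(cols)), info = d)
  }
})

test_that("missing required blocks are an error", {
  blocks <- supermatrix_blocks(n_taxa = 3, seed = 12)
  no_co1 <- blocks[names(blocks) != "CO1"]
  expect_error(build_dataset(no_co1, "P123"), "CO1")
  no_rrna <- blocks[names(blocks) != "srRNA"]
  expect_error(build_dataset(no_rrna, "P123R"), "srRNA")
  # P123 does not need the rRNA blocks
  expect_no_error(build_dataset(no_rrna, "P123"))
})

test_that("PHYLIP and NEXUS round trips preserve the matrix", {
  blocks <- supermatrix_blocks(n_taxa = 3, seed = 13)
  small <- blocks[c("ATP8", "ND4L", "trnV", "srRNA")]
  small$ATP8$gene <- "ATP8"
  sm <- build_dataset(c(blocks[pcg_names()], blocks[c("lrRNA", "srRNA")],
                        blocks[startsWith(names(blocks), "trn")]), "P12R")
  phy <- withr::local_tempfile(fileext = ".phy")
  write_phylip(sm, phy)
  back <- read_phylip(phy)
  expect_identical(back, sm$matrix)

  # cross-check the writer against an independent PHYLIP reader
  skip_if_not_installed("ape")
  ape_m <- ape::read.dna(phy, format = "sequential", as.character = TRUE)
  expect_identical(toupper(unname(ape_m)), unname(sm$matrix))

  nex <- withr::local_tempfile(fileext = ".nex")
  write_nexus(sm, nex)
  expect_match(readLines(nex), "CHARSET CO1_pos1", all = FALSE)
  nxl <- readLines(nex)
  expect_equal(sum(grepl("CHARSET", nxl)), nrow(sm$partitions))

  rax <- withr::local_tempfile(fileext = ".txt")
  write_raxml_partitions(sm, rax)
  expect_equal(length(readLines(rax)), 47)
})
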