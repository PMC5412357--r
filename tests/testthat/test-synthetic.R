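test_that("the generator is deterministic: same seed, identical bytes", {
  cfg <- generator_config(seed = 77)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$genome$features, b$genome$features)
  expect_identical(a$truth, b$truth)
  pa <- withr::local_tempfile(); pb <- withr::local_tempfile()
  write_genbank(a$genome, pa); write_genbank(b$genome, pb)
  expect_identical(readLines(pa), readLines(pb))

  # different seeds give different sequence
  c <- generate_genome(generator_config(seed = 78))
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("the default configuration realizes the study conditions", {
  out <- generate_genome(generator_config(seed = 83))
  g <- out$genome
  cen <- strand_census(g)
  expect_equal(c(cen$J, cen$N), c(23, 14))
  expect_true(compare_gene_order(gene_order_signature(g))$equal)

  # A+T within one percentage point of the target
  expect_lt(abs(skew(g$sequence)$AT_content - 76.9), 1)

  # a different feasible target is also recovered
  out2 <- generate_genome(generator_config(seed = 83, at_target = 0.74))
  expect_lt(abs(skew(out2$genome$sequence)$AT_content - 74), 1)

  # infeasible targets error before emission
  expect_error(generate_genome(generator_config(seed = 83, at_target = 0.99)),
               "infeasible")
})

test_that("emitted GenBank parses cleanly and matches the truth sidecar", {
  out <- generate_genome(generator_config(seed = 89))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(out$genome, path)
  expect_no_warning(g2 <- read_genbank(path))
  expect_equal(nrow(g2$features), 38)

  # truth coordinates are valid against the emitted genome: every planted
  # spacer sequence is literally at its recorded span
  tr <- out$truth$spacers
  for (i in seq_len(nrow(tr)))
    expect_equal(substr(g2$sequence, tr$start0[i] + 1, tr$end0[i]),
                 tr$planted_seq[i])
})

test_that("every truth-sidecar element is recovered by its detector", {
  out <- generate_genome(generator_config(seed = 97))
  g <- out$genome

  # control-region elements under default thresholds
  rep <- cr_report(g)
  truth <- out$truth$cr$elements
  for (k in seq_len(nrow(truth))) {
    t <- truth[k, ]
    hit <- rep$elements[rep$elements$kind == t$kind &
                          rep$elements$start0 == t$start0 &
                          rep$elements$length == t$length, ]
    expect_equal(nrow(hit), 1, info = paste(t$kind, t$start0))
  }

  # planted tRNA stem mismatches via parse + find_mismatches
  tmpl <- trna_templates()
  for (k in seq_len(nrow(out$truth$trna_mismatches))) {
    t <- out$truth$trna_mismatches[k, ]
    i <- match(t$trna, tmpl$name)
    cl <- parse_cloverleaf(extract_region(g, t$trna), tmpl$structure[i],
                           read_arm_map(tmpl$arm_map[i]), name = t$trna)
    mm <- find_mismatches(cl)
    hit <- mm[mm$arm == t$arm & mm$position == t$position, ]
    expect_equal(hit$pair, paste(t$base5, t$base3, sep = "-"))
  }

  # planted spacers via extract_spacer (J-strand literal)
  spans <- out$truth$spacers
  pairs <- list(c("trnE", "trnF"), c("ND5", "trnH"), c("trnS2", "ND1"))
  names(pairs) <- c("trnE-trnF", "ND5-trnH", "trnS2-ND1")
  for (nm in names(pairs)) {
    sp <- extract_spacer(g, pairs[[nm]][1], pairs[[nm]][2])
    planted <- spans$planted_seq[spans$name == nm]
    recovered <- if (attr(sp, "orientation") == "N") revcomp(sp) else
      as.character(sp)
    expect_equal(recovered, planted, info = nm)
  }
})

test_that("truth sidecar text export is stable and complete", {
  out <- generate_genome(generator_config(seed = 101))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_sidecar(out$truth, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "spacer")), 3)
  expect_equal(sum(startsWith(lines, "cr_element")), 6)
  expect_equal(sum(startsWith(lines, "trna_mismatch")), 2)
})

test_that("panel generation covers motif residue sets and stays deterministic", {
  p1 <- generate_genome_panel(generator_config(seed = 103), n = 5)
  p2 <- generate_genome_panel(generator_config(seed = 103), n = 5)
  expect_identical(lapply(p1$genomes, `[[`, "sequence"),
                   lapply(p2$genomes, `[[`, "sequence"))
  expect_equal(length(unique(vapply(p1$genomes, `[[`, character(1), "id"))), 5)
})
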