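## Seeded synthetic insect mitochondrial genome generator with a
## machine-readable truth sidecar. The generator emulates the study
## conditions: the 37-gene ancestral order (23 J / 14 N), AT-rich composition
## with weak J-strand AT-skew and negative GC-skew, canonical starts and an
## incomplete stop, conserved intergenic spacers realized from their IUPAC
## motifs, template cloverleaf tRNAs with planted stem mismatches, and a
## control region carrying poly-T/(TA)n/poly-A stretches, two non-tandem
## macro repeats and a 3' stem-loop.

## conserved spacer motifs (as printed orientation); flanking pairs refer to
## genomic (J-strand) order
SPACER_MOTIFS <- list(
  list(name = "trnE-trnF", up = "trnE", down = "trnF",
       motif = "ACTWAWWWWAWTTMWHWA", orientation = "J"),
  list(name = "ND5-trnH", up = "ND5", down = "trnH",
       motif = "GTGAAWWWTTTATCM", orientation = "N"),
  list(name = "trnS2-ND1", up = "trnS2", down = "ND1",
       motif = "TATBAAWWWWWWWTAGTA", orientation = "N_motif"))

## macro-repeat units planted into the control region (non-tandem, two
## copies each at the positions used for the truth sidecar)
CR_REPEAT_LONG <- paste0("GTTAAATTCCCCTTAATTTAACAATTAATTTTCTTTTATTTATTGGT",
                         "AAGAAAACTTATCAATTAATCAATT")  # 72 bp
CR_REPEAT_SHORT <- "AATTTATAAAACACTAAATTTATAAATTAAAATTTA"  # 36 bp

default_pcg_codons <- function() c(
  ND2 = 341, CO1 = 513, CO2 = 229, ATP8 = 54, ATP6 = 226, CO3 = 263,
  ND3 = 118, ND5 = 573, ND4 = 447, ND4L = 97, ND6 = 175, CYTB = 379,
  ND1 = 313)

default_start_codons <- function() c(
  ND2 = "ATT", CO1 = "ATG", CO2 = "ATG", ATP8 = "ATT", ATP6 = "ATG",
  CO3 = "ATG", ND3 = "ATT", ND5 = "ATT", ND4 = "ATG", ND4L = "ATG",
  ND6 = "ATT", CYTB = "ATG", ND1 = "ATG")

default_stop_codons <- function() c(
  ND2 = "TAA", CO1 = "T", CO2 = "TAA", ATP8 = "TAA", ATP6 = "TAA",
  CO3 = "TAA", ND3 = "TAG", ND5 = "TAA", ND4 = "TAA", ND4L = "TAA",
  ND6 = "TAA", CYTB = "TAG", ND1 = "TAA")

## reference stem mismatches planted into every emitted genome / reference
## cloverleaf set (arm, 1-based stem position, pair in RNA alphabet)
default_trna_mismatches <- function() data.frame(
  trna = c("trnR", "trnL1"), arm = c("acceptor", "anticodon"),
  position = c(2L, 2L), base5 = c("U", "A"), base3 = c("U", "A"),
  stringsAsFactors = FALSE)

#' Configuration for the synthetic genome generator
#'
#' Defaults reproduce the study conditions: overall A+T 76.9% with AT-skew
#' -0.009 and GC-skew -0.174 on the J-strand; codon-position composition
#' around 68/66/90% A+T at positions 1/2/3; the ancestral 37-gene order; the
#' three conserved spacer motifs; two planted reference stem mismatches; and
#' a 1541 bp control region with the four conserved structural elements and
#' two non-tandem macro repeats (72 and 36 bp).
#'
#' @param seed integer seed; fully determines the output.
#' @param id record label.
#' @param taxon_index index of the emulated taxon in a panel (rotates the
#'   spacer-motif realizations so a panel of genomes covers each motif
#'   column's residue set).
#' @param at_target overall genome A+T fraction.
#' @param at_skew,gc_skew J-strand skew targets for background sampling.
#' @param pos_at,pos_at_skew,pos_gc_skew per-codon-position composition
#'   targets for PCG codon sampling.
#' @param pcg_codons named codon counts per PCG.
#' @param trna_mismatches data.frame of planted stem mismatches
#'   (`trna`, `arm`, `position`, `base5`, `base3`).
#' @param cr_length control-region length (nt).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, id = sprintf("SYN%05d", seed),
                             taxon_index = 1L,
                             at_target = 0.769, at_skew = -0.009,
                             gc_skew = -0.174,
                             pos_at = c(0.678, 0.660, 0.900),
                             pos_at_skew = c(-0.09, -0.395, -0.03),
                             pos_gc_skew = c(0.24, -0.15, -0.12),
                             pcg_codons = default_pcg_codons(),
                             trna_mismatches = default_trna_mismatches(),
                             cr_length = 1541L) {
  stopifnot(at_target > 0, at_target < 1, cr_length >= 900)
  out <- list(seed = as.integer(seed), id = id,
              taxon_index = as.integer(taxon_index),
              at_target = at_target, at_skew = at_skew, gc_skew = gc_skew,
              pos_at = pos_at, pos_at_skew = pos_at_skew,
              pos_gc_skew = pos_gc_skew, pcg_codons = pcg_codons,
              trna_mismatches = trna_mismatches,
              cr_length = as.integer(cr_length))
  class(out) <- "generator_config"
  out
}

## codon sampling probabilities from per-position composition targets.
## Stop codons are excluded, which skews the position marginals of a plain
## product profile; an iterative proportional fit restores the per-position
## base-frequency targets on the stop-free codon set.
codon_profile <- function(cfg) {
  targets <- lapply(1:3, function(p)
    base_freqs(cfg$pos_at[p], cfg$pos_at_skew[p], cfg$pos_gc_skew[p]))
  codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                            DNA_BASES, paste0))
  pos_base <- lapply(1:3, function(p) substr(codons, p, p))
  prob <- vapply(seq_along(codons), function(i)
    targets[[1]][pos_base[[1]][i]] * targets[[2]][pos_base[[2]][i]] *
      targets[[3]][pos_base[[3]][i]], numeric(1))
  names(prob) <- codons
  code <- invertebrate_mito_code()
  prob[code[codons] == "*"] <- 0
  prob <- prob / sum(prob)
  for (iter in 1:50) {
    for (p in 1:3) {
      marg <- as.numeric(tapply(prob, pos_base[[p]], sum)[DNA_BASES])
      scale_ <- setNames(targets[[p]] / pmax(marg, 1e-12), DNA_BASES)
      prob <- prob * as.numeric(scale_[pos_base[[p]]])
      prob <- prob / sum(prob)
    }
  }
  prob
}

sample_pcg <- function(gene, cfg, prob) {
  n_inner <- cfg$pcg_codons[[gene]] - 2L
  codons <- sample(names(prob), n_inner, replace = TRUE, prob = prob)
  paste0(default_start_codons()[[gene]], paste(codons, collapse = ""),
         default_stop_codons()[[gene]])
}

## one realization row of an IUPAC motif: column i of taxon t takes the
## ((t-1) mod k)+1 -th residue of the column's k-residue set, so any panel of
## >= 4 taxa covers every set exactly
motif_realization <- function(motif, taxon_index) {
  sets <- iupac_to_set(seq_chars(motif))
  paste(vapply(sets, function(s) s[((taxon_index - 1L) %% length(s)) + 1L],
               character(1)), collapse = "")
}

#' Realize an IUPAC motif as an n-taxon spacer panel
#'
#' Row t takes, in each column, residue `((t-1) mod k)+1` of the column's
#' k-letter IUPAC set; with `n >= 4` the panel's column residue sets equal the
#' motif's sets exactly, so [iupac_consensus()] regenerates the motif
#' letter for letter.
#'
#' @param motif IUPAC motif string.
#' @param n number of taxa (default 5).
#' @return character matrix (rows `taxon1..n`).
#' @export
motif_panel <- function(motif, n = 5) {
  rows <- vapply(seq_len(n), function(t) motif_realization(motif, t),
                 character(1))
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- paste0("taxon", seq_len(n))
  m
}

## mutate a template tRNA: force (base5, base3) at a stem position; stem
## positions whose pair becomes non-canonical are opened (dots) in the
## dot-bracket string
apply_stem_plants <- function(sequence, structure, arm_map, plants) {
  ch <- seq_chars(sequence)
  st <- seq_chars(structure)
  for (k in seq_len(nrow(plants))) {
    p <- plants[k, ]
    a <- arm_map[arm_map$arm == p$arm, ]
    if (!nrow(a) || is.na(a$stem_start5)) stop("no stem for arm ", p$arm)
    pos5 <- a$stem_start5 + p$position - 1L
    pos3 <- a$stem_end3 - p$position + 1L
    ch[pos5] <- chartr("U", "T", p$base5)
    ch[pos3] <- chartr("U", "T", p$base3)
    if (!is_canonical_pair(pair_string(as_rna(ch[pos5]), as_rna(ch[pos3])))) {
      st[pos5] <- "."
      st[pos3] <- "."
    }
  }
  list(sequence = chars_seq(ch), structure = chars_seq(st))
}

## sample n background bases avoiding homopolymer runs >= 6 and A/T
## alternations >= 6, so planted control-region elements stay uniquely
## detectable at the default thresholds
sample_background <- function(n, prob) {
  out <- character(n)
  for (i in seq_len(n)) {
    p <- prob
    if (i >= 6 && length(unique(out[(i - 5):(i - 1)])) == 1L)
      p[out[i - 1]] <- 0
    if (i >= 6) {
      last5 <- out[(i - 5):(i - 1)]
      if (all(last5 %in% c("A", "T")) &&
          all(last5[-1] != last5[-5]))
        p[setdiff(c("A", "T"), out[i - 1])] <- 0
    }
    out[i] <- sample(DNA_BASES, 1, prob = p / sum(p))
  }
  out
}

## build the control region: background plus planted elements at fixed
## layout positions (1-based within the CR); returns sequence + truth rows
build_control_region <- function(cfg, prob) {
  L <- cfg$cr_length
  ch <- sample_background(L, prob)
  plant <- function(ch, pos1, s) {
    ch[pos1:(pos1 + nchar(s) - 1L)] <- seq_chars(s)
    ch
  }
  ## paired macro-repeat cassettes: [36mer] x [72mer], copies ~385 nt apart
  p36 <- c(162L, 547L); p72 <- c(199L, 584L)
  for (p in p36) ch <- plant(ch, p, CR_REPEAT_SHORT)
  for (p in p72) ch <- plant(ch, p, CR_REPEAT_LONG)
  ## insulate flanks so the planted copies are the maximal repeats
  ch[c(161L, 198L, 271L)] <- "C"
  ch[c(546L, 583L, 656L)] <- "G"
  ## poly-T, (TA)n, poly-A, 3' stem-loop
  polyT_pos <- 780L; polyT_len <- 11L
  ch <- plant(ch, polyT_pos, strrep("T", polyT_len))
  ch[polyT_pos - 1L] <- "A"; ch[polyT_pos + polyT_len] <- "A"
  ta_pos <- 800L; ta_units <- 5L
  ch <- plant(ch, ta_pos, strrep("TA", ta_units))
  ch[ta_pos - 1L] <- "T"; ch[ta_pos + 2L * ta_units] <- "A"
  polyA_pos <- L - 61L; polyA_len <- 16L
  ch <- plant(ch, polyA_pos, strrep("A", polyA_len))
  ch[polyA_pos - 1L] <- "T"; ch[polyA_pos + polyA_len] <- "T"
  stem5 <- "ACGTACGGTC"; loop <- "TTCTTC"
  hairpin <- paste0(stem5, loop, revcomp(stem5))
  sl_pos <- L - 35L
  ch <- plant(ch, sl_pos, hairpin)
  ch[sl_pos - 1L] <- "A"; ch[sl_pos + nchar(hairpin)] <- "A"
  elements <- data.frame(
    kind = c("macro_repeat", "macro_repeat", "polyT", "TA_stretch", "polyA",
             "stem_loop"),
    start0 = c(p72[1] - 1L, p36[1] - 1L, polyT_pos - 1L, ta_pos - 1L,
               polyA_pos - 1L, sl_pos - 1L),
    length = c(72L, 36L, polyT_len, 2L * ta_units, polyA_len,
               nchar(hairpin)),
    detail = c(paste0("copies=", p72[1] - 1L, ",", p72[2] - 1L),
               paste0("copies=", p36[1] - 1L, ",", p36[2] - 1L),
               "", paste0("units=", ta_units), "", "stem=10,loop=6"),
    stringsAsFactors = FALSE)
  list(sequence = chars_seq(ch), elements = elements)
}

#' Generate a synthetic annotated mitochondrial genome with truth sidecar
#'
#' @param cfg a [generator_config()].
#' @return list with `genome` (an [annotated_genome()]) and `truth` (list:
#'   `targets`, `spacers`, `cr` with control-region elements, `trna_mismatches`,
#'   `pcg_codons`).
#' @export
generate_genome <- function(cfg = generator_config()) {
  set.seed(derive_seed(cfg$seed, paste0("genome", cfg$taxon_index)))
  prob_codon <- codon_profile(cfg)
  order_tab <- ancestral_gene_order()
  templates <- trna_templates()
  mism <- cfg$trna_mismatches

  ## gene sequences in coding orientation
  gene_seqs <- list()
  for (nm in order_tab$name[order_tab$type == "PCG"])
    gene_seqs[[nm]] <- sample_pcg(nm, cfg, prob_codon)
  for (nm in order_tab$name[order_tab$type == "tRNA"]) {
    i <- match(nm, templates$name)
    plants <- mism[mism$trna == nm, , drop = FALSE]
    if (nrow(plants)) {
      mut <- apply_stem_plants(templates$sequence[i], templates$structure[i],
                               read_arm_map(templates$arm_map[i]), plants)
      gene_seqs[[nm]] <- mut$sequence
    } else gene_seqs[[nm]] <- templates$sequence[i]
  }

  ## fixed-content length and A+T so far, to tune the background fraction
  spacer_real <- lapply(SPACER_MOTIFS, function(sp) {
    r <- motif_realization(sp$motif, cfg$taxon_index)
    if (sp$orientation %in% c("N", "N_motif")) revcomp(r) else r
  })
  names(spacer_real) <- vapply(SPACER_MOTIFS, `[[`, character(1), "name")
  rrna_len <- c(lrRNA = 1334L, srRNA = 786L)
  fixed <- paste0(paste(unlist(gene_seqs), collapse = ""),
                  paste(unlist(spacer_real), collapse = ""))
  cr_planted_len <- 2L * (72L + 36L) + 11L + 10L + 16L + 26L
  n_fixed_at <- sum(seq_chars(fixed) %in% c("A", "T")) +
    round(0.9 * cr_planted_len)   # planted CR elements are ~90% A+T
  total_len <- nchar(fixed) + sum(rrna_len) + cfg$cr_length
  n_tunable <- sum(rrna_len) + cfg$cr_length - cr_planted_len
  at_bg <- (cfg$at_target * total_len - n_fixed_at) / n_tunable
  if (at_bg < 0.05 || at_bg > 0.99)
    stop("infeasible A+T target ", cfg$at_target,
         ": background fraction would be ", round(at_bg, 3))
  prob_bg <- base_freqs(at_bg, cfg$at_skew, cfg$gc_skew)

  for (nm in names(rrna_len))
    gene_seqs[[nm]] <- chars_seq(sample_bases(rrna_len[[nm]], prob_bg))
  cr <- build_control_region(cfg, prob_bg)
  gene_seqs[["CR"]] <- cr$sequence

  ## assemble the J-strand in ancestral order, spacers between their flanks
  spacer_after <- setNames(
    vapply(SPACER_MOTIFS, `[[`, character(1), "name"),
    vapply(SPACER_MOTIFS, `[[`, character(1), "up"))
  seq_parts <- character(0)
  feat <- list(); spac <- list()
  pos <- 0L
  for (k in seq_len(nrow(order_tab))) {
    nm <- order_tab$name[k]
    strand <- order_tab$strand[k]
    coding <- gene_seqs[[nm]]
    dna <- if (strand == "N") revcomp(coding) else coding
    feat[[nm]] <- data.frame(
      name = nm, type = order_tab$type[k], strand = strand,
      start0 = pos, end0 = pos + nchar(dna), wrap_end0 = NA_integer_,
      anticodon = if (order_tab$type[k] == "tRNA")
        templates$anticodon[match(nm, templates$name)] else NA_character_,
      inferred = FALSE, stringsAsFactors = FALSE)
    seq_parts <- c(seq_parts, dna)
    pos <- pos + nchar(dna)
    if (nm %in% names(spacer_after)) {
      sp_name <- spacer_after[[nm]]
      s <- spacer_real[[sp_name]]
      spac[[sp_name]] <- data.frame(
        name = sp_name, start0 = pos, end0 = pos + nchar(s),
        planted_seq = s, stringsAsFactors = FALSE)
      seq_parts <- c(seq_parts, s)
      pos <- pos + nchar(s)
    }
  }
  sequence <- paste(seq_parts, collapse = "")
  features <- do.call(rbind, feat)
  genome <- annotated_genome(cfg$id, sequence, features, "circular")

  cr_start0 <- features$start0[features$name == "CR"]
  truth <- list(
    targets = list(at = cfg$at_target, at_skew = cfg$at_skew,
                   gc_skew = cfg$gc_skew, pos_at = cfg$pos_at),
    spacers = do.call(rbind, spac),
    cr = list(start0 = cr_start0,
              elements = transform(cr$elements,
                                   genome_start0 = start0 + cr_start0)),
    trna_mismatches = mism,
    pcg_codons = cfg$pcg_codons)
  list(genome = genome, truth = truth)
}

#' Generate a panel of synthetic genomes
#'
#' Taxon indices rotate the spacer-motif realizations so that the panel's
#' spacer columns jointly cover each motif position's IUPAC residue set.
#'
#' @param cfg a [generator_config()]; `cfg$seed` seeds the whole panel.
#' @param n number of genomes (default 5).
#' @return list with `genomes` (list of [annotated_genome()]) and `truths`.
#' @export
generate_genome_panel <- function(cfg = generator_config(), n = 5) {
  out <- lapply(seq_len(n), function(t) {
    cfg_t <- cfg
    cfg_t$taxon_index <- t
    cfg_t$id <- sprintf("%s_T%d", cfg$id, t)
    generate_genome(cfg_t)
  })
  list(genomes = lapply(out, `[[`, "genome"),
       truths = lapply(out, `[[`, "truth"))
}

#' Write a truth sidecar as tab-separated text
#' @param truth the `truth` element of [generate_genome()].
#' @param path output path.
#' @export
write_truth_sidecar <- function(truth, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# synthetic-genome truth sidecar", con)
  writeLines(sprintf("target\t%s\t%s",
                     c("at", "at_skew", "gc_skew"),
                     c(truth$targets$at, truth$targets$at_skew,
                       truth$targets$gc_skew)), con)
  sp <- truth$spacers
  writeLines(sprintf("spacer\t%s\t%d\t%d\t%s", sp$name, sp$start0, sp$end0,
                     sp$planted_seq), con)
  e <- truth$cr$elements
  writeLines(sprintf("cr_element\t%s\t%d\t%d\t%s", e$kind, e$genome_start0,
                     e$length, e$detail), con)
  m <- truth$trna_mismatches
  writeLines(sprintf("trna_mismatch\t%s\t%s\t%d\t%s-%s", m$trna, m$arm,
                     m$position, m$base5, m$base3), con)
  invisible(path)
}
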