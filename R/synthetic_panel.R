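## Seeded generators for alignment panels with exact planted properties:
## per-gene %INUC (identical-column counts planted exactly), %INUC ~ A+T
## panels with an imposed sample correlation, cloverleaf panels with planted
## stem-change categories, and supermatrix block sets whose widths reproduce
## realistic post-filtering gene lengths.

#' Build an alignment with an exact number of identical columns
#'
#' Exactly `n_identical` columns carry the same residue in all rows; every
#' other column is forced variable (two distinct residues at least). Residues
#' are drawn from an A+T-biased background.
#'
#' @param n_rows,n_cols alignment dimensions.
#' @param n_identical planted identical-column count.
#' @param at_target background A+T fraction (default 0.78).
#' @param seed integer seed.
#' @param taxa row names (default `taxon1..n`).
#' @return character matrix.
#' @export
planted_alignment <- function(n_rows, n_cols, n_identical, at_target = 0.78,
                              seed = 1L, taxa = paste0("taxon", seq_len(n_rows))) {
  if (n_identical > n_cols) stop("identical-column target exceeds length")
  if (n_rows < 2) stop("need >= 2 rows")
  set.seed(derive_seed(seed, paste("aln", n_rows, n_cols, n_identical)))
  prob <- base_freqs(at_target)
  m <- matrix("", n_rows, n_cols, dimnames = list(taxa, NULL))
  ident_cols <- sort(sample.int(n_cols, n_identical))
  for (j in seq_len(n_cols)) {
    if (j %in% ident_cols) {
      m[, j] <- sample_bases(1, prob)
    } else {
      col <- sample_bases(n_rows, prob)
      if (length(unique(col)) == 1L) {
        alt <- setdiff(DNA_BASES, col[1])
        col[sample.int(n_rows, 1)] <- sample(alt, 1)
      }
      m[, j] <- col
    }
  }
  m
}

#' Generate alignment profiles with an imposed %INUC ~ A+T correlation
#'
#' Target (%INUC, A+T) pairs are constructed with a sample Pearson
#' correlation of exactly `r` (Gram-Schmidt construction on a deterministic
#' base vector plus seeded noise), then realized as alignments via
#' [planted_alignment()]; realized values differ from the targets only by
#' column quantization and residue-sampling noise.
#'
#' @param n_genes number of profiles (default 22, one per tRNA).
#' @param r imposed correlation (default 0.2).
#' @param n_rows,n_cols alignment dimensions per gene.
#' @param inuc_mean,inuc_sd,at_mean,at_sd target moments (percent).
#' @param seed integer seed.
#' @return list with `profiles` (list of `alignment_profile`) and `targets`
#'   (data.frame `gene`, `inuc`, `at`).
#' @export
correlated_profiles <- function(n_genes = 22, r = 0.2, n_rows = 5,
                                n_cols = 1000, inuc_mean = 55, inuc_sd = 10,
                                at_mean = 78, at_sd = 5, seed = 1L) {
  set.seed(derive_seed(seed, "corr"))
  x <- scale(seq_len(n_genes))[, 1]
  z <- stats::rnorm(n_genes)
  z <- stats::residuals(stats::lm(z ~ x))
  z <- z / stats::sd(z) * sqrt((n_genes - 1) / n_genes)
  z <- scale(z)[, 1]
  y <- r * x + sqrt(1 - r^2) * z
  inuc <- pmin(95, pmax(20, inuc_mean + inuc_sd * x))
  at <- pmin(95, pmax(55, at_mean + at_sd * y))
  genes <- paste0("gene", seq_len(n_genes))
  profiles <- lapply(seq_len(n_genes), function(i) {
    m <- planted_alignment(n_rows, n_cols, round(inuc[i] / 100 * n_cols),
                           at_target = at[i] / 100,
                           seed = derive_seed(seed, paste0("gene", i)))
    profile_alignment(m, gene = genes[i])
  })
  list(profiles = profiles,
       targets = data.frame(gene = genes, inuc = inuc, at = at))
}

#' Generate grouped alignment panels with planted per-group mean %INUC
#'
#' Each group's gene alignments realize %INUC values placed symmetrically
#' around the planted group mean, so the recovered group mean equals the
#' planted one exactly (up to column quantization, which the defaults avoid).
#'
#' @param group_means named numeric vector of planted mean %INUC per group.
#' @param genes_per_group alignments per group (even numbers keep the mean
#'   exact with the symmetric offsets).
#' @param n_rows,n_cols alignment dimensions (with `n_cols = 100` any
#'   integer %INUC is exactly realizable).
#' @param spread half-range of the symmetric offsets (percent).
#' @param seed integer seed.
#' @return list with `profiles`, `grouping` (taxon -> group) and `planted`
#'   (the input means).
#' @export
grouped_profiles <- function(group_means = c(A = 80, B = 60, C = 70),
                             genes_per_group = 4, n_rows = 3, n_cols = 100,
                             spread = 5, seed = 1L) {
  offsets <- seq(-spread, spread, length.out = genes_per_group)
  profiles <- list(); grouping <- character(0)
  for (g in names(group_means)) {
    taxa <- paste0(g, "_taxon", seq_len(n_rows))
    grouping[taxa] <- g
    for (k in seq_len(genes_per_group)) {
      inuc <- group_means[[g]] + offsets[k]
      m <- planted_alignment(n_rows, n_cols, round(inuc / 100 * n_cols),
                             seed = derive_seed(seed, paste(g, k)),
                             taxa = taxa)
      profiles[[paste0(g, "_gene", k)]] <-
        profile_alignment(m, gene = paste0(g, "_gene", k))
    }
  }
  list(profiles = profiles, grouping = grouping, planted = group_means)
}

## ---- cloverleaf pattern panels -------------------------------------------

## replacement pair of the requested category relative to a reference pair
pair_for_category <- function(ref_pair, category) {
  canonical <- is_canonical_pair(ref_pair)
  b1 <- substr(ref_pair, 1, 1); b2 <- substr(ref_pair, 2, 2)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  out <- switch(category,
    cbc = if (canonical)
      c(AU = "GC", UA = "CG", GC = "AU", CG = "UA", GU = "UA",
        UG = "AU")[[ref_pair]]
      else stop("cbc needs a canonical reference pair"),
    hemi_cbc = if (canonical)
      c(AU = "GU", UA = "UG", GC = "GU", CG = "UG", GU = "AU",
        UG = "UA")[[ref_pair]]
      else stop("hemi_cbc needs a canonical reference pair"),
    mbc = if (canonical) paste0(b2, b1)
      else stop("mbc needs a canonical reference pair"),
    rbc = if (canonical) paste0(b1, b1)       # break the pair
      else paste0(b1, comp[[b1]]),            # or repair it
    nrbc = if (!canonical)
      paste0(b1, setdiff(c("A", "C", "G", "U"),
                         c(b2, comp[[b1]], if (b1 %in% c("G", "U"))
                           c(G = "U", U = "G")[[b1]]))[1])
      else stop("nrbc needs a non-canonical reference pair"),
    stop("unknown category ", category))
  stopifnot(classify_pair_change(ref_pair, out) == category)
  out
}

default_pattern_plants <- function() data.frame(
  taxon = c(2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L),
  trna = c("trnK", "trnD", "trnW", "trnL1", "trnS1", "trnE", "trnR", "trnV"),
  arm = c("acceptor", "TPsiC", "anticodon", "anticodon", "acceptor", "DHU",
          "acceptor", "TPsiC"),
  position = c(3L, 2L, 2L, 2L, 1L, 2L, 2L, 3L),
  category = c("cbc", "hemi_cbc", "cbc", "rbc", "mbc", "cbc", "nrbc",
               "hemi_cbc"),
  stringsAsFactors = FALSE)

#' Generate a cloverleaf panel with planted stem-change categories
#'
#' Taxon 1 is the reference: the packaged templates carrying the configured
#' reference mismatches (by default a U-U acceptor pair in tRNA-Arg and an
#' A-A anticodon pair in tRNA-Leu(CUN)). Every other taxon starts from the
#' reference and receives its planted stem changes, each of a requested
#' category, verified at construction time.
#'
#' @param plants data.frame (`taxon`, `trna`, `arm`, `position`, `category`);
#'   the default plants the category histogram cbc 3, hemi_cbc 2, rbc 1,
#'   mbc 1, nrbc 1 across taxa 2-5.
#' @param n_taxa panel size (default 5).
#' @param ref_mismatches reference stem mismatches (see
#'   [generator_config()]).
#' @return list with `cloverleaves` (list taxon -> tRNA -> `cloverleaf`),
#'   `plants` (truth, with realized pairs) and `ref_mismatches`.
#' @export
pattern_panel <- function(plants = default_pattern_plants(), n_taxa = 5,
                          ref_mismatches = default_trna_mismatches()) {
  templates <- trna_templates()
  base <- list()  # per-tRNA sequence/structure of the reference
  for (i in seq_len(nrow(templates))) {
    nm <- templates$name[i]
    pl <- ref_mismatches[ref_mismatches$trna == nm, , drop = FALSE]
    rec <- list(sequence = templates$sequence[i],
                structure = templates$structure[i],
                arm_map = read_arm_map(templates$arm_map[i]))
    if (nrow(pl)) {
      mut <- apply_stem_plants(rec$sequence, rec$structure, rec$arm_map, pl)
      rec$sequence <- mut$sequence; rec$structure <- mut$structure
    }
    base[[nm]] <- rec
  }
  truth <- plants
  truth$pair_ref <- truth$pair_new <- NA_character_
  taxa <- lapply(seq_len(n_taxa), function(t) base)
  for (k in seq_len(nrow(plants))) {
    p <- plants[k, ]
    rec <- taxa[[p$taxon]][[p$trna]]
    a <- rec$arm_map[rec$arm_map$arm == p$arm, ]
    pos5 <- a$stem_start5 + p$position - 1L
    pos3 <- a$stem_end3 - p$position + 1L
    ref_pair <- as_rna(paste0(substr(rec$sequence, pos5, pos5),
                              substr(rec$sequence, pos3, pos3)))
    new_pair <- pair_for_category(ref_pair, p$category)
    mut <- apply_stem_plants(rec$sequence, rec$structure, rec$arm_map,
                             data.frame(trna = p$trna, arm = p$arm,
                                        position = p$position,
                                        base5 = substr(new_pair, 1, 1),
                                        base3 = substr(new_pair, 2, 2)))
    taxa[[p$taxon]][[p$trna]] <- modifyList(rec, mut)
    truth$pair_ref[k] <- ref_pair
    truth$pair_new[k] <- new_pair
  }
  cloverleaves <- lapply(seq_len(n_taxa), function(t)
    lapply(names(base), function(nm)
      parse_cloverleaf(taxa[[t]][[nm]]$sequence, taxa[[t]][[nm]]$structure,
                       taxa[[t]][[nm]]$arm_map, name = nm)))
  for (t in seq_len(n_taxa)) names(cloverleaves[[t]]) <- names(base)
  names(cloverleaves) <- paste0("taxon", seq_len(n_taxa))
  list(cloverleaves = cloverleaves, plants = truth,
       ref_mismatches = ref_mismatches)
}

## ---- supermatrix block panels --------------------------------------------

## post-filtering alignment widths (in codons for PCGs, columns for RNAs)
## calibrated to the concatenated matrix sizes analyzed in the study
supermatrix_widths <- function() {
  list(pcg_codons = c(ND2 = 341, CO1 = 496, CO2 = 227, ATP8 = 53,
                      ATP6 = 224, CO3 = 262, ND3 = 117, ND5 = 545,
                      ND4 = 434, ND4L = 96, ND6 = 174, CYTB = 378,
                      ND1 = 312),
       rrna = c(lrRNA = 1350, srRNA = 795),
       trna = c(trnI = 41, trnQ = 41, trnM = 41, trnW = 41, trnC = 41,
                trnY = 41, trnL2 = 42, trnK = 41, trnD = 41, trnG = 41,
                trnA = 41, trnR = 41, trnN = 41, trnS1 = 41, trnE = 41,
                trnF = 41, trnH = 41, trnT = 41, trnP = 41, trnS2 = 41,
                trnL1 = 42, trnV = 41))
}

#' Generate aligned gene blocks for supermatrix assembly
#'
#' Gap-free, frame-complete blocks for 13 PCGs, 2 rRNAs and 22 tRNAs over a
#' synthetic taxon panel. Default widths are the package's post-filtering
#' gene lengths, under which the four datasets have 10,977 (P123), 13,903
#' (P123R), 7,318 (P12) and 10,244 (P12R) columns with the default tRNA
#' exclusions.
#'
#' @param n_taxa panel size (default 5).
#' @param seed integer seed.
#' @param widths width table as from [supermatrix_widths()].
#' @return list of [gene_block()]s.
#' @export
supermatrix_blocks <- function(n_taxa = 5, seed = 1L,
                               widths = supermatrix_widths()) {
  set.seed(derive_seed(seed, "blocks"))
  taxa <- paste0("taxon", seq_len(n_taxa))
  prob <- base_freqs(0.77)
  mk <- function(ncol) {
    m <- matrix(sample_bases(n_taxa * ncol, prob), n_taxa, ncol)
    rownames(m) <- taxa
    m
  }
  blocks <- list()
  for (g in names(widths$pcg_codons))
    blocks[[g]] <- gene_block(g, "PCG", mk(3L * widths$pcg_codons[[g]]),
                              frame = 1L)
  for (g in names(widths$rrna))
    blocks[[g]] <- gene_block(g, "rRNA", mk(widths$rrna[[g]]))
  for (g in names(widths$trna))
    blocks[[g]] <- gene_block(g, "tRNA", mk(widths$trna[[g]]))
  blocks
}
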