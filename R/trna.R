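## tRNA cloverleaf structure: arm-decomposed stems, mismatch detection and
## the five-way classification of stem base-pair substitutions between
## homologous tRNAs (compensatory, hemi-compensatory, reparative, mirrored,
## non-reparative). Sequences are handled in the RNA alphabet; T on input is
## mapped to U. G-U counts as a canonical pair throughout.

CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

as_rna <- function(s) chartr("Tt", "Uu", toupper(s))

## pairs from a dot-bracket string, via a stack; errors on imbalance
dotbracket_pairs <- function(structure) {
  ch <- seq_chars(structure)
  if (any(!ch %in% c("(", ")", ".")))
    stop("structure contains characters other than '(', ')', '.'")
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets at position ", i)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced brackets: ", length(stack), " unclosed")
  pairs
}

#' Read an arm-boundary table
#'
#' Tab-separated columns: `arm`, `stem_start5`, `stem_end5`, `stem_start3`,
#' `stem_end3`, `loop_start`, `loop_end` (1-based inclusive; `NA` stem
#' columns denote an armless/loop-only entry, e.g. the missing DHU arm of
#' tRNA-Ser(AGN)).
#'
#' @param path file path, or one of the packaged layouts `"standard"` /
#'   `"noDHU"`.
#' @return data.frame.
#' @export
read_arm_map <- function(path) {
  if (path %in% c("standard", "noDHU"))
    path <- mc_extdata(paste0("trna_arm_map_", path, ".tsv"))
  read.delim(path, stringsAsFactors = FALSE)
}

#' Parse a tRNA into an arm-decomposed cloverleaf
#'
#' Stems are taken from the arm map's expected extents: the k-th pair of an
#' arm joins `stem_start5 + k - 1` with `stem_end3 - k + 1`. The dot-bracket
#' string (same length as the sequence, balanced) marks which of those
#' positions are actually paired; expected stem positions that are unpaired in
#' the structure are retained as mismatch candidates.
#'
#' @param sequence tRNA sequence (T accepted, mapped to U).
#' @param structure dot-bracket string.
#' @param arm_map arm-boundary data.frame (see [read_arm_map()]).
#' @param name tRNA identity label (e.g. `"trnR"`).
#' @return object of class `cloverleaf`: `name`, `sequence` (RNA), `arms`
#'   (per arm: `stems` data.frame with `pos5`, `pos3`, `base5`, `base3`,
#'   `paired`; `loop` index range), `extra_arm`, `anticodon`.
#' @export
parse_cloverleaf <- function(sequence, structure, arm_map, name = "tRNA") {
  rna <- as_rna(sequence)
  if (nchar(rna) != nchar(structure))
    stop("sequence and structure lengths differ (", nchar(rna), " vs ",
         nchar(structure), ")")
  pairs <- dotbracket_pairs(structure)
  paired_key <- paste(pairs[, 1], pairs[, 2])
  ch <- seq_chars(rna)
  arms <- list()
  for (k in seq_len(nrow(arm_map))) {
    a <- arm_map[k, ]
    if (!is.na(a$stem_start5)) {
      depth <- a$stem_end5 - a$stem_start5 + 1L
      pos5 <- a$stem_start5 + seq_len(depth) - 1L
      pos3 <- a$stem_end3 - seq_len(depth) + 1L
      stems <- data.frame(pos5 = pos5, pos3 = pos3,
                          base5 = ch[pos5], base3 = ch[pos3],
                          paired = paste(pos5, pos3) %in% paired_key)
    } else {
      stems <- data.frame(pos5 = integer(0), pos3 = integer(0),
                          base5 = character(0), base3 = character(0),
                          paired = logical(0))
    }
    loop <- if (!is.na(a$loop_start)) c(a$loop_start, a$loop_end) else NULL
    arms[[a$arm]] <- list(stems = stems, loop = loop)
  }
  anticodon <- NA_character_
  ac_arm <- arms[["anticodon"]]
  if (!is.null(ac_arm$loop)) {
    mid <- (ac_arm$loop[1] + ac_arm$loop[2]) %/% 2
    anticodon <- chars_seq(ch[(mid - 1):(mid + 1)])
  }
  extra <- arms[["extra"]]
  arms[["extra"]] <- NULL
  out <- list(name = name, sequence = rna, arms = arms,
              extra_arm = extra$loop, anticodon = anticodon)
  class(out) <- "cloverleaf"
  out
}

#' @export
print.cloverleaf <- function(x, ...) {
  depths <- vapply(x$arms, function(a) nrow(a$stems), integer(1))
  cat(sprintf("<cloverleaf> %s (%d nt; stems: %s; anticodon %s)\n",
              x$name, nchar(x$sequence),
              paste(names(depths), depths, sep = "=", collapse = ", "),
              x$anticodon))
  invisible(x)
}

pair_string <- function(b5, b3) paste0(b5, b3)

is_canonical_pair <- function(p) p %in% CANONICAL_PAIRS

#' Find non-canonical (mismatched) stem pairs in a cloverleaf
#'
#' Every stem position whose base pair is outside the canonical set
#' {A-U, U-A, G-C, C-G, G-U, U-G} is reported.
#'
#' @param cl a [parse_cloverleaf()] object.
#' @return data.frame with columns `arm`, `position` (1-based from the stem's
#'   5' end), `pair` (e.g. `"U-U"`).
#' @export
find_mismatches <- function(cl) {
  rows <- lapply(names(cl$arms), function(arm) {
    st <- cl$arms[[arm]]$stems
    if (!nrow(st)) return(NULL)
    bad <- which(!is_canonical_pair(pair_string(st$base5, st$base3)))
    if (!length(bad)) return(NULL)
    data.frame(arm = arm, position = bad,
               pair = paste(st$base5[bad], st$base3[bad], sep = "-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(arm = character(0), position = integer(0),
                      pair = character(0))
  out
}

#' Classify the change between two homologous stem base pairs
#'
#' The comparison is undirected. With the canonical pair set
#' {A-U, U-A, G-C, C-G, G-U, U-G}:
#' equal pairs are `identity`; two canonical pairs differing in one base are a
#' hemi-compensatory change (`hemi_cbc`); two canonical pairs differing in
#' both bases are `mbc` when one is the reversal of the other (the mirror test
#' precedes the compensatory one) and `cbc` otherwise; a canonical paired with
#' a non-canonical pair (either direction) is reparative (`rbc`); two
#' non-canonical pairs are non-reparative (`nrbc`).
#'
#' @param pair_a,pair_b base pairs as 2-character strings (`"GC"`) or
#'   2-vectors; T is accepted and mapped to U.
#' @return one of `"identity"`, `"cbc"`, `"hemi_cbc"`, `"rbc"`, `"mbc"`,
#'   `"nrbc"`.
#' @export
classify_pair_change <- function(pair_a, pair_b) {
  norm <- function(p) {
    if (length(p) == 2) p <- paste0(p[1], p[2])
    p <- as_rna(p)
    if (nchar(p) != 2 || grepl("[^ACGU]", p))
      stop("not a nucleotide base pair: ", p)
    p
  }
  a <- norm(pair_a); b <- norm(pair_b)
  if (a == b) return("identity")
  can_a <- is_canonical_pair(a); can_b <- is_canonical_pair(b)
  if (can_a && can_b) {
    ndiff <- (substr(a, 1, 1) != substr(b, 1, 1)) +
      (substr(a, 2, 2) != substr(b, 2, 2))
    if (ndiff == 1) return("hemi_cbc")
    if (b == paste0(substr(a, 2, 2), substr(a, 1, 1))) return("mbc")
    return("cbc")
  }
  if (can_a || can_b) return("rbc")
  "nrbc"
}

#' Compare two cloverleaves of the same tRNA position by position
#'
#' Stems are compared index-by-index from each stem's 5' end over the shared
#' depth; surplus positions of a deeper stem are reported with category
#' `"unaligned"`. For reparative changes the taxon holding the canonical
#' state is annotated.
#'
#' @param ref,other [parse_cloverleaf()] objects with the same `name`.
#' @return data.frame of class `stem_change_table`: `arm`, `position`,
#'   `pair_ref`, `pair_other`, `category`, `canonical_in`.
#' @export
compare_trnas <- function(ref, other) {
  if (!identical(ref$name, other$name))
    stop("tRNA identity mismatch: ", ref$name, " vs ", other$name)
  rows <- lapply(names(ref$arms), function(arm) {
    sr <- ref$arms[[arm]]$stems
    so <- other$arms[[arm]]$stems
    depth <- min(nrow(sr), nrow(so))
    shared <- if (depth > 0) {
      pa <- pair_string(sr$base5[1:depth], sr$base3[1:depth])
      pb <- pair_string(so$base5[1:depth], so$base3[1:depth])
      cat_ <- mapply(classify_pair_change, pa, pb)
      can <- ifelse(cat_ != "rbc", NA_character_,
                    ifelse(is_canonical_pair(pa), "ref", "other"))
      data.frame(arm = arm, position = seq_len(depth),
                 pair_ref = paste(substr(pa, 1, 1), substr(pa, 2, 2), sep = "-"),
                 pair_other = paste(substr(pb, 1, 1), substr(pb, 2, 2), sep = "-"),
                 category = unname(cat_), canonical_in = can,
                 stringsAsFactors = FALSE)
    } else NULL
    extra_n <- max(nrow(sr), nrow(so)) - depth
    surplus <- if (extra_n > 0) {
      deeper <- if (nrow(sr) > nrow(so)) sr else so
      who <- if (nrow(sr) > nrow(so)) "ref" else "other"
      idx <- (depth + 1):(depth + extra_n)
      data.frame(arm = arm, position = idx,
                 pair_ref = if (who == "ref")
                   paste(deeper$base5[idx], deeper$base3[idx], sep = "-") else NA,
                 pair_other = if (who == "other")
                   paste(deeper$base5[idx], deeper$base3[idx], sep = "-") else NA,
                 category = "unaligned", canonical_in = NA_character_,
                 stringsAsFactors = FALSE)
    } else NULL
    rbind(shared, surplus)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stem_change_table", "data.frame")
  out
}

#' Load the packaged cloverleaf templates
#'
#' 22 template cloverleaves in the standard insect mitochondrial layout
#' (tRNA-Ser(AGN) lacks the DHU stem), used by the synthetic-genome generator
#' and as comparison references.
#'
#' @return data.frame with columns `name`, `anticodon`, `arm_map`, `length`,
#'   `sequence`, `structure`.
#' @export
trna_templates <- function() {
  read.delim(mc_extdata("trna_templates.tsv"), stringsAsFactors = FALSE)
}

#' Parse one packaged template into a cloverleaf
#' @param name canonical tRNA name (e.g. `"trnS1"`).
#' @return a `cloverleaf`.
#' @export
template_cloverleaf <- function(name) {
  tab <- trna_templates()
  i <- match(name, tab$name)
  if (is.na(i)) stop("no template for ", name)
  parse_cloverleaf(tab$sequence[i], tab$structure[i],
                   read_arm_map(tab$arm_map[i]), name = name)
}

#' Write a stem-change table as TSV
#' @param x `stem_change_table` (with optional `taxon`/`tRNA` columns added).
#' @param path output path.
#' @export
write_stem_changes <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
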