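#' @importFrom stats cor runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' Vectorised over its input. IUPAC ambiguity codes are complemented as well;
#' gaps (`-`) are preserved.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## split a sequence string into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## paste a character vector of bases back into one string
chars_seq <- function(ch) paste(ch, collapse = "")

## map between IUPAC codes and sorted residue-set strings ("AT" -> "W", ...)
iupac_from_set <- local({
  map <- NULL
  function(set_string) {
    if (is.null(map)) {
      cm <- Biostrings::IUPAC_CODE_MAP
      map <<- setNames(names(cm), vapply(strsplit(cm, ""), function(x)
        paste(sort(x), collapse = ""), character(1)))
    }
    unname(map[set_string])
  }
})

iupac_to_set <- function(code) {
  sets <- Biostrings::IUPAC_CODE_MAP[toupper(code)]
  if (anyNA(sets)) stop("unknown IUPAC code: ",
                        paste(code[is.na(sets)], collapse = ", "))
  strsplit(unname(sets), "", fixed = TRUE)
}

## derive a substream seed (< 2^31) from a master seed and a stream label
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 65537L)
}

## sample bases with given per-base probabilities
sample_bases <- function(n, prob) {
  stopifnot(length(prob) == 4L, abs(sum(prob) - 1) < 1e-8)
  sample(DNA_BASES, n, replace = TRUE, prob = prob)
}

## base frequencies from AT fraction and the two skews:
## A - T = at_skew * (A + T), G - C = gc_skew * (G + C)
base_freqs <- function(at, at_skew = 0, gc_skew = 0) {
  gc <- 1 - at
  c(A = at * (1 + at_skew) / 2, C = gc * (1 - gc_skew) / 2,
    G = gc * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
}

## path to a packaged data file
mc_extdata <- function(file) {
  p <- system.file("extdata", file, package = "mitocomp")
  if (!nzchar(p)) stop("packaged data file not found: ", file)
  p
}

#' Ancestral insect mitochondrial gene order
#'
#' The inferred ancestral 37-gene order (23 J-strand, 14 N-strand genes) plus
#' the control region, as a data frame in genomic order starting at tRNA-Ile.
#'
#' @return data.frame with columns `position`, `name`, `strand`, `type`.
#' @export
ancestral_gene_order <- function() {
  read.delim(mc_extdata("ancestral_gene_order.tsv"), stringsAsFactors = FALSE)
}

#' Gene-name synonym table
#'
#' Packaged, editable mapping from deposited gene labels to the canonical
#' symbols used throughout the package (13 PCGs, 22 tRNAs with Leu/Ser
#' isoacceptor suffixes, 2 rRNAs, control region).
#'
#' @return data.frame with columns `synonym`, `canonical`.
#' @export
gene_synonyms <- function() {
  read.delim(mc_extdata("gene_synonyms.tsv"), stringsAsFactors = FALSE)
}

#' Normalize a gene name to its canonical symbol
#'
#' Matching is case-insensitive and ignores spaces and underscores. Unknown
#' names are returned unchanged with a warning (the caller keeps the feature).
#'
#' @param name character vector of raw gene labels.
#' @param warn warn on unknown names?
#' @return character vector of canonical symbols (or the raw name if unknown).
#' @export
normalize_gene_name <- function(name, warn = TRUE) {
  syn <- gene_synonyms()
  key <- toupper(gsub("[ _]", "", name))
  hit <- syn$canonical[match(key, syn$synonym)]
  unknown <- is.na(hit)
  if (any(unknown) && warn)
    warning("unknown gene name(s) kept as-is: ",
            paste(unique(name[unknown]), collapse = ", "))
  hit[unknown] <- name[unknown]
  hit
}

#' Canonical mitochondrial gene name sets
#'
#' The 13 protein-coding genes, 22 tRNAs, 2 rRNAs, and the full canonical
#' 37-gene set, in the package's canonical nomenclature.
#'
#' @return character vector of gene symbols.
#' @export
pcg_names <- function() c("ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3", "ND3",
                          "ND5", "ND4", "ND4L", "ND6", "CYTB", "ND1")

#' @rdname pcg_names
#' @export
trna_names <- function() {
  ord <- ancestral_gene_order()
  ord$name[ord$type == "tRNA"]
}

#' @rdname pcg_names
#' @export
rrna_names <- function() c("lrRNA", "srRNA")

#' @rdname pcg_names
#' @export
canonical_37 <- function() {
  ord <- ancestral_gene_order()
  ord$name[ord$type != "control_region"]
}
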