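## Base composition, strand skews and codon usage.
##
## AT-skew = (A - T) / (A + T), GC-skew = (G - C) / (G + C), computed at full
## precision on the deposited J-strand (or any supplied region); rounding to
## 3 decimals (skews) / 1 decimal (percentages) happens only at presentation.

#' Base counts, A+T content and strand skews of a sequence
#'
#' @param sequence nucleotide string (N and other ambiguity codes are
#'   excluded from all counts).
#' @param label region label carried into the report.
#' @return list of class `skew_report`: `label`, `counts` (named integer A/C/G/T),
#'   `AT_content` (percent), `AT_skew`, `GC_skew` (NA and flagged in
#'   `undefined` when the corresponding denominator is zero).
#' @export
skew <- function(sequence, label = "region") {
  if (!nzchar(sequence)) stop("empty sequence")
  ch <- seq_chars(toupper(sequence))
  counts <- vapply(DNA_BASES, function(b) sum(ch == b), integer(1))
  a <- counts[["A"]]; t <- counts[["T"]]; g <- counts[["G"]]; c <- counts[["C"]]
  at <- a + t; gc <- g + c
  out <- list(label = label, counts = counts,
              AT_content = 100 * at / (at + gc),
              AT_skew = if (at > 0) (a - t) / at else NA_real_,
              GC_skew = if (gc > 0) (g - c) / gc else NA_real_,
              undefined = c(AT_skew = at == 0, GC_skew = gc == 0))
  class(out) <- "skew_report"
  out
}

#' @export
print.skew_report <- function(x, ...) {
  cat(sprintf("<skew_report> %s: A+T %.1f%%, AT-skew %.3f, GC-skew %.3f\n",
              x$label, x$AT_content, x$AT_skew, x$GC_skew))
  invisible(x)
}

split_codons <- function(s) {
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return(character(0))
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

#' Codon-position composition of a set of coding sequences
#'
#' Aggregates base counts separately for first, second and third codon
#' positions over all input genes (coding orientation, frame 0; trailing
#' incomplete codons are dropped). Statistics are identical whether genes are
#' profiled separately or concatenated.
#'
#' @param cds_set character vector (or list) of in-frame coding sequences.
#' @return list of three `skew_report`s named `pos1`, `pos2`, `pos3`.
#' @export
codon_position_composition <- function(cds_set) {
  cds_set <- unlist(cds_set, use.names = FALSE)
  short <- nchar(cds_set) < 3
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than one codon skipped")
    cds_set <- cds_set[!short]
  }
  if (!length(cds_set)) stop("no usable coding sequences")
  codons <- unlist(lapply(toupper(cds_set), split_codons))
  pos_seq <- vapply(1:3, function(p) chars_seq(substr(codons, p, p)), character(1))
  out <- lapply(1:3, function(p) skew(pos_seq[p], label = paste0("pos", p)))
  names(out) <- paste0("pos", 1:3)
  out
}

#' Invertebrate mitochondrial genetic code (DNA alphabet)
#'
#' @return named character vector mapping codons to amino acids (`*` = stop).
#' @export
invertebrate_mito_code <- function() {
  Biostrings::getGeneticCode("SGC4")
}

#' Start and stop codons of every protein-coding gene
#'
#' The start codon is the first three nucleotides of the coding sequence. For
#' a CDS whose length is a multiple of three, the stop is its trailing codon;
#' otherwise the trailing one or two nucleotides are reported as an incomplete
#' stop, which is only legal when they are `T` or `TA` (completed to TAA by
#' polyadenylation). Any other remainder is an annotation inconsistency.
#'
#' @param g an [annotated_genome()].
#' @return data.frame with columns `gene`, `start`, `stop`, `incomplete`.
#' @export
start_stop_table <- function(g) {
  genes <- g$features$name[g$features$type == "PCG"]
  rows <- lapply(genes, function(nm) {
    cds <- extract_region(g, nm)
    ss <- start_stop_of_cds(cds, nm)
    data.frame(gene = nm, start = ss$start, stop = ss$stop,
               incomplete = ss$incomplete, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

start_stop_of_cds <- function(cds, gene = "CDS") {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 6) stop("coding sequence too short for ", gene)
  start <- substr(cds, 1, 3)
  rem <- n %% 3
  if (rem == 0) {
    list(start = start, stop = substr(cds, n - 2, n), incomplete = FALSE)
  } else {
    tailseq <- substr(cds, n - rem + 1, n)
    if (!tailseq %in% c("T", "TA"))
      stop("annotation inconsistency in ", gene,
           ": trailing residues \"", tailseq, "\" are not an incomplete stop")
    list(start = start, stop = tailseq, incomplete = TRUE)
  }
}

#' Relative synonymous codon usage (RSCU)
#'
#' Counts codons over the invertebrate mitochondrial code (stop codons
#' excluded) and computes, within each synonymous family,
#' `RSCU(c) = count(c) * family_size / family_total`. Codons of a family with
#' zero total are reported with `RSCU = NA` (absent family); an unused codon
#' in a used family has `RSCU = 0`.
#'
#' @param cds_set character vector of in-frame coding sequences. Trailing
#'   incomplete codons are dropped.
#' @return data.frame of class `codon_usage`: `codon`, `amino_acid`, `count`,
#'   `RSCU`, sorted by amino acid then codon.
#' @export
rscu <- function(cds_set) {
  code <- invertebrate_mito_code()
  sense <- code[code != "*"]
  codons <- unlist(lapply(toupper(unlist(cds_set)), split_codons))
  codons <- codons[codons %in% names(sense)]
  counts <- table(factor(codons, levels = names(sense)))
  fam_total <- tapply(as.integer(counts), sense, sum)
  fam_size <- table(sense)
  out <- data.frame(codon = names(sense), amino_acid = unname(sense),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  tot <- as.numeric(fam_total[out$amino_acid])
  sz <- as.numeric(fam_size[out$amino_acid])
  out$RSCU <- ifelse(tot > 0, out$count * sz / tot, NA_real_)
  out <- out[order(out$amino_acid, out$codon), ]
  rownames(out) <- NULL
  class(out) <- c("codon_usage", "data.frame")
  out
}

#' Write a per-codon RSCU table
#' @param x a `codon_usage` table from [rscu()].
#' @param path output TSV path.
#' @export
write_rscu <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
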