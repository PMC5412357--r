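## Alignment conservation: percent identical nucleotides (%INUC), A+T
## content, per-group summaries and the %INUC ~ A+T correlation.

as_alignment_matrix <- function(alignment) {
  if (is.character(alignment) && is.null(dim(alignment))) {
    if (length(unique(nchar(alignment))) != 1) stop("ragged alignment")
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
    m
  } else {
    m <- as.matrix(alignment)
    m[] <- toupper(m)
    m
  }
}

#' Conservation and composition profile of a multiple alignment
#'
#' A column is identical iff all rows carry the same unambiguous non-gap
#' residue (case-insensitive; any gap or ambiguity code makes the column
#' variable). Gap-containing columns stay in the denominator;
#' `percent_INUC_nogap` additionally reports the denominator that excludes
#' gap-only columns. A+T content is computed over non-gap A/T/U residues
#' relative to all non-gap residues.
#'
#' @param alignment character matrix (rows = sequences) or character vector of
#'   equal-length gapped strings; >= 2 rows.
#' @param gene gene label carried into the profile.
#' @param strand `"J"` or `"N"` (annotation only).
#' @param domains optional named list of column ranges `c(from, to)` (1-based
#'   inclusive), e.g. rRNA structural domains; a per-domain profile list is
#'   attached.
#' @return list of class `alignment_profile`: `gene`, `n_rows`, `n_columns`,
#'   `n_identical_columns`, `percent_INUC`, `percent_INUC_nogap`,
#'   `AT_content`, `strand`, `taxa`, `domains`.
#' @export
profile_alignment <- function(alignment, gene = "gene", strand = "J",
                              domains = NULL) {
  m <- as_alignment_matrix(alignment)
  if (nrow(m) < 2) stop("need at least two rows")
  ident <- apply(m, 2, function(col)
    all(col == col[1]) && col[1] %in% c("A", "C", "G", "T", "U"))
  res <- m[m != "-"]
  at <- 100 * sum(res %in% c("A", "T", "U")) / length(res)
  gap_only <- apply(m, 2, function(col) all(col == "-"))
  dom <- NULL
  if (!is.null(domains)) {
    dom <- lapply(names(domains), function(d) {
      rng <- domains[[d]]
      profile_alignment(m[, rng[1]:rng[2], drop = FALSE],
                        gene = paste0(gene, ":", d), strand = strand)
    })
    names(dom) <- names(domains)
  }
  out <- list(gene = gene, n_rows = nrow(m), n_columns = ncol(m),
              n_identical_columns = sum(ident),
              percent_INUC = 100 * sum(ident) / ncol(m),
              percent_INUC_nogap = 100 * sum(ident) / sum(!gap_only),
              AT_content = at, strand = strand,
              taxa = rownames(m), domains = dom)
  class(out) <- "alignment_profile"
  out
}

#' @export
print.alignment_profile <- function(x, ...) {
  cat(sprintf("<alignment_profile> %s (%s): %d x %d, %%INUC %.1f, A+T %.1f\n",
              x$gene, x$strand, x$n_rows, x$n_columns, x$percent_INUC,
              x$AT_content))
  invisible(x)
}

#' Pearson correlation between %INUC and A+T content across profiles
#'
#' @param profiles list of `alignment_profile`s (>= 3).
#' @return list with `r` (full-precision Pearson coefficient, `NA` when
#'   either variable has zero variance) and `undefined` flag.
#' @export
correlate_profiles <- function(profiles) {
  if (length(profiles) < 3) stop("need at least three profiles")
  inuc <- vapply(profiles, `[[`, numeric(1), "percent_INUC")
  at <- vapply(profiles, `[[`, numeric(1), "AT_content")
  if (stats::sd(inuc) == 0 || stats::sd(at) == 0)
    return(list(r = NA_real_, undefined = TRUE))
  list(r = cor(inuc, at), undefined = FALSE)
}

#' Per-group conservation summary
#'
#' Groups profiles by the group of their taxa (all taxa of a profile must map
#' to one group) and reports per-group min/mean/max of %INUC and A+T content.
#' Groups represented by fewer than `min_genomes` genomes are flagged.
#'
#' @param profiles list of `alignment_profile`s.
#' @param grouping named character vector mapping taxon -> group.
#' @param min_genomes flag groups with fewer genomes than this (default 3,
#'   i.e. "more than two").
#' @return data.frame: `group`, `n_profiles`, `n_genomes`, `INUC_min`,
#'   `INUC_mean`, `INUC_max`, `AT_min`, `AT_mean`, `AT_max`, `flagged`.
#' @export
group_summary <- function(profiles, grouping, min_genomes = 3) {
  prof_group <- vapply(profiles, function(p) {
    taxa <- p$taxa
    if (is.null(taxa)) stop("profile ", p$gene, " carries no taxon names")
    unmapped <- setdiff(taxa, names(grouping))
    if (length(unmapped))
      stop("unmapped taxon/taxa: ", paste(unmapped, collapse = ", "))
    grp <- unique(unname(grouping[taxa]))
    if (length(grp) != 1)
      stop("profile ", p$gene, " mixes groups: ", paste(grp, collapse = ", "))
    grp
  }, character(1))
  rows <- lapply(split(seq_along(profiles), prof_group), function(idx) {
    inuc <- vapply(profiles[idx], `[[`, numeric(1), "percent_INUC")
    at <- vapply(profiles[idx], `[[`, numeric(1), "AT_content")
    taxa <- unique(unlist(lapply(profiles[idx], `[[`, "taxa")))
    data.frame(group = prof_group[idx[1]], n_profiles = length(idx),
               n_genomes = length(taxa),
               INUC_min = min(inuc), INUC_mean = mean(inuc), INUC_max = max(inuc),
               AT_min = min(at), AT_mean = mean(at), AT_max = max(at),
               flagged = length(taxa) < min_genomes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write alignment FASTA as a character matrix
#' @param path FASTA path.
#' @return character matrix (rows = sequences).
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  as_alignment_matrix(setNames(as.character(x), names(x)))
}

#' @param alignment character matrix.
#' @rdname read_alignment_fasta
#' @export
write_alignment_fasta <- function(alignment, path) {
  rows <- apply(alignment, 1, paste, collapse = "")
  x <- Biostrings::BStringSet(setNames(rows, rownames(alignment)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Emit a tab-separated profile report
#' @param profiles list of `alignment_profile`s.
#' @param path output path.
#' @return the report data.frame, invisibly.
#' @export
write_profile_report <- function(profiles, path) {
  tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(gene = p$gene, strand = p$strand, n_rows = p$n_rows,
               n_columns = p$n_columns,
               n_identical_columns = p$n_identical_columns,
               percent_INUC = round(p$percent_INUC, 1),
               percent_INUC_nogap = round(p$percent_INUC_nogap, 1),
               AT_content = round(p$AT_content, 1))))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
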