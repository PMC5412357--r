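## Conserved intergenic spacers: extraction across a genome panel, a small
## deterministic progressive aligner, and IUPAC-ambiguity consensus motifs.

#' Extract the intergenic spacer between two annotated genes
#'
#' Returns the nucleotide sequence strictly between feature `up` and feature
#' `down`, where `down` follows `up` in (circular) genome order. When both
#' flanking genes lie on the N-strand the spacer is reported
#' reverse-complemented (N orientation); mixed- or J-strand flanks are
#' reported J-strand.
#'
#' @param g an [annotated_genome()].
#' @param up,down canonical gene names.
#' @return character string with attributes `orientation` ("J"/"N") and
#'   `span0` (zero-based half-open J-strand interval). Abutting or
#'   overlapping features yield an empty spacer.
#' @export
extract_spacer <- function(g, up, down) {
  fu <- get_feature(g, up); fd <- get_feature(g, down)
  L <- nchar(g$sequence)
  from <- if (!is.na(fu$wrap_end0)) fu$wrap_end0 else fu$end0
  to <- fd$start0
  orientation <- if (fu$strand == "N" && fd$strand == "N") "N" else "J"
  if (to >= from) {
    s <- if (to > from) substr(g$sequence, from + 1L, to) else ""
    span <- c(from, to)
  } else {
    if (g$topology != "circular")
      stop("features are not in order on a linear genome")
    s <- paste0(substr(g$sequence, from + 1L, L), substr(g$sequence, 1L, to))
    span <- c(from, to + L)
  }
  if (orientation == "N" && nzchar(s)) s <- revcomp(s)
  structure(s, orientation = orientation, span0 = span)
}

#' Collect one named spacer across a genome panel
#'
#' @param genomes list of [annotated_genome()]s.
#' @param up,down flanking gene names.
#' @return list of class `spacer_set` with `up`, `down`, `orientation` and
#'   `sequences` (named by genome id).
#' @export
spacer_set <- function(genomes, up, down) {
  seqs <- lapply(genomes, extract_spacer, up = up, down = down)
  ori <- unique(vapply(seqs, attr, character(1), "orientation"))
  structure(list(up = up, down = down, orientation = ori[1],
                 sequences = setNames(vapply(seqs, as.character, character(1)),
                                      vapply(genomes, `[[`, character(1), "id"))),
            class = "spacer_set")
}

## ---- alignment ------------------------------------------------------------

## Global alignment of one sequence against an existing alignment profile.
## Scoring: +1 per matching residue (averaged over non-gap profile rows),
## mismatch 0, gap -2, terminal gaps free. Deterministic tie-break prefers
## diagonal, then consuming a profile column, then a gap in the profile.
align_seq_to_profile <- function(profile, s) {
  rows <- nrow(profile); m <- ncol(profile); x <- seq_chars(s); n <- length(x)
  colscore <- function(j, ch) {
    col <- profile[, j]
    nz <- col != "-"
    if (!any(nz)) return(0)
    sum(col[nz] == ch) / sum(nz)
  }
  S <- matrix(-Inf, m + 1, n + 1)
  P <- matrix(0L, m + 1, n + 1)  # 1 diag, 2 up (profile col vs gap), 3 left
  S[1, ] <- 0; S[, 1] <- 0      # terminal gaps free
  gap <- -2
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      d <- S[i, j] + colscore(i, x[j])
      u <- S[i, j + 1] + if (j == n) 0 else gap   # gap in new sequence
      l <- S[i + 1, j] + if (i == m) 0 else gap   # gap column in profile
      best <- max(d, u, l)
      S[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }
  ## traceback from (m+1, n+1)
  i <- m + 1; j <- n + 1
  ops <- integer(0)
  while (i > 1 || j > 1) {
    if (i == 1) { ops <- c(3L, ops); j <- j - 1 }
    else if (j == 1) { ops <- c(2L, ops); i <- i - 1 }
    else {
      op <- P[i, j]
      ops <- c(op, ops)
      if (op == 1L) { i <- i - 1; j <- j - 1 }
      else if (op == 2L) i <- i - 1
      else j <- j - 1
    }
  }
  ## rebuild alignment
  new_profile <- matrix("", rows + 1, length(ops))
  pi <- 1; si <- 1
  for (k in seq_along(ops)) {
    if (ops[k] == 1L) {
      new_profile[seq_len(rows), k] <- profile[, pi]; pi <- pi + 1
      new_profile[rows + 1, k] <- x[si]; si <- si + 1
    } else if (ops[k] == 2L) {
      new_profile[seq_len(rows), k] <- profile[, pi]; pi <- pi + 1
      new_profile[rows + 1, k] <- "-"
    } else {
      new_profile[seq_len(rows), k] <- "-"
      new_profile[rows + 1, k] <- x[si]; si <- si + 1
    }
  }
  new_profile
}

#' Progressively align a set of spacer sequences
#'
#' Progressive global alignment in input order (match +1, mismatch 0,
#' gap -2, terminal gaps free); deterministic for a fixed input order.
#' Identical-length inputs yield a gap-free alignment.
#'
#' @param x a `spacer_set` or character vector of sequences (>= 2).
#' @param max_length_ratio refuse to align sets whose longest/shortest length
#'   ratio exceeds this (default 2): such sets need manual review.
#' @return character matrix (rows = sequences, columns = alignment columns).
#' @export
align_spacers <- function(x, max_length_ratio = 2) {
  seqs <- if (inherits(x, "spacer_set")) x$sequences else x
  if (length(seqs) < 2) stop("need at least two sequences")
  if (any(!nzchar(seqs))) stop("cannot align empty spacer sequences")
  lens <- nchar(seqs)
  if (max(lens) / min(lens) > max_length_ratio)
    stop("spacer length ratio ", round(max(lens) / min(lens), 2),
         " exceeds ", max_length_ratio, "; manual review suggested")
  profile <- matrix(seq_chars(toupper(seqs[[1]])), nrow = 1)
  for (k in seq_along(seqs)[-1])
    profile <- align_seq_to_profile(profile, toupper(seqs[[k]]))
  rownames(profile) <- names(seqs)
  profile
}

## ---- consensus ------------------------------------------------------------

#' IUPAC-ambiguity consensus of an aligned sequence set
#'
#' Each column's set of distinct non-gap residues (ambiguity letters in the
#' input are expanded to their residue sets) maps to the IUPAC code of exactly
#' that set; columns that are gap in at least half of the rows are dropped,
#' trimming the consensus to the common core.
#'
#' @param alignment character matrix (rows = sequences), or character vector
#'   of equal-length gapped strings.
#' @return list of class `consensus_motif`: `consensus` (string),
#'   `column_sets` (list of residue sets for retained columns),
#'   `kept_columns` (original column indices), `n_sequences`.
#' @export
iupac_consensus <- function(alignment) {
  if (is.character(alignment) && is.null(dim(alignment))) {
    if (length(unique(nchar(alignment))) != 1) stop("ragged alignment")
    alignment <- do.call(rbind, strsplit(toupper(alignment), ""))
  }
  if (!nrow(alignment)) stop("empty alignment")
  alignment[] <- toupper(alignment)
  nr <- nrow(alignment)
  gap_frac <- colMeans(alignment == "-")
  keep <- which(gap_frac < 0.5)
  sets <- lapply(keep, function(j) {
    res <- alignment[, j]
    res <- res[res != "-"]
    sort(unique(unlist(iupac_to_set(res))))
  })
  letters <- vapply(sets, function(s) iupac_from_set(paste(s, collapse = "")),
                    character(1))
  structure(list(consensus = paste(letters, collapse = ""),
                 column_sets = sets, kept_columns = keep, n_sequences = nr),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat(sprintf("<consensus_motif> %s (%d sequences, %d columns)\n",
              x$consensus, x$n_sequences, length(x$kept_columns)))
  invisible(x)
}

#' Does a sequence match a consensus motif under IUPAC-compatible matching?
#'
#' @param sequence ungapped nucleotide string of the motif's length.
#' @param motif a `consensus_motif`.
#' @return logical.
#' @export
matches_consensus <- function(sequence, motif) {
  ch <- seq_chars(toupper(sequence))
  if (length(ch) != length(motif$column_sets)) return(FALSE)
  all(mapply(function(r, set) all(iupac_to_set(r)[[1]] %in% set),
             ch, motif$column_sets))
}

#' Write an aligned spacer panel plus its consensus as FASTA
#'
#' @param alignment character matrix from [align_spacers()].
#' @param motif a `consensus_motif`.
#' @param path output path.
#' @param params free-text parameter record written into the header line.
#' @export
write_spacer_fasta <- function(alignment, motif, path, params = "") {
  rows <- apply(alignment, 1, paste, collapse = "")
  con <- file(path, "w"); on.exit(close(con))
  if (nzchar(params)) writeLines(paste0("; ", params), con)
  for (i in seq_along(rows))
    writeLines(c(paste0(">", rownames(alignment)[i]), rows[i]), con)
  writeLines(c(">consensus", motif$consensus), con)
  invisible(path)
}
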