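## Concatenated phylogenetic matrices (P123 / P123R / P12 / P12R) with
## codon-position partition schemes. Blocks are pre-aligned gene alignments;
## alignment construction for real data happens upstream.

#' Construct a gene block
#'
#' @param gene gene name.
#' @param type `"PCG"`, `"tRNA"` or `"rRNA"`.
#' @param alignment character matrix (rows = taxa) or named character vector
#'   of equal-length (gapped) sequences.
#' @param frame codon position of column 1 (PCG blocks only; 1, 2 or 3).
#' @return list of class `gene_block`.
#' @export
gene_block <- function(gene, type = c("PCG", "tRNA", "rRNA"), alignment,
                       frame = if (type == "PCG") 1L else NA_integer_) {
  type <- match.arg(type)
  m <- as_alignment_matrix(alignment)
  if (is.null(rownames(m))) stop("block alignment needs taxon names")
  out <- list(gene = gene, type = type, alignment = m, frame = as.integer(frame))
  class(out) <- "gene_block"
  out
}

#' @export
print.gene_block <- function(x, ...) {
  cat(sprintf("<gene_block> %s (%s): %d taxa x %d columns\n", x$gene, x$type,
              nrow(x$alignment), ncol(x$alignment)))
  invisible(x)
}

## codon position (1/2/3) of every column of a PCG block
block_phases <- function(block) {
  ((block$frame - 1L + seq_len(ncol(block$alignment)) - 1L) %% 3L) + 1L
}

#' Concatenate gene blocks
#'
#' Columns are appended in the given order; all blocks must share the same
#' taxon set (row order follows the first block). The column map records each
#' block's half-open column range.
#'
#' @param blocks list of [gene_block()]s.
#' @return list with `matrix` (character matrix) and `column_map` (data.frame
#'   `gene`, `type`, `from`, `to`, 1-based inclusive).
#' @export
concatenate_blocks <- function(blocks) {
  taxa <- rownames(blocks[[1]]$alignment)
  for (b in blocks) {
    other <- rownames(b$alignment)
    if (!setequal(taxa, other))
      stop("taxon set mismatch in block ", b$gene, ": ",
           paste(union(setdiff(taxa, other), setdiff(other, taxa)),
                 collapse = ", "))
  }
  mats <- lapply(blocks, function(b) b$alignment[taxa, , drop = FALSE])
  widths <- vapply(mats, ncol, integer(1))
  to <- cumsum(widths)
  from <- to - widths + 1L
  list(matrix = do.call(cbind, mats),
       column_map = data.frame(gene = vapply(blocks, `[[`, character(1), "gene"),
                               type = vapply(blocks, `[[`, character(1), "type"),
                               from = from, to = to,
                               stringsAsFactors = FALSE))
}

#' Remove third codon positions from a PCG block
#'
#' Drops every column whose codon position is 3. The surviving columns are
#' renumbered and the result carries `frame = 1` with positions re-counted
#' 1,2,1,2,...; applying the operation twice therefore removes third
#' positions of the *new* numbering (it is not idempotent).
#'
#' @param block a PCG [gene_block()].
#' @return a [gene_block()] without third positions.
#' @export
exclude_third_positions <- function(block) {
  if (block$type != "PCG")
    stop("third-position exclusion applies only to PCG blocks, not ",
         block$type)
  keep <- block_phases(block) != 3L
  gene_block(block$gene, "PCG",
             block$alignment[, keep, drop = FALSE], frame = 1L)
}

SUPERMATRIX_DATASETS <- c("P123", "P123R", "P12", "P12R")

#' Assemble a named supermatrix dataset with its partition scheme
#'
#' * `P123`: all codon positions of the 13 PCGs (3 partitions per PCG).
#' * `P123R`: `P123` plus the 2 rRNA and the non-excluded tRNA blocks (one
#'   partition per RNA gene).
#' * `P12` / `P12R`: as above with third codon positions excluded from the
#'   PCG blocks (2 partitions per PCG).
#'
#' Codon-position partitions are interleaved column classes encoded with
#' stride notation (`from-to\\3` for P123-style blocks, `\\2` after
#' third-position exclusion).
#'
#' @param blocks list of [gene_block()]s covering 13 PCGs, 2 rRNAs and the
#'   tRNAs.
#' @param name dataset name (`"P123"`, `"P123R"`, `"P12"`, `"P12R"`).
#' @param trna_exclude tRNAs left out of the RNA block set (default
#'   tRNA-Ile, tRNA-Gln, tRNA-Met, which are not available for all sampled
#'   taxa).
#' @return list of class `supermatrix`: `name`, `matrix`, `column_map`,
#'   `partitions` (data.frame `partition`, `from`, `to`, `stride`, `offset`),
#'   `excluded_third`.
#' @export
build_dataset <- function(blocks, name,
                          trna_exclude = c("trnI", "trnQ", "trnM")) {
  name <- match.arg(name, SUPERMATRIX_DATASETS)
  types <- vapply(blocks, `[[`, character(1), "type")
  genes <- vapply(blocks, `[[`, character(1), "gene")
  pcg <- blocks[types == "PCG"]
  missing_pcg <- setdiff(pcg_names(), genes[types == "PCG"])
  if (length(missing_pcg))
    stop("missing required PCG block(s): ", paste(missing_pcg, collapse = ", "))
  pcg <- pcg[order(match(vapply(pcg, `[[`, character(1), "gene"), pcg_names()))]
  rna <- blocks[types != "PCG" & !genes %in% trna_exclude]
  with_rna <- name %in% c("P123R", "P12R")
  drop3 <- name %in% c("P12", "P12R")
  if (with_rna) {
    missing_rrna <- setdiff(rrna_names(),
                            vapply(rna, `[[`, character(1), "gene"))
    if (length(missing_rrna))
      stop("missing required rRNA block(s): ",
           paste(missing_rrna, collapse = ", "))
  }
  if (drop3) pcg <- lapply(pcg, exclude_third_positions)
  used <- c(pcg, if (with_rna) rna)
  cc <- concatenate_blocks(used)
  ## partitions: codon-position classes per PCG, one per RNA gene
  parts <- list()
  for (i in seq_along(used)) {
    b <- used[[i]]
    rng <- cc$column_map[i, ]
    if (b$type == "PCG") {
      stride <- if (drop3) 2L else 3L
      npos <- if (drop3) 2L else 3L
      for (p in seq_len(npos))
        parts[[length(parts) + 1L]] <- data.frame(
          partition = sprintf("%s_pos%d", b$gene, p),
          from = rng$from + p - 1L, to = rng$to, stride = stride, offset = p)
    } else {
      parts[[length(parts) + 1L]] <- data.frame(
        partition = b$gene, from = rng$from, to = rng$to, stride = 1L,
        offset = 1L)
    }
  }
  out <- list(name = name, matrix = cc$matrix, column_map = cc$column_map,
              partitions = do.call(rbind, parts), excluded_third = drop3)
  class(out) <- "supermatrix"
  out
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %s: %d taxa x %d columns, %d partitions\n",
              x$name, nrow(x$matrix), ncol(x$matrix), nrow(x$partitions)))
  invisible(x)
}

#' Columns covered by each partition
#'
#' @param sm a [build_dataset()] result.
#' @return list of integer column vectors, named by partition.
#' @export
partition_columns <- function(sm) {
  p <- sm$partitions
  setNames(lapply(seq_len(nrow(p)), function(i)
    seq(p$from[i], p$to[i], by = p$stride[i])), p$partition)
}

## ---- writers / readers ----------------------------------------------------

#' Write a supermatrix in relaxed sequential PHYLIP format
#' @param sm a `supermatrix` (or any character alignment matrix).
#' @param path output path.
#' @export
write_phylip <- function(sm, path) {
  m <- if (inherits(sm, "supermatrix")) sm$matrix else sm
  rows <- apply(m, 1, paste, collapse = "")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  writeLines(sprintf("%s  %s", rownames(m), rows), con)
  invisible(path)
}

#' Read a relaxed sequential PHYLIP alignment
#' @param path file path.
#' @return character matrix.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(body), "\\s+")
  m <- do.call(rbind, strsplit(toupper(vapply(parts, `[`, character(1), 2)), ""))
  rownames(m) <- vapply(parts, `[`, character(1), 1)
  if (nrow(m) != hdr[1] || ncol(m) != hdr[2])
    stop("PHYLIP dimensions disagree with header")
  m
}

#' Write a supermatrix as NEXUS with a sets block
#' @param sm a `supermatrix`.
#' @param path output path.
#' @export
write_nexus <- function(sm, path) {
  m <- sm$matrix
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)), con)
  writeLines("  FORMAT DATATYPE=DNA MISSING=? GAP=-;", con)
  writeLines("  MATRIX", con)
  writeLines(sprintf("    %s  %s", rownames(m),
                     apply(m, 1, paste, collapse = "")), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  writeLines("BEGIN SETS;", con)
  p <- sm$partitions
  writeLines(sprintf("  CHARSET %s = %d-%d%s;", p$partition, p$from, p$to,
                     ifelse(p$stride > 1, paste0("\\", p$stride), "")), con)
  writeLines("END;", con)
  invisible(path)
}

#' Write a RAxML-style partition file
#' @param sm a `supermatrix`.
#' @param path output path.
#' @export
write_raxml_partitions <- function(sm, path) {
  p <- sm$partitions
  writeLines(sprintf("DNA, %s = %d-%d%s", p$partition, p$from, p$to,
                     ifelse(p$stride > 1, paste0("\\", p$stride), "")), path)
  invisible(path)
}

#' Write a PartitionFinder-style configuration
#' @param sm a `supermatrix`.
#' @param path output path.
#' @param alignment_file alignment filename referenced in the config.
#' @export
write_partitionfinder_cfg <- function(sm, path,
                                      alignment_file = "supermatrix.phy") {
  p <- sm$partitions
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("alignment = %s;", alignment_file),
               "branchlengths = unlinked;",
               "models = all;", "model_selection = BIC;",
               "[data_blocks]"), con)
  writeLines(sprintf("%s = %d-%d%s;", p$partition, p$from, p$to,
                     ifelse(p$stride > 1, paste0("\\", p$stride), "")), con)
  writeLines(c("[schemes]", "search = greedy;"), con)
  invisible(path)
}
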