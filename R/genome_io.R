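## Internal coordinate convention: zero-based half-open intervals on the
## J-strand (the deposited strand). Origin-wrapping features on a circular
## genome carry a second span [0, wrap_end0) in addition to [start0, end0),
## where end0 equals the genome length. All printed/exchange formats use
## 1-based inclusive GenBank-style coordinates.

#' Construct an annotated mitochondrial genome
#'
#' @param id accession or label.
#' @param sequence J-strand nucleotide string (A/C/G/T/N).
#' @param features data.frame with columns `name`, `type`
#'   (PCG/tRNA/rRNA/control_region/spacer), `strand` (J/N), `start0`, `end0`
#'   (zero-based half-open) and optionally `wrap_end0` (origin-wrapping
#'   second-span end), `anticodon`, `inferred`.
#' @param topology `"circular"` or `"linear"`.
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence, features, topology = "circular") {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside A/C/G/T/N")
  topology <- match.arg(topology, c("circular", "linear"))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  for (col in c("name", "type", "strand", "start0", "end0"))
    if (!col %in% names(features)) stop("features lack column ", col)
  if (!"wrap_end0" %in% names(features)) features$wrap_end0 <- NA_integer_
  if (!"anticodon" %in% names(features)) features$anticodon <- NA_character_
  if (!"inferred" %in% names(features)) features$inferred <- FALSE
  L <- nchar(sequence)
  if (any(features$end0 > L) || any(features$start0 < 0))
    stop("feature span exceeds sequence bounds")
  if (any(!is.na(features$wrap_end0)) && topology != "circular")
    stop("origin-wrapping features require circular topology")
  len <- feature_lengths(features)
  if (any(len < 1) || any(len > L)) stop("feature length out of range")
  canon <- features$name[features$name %in% canonical_37()]
  if (anyDuplicated(canon))
    stop("duplicated canonical gene(s): ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "))
  features <- features[order(features$start0), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(id = id, sequence = sequence, features = features,
                 topology = topology),
            class = "annotated_genome")
}

feature_lengths <- function(features) {
  (features$end0 - features$start0) +
    ifelse(is.na(features$wrap_end0), 0L, features$wrap_end0)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, %s, %d features\n",
              x$id, nchar(x$sequence), x$topology, nrow(x$features)))
  invisible(x)
}

## ---- GenBank flat file ----------------------------------------------------

parse_gb_location <- function(loc, line_no) {
  strand <- "J"
  s <- gsub(" ", "", loc)
  if (grepl("^complement\\(", s)) {
    strand <- "N"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^join\\(", s)) s <- sub("^join\\((.*)\\)$", "\\1", s)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", parts))
  if (any(lengths(m) != 3))
    stop("malformed feature location at line ", line_no, ": ", loc)
  spans <- do.call(rbind, lapply(m, function(x) as.integer(x[2:3])))
  list(strand = strand, spans = spans)
}

#' Read a GenBank flat file
#'
#' Parses a single-record GenBank flat file into an [annotated_genome()].
#' 1-based inclusive coordinates become zero-based half-open; features on the
#' complement strand are marked `strand = "N"`; gene names are normalized via
#' the packaged synonym table. Unknown gene names raise a warning and the
#' feature is retained with its raw name and a type inferred from the feature
#' key. A record lacking a control-region feature gets one inferred as the
#' longest unannotated region between srRNA and tRNA-Ile (flagged
#' `inferred = TRUE`).
#'
#' @param path file path.
#' @param infer_cr infer a missing control region?
#' @return an [annotated_genome()].
#' @export
read_genbank <- function(path, infer_cr = TRUE) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1)
    stop("malformed record: expected one LOCUS line, line ",
         if (length(locus_i)) locus_i[2] else 1)
  locus <- strsplit(trimws(lines[locus_i]), "\\s+")[[1]]
  id <- locus[2]
  topology <- if (any(tolower(locus) == "linear")) "linear" else "circular"

  feat_start <- grep("^FEATURES", lines)
  orig_start <- grep("^ORIGIN", lines)
  if (length(feat_start) != 1 || length(orig_start) != 1)
    stop("malformed record: need FEATURES and ORIGIN sections in ", path)

  ## sequence
  seq_lines <- lines[(orig_start + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[ 0-9]", "", paste(seq_lines, collapse = "")))

  ## features: key lines start at column 6, continuations/qualifiers at 22
  keep_keys <- c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop")
  rows <- list()
  i <- feat_start + 1
  while (i < orig_start) {
    ln <- lines[i]
    key <- trimws(substr(ln, 1, 20))
    if (nzchar(key) && !grepl("^ {0,4}\\S", ln)) {
      loc <- trimws(substr(ln, 21, nchar(ln)))
      line_no <- i
      ## location may continue on following lines until a qualifier starts
      j <- i + 1
      while (j < orig_start && !grepl("^\\s+/", lines[j]) &&
             !nzchar(trimws(substr(lines[j], 1, 20)))) {
        loc <- paste0(loc, trimws(lines[j])); j <- j + 1
      }
      quals <- character()
      while (j < orig_start && grepl("^\\s+/", lines[j])) {
        quals <- c(quals, trimws(lines[j])); j <- j + 1
      }
      if (key %in% keep_keys) {
        getq <- function(q) {
          hit <- grep(paste0("^/", q, "="), quals, value = TRUE)
          if (!length(hit)) return(NA_character_)
          gsub('^/[a-z_]+="?|"$', "", hit[1])
        }
        parsed <- parse_gb_location(loc, line_no)
        raw <- getq("gene")
        if (is.na(raw)) raw <- getq("product")
        if (is.na(raw)) raw <- getq("note")
        type <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       "control_region")
        rows[[length(rows) + 1]] <- list(raw = raw, type = type,
                                         strand = parsed$strand,
                                         spans = parsed$spans,
                                         anticodon = getq("anticodon"))
      }
      i <- j
    } else i <- i + 1
  }
  if (!length(rows)) stop("malformed record: no features parsed from ", path)

  L <- nchar(sequence)
  features <- do.call(rbind, lapply(rows, function(r) {
    sp <- r$spans
    if (nrow(sp) == 1) {
      start0 <- sp[1, 1] - 1L; end0 <- sp[1, 2]; wrap <- NA_integer_
    } else if (nrow(sp) == 2 && sp[1, 2] == L && sp[2, 1] == 1) {
      start0 <- sp[1, 1] - 1L; end0 <- L; wrap <- sp[2, 2]
    } else stop("unsupported multi-span location for feature ", r$raw)
    data.frame(name = if (is.na(r$raw)) "unknown" else r$raw, type = r$type,
               strand = r$strand, start0 = start0, end0 = end0,
               wrap_end0 = wrap, anticodon = r$anticodon,
               inferred = FALSE, stringsAsFactors = FALSE)
  }))
  features$name <- ifelse(features$type == "control_region" &
                            features$name == "unknown",
                          "CR", features$name)
  features$name <- normalize_gene_name(features$name)
  g <- annotated_genome(id, sequence, features, topology)
  if (infer_cr && !any(g$features$type == "control_region"))
    g <- infer_control_region(g)
  g
}

format_gb_location <- function(f, L) {
  loc <- if (!is.na(f$wrap_end0))
    sprintf("join(%d..%d,1..%d)", f$start0 + 1L, f$end0, f$wrap_end0)
  else sprintf("%d..%d", f$start0 + 1L, f$end0)
  if (f$strand == "N") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a GenBank flat file
#'
#' Emits a minimal single-record flat file (LOCUS, FEATURES, ORIGIN) that
#' [read_genbank()] reparses to an identical feature table. Internal half-open
#' coordinates are converted back to 1-based inclusive.
#'
#' @param g an [annotated_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  L <- nchar(g$sequence)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %s%17d bp    DNA     %s   INV",
                     formatC(g$id, width = -16), L, g$topology), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, synthetic record.", g$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (k in seq_len(nrow(g$features))) {
    f <- g$features[k, ]
    key <- switch(f$type, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "D-loop", spacer = "misc_feature")
    writeLines(sprintf("     %s%s", formatC(key, width = -16),
                       format_gb_location(f, L)), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
    if (!is.na(f$anticodon))
      writeLines(sprintf("                     /anticodon=\"%s\"", f$anticodon), con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1, L, by = 60)
  for (p in pos) {
    chunk <- substr(g$sequence, p, min(p + 59, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

## ---- feature table / FASTA ------------------------------------------------

#' Write / read a tab-separated feature table (1-based inclusive coordinates)
#'
#' Origin-wrapping features are written with `end` < `start`; the reader
#' restores the span pair.
#'
#' @param g an [annotated_genome()] (writer) .
#' @param path file path.
#' @return writer: `path` invisibly; reader: feature data.frame in internal
#'   coordinates.
#' @export
write_feature_table <- function(g, path) {
  f <- g$features
  tab <- data.frame(name = f$name, type = f$type, strand = f$strand,
                    start = f$start0 + 1L,
                    end = ifelse(is.na(f$wrap_end0), f$end0, f$wrap_end0))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param genome_length genome length, needed to restore wrapping spans.
#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, genome_length) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  wrap <- tab$end < tab$start
  data.frame(name = tab$name, type = tab$type, strand = tab$strand,
             start0 = tab$start - 1L,
             end0 = ifelse(wrap, genome_length, tab$end),
             wrap_end0 = ifelse(wrap, tab$end, NA_integer_),
             stringsAsFactors = FALSE)
}

#' Write genome sequence as FASTA
#' @param g an [annotated_genome()].
#' @param path output path.
#' @export
write_genome_fasta <- function(g, path) {
  x <- Biostrings::DNAStringSet(setNames(g$sequence, g$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## ---- accessors / analyses -------------------------------------------------

get_feature <- function(g, name) {
  i <- which(g$features$name == name)
  if (!length(i)) stop("feature not annotated: ", name)
  g$features[i[1], ]
}

#' Extract a feature's nucleotide sequence in coding orientation
#'
#' J-strand features are returned as deposited; N-strand features are
#' reverse-complemented. Origin-wrapping spans are concatenated across the
#' origin before orientation is applied.
#'
#' @param g an [annotated_genome()].
#' @param f a feature row of `g$features`, or a gene name.
#' @return nucleotide string.
#' @export
extract_region <- function(g, f) {
  if (is.character(f)) f <- get_feature(g, f)
  if (f$end0 > nchar(g$sequence) || f$start0 < 0)
    stop("span outside sequence for ", f$name)
  s <- substr(g$sequence, f$start0 + 1L, f$end0)
  if (!is.na(f$wrap_end0)) s <- paste0(s, substr(g$sequence, 1L, f$wrap_end0))
  if (f$strand == "N") revcomp(s) else s
}

#' Count genes per strand
#'
#' Counts J- and N-strand genes over the 37 canonical mitochondrial genes
#' (control region and spacers excluded). Missing canonical genes are listed.
#'
#' @param g an [annotated_genome()].
#' @return list with `J`, `N` (integer counts) and `missing` (character).
#' @export
strand_census <- function(g) {
  f <- g$features[g$features$name %in% canonical_37(), ]
  list(J = sum(f$strand == "J"), N = sum(f$strand == "N"),
       missing = setdiff(canonical_37(), f$name))
}

#' Rotation-normalized gene order signature
#'
#' Returns the genome's ordered list of (name, strand), rotated so that
#' tRNA-Ile comes first (or the first annotated gene when tRNA-Ile is absent).
#' Spacers are excluded.
#'
#' @param g an [annotated_genome()].
#' @return data.frame with columns `name`, `strand` in normalized order.
#' @export
gene_order_signature <- function(g) {
  f <- g$features[g$features$type != "spacer", c("name", "strand")]
  start <- which(f$name == "trnI")
  if (!length(start)) start <- 1L
  idx <- c(seq(start[1], nrow(f)), seq_len(start[1] - 1L))
  out <- f[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare a gene order signature against a reference order
#'
#' @param sig data.frame from [gene_order_signature()].
#' @param reference reference order (default the packaged ancestral insect
#'   order); any data.frame with `name` and `strand` columns.
#' @return list with `equal` (logical) and `first_divergence` (1-based
#'   position of the first differing entry, `NA` when equal).
#' @export
compare_gene_order <- function(sig, reference = ancestral_gene_order()) {
  a <- paste(sig$name, sig$strand)
  b <- paste(reference$name, reference$strand)
  n <- min(length(a), length(b))
  diff <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(diff)) return(list(equal = FALSE, first_divergence = diff[1]))
  if (length(a) != length(b)) return(list(equal = FALSE, first_divergence = n + 1L))
  list(equal = TRUE, first_divergence = NA_integer_)
}

#' Infer a missing control region
#'
#' Labels the longest unannotated region between srRNA and tRNA-Ile as the
#' control region, with `inferred = TRUE` as a provenance flag.
#'
#' @param g an [annotated_genome()].
#' @return `g` with a control-region feature added.
#' @export
infer_control_region <- function(g) {
  if (any(g$features$type == "control_region")) return(g)
  sr <- get_feature(g, "srRNA"); ile <- get_feature(g, "trnI")
  L <- nchar(g$sequence)
  from <- sr$end0
  to <- ile$start0
  if (is.na(from) || is.na(to)) stop("cannot infer control region")
  if (to == from) stop("no unannotated gap between srRNA and trnI")
  cr <- if (to > from)
    data.frame(name = "CR", type = "control_region", strand = "J",
               start0 = from, end0 = to, wrap_end0 = NA_integer_,
               anticodon = NA_character_, inferred = TRUE)
  else  # wraps the origin
    data.frame(name = "CR", type = "control_region", strand = "J",
               start0 = from, end0 = L, wrap_end0 = to,
               anticodon = NA_character_, inferred = TRUE)
  annotated_genome(g$id, g$sequence, rbind(g$features, cr), g$topology)
}

#' Fetch a GenBank record from NCBI (network required)
#'
#' Convenience helper around NCBI E-utilities; no analysis in this package
#' depends on it.
#'
#' @param accession accession string.
#' @param path destination file.
#' @return `path` invisibly.
#' @export
fetch_accession <- function(accession, path = paste0(accession, ".gb")) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&rettype=gb&retmode=text&id=", accession)
  utils::download.file(url, path, quiet = TRUE)
  invisible(path)
}
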