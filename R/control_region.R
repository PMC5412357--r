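## Control-region structural elements: homopolymer stretches, (TA)n-like
## stretches, non-tandem exact macro repeats and stem-loops (inverted
## repeats). Coordinates are zero-based half-open within the scanned
## sequence; cr_report() additionally reports genome coordinates.

cr_element <- function(kind, start0, end0, detail = "") {
  data.frame(kind = kind, start0 = start0, end0 = end0,
             length = end0 - start0, detail = detail,
             stringsAsFactors = FALSE)
}

empty_elements <- function() {
  data.frame(kind = character(0), start0 = integer(0), end0 = integer(0),
             length = integer(0), detail = character(0))
}

#' Find homopolymer stretches
#'
#' Maximal runs of one base with length >= `min_len`, reported left to right.
#'
#' @param seq nucleotide string.
#' @param base the run base, `"A"` or `"T"`.
#' @param min_len minimum run length (default 10, >= 2).
#' @return data.frame of elements (`kind` = `polyA`/`polyT`).
#' @export
find_homopolymer <- function(seq, base = c("T", "A"), min_len = 10) {
  base <- match.arg(base)
  stopifnot(min_len >= 2)
  ch <- seq_chars(toupper(seq))
  r <- rle(ch == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_len)
  if (!length(hit)) return(empty_elements())
  cr_element(paste0("poly", base), starts[hit] - 1L, ends[hit])
}

#' Find (TA)n-like stretches
#'
#' Maximal exact (TA)n / (AT)n runs with at least `min_units` dinucleotide
#' units. A maximal alternating A/T run of odd length is trimmed by its final
#' base so the reported stretch is a whole number of units.
#'
#' @param seq nucleotide string.
#' @param min_units minimum number of TA/AT units (default 3).
#' @return data.frame of elements (`kind` = `TA_stretch`).
#' @export
find_ta_stretch <- function(seq, min_units = 3) {
  stopifnot(min_units >= 1)
  ch <- seq_chars(toupper(seq))
  n <- length(ch)
  is_at <- ch %in% c("A", "T")
  ## alternation breaks between i and i+1
  alt <- is_at[-n] & is_at[-1] & ch[-n] != ch[-1]
  out <- empty_elements()
  i <- 1L
  while (i < n) {
    if (alt[i]) {
      j <- i
      while (j < n && alt[j]) j <- j + 1L
      run_len <- j - i + 1L              # bases i..j alternate
      keep <- run_len - run_len %% 2L    # whole units only
      if (keep >= 2L * min_units)
        out <- rbind(out, cr_element("TA_stretch", i - 1L, i - 1L + keep))
      i <- j
    } else i <- i + 1L
  }
  rownames(out) <- NULL
  out
}

## all start positions (1-based) of fixed pattern `pat` in `s`, overlapping
find_all_occ <- function(s, pat) {
  hits <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
    if (i < 0) break
    hits <- c(hits, from + i - 1L)
    from <- from + i
  }
  hits
}

## greedily select occurrences that are mutually non-overlapping and
## separated by at least `min_gap` nt (1-based starts)
select_nonoverlapping <- function(starts, len, min_gap = 1L) {
  keep <- integer(0)
  last_end <- -Inf
  for (s in sort(starts)) {
    if (s >= last_end + 1L + min_gap) {
      keep <- c(keep, s)
      last_end <- s + len - 1L
    }
  }
  keep
}

#' Find non-tandem exact macro repeats
#'
#' Maximal exact repeated substrings of length >= `min_len` occurring at
#' least twice at non-overlapping positions separated by >= 1 nt. Maximality:
#' no left or right extension preserves all occurrences. Sub-repeats whose
#' occurrences all lie inside occurrences of a longer reported repeat are
#' suppressed. Repeats whose only extra copies abut a previous copy (gap 0)
#' are tandem arrays and are returned separately.
#'
#' @param seq nucleotide string.
#' @param min_len minimum repeat length (default 30, >= 10 advised; smaller
#'   values are accepted for testing).
#' @return list with `repeats` (data.frame: `length`, `n_occ`, `starts0`
#'   comma-separated zero-based starts, `seq`) and `tandem` (same layout) —
#'   both sorted by decreasing length.
#' @export
find_macro_repeats <- function(seq, min_len = 30) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < min_len + 1L)
    return(list(repeats = empty_repeats(), tandem = empty_repeats()))
  ## level-wise scan: a repeated (L+1)-mer implies a repeated L-mer, so the
  ## lengths carrying duplicated substrings are contiguous from min_len up;
  ## at each level keep the duplicated substrings that are flank-maximal
  ## (no single character extends *all* occurrences on that side)
  maximal <- list()
  L <- as.integer(min_len)
  repeat {
    if (L > n - 1L) break
    subs <- substring(s, 1:(n - L + 1L), L:n)
    dup_vals <- unique(subs[duplicated(subs)])
    if (!length(dup_vals)) break
    for (v in dup_vals) {
      occ <- which(subs == v)
      right_ch <- ifelse(occ + L <= n, substring(s, occ + L, occ + L), NA)
      left_ch <- ifelse(occ > 1L, substring(s, occ - 1L, occ - 1L), NA)
      right_max <- anyNA(right_ch) || length(unique(right_ch)) > 1L
      left_max <- anyNA(left_ch) || length(unique(left_ch)) > 1L
      if (right_max && left_max)
        maximal[[length(maximal) + 1L]] <- list(seq = v, occ = occ)
    }
    L <- L + 1L
  }
  if (!length(maximal))
    return(list(repeats = empty_repeats(), tandem = empty_repeats()))
  rows <- lapply(maximal, function(rec) {
    occ <- rec$occ
    len <- nchar(rec$seq)
    ## non-tandem: >= 2 mutually non-overlapping copies separated by >= 1 nt
    occ_gap <- select_nonoverlapping(occ, len, min_gap = 1L)
    if (length(occ_gap) >= 2) {
      return(data.frame(length = len, n_occ = length(occ_gap),
                        starts0 = paste(occ_gap - 1L, collapse = ","),
                        seq = rec$seq, tandem = FALSE,
                        stringsAsFactors = FALSE))
    }
    ## tandem array: >= 2 non-overlapping copies allowed to abut (gap 0)
    occ_abut <- select_nonoverlapping(occ, len, min_gap = 0L)
    if (length(occ_abut) >= 2) {
      return(data.frame(length = len, n_occ = length(occ_abut),
                        starts0 = paste(occ_abut - 1L, collapse = ","),
                        seq = rec$seq, tandem = TRUE,
                        stringsAsFactors = FALSE))
    }
    NULL
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(list(repeats = empty_repeats(),
                                tandem = empty_repeats()))
  reps <- tab[!tab$tandem, , drop = FALSE]
  ## suppress nested sub-repeats: all occurrences inside a longer repeat's
  ## occurrences
  if (nrow(reps) > 1) {
    ord <- order(-reps$length)
    reps <- reps[ord, , drop = FALSE]
    spans <- lapply(seq_len(nrow(reps)), function(i) {
      st <- as.integer(strsplit(reps$starts0[i], ",")[[1]])
      cbind(st, st + reps$length[i])
    })
    nested <- rep(FALSE, nrow(reps))
    for (i in seq_len(nrow(reps))[-1]) {
      for (j in seq_len(i - 1)) {
        if (nested[j]) next
        inside <- apply(spans[[i]], 1, function(sp)
          any(spans[[j]][, 1] <= sp[1] & sp[2] <= spans[[j]][, 2]))
        if (all(inside)) { nested[i] <- TRUE; break }
      }
    }
    reps <- reps[!nested, , drop = FALSE]
  }
  tandem <- tab[tab$tandem, , drop = FALSE]
  reps <- reps[order(-reps$length), setdiff(names(reps), "tandem"), drop = FALSE]
  tandem <- tandem[order(-tandem$length), setdiff(names(tandem), "tandem"),
                   drop = FALSE]
  rownames(reps) <- rownames(tandem) <- NULL
  list(repeats = reps, tandem = tandem)
}

empty_repeats <- function() {
  data.frame(length = integer(0), n_occ = integer(0), starts0 = character(0),
             seq = character(0))
}

## ---- stem-loops -----------------------------------------------------------

DNA_PAIR_OK <- local({
  b <- c("A", "C", "G", "T")
  ok <- matrix(FALSE, 4, 4, dimnames = list(b, b))
  ok["A", "T"] <- ok["T", "A"] <- ok["G", "C"] <- ok["C", "G"] <- TRUE
  ok["G", "T"] <- ok["T", "G"] <- TRUE   # G-T wobble allowed
  ok
})

#' Find stem-loop structures (inverted repeats)
#'
#' Enumerates all maximal perfect hairpins: a loop of `loop_range` unpaired
#' nucleotides closed by a stem of >= `min_stem` consecutive pairs
#' (Watson-Crick plus G-T wobble, zero mismatches). A candidate loop whose
#' innermost flanking bases could still pair (with the shrunken loop staying
#' within range) is subsumed by the longer-stem hairpin and not reported
#' twice. Results are ranked by stem length, ties broken by 3'-proximity.
#'
#' @param seq nucleotide string.
#' @param min_stem minimum stem length in base pairs (default 6).
#' @param loop_range `c(min, max)` loop length in nt (default `c(3, 20)`).
#' @param flank_motifs also check for the conserved `TATA` box 5' of the stem
#'   and a `G(A)nT` motif 3' of it, reported per hairpin.
#' @return data.frame: `start0`, `end0`, `stem`, `loop`, `loop_start0`,
#'   `tata_5p`, `gant_3p`.
#' @export
find_stem_loops <- function(seq, min_stem = 6, loop_range = c(3, 20),
                            flank_motifs = TRUE) {
  s <- toupper(seq)
  ch <- seq_chars(s)
  n <- length(ch)
  pair_ok <- function(i, j) {
    a <- ch[i]; b <- ch[j]
    a %in% DNA_BASES && b %in% DNA_BASES && DNA_PAIR_OK[a, b]
  }
  out <- list()
  for (a in seq_len(n)) {
    for (l in seq(loop_range[1], loop_range[2])) {
      b <- a + l - 1L                 # loop spans a..b
      if (b + 1L > n || a - 1L < 1L) next
      ## skip loops that could shrink further (inner bases pair and the
      ## shrunken loop is still valid)
      if (l - 2L >= loop_range[1] && pair_ok(a, b)) next
      if (!pair_ok(a - 1L, b + 1L)) next
      k <- 0L
      while (a - 1L - k >= 1L && b + 1L + k <= n &&
             pair_ok(a - 1L - k, b + 1L + k)) k <- k + 1L
      if (k >= min_stem) {
        start1 <- a - k; end1 <- b + k   # 1-based inclusive hairpin span
        tata <- gant <- NA
        if (flank_motifs) {
          up <- substr(s, max(1, start1 - 6), start1 - 1)
          down <- substr(s, end1 + 1, min(n, end1 + 8))
          tata <- grepl("TATA", up, fixed = TRUE)
          gant <- grepl("^.{0,2}GA+T", down)
        }
        out[[length(out) + 1]] <- data.frame(
          start0 = start1 - 1L, end0 = end1, stem = k, loop = l,
          loop_start0 = a - 1L, tata_5p = tata, gant_3p = gant)
      }
    }
  }
  if (!length(out))
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      stem = integer(0), loop = integer(0),
                      loop_start0 = integer(0), tata_5p = logical(0),
                      gant_3p = logical(0)))
  tab <- unique(do.call(rbind, out))
  tab <- tab[order(-tab$stem, -tab$end0), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

## ---- combined report ------------------------------------------------------

#' Structural-element report for a genome's control region
#'
#' Runs the poly-T, poly-A, (TA)n, stem-loop and macro-repeat finders on the
#' (annotated or inferred) control region and flags the presence of the four
#' conserved elements. Elements are ordered by position.
#'
#' @param g an [annotated_genome()].
#' @param min_homopolymer,min_ta_units,min_repeat,min_stem,loop_range finder
#'   thresholds (defaults 10, 3, 30, 6, c(3, 20)).
#' @return list of class `cr_report`: `region` (zero-based half-open genome
#'   span), `elements` (data.frame ordered by position, with both CR-relative
#'   and genome coordinates), `repeats`, `tandem`, `present` (named logical:
#'   polyT, TA_stretch, polyA, stem_loop).
#' @export
cr_report <- function(g, min_homopolymer = 10, min_ta_units = 3,
                      min_repeat = 30, min_stem = 6, loop_range = c(3, 20)) {
  if (!any(g$features$type == "control_region")) g <- infer_control_region(g)
  f <- g$features[g$features$type == "control_region", ][1, ]
  cr <- extract_region(g, f)
  polyT <- find_homopolymer(cr, "T", min_homopolymer)
  polyA <- find_homopolymer(cr, "A", min_homopolymer)
  ta <- find_ta_stretch(cr, min_ta_units)
  sl <- find_stem_loops(cr, min_stem, loop_range)
  mr <- find_macro_repeats(cr, min_repeat)
  sl_el <- if (nrow(sl)) cr_element("stem_loop", sl$start0, sl$end0,
                                    sprintf("stem=%d,loop=%d", sl$stem, sl$loop))
    else empty_elements()
  mr_el <- if (nrow(mr$repeats))
    cr_element("macro_repeat",
               vapply(strsplit(mr$repeats$starts0, ","),
                      function(x) as.integer(x[1]), integer(1)),
               vapply(strsplit(mr$repeats$starts0, ","),
                      function(x) as.integer(x[1]), integer(1)) +
                 mr$repeats$length,
               sprintf("copies=%s,len=%d", mr$repeats$starts0,
                       mr$repeats$length))
    else empty_elements()
  elements <- rbind(polyT, polyA, ta, sl_el, mr_el)
  elements <- elements[order(elements$start0), , drop = FALSE]
  rownames(elements) <- NULL
  elements$genome_start0 <- (f$start0 + elements$start0) %% nchar(g$sequence)
  elements$genome_end0 <- elements$genome_start0 + elements$length
  out <- list(region = c(f$start0, f$end0, wrap = f$wrap_end0),
              elements = elements, repeats = mr$repeats, tandem = mr$tandem,
              present = c(polyT = nrow(polyT) > 0,
                          TA_stretch = nrow(ta) > 0,
                          polyA = nrow(polyA) > 0,
                          stem_loop = nrow(sl) > 0))
  class(out) <- "cr_report"
  out
}

#' @export
print.cr_report <- function(x, ...) {
  cat(sprintf("<cr_report> %d elements; present: %s\n", nrow(x$elements),
              paste(names(x$present)[x$present], collapse = ", ")))
  invisible(x)
}

#' Write control-region elements as BED
#'
#' @param report a [cr_report()].
#' @param path output path.
#' @param chrom chromosome/record name.
#' @param coordinates `"region"` (control-region-relative) or `"genome"`.
#' @export
write_cr_bed <- function(report, path, chrom = "CR",
                         coordinates = c("region", "genome")) {
  coordinates <- match.arg(coordinates)
  e <- report$elements
  bed <- if (coordinates == "region")
    data.frame(chrom, e$start0, e$end0, e$kind)
  else data.frame(chrom, e$genome_start0, e$genome_end0, e$kind)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
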