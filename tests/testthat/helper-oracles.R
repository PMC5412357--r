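# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs. These deliberately take naive routes:
# exhaustive enumeration and character-by-character checks.

# ---- exhaustive pairwise global alignment ---------------------------------
# Enumerates every global alignment of a and b and scores it with
# match +1, mismatch 0, gap -2, terminal gaps free. Returns the maximum
# score and the set of optimal alignments (as rbind-ed 2-row matrices).
oracle_best_alignments <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  results <- list()
  recurse <- function(i, j, ra, rb) {
    if (i > length(av) && j > length(bv)) {
      results[[length(results) + 1L]] <<- rbind(ra, rb)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      recurse(i + 1, j + 1, c(ra, av[i]), c(rb, bv[j]))
    if (i <= length(av)) recurse(i + 1, j, c(ra, av[i]), c(rb, "-"))
    if (j <= length(bv)) recurse(i, j + 1, c(ra, "-"), c(rb, bv[j]))
  }
  recurse(1, 1, character(0), character(0))
  scores <- vapply(results, score_alignment_rows, numeric(1))
  best <- max(scores)
  list(score = best, alignments = results[scores == best])
}

# score a 2..n-row alignment column-wise under the same scheme (gaps in a
# column are scored -2 against each non-gap residue unless terminal; each
# pair of matching residues scores +1 within the column, counted pairwise
# for 2 rows only here)
score_alignment_rows <- function(m) {
  stopifnot(nrow(m) == 2)
  n <- ncol(m)
  # identify terminal gap runs per row
  terminal <- matrix(FALSE, 2, n)
  for (r in 1:2) {
    k <- 1
    while (k <= n && m[r, k] == "-") { terminal[r, k] <- TRUE; k <- k + 1 }
    k <- n
    while (k >= 1 && m[r, k] == "-") { terminal[r, k] <- TRUE; k <- k - 1 }
  }
  s <- 0
  for (k in seq_len(n)) {
    x <- m[1, k]; y <- m[2, k]
    if (x == "-" || y == "-") {
      if (!(terminal[1, k] || terminal[2, k])) s <- s - 2
    } else if (x == y) s <- s + 1
  }
  s
}

# ---- stem pair-change classification --------------------------------------
# Re-derives the category from first principles, structured differently from
# the package implementation (explicit property flags, no early returns).
oracle_classify <- function(a, b) {
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  a1 <- substr(a, 1, 1); a2 <- substr(a, 2, 2)
  b1 <- substr(b, 1, 1); b2 <- substr(b, 2, 2)
  equal <- a == b
  ca <- a %in% canon; cb <- b %in% canon
  nchanged <- sum(c(a1 != b1, a2 != b2))
  mirrored <- (a1 == b2) && (a2 == b1)
  if (equal) "identity"
  else if (ca && cb && nchanged == 1) "hemi_cbc"
  else if (ca && cb && nchanged == 2 && mirrored) "mbc"
  else if (ca && cb && nchanged == 2) "cbc"
  else if (xor(ca, cb)) "rbc"
  else "nrbc"
}

# ---- macro repeats --------------------------------------------------------
# Brute force over all substring lengths: finds every flank-maximal repeated
# substring via naive string search, then applies the non-tandem /
# nested-suppression rules by direct checking. Returns the same list shape
# as find_macro_repeats but with occurrence existence checked exhaustively.
oracle_macro_repeats <- function(s, min_len) {
  s <- toupper(s); n <- nchar(s)
  found <- list()
  for (L in min_len:(n - 1)) {
    any_dup <- FALSE
    seen <- new.env()
    for (i in 1:(n - L + 1)) {
      v <- substr(s, i, i + L - 1)
      if (is.null(seen[[v]])) seen[[v]] <- i else seen[[v]] <- c(seen[[v]], i)
    }
    for (v in ls(seen)) {
      occ <- seen[[v]]
      if (length(occ) < 2) next
      any_dup <- TRUE
      lmax <- any(occ == 1) ||
        length(unique(substr(rep(s, length(occ)), occ - 1, occ - 1))) > 1
      rmax <- any(occ + L - 1 == n) ||
        length(unique(substr(rep(s, length(occ)), occ + L, occ + L))) > 1
      if (lmax && rmax) found[[length(found) + 1L]] <- list(seq = v, occ = occ)
    }
    if (!any_dup) break
  }
  # keep those with >= 2 mutually non-overlapping, gap >= 1 occurrences
  # (existence checked over all occurrence pairs)
  keep <- Filter(function(rec) {
    occ <- sort(rec$occ); L <- nchar(rec$seq)
    any(outer(occ, occ, function(x, y) y >= x + L + 1))
  }, found)
  # suppress repeats nested inside a longer kept repeat's occurrences
  lens <- vapply(keep, function(r) nchar(r$seq), integer(1))
  nested <- rep(FALSE, length(keep))
  for (i in seq_along(keep)) {
    for (j in seq_along(keep)) {
      if (i == j || lens[j] <= lens[i] || nested[j]) next
      inside <- all(vapply(keep[[i]]$occ, function(p)
        any(keep[[j]]$occ <= p &
              p + lens[i] <= keep[[j]]$occ + lens[j]), logical(1)))
      if (inside) { nested[i] <- TRUE; break }
    }
  }
  keep <- keep[!nested]
  data.frame(seq = vapply(keep, `[[`, character(1), "seq"),
             length = vapply(keep, function(r) nchar(r$seq), integer(1)),
             stringsAsFactors = FALSE)
}

# ---- stem-loops -----------------------------------------------------------
# Checks every (start, stem, loop) triple directly against the documented
# hairpin definition.
oracle_stem_loops <- function(s, min_stem, loop_range, max_stem = 30) {
  ch <- strsplit(toupper(s), "")[[1]]; n <- length(ch)
  pairs_ok <- function(i, j) {
    key <- paste0(ch[i], ch[j])
    key %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  out <- list()
  for (i in seq_len(n)) {
    for (l in loop_range[1]:loop_range[2]) {
      for (k in min_stem:max_stem) {
        jend <- i + 2 * k + l - 1
        if (jend > n) break
        ok <- TRUE
        for (t in 0:(k - 1)) {
          if (!pairs_ok(i + t, jend - t)) { ok <- FALSE; break }
        }
        if (!ok) next  # a longer stem shifts jend, so keep scanning k
        # outward maximality
        if (i > 1 && jend < n && pairs_ok(i - 1, jend + 1)) next
        # loop not shrinkable
        a <- i + k; b <- jend - k
        if (l - 2 >= loop_range[1] && pairs_ok(a, b)) next
        # stem of exactly k adjacent to loop: inner position must be loop
        out[[length(out) + 1L]] <- data.frame(start0 = i - 1L, end0 = jend,
                                              stem = k, loop = l)
      }
    }
  }
  if (!length(out)) return(data.frame(start0 = integer(0), end0 = integer(0),
                                      stem = integer(0), loop = integer(0)))
  unique(do.call(rbind, out))
}

# ---- RSCU -----------------------------------------------------------------
# Recomputes counts and family totals by direct looping over the code table.
oracle_rscu <- function(codons) {
  code <- Biostrings::getGeneticCode("SGC4")
  sense <- names(code)[code != "*"]
  out <- data.frame(codon = sense, amino_acid = code[sense],
                    count = 0, RSCU = NA_real_, stringsAsFactors = FALSE)
  for (cd in codons) {
    i <- which(out$codon == cd)
    if (length(i)) out$count[i] <- out$count[i] + 1
  }
  for (aa in unique(out$amino_acid)) {
    idx <- which(out$amino_acid == aa)
    tot <- sum(out$count[idx])
    if (tot > 0) out$RSCU[idx] <- out$count[idx] * length(idx) / tot
  }
  out[order(out$amino_acid, out$codon), ]
}

# deterministic random DNA string
random_dna <- function(n, seed, prob = c(0.3, 0.2, 0.2, 0.3)) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
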