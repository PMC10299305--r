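# Independent brute-force oracles used to pin down the string-algorithm
# contracts. These are written as plainly as possible (nested loops, direct
# substring comparisons, textbook DP) and share no code path with the
# package implementations they check.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_protein_str <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Longest common exact substring via the classic suffix DP
# M[i,j] = (a[i]==b[j]) * (1 + M[i+1,j+1]); N never matches.
# Ties: longest, then lexicographically smallest substring, then smaller
# posA, then smaller posB. Returns 0-based positions.
oracle_lcs_oriented <- function(a, b) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  below <- integer(m + 1L)  # row i+1, padded
  best <- list(length = 0L, posA = 0L, posB = 0L, sub = "")
  for (i in n:1) {
    eq <- av[i] == bv & av[i] != "N"
    row <- integer(m + 1L)
    row[1:m] <- ifelse(eq, 1L + below[2:(m + 1L)], 0L)
    for (j in 1:m) {
      len <- row[j]
      if (len < best$length || len == 0L) next
      sub <- substr(a, i, i + len - 1L)
      if (len > best$length || sub < best$sub ||
          (sub == best$sub && (i - 1L < best$posA ||
                               (i - 1L == best$posA && j - 1L < best$posB)))) {
        best <- list(length = len, posA = i - 1L, posB = j - 1L, sub = sub)
      }
    }
    below <- row
  }
  best
}

# Full contract of longest_common_exact incl. the orientation preference
# (forward wins unless revcomp is longer or lexicographically smaller).
oracle_lcs <- function(a, b, consider_revcomp = TRUE) {
  fw <- oracle_lcs_oriented(a, b)
  fw$orientation <- "forward"
  best <- fw
  if (consider_revcomp) {
    rc <- oracle_lcs_oriented(a, oracle_revcomp(b))
    rc$posB <- nchar(b) - rc$posB - rc$length
    rc$orientation <- "revcomp"
    if (rc$length > best$length ||
        (rc$length == best$length && rc$length > 0L && rc$sub < best$sub))
      best <- rc
  }
  best
}

# Textbook affine-gap Smith-Waterman (three matrices, plain loops).
# A gap of length g costs open + g * extend. Score only, clamped at 0.
oracle_sw_score <- function(q, t, mat, open = 11, extend = 1) {
  n <- nchar(q); m <- nchar(t)
  qv <- strsplit(q, "")[[1]]; tv <- strsplit(t, "")[[1]]
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)  # gap in query (consumes t)
  F <- matrix(NEG, n + 1L, m + 1L)  # gap in target (consumes q)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - extend, E[i, j - 1L] - extend)
      F[i, j] <- max(H[i - 1L, j] - open - extend, F[i - 1L, j] - extend)
      diag <- H[i - 1L, j - 1L] + mat[qv[i - 1L], tv[j - 1L]]
      H[i, j] <- max(0, diag, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# All maximal even-length perfect palindromes (revcomp-invariant substrings)
# by exhaustive enumeration. 0-based positions.
oracle_palindromes <- function(s, min_len = 6L) {
  n <- nchar(s)
  is_pal <- function(pos, len) {  # pos 1-based
    if (pos < 1L || pos + len - 1L > n) return(FALSE)
    sub <- substr(s, pos, pos + len - 1L)
    !grepl("N", sub, fixed = TRUE) && sub == oracle_revcomp(sub)
  }
  out <- list()
  for (len in seq(min_len, n, by = 2L)) {
    for (pos in 1:(n - len + 1L)) {
      if (is_pal(pos, len) && !is_pal(pos - 1L, len + 2L))
        out[[length(out) + 1L]] <- c(pos = pos - 1L, length = len)
    }
  }
  if (!length(out)) return(data.frame(pos = integer(), length = integer()))
  res <- as.data.frame(do.call(rbind, out))
  res[order(res$pos, res$length), , drop = FALSE]
}

# All k-mer position pairs (direct / inverted) by all-pairs comparison.
oracle_repeat_pairs <- function(s, k = 9L) {
  n <- nchar(s)
  out <- list()
  if (n >= k) {
    for (i in 1:(n - k + 1L)) {
      ki <- substr(s, i, i + k - 1L)
      if (grepl("N", ki, fixed = TRUE)) next
      for (j in i:(n - k + 1L)) {
        if (j == i) next
        kj <- substr(s, j, j + k - 1L)
        if (grepl("N", kj, fixed = TRUE)) next
        if (ki == kj)
          out[[length(out) + 1L]] <- data.frame(
            unit_length = k, pos1 = i - 1L, pos2 = j - 1L,
            orientation = "direct", stringsAsFactors = FALSE)
        if (kj == oracle_revcomp(ki))
          out[[length(out) + 1L]] <- data.frame(
            unit_length = k, pos1 = i - 1L, pos2 = j - 1L,
            orientation = "inverted", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(unit_length = integer(), pos1 = integer(),
                      pos2 = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$pos1, res$pos2, res$orientation), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# All maximal exact matches >= min_len between a and b (one orientation),
# by scanning every (i, j) pair that starts a match run.
oracle_maximal_matches <- function(a, b, min_len) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  eqc <- function(x, y) x == y && x != "N" && y != "N"
  out <- list()
  for (i in 1:n) {
    for (j in 1:m) {
      if (!eqc(av[i], bv[j])) next
      if (i > 1L && j > 1L && eqc(av[i - 1L], bv[j - 1L])) next  # not a run start
      len <- 0L
      while (i + len <= n && j + len <= m && eqc(av[i + len], bv[j + len]))
        len <- len + 1L
      if (len >= min_len)
        out[[length(out) + 1L]] <- data.frame(length = len, posA = i - 1L,
                                              posB = j - 1L)
    }
  }
  if (!length(out))
    return(data.frame(length = integer(), posA = integer(), posB = integer()))
  do.call(rbind, out)
}

oracle_shared_repeats <- function(a, b, min_len, include_inverted = TRUE) {
  d <- oracle_maximal_matches(a, b, min_len)
  if (nrow(d)) d$orientation <- "direct"
  out <- d
  if (include_inverted) {
    inv <- oracle_maximal_matches(a, oracle_revcomp(b), min_len)
    if (nrow(inv)) {
      inv$posB <- nchar(b) - inv$posB - inv$length
      inv$orientation <- "inverted"
      out <- rbind(out, inv)
    }
  }
  if (nrow(out) == 0L)
    return(data.frame(length = integer(), posA = integer(), posB = integer(),
                      orientation = character(), stringsAsFactors = FALSE))
  out <- out[order(out$posA, out$posB, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Tandem arrays: plain-loop periodicity scan at the requested period, then
# re-expression of each region at its smallest period (the same contract as
# tandem_scan, independently coded).
oracle_tandem <- function(s, unit_len = 5L, min_copies = 2L) {
  n <- nchar(s)
  v <- strsplit(s, "")[[1]]
  p <- unit_len
  eqc <- function(i, q) v[i] == v[i + q] && v[i] != "N" && v[i + q] != "N"
  out <- list(); seen <- character()
  i <- 1L
  while (i <= n - p) {
    if (!eqc(i, p)) { i <- i + 1L; next }
    j <- i
    while (j <= n - p && eqc(j, p)) j <- j + 1L
    rs <- i; re <- j - 1L + p
    i <- j + 1L
    if ((re - rs + 1L) %/% p < min_copies) next
    len <- re - rs + 1L
    q <- len
    for (cand in 1:(len - 1L)) {
      ok <- TRUE
      for (x in rs:(re - cand)) if (!eqc(x, cand)) { ok <- FALSE; break }
      if (ok) { q <- cand; break }
    }
    while (rs > 1L && eqc(rs - 1L, q)) rs <- rs - 1L
    while (re < n && v[re + 1L] != "N" && v[re + 1L] == v[re + 1L - q]) re <- re + 1L
    copies <- (re - rs + 1L) %/% q
    if (copies < min_copies) next
    key <- paste(rs, q)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- data.frame(
      unit = substr(s, rs, rs + q - 1L), unit_length = q, copies = copies,
      start = rs - 1L, purity = 1.0, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(unit = character(), unit_length = integer(),
                      copies = integer(), start = integer(),
                      purity = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Six-frame ORF scan: enumerate every start codon, walk in frame to the
# first stop (codons containing N break the walk), keep the earliest start
# per (strand, frame, stop). Forward-strand 0-based half-open coordinates.
oracle_orfs <- function(s, min_nt = 150L,
                        start_codons = c("ATG", "GTG", "TTG")) {
  L <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") s else oracle_revcomp(s)
    for (p0 in 0:(L - 3L)) {
      cod <- substr(w, p0 + 1L, p0 + 3L)
      if (!(cod %in% start_codons) || grepl("N", cod, fixed = TRUE)) next
      q <- p0 + 3L
      stop_at <- NA
      while (q + 3L <= L) {
        c2 <- substr(w, q + 1L, q + 3L)
        if (grepl("N", c2, fixed = TRUE)) break
        if (c2 %in% stops) { stop_at <- q; break }
        q <- q + 3L
      }
      if (is.na(stop_at)) next
      out[[length(out) + 1L]] <- data.frame(
        strand = strand, frame = p0 %% 3L, lstart = p0, lend = stop_at + 3L)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  d <- do.call(rbind, out)
  keep <- do.call(rbind, lapply(
    split(d, list(d$strand, d$frame, d$lend), drop = TRUE),
    function(g) g[which.min(g$lstart), ]))
  keep <- keep[keep$lend - keep$lstart >= min_nt, , drop = FALSE]
  res <- data.frame(
    start = ifelse(keep$strand == "+", keep$lstart, L - keep$lend),
    end = ifelse(keep$strand == "+", keep$lend, L - keep$lstart),
    strand = keep$strand, stringsAsFactors = FALSE)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
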