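#' Detect adjacent-ORF programmed frameshift candidates
#'
#' Finds same-strand ORF pairs in which the downstream ORF's start codon
#' lies inside the upstream ORF (before its stop codon) in a reading frame
#' offset by +1 or -1 — the overlap architecture of a programmed ribosomal
#' frameshift. For each candidate the junction window is scanned for the
#' three evidence classes: slippery heptamers (`XXXYYYN`), perfect even
#' palindromes, and short direct/inverted repeat pairs. The putative fusion
#' protein is built by translating the upstream frame to the shift point
#' (the last upstream-frame codon boundary before the downstream start) and
#' the downstream frame thereafter.
#'
#' @param orfs ORF table from [find_orfs()] called on `seq`.
#' @param seq the DNA sequence the ORFs were called on.
#' @param window_w half-width (nt) of the evidence window around the junction.
#' @param slippery_min_len,palindrome_min_len,repeat_k evidence scan
#'   parameters (see [scan_slippery()], [find_palindromes()],
#'   [find_short_repeats()]).
#' @param weights evidence weights passed to [score_evidence()].
#' @return a list of candidates (class `gta_frameshift_set`). Each candidate
#'   holds `upstream`/`downstream` ORF rows, `shift` (`"+1"` or `"-1"`),
#'   `junction` (forward-strand, 0-based), `window` (forward-strand bounds),
#'   evidence tables `slippery`, `palindromes`, `repeats` (coding-strand
#'   0-based positions), `fusion_protein` and `evidence_score`.
#' @export
detect_fusion_candidates <- function(orfs, seq, window_w = 60L,
                                     palindrome_min_len = 6L, repeat_k = 9L,
                                     weights = c(slippery = 1, palindrome = 1,
                                                 inverted = 1, direct = 1)) {
  L <- nchar(seq)
  out <- list()
  if (nrow(orfs) < 2L) return(structure(out, class = "gta_frameshift_set"))
  for (i in seq_len(nrow(orfs))) {
    for (j in seq_len(nrow(orfs))) {
      if (i == j) next
      u <- orfs[i, ]; v <- orfs[j, ]
      if (u$strand != v$strand) next
      # strand-local coordinates (transcription direction)
      if (u$strand == "+") {
        lu <- c(u$start, u$end); lv <- c(v$start, v$end)
      } else {
        lu <- c(L - u$end, L - u$start); lv <- c(L - v$end, L - v$start)
      }
      # downstream start codon strictly inside upstream ORF, before its stop
      if (!(lv[1] > lu[1] && lv[1] < lu[2] - 3L)) next
      off <- (lv[1] - lu[1]) %% 3L
      if (off == 0L) next
      shift <- if (off == 1L) "+1" else "-1"
      s_loc <- if (u$strand == "+") seq else revcomp(seq)
      junction_loc <- lv[1]
      ws <- max(0L, junction_loc - window_w)
      we <- min(L, junction_loc + window_w)
      win <- substr(s_loc, ws + 1L, we)
      slip <- scan_slippery(win)
      pal <- find_palindromes(win, min_len = palindrome_min_len)
      reps <- find_short_repeats(win, k = repeat_k)
      # shift point: last upstream-frame codon boundary before downstream start
      sp <- lu[1] + 3L * ((junction_loc - lu[1]) %/% 3L)
      up_part <- if (sp > lu[1]) {
        translate_orf(paste0(substr(s_loc, lu[1] + 1L, sp), "TAA"))
      } else ""
      down_prot <- translate_orf(substr(s_loc, lv[1] + 1L, lv[2]))
      fusion <- paste0(up_part, down_prot)
      junction_fwd <- if (u$strand == "+") junction_loc else L - junction_loc - 3L
      cand <- list(upstream = u, downstream = v, shift = shift,
                   junction = junction_fwd, strand = u$strand,
                   window = c(start = ws, end = we),
                   slippery = slip, palindromes = pal, repeats = reps,
                   fusion_protein = fusion)
      cand$evidence_score <- score_evidence(cand, weights)
      out[[length(out) + 1L]] <- cand
    }
  }
  structure(out, class = "gta_frameshift_set")
}

#' @export
print.gta_frameshift_set <- function(x, ...) {
  cat(sprintf("%d frameshift candidate(s)\n", length(x)))
  for (cand in x) {
    cat(sprintf("  %s shift at %d (%s strand): %d slippery, %d palindrome(s), %d repeat pair(s); fusion %d aa; score %.1f\n",
                cand$shift, cand$junction, cand$strand, nrow(cand$slippery),
                nrow(cand$palindromes), nrow(cand$repeats),
                nchar(cand$fusion_protein), cand$evidence_score))
  }
  invisible(x)
}

#' Scan for slippery heptamers
#'
#' Reports every position whose heptamer matches the `XXXYYYN` pattern: a
#' homotrinucleotide run of base X, a homotrinucleotide run of a different
#' base Y, then any base. `N` in the sequence never matches.
#'
#' @param window_seq DNA sequence to scan.
#' @return `data.frame` with 0-based `pos` and the matched `heptamer`.
#' @export
#' @examples
#' scan_slippery("GGGAAATTTTCCC")  # AAATTTT at offset 3
scan_slippery <- function(window_seq) {
  n <- nchar(window_seq)
  empty <- data.frame(pos = integer(), heptamer = character(),
                      stringsAsFactors = FALSE)
  if (n < 7L) return(empty)
  v <- .chars(window_seq)
  i <- seq_len(n - 6L)
  ok <- v[i] %in% c("A", "C", "G", "T") &
    v[i] == v[i + 1L] & v[i] == v[i + 2L] &
    v[i + 3L] %in% c("A", "C", "G", "T") &
    v[i + 3L] == v[i + 4L] & v[i + 3L] == v[i + 5L] &
    v[i] != v[i + 3L] &
    v[i + 6L] %in% c("A", "C", "G", "T")
  hit <- i[ok]
  if (length(hit) == 0L) return(empty)
  data.frame(pos = hit - 1L,
             heptamer = substring(window_seq, hit, hit + 6L),
             stringsAsFactors = FALSE)
}

#' Find maximal even-length palindromes
#'
#' A palindrome here is a substring equal to its own reverse complement
#' (perfect, even-length). Each reported palindrome is maximal: it cannot be
#' extended symmetrically in either direction. `N` never matches.
#'
#' @param window_seq DNA sequence to scan.
#' @param min_len minimum palindrome length; must be even and at least 4.
#' @return `data.frame` with 0-based `pos` and `length`.
#' @export
#' @examples
#' find_palindromes("AAGAATTCAA")  # GAATTC at offset 2
find_palindromes <- function(window_seq, min_len = 6L) {
  if (min_len %% 2L != 0L || min_len < 4L)
    stop("min_len must be even and >= 4", call. = FALSE)
  n <- nchar(window_seq)
  empty <- data.frame(pos = integer(), length = integer())
  if (n < min_len) return(empty)
  v <- .chars(window_seq)
  cmp <- .chars(chartr("ACGTN", "TGCAN", window_seq))
  res <- list()
  for (c0 in seq_len(n - 1L)) {      # center between c0 and c0+1
    l <- c0; r <- c0 + 1L
    while (l >= 1L && r <= n && v[l] != "N" && v[l] == cmp[r]) {
      l <- l - 1L; r <- r + 1L
    }
    len <- r - l - 1L
    if (len >= min_len)
      res[[length(res) + 1L]] <- c(pos = l, length = len)  # l is 0-based start
  }
  if (!length(res)) return(empty)
  out <- as.data.frame(do.call(rbind, res))
  out[order(out$pos), , drop = FALSE]
}

#' Find short repeat pairs
#'
#' Reports all position pairs `(i, j)`, `i < j`, at which the two k-mers are
#' identical (direct) or reverse complements of one another (inverted).
#' Overlapping pairs are permitted. K-mers containing `N` never match.
#'
#' @param window_seq DNA sequence to scan.
#' @param k repeat unit length; must be at least 5.
#' @return `data.frame` with `unit_length`, 0-based `pos1` and `pos2`, and
#'   `orientation` (`"direct"` or `"inverted"`).
#' @export
find_short_repeats <- function(window_seq, k = 9L) {
  if (k < 5L) stop("k must be >= 5", call. = FALSE)
  n <- nchar(window_seq)
  empty <- data.frame(unit_length = integer(), pos1 = integer(),
                      pos2 = integer(), orientation = character(),
                      stringsAsFactors = FALSE)
  if (n < k) return(empty)
  starts <- seq_len(n - k + 1L)
  km <- substring(window_seq, starts, starts + k - 1L)
  valid <- !grepl("N", km, fixed = TRUE)
  res <- list()
  by_kmer <- split(starts[valid], km[valid])
  for (positions in by_kmer) {
    if (length(positions) < 2L) next
    pr <- utils::combn(positions, 2L)
    res[[length(res) + 1L]] <- data.frame(
      unit_length = k, pos1 = pr[1, ] - 1L, pos2 = pr[2, ] - 1L,
      orientation = "direct", stringsAsFactors = FALSE)
  }
  for (u in names(by_kmer)) {
    rc <- revcomp(u)
    if (u >= rc) next  # visit each {kmer, revcomp} pair once
    if (!is.null(by_kmer[[rc]])) {
      pr <- expand.grid(p = by_kmer[[u]], q = by_kmer[[rc]])
      res[[length(res) + 1L]] <- data.frame(
        unit_length = k, pos1 = pmin(pr$p, pr$q) - 1L,
        pos2 = pmax(pr$p, pr$q) - 1L,
        orientation = "inverted", stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$pos1, out$pos2, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally frameshift evidence into a transparent score
#'
#' The score is a weighted count of evidence items
#' (`w_s * slippery + w_p * palindromes + w_i * inverted pairs +
#' w_d * direct pairs`), reported alongside the raw counts, never alone. It
#' is a tally, not a calibrated statistic.
#'
#' @param candidate a frameshift candidate (see [detect_fusion_candidates()]).
#' @param weights named non-negative weights `slippery`, `palindrome`,
#'   `inverted`, `direct`.
#' @return numeric score.
#' @export
score_evidence <- function(candidate, weights = c(slippery = 1, palindrome = 1,
                                                  inverted = 1, direct = 1)) {
  w <- weights[c("slippery", "palindrome", "inverted", "direct")]
  if (anyNA(w)) stop("weights must name slippery, palindrome, inverted, direct",
                     call. = FALSE)
  if (any(w < 0)) stop("negative evidence weight", call. = FALSE)
  counts <- c(slippery = nrow(candidate$slippery),
              palindrome = nrow(candidate$palindromes),
              inverted = sum(candidate$repeats$orientation == "inverted"),
              direct = sum(candidate$repeats$orientation == "direct"))
  unname(sum(w * counts))
}
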