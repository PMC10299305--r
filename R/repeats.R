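#' Maximal exact repeats shared by two sequences
#'
#' Enumerates all maximal exact matches of at least `min_len` nucleotides
#' between `a` and `b`, optionally also between `a` and the reverse
#' complement of `b`. Maximal means the match can be extended in neither
#' direction. Matching is seeded with shared `min_len`-mers and resolved per
#' diagonal, so every reported hit re-verifies by direct substring
#' comparison. `N` never matches.
#'
#' @param a,b non-empty DNA sequences.
#' @param min_len minimum hit length; values below 8 are rejected (a guard
#'   against hit explosion on short words).
#' @param include_inverted also report reverse-complement matches.
#' @return `data.frame` with `length`, 0-based `posA`, `posB` (forward-strand
#'   position in `b`), `orientation` (`"direct"`/`"inverted"`) and `seq` (the
#'   matched sequence as it reads in `a`), sorted by `posA` then `posB`.
#' @export
shared_exact_repeats <- function(a, b, min_len = 50L, include_inverted = TRUE) {
  if (min_len < 8L) stop("min_len below 8 rejected (hit explosion guard)", call. = FALSE)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  .check_dna_alphabet(a, "a"); .check_dna_alphabet(b, "b")
  direct <- .maximal_matches(a, b, min_len)
  if (nrow(direct)) direct$orientation <- "direct"
  out <- direct
  if (include_inverted) {
    inv <- .maximal_matches(a, revcomp(b), min_len)
    if (nrow(inv)) {
      inv$posB <- nchar(b) - inv$posB - inv$length
      inv$orientation <- "inverted"
      out <- rbind(out, inv)
    }
  }
  if (nrow(out) == 0L)
    return(data.frame(length = integer(), posA = integer(), posB = integer(),
                      orientation = character(), seq = character(),
                      stringsAsFactors = FALSE))
  out$seq <- substring(a, out$posA + 1L, out$posA + out$length)
  out <- out[order(out$posA, out$posB, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("length", "posA", "posB", "orientation", "seq")]
}

## All maximal exact matches >= min_len between a and b (as oriented).
.maximal_matches <- function(a, b, min_len) {
  n <- nchar(a); m <- nchar(b)
  empty <- data.frame(length = integer(), posA = integer(), posB = integer())
  if (n < min_len || m < min_len) return(empty)
  k <- min_len
  sa <- seq_len(n - k + 1L); sb <- seq_len(m - k + 1L)
  ka <- substring(a, sa, sa + k - 1L)
  kb <- substring(b, sb, sb + k - 1L)
  va <- sa[!grepl("N", ka, fixed = TRUE)]
  vb <- sb[!grepl("N", kb, fixed = TRUE)]
  if (!length(va) || !length(vb)) return(empty)
  idx_b <- split(vb, kb[vb])
  hit <- match(ka[va], names(idx_b))
  keep <- which(!is.na(hit))
  if (!length(keep)) return(empty)
  diags <- unique(unlist(lapply(keep, function(i) idx_b[[hit[i]]] - va[i]),
                         use.names = FALSE))
  av <- .chars(a); bv <- .chars(b)
  res <- list()
  for (d in diags) {
    ia <- max(1L, 1L - d):min(n, m - d)
    eq <- av[ia] == bv[ia + d] & av[ia] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_len)) {
      pa <- ia[starts[j]] - 1L
      res[[length(res) + 1L]] <- c(length = r$lengths[j], posA = pa,
                                   posB = pa + d)
    }
  }
  if (!length(res)) return(empty)
  as.data.frame(do.call(rbind, res))
}

#' Perfect tandem repeat arrays
#'
#' Finds all maximal perfect tandem arrays with the requested repeat-unit
#' length and at least `min_copies` full copies. An array whose repeating
#' region is itself periodic with a smaller period is reported at its
#' smallest period only (so a homopolymer run scanned at unit length 5 is
#' reported as a period-1 array).
#'
#' @param seq DNA sequence.
#' @param unit_len repeat unit length in nt (at least 2).
#' @param min_copies minimum number of full copies.
#' @return `data.frame` with `unit`, `unit_length`, `copies`, 0-based
#'   `start`, and `purity` (1.0: arrays are exact by construction).
#' @export
#' @examples
#' tandem_scan("ACGTGACGTGACGTG", unit_len = 5)
tandem_scan <- function(seq, unit_len = 5L, min_copies = 2L) {
  if (unit_len < 2L) stop("unit_len must be >= 2", call. = FALSE)
  .check_dna_alphabet(seq, "<seq>")
  n <- nchar(seq)
  empty <- data.frame(unit = character(), unit_length = integer(),
                      copies = integer(), start = integer(), purity = numeric(),
                      stringsAsFactors = FALSE)
  if (n < unit_len * min_copies) return(empty)
  v <- .chars(seq)
  p <- unit_len
  eq <- v[seq_len(n - p)] == v[seq_len(n - p) + p] & v[seq_len(n - p)] != "N"
  r <- rle(eq)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  seen <- character()
  res <- list()
  for (j in which(r$values)) {
    region_len <- r$lengths[j] + p
    if (region_len %/% p < min_copies) next
    rs <- starts[j]; re <- ends[j] + p   # 1-based region bounds
    q <- .smallest_period(v, rs, re)
    # re-extend maximally under the smallest period
    while (rs > 1L && v[rs - 1L] != "N" && v[rs - 1L] == v[rs - 1L + q]) rs <- rs - 1L
    while (re < n && v[re + 1L] != "N" && v[re + 1L] == v[re + 1L - q]) re <- re + 1L
    copies <- (re - rs + 1L) %/% q
    if (copies < min_copies) next
    key <- paste(rs, q)
    if (key %in% seen) next
    seen <- c(seen, key)
    res[[length(res) + 1L]] <- data.frame(
      unit = substr(seq, rs, rs + q - 1L), unit_length = q,
      copies = copies, start = rs - 1L, purity = 1.0,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Smallest q (1..re-rs) such that chars rs..re have period q.
.smallest_period <- function(v, rs, re) {
  len <- re - rs + 1L
  for (q in seq_len(len - 1L)) {
    i <- rs:(re - q)
    if (all(v[i] == v[i + q])) return(q)
  }
  len
}
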