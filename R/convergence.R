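#' Filter contigs by assembler coverage
#'
#' Keeps exactly the contigs with coverage greater than or equal to the
#' cutoff, preserving input order. Contigs without a coverage value are an
#' error: the coverage axis is what separates a packaged element from
#' background, so silent retention would be misleading.
#'
#' @param contigs contig table (columns `id`, `seq`, `coverage`, ...).
#' @param cutoff non-negative coverage cutoff.
#' @return the surviving rows of `contigs`.
#' @export
filter_by_coverage <- function(contigs, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0)
  if (anyNA(contigs$coverage)) {
    bad <- contigs$id[which(is.na(contigs$coverage))[1]]
    stop(sprintf("contig '%s' has no coverage value", bad), call. = FALSE)
  }
  contigs[contigs$coverage >= cutoff, , drop = FALSE]
}

## Longest common exact substring of two oriented sequences.
## k-mer anchored: try descending seed sizes; any common substring of length
## >= k contains a shared k-mer, so the first seed size that produces anchors
## bounds the answer from below and the per-diagonal match runs give the
## exact maximum. Returns 0-based positions.
.lce_oriented <- function(a, b) {
  n <- nchar(a); m <- nchar(b)
  av <- .chars(a); bv <- .chars(b)
  diags <- NULL
  for (k in unique(pmin(c(31L, 15L, 8L, 4L, 2L, 1L), min(n, m)))) {
    ka <- substring(a, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    kb <- substring(b, seq_len(m - k + 1L), seq_len(m - k + 1L) + k - 1L)
    va <- which(!grepl("N", ka, fixed = TRUE))
    vb <- which(!grepl("N", kb, fixed = TRUE))
    if (length(va) == 0L || length(vb) == 0L) next
    idx_b <- split(vb, kb[vb])
    hit <- match(ka[va], names(idx_b))
    keep <- which(!is.na(hit))
    if (length(keep) == 0L) next
    dd <- unlist(lapply(keep, function(i) idx_b[[hit[i]]] - va[i]), use.names = FALSE)
    diags <- unique(dd)
    break
  }
  if (is.null(diags))
    return(list(length = 0L, posA = 0L, posB = 0L, sub = ""))
  best_len <- 0L
  cand <- list()
  for (d in diags) {
    ia <- max(1L, 1L - d):min(n, m - d)
    eq <- av[ia] == bv[ia + d] & av[ia] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tr <- which(r$values & r$lengths >= best_len & r$lengths > 0L)
    for (j in tr) {
      len <- r$lengths[j]
      pa <- ia[starts[j]] - 1L   # 0-based
      if (len > best_len) {
        best_len <- len
        cand <- list(list(length = len, posA = pa, posB = pa + d))
      } else if (len == best_len && best_len > 0L) {
        cand[[length(cand) + 1L]] <- list(length = len, posA = pa, posB = pa + d)
      }
    }
  }
  if (best_len == 0L)
    return(list(length = 0L, posA = 0L, posB = 0L, sub = ""))
  subs <- vapply(cand, function(x) substr(a, x$posA + 1L, x$posA + x$length),
                 character(1))
  ord <- order(subs, vapply(cand, function(x) x$posA, integer(1)),
               vapply(cand, function(x) x$posB, integer(1)))
  pick <- cand[[ord[1]]]
  pick$sub <- subs[ord[1]]
  pick
}

#' Longest common exact substring of two DNA sequences
#'
#' Finds a maximal-length exact common substring of `a` and `b`, optionally
#' also considering the reverse complement of `b`. `N` never matches any
#' base. Ties are broken towards the longer match, then the
#' lexicographically smaller substring, then the smaller position in `a`,
#' with forward orientation preferred over reverse complement.
#'
#' @param a,b non-empty DNA sequences.
#' @param consider_revcomp also search `a` against `revcomp(b)`.
#' @return a list with `length`, `posA`, `posB` (0-based starts; `posB` is
#'   always a position on the forward strand of `b`), `orientation`
#'   (`"forward"` or `"revcomp"`) and `substring` (as it reads in `a`).
#' @export
longest_common_exact <- function(a, b, consider_revcomp = TRUE) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  .check_dna_alphabet(a, "a"); .check_dna_alphabet(b, "b")
  fw <- .lce_oriented(a, b)
  fw$orientation <- "forward"
  best <- fw
  if (consider_revcomp) {
    rc <- .lce_oriented(a, revcomp(b))
    rc$posB <- nchar(b) - rc$posB - rc$length  # back to forward-strand coords
    rc$orientation <- "revcomp"
    if (rc$length > best$length ||
        (rc$length == best$length && rc$length > 0L && rc$sub < best$sub))
      best <- rc
  }
  list(length = best$length, posA = best$posA, posB = best$posB,
       orientation = best$orientation, substring = best$sub)
}

#' Coverage-stringency convergence of two contig sets
#'
#' Walks an ascending schedule of coverage cutoffs over two independently
#' assembled contig sets. At the first cutoff where each set has at most
#' `max_survivors` surviving contigs and the best cross-set longest common
#' exact substring reaches `min_core` nucleotides, the sweep stops and the
#' shared core is emitted. This mirrors the manual procedure of raising the
#' assembler coverage criterion until both preparations are represented by a
#' handful of contigs that agree on one identical sequence.
#'
#' @param setA,setB contig tables with coverage values.
#' @param schedule ascending numeric cutoffs (default 0 to 3000).
#' @param max_survivors maximum surviving contigs per dataset at convergence.
#' @param min_core minimum length (nt) of the shared core; guards against
#'   convergence onto short shared repeats.
#' @param consider_revcomp allow the core to match in reverse complement.
#' @return an object of class `gta_sweep`: a list with `cutoff_schedule`,
#'   `survivors_per_cutoff` (matrix, datasets x cutoffs), `stop_cutoff`,
#'   `converged`, and `core` (class `gta_core`, or `NULL`). The core carries
#'   `core_seq`, `length`, per-dataset `offsets` and a `flank_report`.
#' @export
sweep_convergence <- function(setA, setB,
                              schedule = c(0, 5, 10, 50, 100, 500, 1000, 2000, 3000),
                              max_survivors = 3L, min_core = 5000L,
                              consider_revcomp = TRUE) {
  if (length(schedule) == 0L) stop("empty cutoff schedule", call. = FALSE)
  if (is.unsorted(schedule, strictly = TRUE))
    stop("cutoff schedule must be strictly ascending", call. = FALSE)
  if (nrow(setA) == 0L || nrow(setB) == 0L)
    stop("both contig sets must be non-empty", call. = FALSE)
  surv <- matrix(NA_integer_, nrow = 2L, ncol = length(schedule),
                 dimnames = list(c("A", "B"), as.character(schedule)))
  stop_cutoff <- NA_real_
  core <- NULL
  for (ci in seq_along(schedule)) {
    cutoff <- schedule[ci]
    sa <- filter_by_coverage(setA, cutoff)
    sb <- filter_by_coverage(setB, cutoff)
    surv["A", ci] <- nrow(sa)
    surv["B", ci] <- nrow(sb)
    if (!is.na(stop_cutoff)) next
    if (nrow(sa) == 0L || nrow(sb) == 0L) next
    if (nrow(sa) > max_survivors || nrow(sb) > max_survivors) next
    best <- NULL
    for (i in seq_len(nrow(sa))) {
      for (j in seq_len(nrow(sb))) {
        r <- longest_common_exact(sa$seq[i], sb$seq[j], consider_revcomp)
        if (is.null(best) || r$length > best$r$length ||
            (r$length == best$r$length && r$substring < best$r$substring)) {
          best <- list(r = r, i = i, j = j)
        }
      }
    }
    if (!is.null(best) && best$r$length >= min_core) {
      stop_cutoff <- cutoff
      r <- best$r
      ca <- sa[best$i, ]; cb <- sb[best$j, ]
      core <- structure(list(
        core_seq = r$substring,
        length = r$length,
        offsets = list(
          A = list(contig_id = ca$id, start = r$posA,
                   end = r$posA + r$length, orientation = "forward"),
          B = list(contig_id = cb$id, start = r$posB,
                   end = r$posB + r$length, orientation = r$orientation)),
        flank_report = NULL), class = "gta_core")
      core$flank_report <- flank_variation(ca, cb, core)
    }
  }
  structure(list(cutoff_schedule = schedule,
                 survivors_per_cutoff = surv,
                 stop_cutoff = stop_cutoff,
                 converged = !is.null(core),
                 core = core),
            class = "gta_sweep")
}

#' @export
print.gta_sweep <- function(x, ...) {
  cat("Coverage-stringency sweep\n")
  cat("  schedule:", paste(x$cutoff_schedule, collapse = ", "), "\n")
  cat("  survivors (A):", paste(x$survivors_per_cutoff["A", ], collapse = ", "), "\n")
  cat("  survivors (B):", paste(x$survivors_per_cutoff["B", ], collapse = ", "), "\n")
  if (x$converged) {
    cat(sprintf("  converged at cutoff %s on a %d nt core\n",
                format(x$stop_cutoff), x$core$length))
  } else cat("  did not converge\n")
  invisible(x)
}

#' @export
print.gta_core <- function(x, ...) {
  cat(sprintf("Shared core: %d nt\n", x$length))
  for (d in names(x$offsets)) {
    o <- x$offsets[[d]]
    cat(sprintf("  %s: %s [%d, %d) %s\n", d, o$contig_id, o$start, o$end,
                o$orientation))
  }
  invisible(x)
}

#' Flanking-sequence comparison around a converged core
#'
#' Reports, per dataset, how much sequence flanks the core on its 5' and 3'
#' sides, and whether those flanks agree exactly between the two datasets.
#' Two preparations of the same element are expected to agree on the core
#' and differ only in their flanks.
#'
#' @param contigA,contigB single-row contig tables holding the core-bearing
#'   contig of each dataset.
#' @param core a `gta_core` object whose offsets refer to these contigs.
#' @return a list with per-dataset `five_prime`/`three_prime` flank lengths
#'   and logical `five_prime_agree`/`three_prime_agree` flags.
#' @export
flank_variation <- function(contigA, contigB, core) {
  oa <- core$offsets$A; ob <- core$offsets$B
  a <- contigA$seq
  b <- if (ob$orientation == "revcomp") revcomp(contigB$seq) else contigB$seq
  bstart <- if (ob$orientation == "revcomp") nchar(b) - ob$end else ob$start
  bend <- bstart + core$length
  if (oa$start < 0L || oa$end > nchar(a) || bstart < 0L || bend > nchar(b))
    stop("core offsets outside contig bounds", call. = FALSE)
  if (substr(a, oa$start + 1L, oa$end) != core$core_seq ||
      substr(b, bstart + 1L, bend) != core$core_seq)
    stop("core offsets do not reproduce the core sequence", call. = FALSE)
  a5 <- substr(a, 1L, oa$start); a3 <- substr(a, oa$end + 1L, nchar(a))
  b5 <- substr(b, 1L, bstart);   b3 <- substr(b, bend + 1L, nchar(b))
  list(A = list(five_prime = nchar(a5), three_prime = nchar(a3)),
       B = list(five_prime = nchar(b5), three_prime = nchar(b3)),
       five_prime_agree = identical(a5, b5),
       three_prime_agree = identical(a3, b3))
}
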