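#' Six-frame open reading frame calling
#'
#' Scans all six frames of a DNA sequence under the bacterial genetic code.
#' Within each frame, every stop-delimited interval contributes at most one
#' ORF: from its first start codon to the closing stop codon (stop included
#' in the nucleotide span, excluded from the translation). Codons containing
#' `N` break intervals and no ORF is emitted across them. Coordinates are
#' always reported on the forward strand, 0-based half-open.
#'
#' @param seq DNA sequence (character scalar over `{A,C,G,T,N}`).
#' @param seq_id identifier recorded in the output.
#' @param min_nt minimum ORF length in nucleotides (stop codon included).
#' @param start_codons allowed start codons.
#' @return a `data.frame` with columns `seq_id`, `start`, `end`, `strand`,
#'   `frame` (0-2 relative to the ORF's own strand), `nt_length`, `protein`,
#'   and annotation placeholders `role_name`, `align_score`, `identity_frac`,
#'   `panel_cov_frac`.
#' @export
#' @examples
#' find_orfs("ATGAAATAA", min_nt = 6)
find_orfs <- function(seq, seq_id = "seq", min_nt = 150L,
                      start_codons = c("ATG", "GTG", "TTG")) {
  .check_dna_alphabet(seq, seq_id)
  L <- nchar(seq)
  gc <- .genetic_code()
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      if (ncod < 2L) next
      cod_start <- f + 3L * (seq_len(ncod) - 1L)  # 0-based
      cods <- substring(s, cod_start + 1L, cod_start + 3L)
      has_n <- grepl("N", cods, fixed = TRUE)
      is_stop <- cods %in% .STOP_CODONS & !has_n
      brk <- is_stop | has_n
      is_start <- (cods %in% start_codons) & !has_n
      if (!any(is_stop)) next
      grp <- cumsum(c(0L, brk[-ncod]))  # breaking codon closes its own group
      for (g in unique(grp[is_stop])) {
        idx <- which(grp == g)
        stop_i <- idx[length(idx)]
        if (!is_stop[stop_i]) next
        starts <- idx[is_start[idx] & idx < stop_i]
        if (length(starts) == 0L) next
        st <- starts[1]
        nt_len <- (stop_i - st + 1L) * 3L
        if (nt_len < min_nt) next
        local_start <- cod_start[st]
        local_end <- cod_start[stop_i] + 3L
        body <- cods[st:(stop_i - 1L)]
        prot <- paste(c("M", gc[body[-1]]), collapse = "")
        if (strand == "+") {
          fwd_start <- local_start; fwd_end <- local_end
        } else {
          fwd_start <- L - local_end; fwd_end <- L - local_start
        }
        out[[length(out) + 1L]] <- data.frame(
          seq_id = seq_id, start = fwd_start, end = fwd_end,
          strand = strand, frame = f, nt_length = nt_len, protein = prot,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               strand = character(), frame = integer(), nt_length = integer(),
               protein = character(), stringsAsFactors = FALSE)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res$role_name <- rep(NA_character_, nrow(res))
  res$align_score <- rep(NA_real_, nrow(res))
  res$identity_frac <- rep(NA_real_, nrow(res))
  res$panel_cov_frac <- rep(NA_real_, nrow(res))
  res
}

#' Translate a complete ORF under the bacterial genetic code
#'
#' The nucleotide sequence must be a whole number of codons and end with a
#' stop codon. GTG/TTG initiation codons are recoded to methionine; the stop
#' is excluded from the product, so an `n`-nt ORF yields an `n/3 - 1` residue
#' protein.
#'
#' @param orf_nt ORF nucleotide sequence including the terminal stop codon.
#' @return the translated protein (character scalar).
#' @export
#' @examples
#' translate_orf("GTGAAATAA")  # "MK"
translate_orf <- function(orf_nt) {
  .check_dna_alphabet(orf_nt, "<orf>")
  n <- nchar(orf_nt)
  if (n %% 3L != 0L)
    stop(sprintf("ORF length %d is not divisible by 3", n), call. = FALSE)
  if (n < 6L) stop("ORF must contain at least a start and a stop codon", call. = FALSE)
  cods <- substring(orf_nt, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  ncod <- length(cods)
  if (!cods[ncod] %in% .STOP_CODONS)
    stop(sprintf("terminal codon '%s' is not a stop codon", cods[ncod]), call. = FALSE)
  internal <- which(cods[-ncod] %in% .STOP_CODONS)
  if (length(internal))
    stop(sprintf("internal stop codon at codon %d", internal[1]), call. = FALSE)
  gc <- .genetic_code()
  aa <- gc[cods[-ncod]]
  if (anyNA(aa))
    stop("codon containing ambiguous base cannot be translated", call. = FALSE)
  aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Fraction of ORFs on the majority strand
#'
#' @param orfs an ORF table as returned by [find_orfs()].
#' @return the maximum over strands of (ORFs on that strand)/(total ORFs).
#' @export
strand_consistency <- function(orfs) {
  if (is.null(orfs) || nrow(orfs) == 0L)
    stop("strand_consistency requires at least one ORF", call. = FALSE)
  max(table(factor(orfs$strand, levels = c("+", "-")))) / nrow(orfs)
}
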