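#' @keywords internal
"_PACKAGE"

## Stop codons of the bacterial genetic code (table 11).
.STOP_CODONS <- c("TAA", "TAG", "TGA")

## Default start codon set; "legitimate bacterial start codons".
.START_CODONS <- c("ATG", "GTG", "TTG")

## IUPAC nucleotide codes -> set of concrete bases each code is compatible with.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.pkg_cache <- new.env(parent = emptyenv())

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. `N` complements to `N`.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Split a scalar string into a character vector of single letters.
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## Evaluate `expr` under a fixed RNG seed without clobbering the caller's
## RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Random DNA with a target GC fraction; per-position independent sampling.
.random_dna <- function(n, gc = 0.36) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## Validate a DNA sequence alphabet; returns invisible(TRUE) or stops with
## the offending record id and 1-based position.
.check_dna_alphabet <- function(seq, id = "<sequence>") {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 substr(seq, bad, bad), id, bad), call. = FALSE)
  }
  invisible(TRUE)
}

## Genetic code lookup table (named character vector, codon -> one-letter AA).
.genetic_code <- function() {
  if (is.null(.pkg_cache$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$gc <- stats::setNames(as.character(gc), names(gc))
  }
  .pkg_cache$gc
}

## Codon choices per amino acid (stops excluded), for reverse translation.
.codons_by_aa <- function() {
  if (is.null(.pkg_cache$cba)) {
    gc <- .genetic_code()
    gc <- gc[gc != "*"]
    .pkg_cache$cba <- split(names(gc), gc)
  }
  .pkg_cache$cba
}

## Reverse-translate a protein into DNA (start codon ATG, trailing TAA stop),
## with optional fixed codons at given 1-based residue positions.
.reverse_translate <- function(protein, fixed_codons = NULL) {
  aa <- .chars(protein)
  if (aa[1] != "M") stop("protein must start with M", call. = FALSE)
  cba <- .codons_by_aa()
  if (is.null(.pkg_cache$codon_mat)) {
    mx <- max(lengths(cba))
    M <- matrix(NA_character_, nrow = length(cba), ncol = mx,
                dimnames = list(names(cba), NULL))
    for (nm in names(cba)) M[nm, seq_along(cba[[nm]])] <- cba[[nm]]
    .pkg_cache$codon_mat <- M
    .pkg_cache$codon_n <- stats::setNames(lengths(cba), names(cba))
  }
  row <- match(aa, rownames(.pkg_cache$codon_mat))
  if (anyNA(row))
    stop(sprintf("no codon for residue '%s'", aa[which(is.na(row))[1]]), call. = FALSE)
  cnt <- .pkg_cache$codon_n[row]
  pick <- 1L + as.integer(floor(stats::runif(length(aa)) * cnt))
  pick <- pmin(pick, cnt)
  cods <- .pkg_cache$codon_mat[cbind(row, pick)]
  cods[1] <- "ATG"
  if (!is.null(fixed_codons)) {
    idx <- as.integer(names(fixed_codons))
    for (i in seq_along(idx)) {
      pos <- idx[i]
      cod <- fixed_codons[[i]]
      if (.genetic_code()[[cod]] != aa[pos]) {
        stop(sprintf(
          "fixed codon %s at residue %d encodes %s, panel protein has %s",
          cod, pos, .genetic_code()[[cod]], aa[pos]), call. = FALSE)
      }
      cods[pos] <- cod
    }
  }
  paste(c(cods, "TAA"), collapse = "")
}

## A 24-nt spacer carrying stop codons in all three forward frames
## (TAA at offsets 0/4/8, TAG at 13/17/21) and in all three reverse-strand
## frames (TTA at offsets 12/16/20 reads TAA on the minus strand). Placed
## around every synthetic gene so open reading frames can never run across
## gene boundaries on either strand.
.FRAME_INSULATOR <- "TAACTAACTAACTTAGTTAGTTAG"
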