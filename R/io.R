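#' Read contigs from a FASTA file
#'
#' Reads a FASTA file into a contig table. Sequences are uppercased, `U` is
#' mapped to `T`, and any character outside `{A,C,G,T,N}` is rejected with an
#' error naming the offending record and position. Per-contig coverage is
#' parsed from assembler-style headers carrying a `_cov_` token (see
#' [parse_coverage_header()]); an optional sidecar TSV (columns `id`,
#' `coverage`) overrides header-derived values.
#'
#' @param path path to a FASTA file.
#' @param dataset_label label attached to every record (e.g. `"A"`, `"2016"`).
#' @param sidecar optional path to a two-column TSV (`id`, `coverage`) whose
#'   values override header-derived coverage.
#' @return a `data.frame` with columns `id`, `seq`, `coverage` (`NA` when
#'   absent) and `dataset_label`.
#' @export
read_fasta <- function(path, dataset_label = NA_character_, sidecar = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  ids <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L)
      stop(sprintf("empty sequence for record '%s'", ids[i]), call. = FALSE)
    .check_dna_alphabet(seqs[i], ids[i])
  }
  cov <- vapply(ids, parse_coverage_header, numeric(1), USE.NAMES = FALSE)
  out <- data.frame(id = ids, seq = seqs, coverage = cov,
                    dataset_label = dataset_label,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(sidecar)) {
    sc <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    if (!all(c("id", "coverage") %in% names(sc)))
      stop("coverage sidecar must have columns 'id' and 'coverage'", call. = FALSE)
    m <- match(out$id, sc$id)
    out$coverage[!is.na(m)] <- as.numeric(sc$coverage[m[!is.na(m)]])
  }
  if (any(!is.na(out$coverage) & out$coverage < 0))
    stop("negative coverage value", call. = FALSE)
  out
}

#' Write contigs to a FASTA file
#'
#' @param contigs contig table as returned by [read_fasta()], or any data
#'   frame with `id` and `seq` columns.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(contigs$seq)
  names(set) <- contigs$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Parse a coverage value from an assembler-style FASTA header
#'
#' Extracts the numeric value following the last `_cov_` token of a header
#' (SPAdes dialect, e.g. `NODE_1_length_15638_cov_3425.0`). Returns `NA` when
#' the header carries no such token.
#'
#' @param header a FASTA description line without the leading `>`.
#' @return coverage as a numeric scalar, or `NA_real_` when absent.
#' @export
#' @examples
#' parse_coverage_header("NODE_1_length_15638_cov_3425.0")
#' parse_coverage_header("contig_7")
parse_coverage_header <- function(header) {
  stopifnot(is.character(header), length(header) == 1L)
  m <- gregexpr("_cov_", header, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(NA_real_)
  tail_txt <- substring(header, m[length(m)] + 5L)
  num <- regmatches(tail_txt, regexpr("^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?", tail_txt))
  if (length(num) == 0L || nchar(num) == 0L)
    stop(sprintf("malformed coverage value in header '%s'", header), call. = FALSE)
  as.numeric(num)
}

.ROLE_CATEGORIES <- c("packaging", "head", "tail", "baseplate", "lysis",
                      "EAM", "regulatory", "other")

#' Load a protein role panel
#'
#' A role panel is a TSV with columns `role_name`, `category` and
#' `protein_seq`; it supplies the reference proteins against which called
#' ORFs are annotated. Categories are restricted to
#' packaging, head, tail, baseplate, lysis, EAM, regulatory, other.
#'
#' @param path path to the panel TSV.
#' @return a `data.frame` with columns `role_name`, `category`, `protein_seq`.
#' @export
load_role_panel <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("role_name", "category", "protein_seq")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("role panel missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  dup <- tab$role_name[duplicated(tab$role_name)]
  if (length(dup))
    stop(sprintf("duplicate role_name in panel: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  bad_cat <- setdiff(unique(tab$category), .ROLE_CATEGORIES)
  if (length(bad_cat))
    stop(sprintf("unknown panel category: %s", paste(bad_cat, collapse = ", ")),
         call. = FALSE)
  if (any(nchar(tab$protein_seq) == 0L))
    stop("empty protein_seq in role panel", call. = FALSE)
  bad <- grepl(sprintf("[^%sX]", paste(.AA_ALPHABET, collapse = "")), tab$protein_seq)
  if (any(bad))
    stop(sprintf("illegal residue in panel entry '%s'", tab$role_name[which(bad)[1]]),
         call. = FALSE)
  tab[need]
}

#' The packaged synthetic role panel
#'
#' Loads the role panel shipped with the package
#' (`extdata/role_panel_synthetic.tsv`). The panel is synthetic: its protein
#' sequences are generated, not database orthologs, and exist so that the
#' synthetic-data generator and the annotator share a common vocabulary of
#' phage structural roles (terminase, portal, major capsid, tail/baseplate,
#' hydrolases, EAM-class proteins, ...).
#'
#' @return a role-panel `data.frame` (see [load_role_panel()]).
#' @export
default_role_panel <- function() {
  load_role_panel(system.file("extdata", "role_panel_synthetic.tsv",
                              package = "gtasieve", mustWork = TRUE))
}

#' The packaged synthetic foreign (insect decoy) panel
#'
#' Synthetic stand-ins for host-insect proteins, used by
#' [foreign_orf_check()] to ask whether any long ORF looks like packaged
#' mosquito DNA rather than bacterial/phage material.
#'
#' @return a role-panel `data.frame`.
#' @export
default_foreign_panel <- function() {
  load_role_panel(system.file("extdata", "foreign_panel_synthetic.tsv",
                              package = "gtasieve", mustWork = TRUE))
}

#' Write features to a GFF3 file
#'
#' Features use 0-based half-open coordinates internally and are converted to
#' the 1-based inclusive convention on write (`start+1`, `end`).
#'
#' @param features a `data.frame` with columns `seq_id`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"` or `"-"`), `feature_type`, and
#'   optionally `attributes` (a list column of named character vectors) and
#'   `score`.
#' @param path output path.
#' @param seq_lengths optional named integer vector of parent sequence
#'   lengths; when supplied, coordinates are checked against it.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(features, path, seq_lengths = NULL) {
  lines <- "##gff-version 3"
  if (nrow(features) > 0) {
    if (any(features$end <= features$start))
      stop("feature with end <= start (internal half-open coordinates)", call. = FALSE)
    if (any(features$start < 0))
      stop("negative feature coordinate", call. = FALSE)
    if (!all(features$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'", call. = FALSE)
    if (!is.null(seq_lengths)) {
      lim <- seq_lengths[features$seq_id]
      if (any(is.na(lim)) || any(features$end > lim))
        stop("feature coordinate outside parent sequence", call. = FALSE)
    }
    attrs <- if (!is.null(features$attributes)) {
      vapply(features$attributes, function(a) {
        if (is.null(a) || length(a) == 0L) return(".")
        paste(sprintf("%s=%s", names(a), vapply(a, .gff3_escape, character(1))),
              collapse = ";")
      }, character(1))
    } else rep(".", nrow(features))
    score <- if (!is.null(features$score)) {
      ifelse(is.na(features$score), ".", format(features$score))
    } else rep(".", nrow(features))
    lines <- c(lines, sprintf("%s\tgtasieve\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                              features$seq_id, features$feature_type,
                              features$start + 1L, features$end,
                              score, features$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

.gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x
}
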