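#' Classify an element as GTA-like, prophage-like or ambiguous
#'
#' Applies five criteria to an annotated element: compact size, single-strand
#' gene orientation, a complete head-tail module (terminase, portal and major
#' capsid present plus at least two tail/baseplate roles), absence of
#' EAM-class content (no EAM-category role and no ORF longer than
#' `eam_orf_threshold`), and absence of regulatory-category roles. An element
#' meeting all five is GTA-like; an element with a complete head-tail module
#' that is oversized or carries EAM content is prophage-like; anything else
#' is ambiguous. Strand consistency is computed over the role-assigned ORFs
#' (falling back to all ORFs when none is assigned), so spurious unannotated
#' calls on the opposite strand do not flip the verdict.
#'
#' @param orfs annotated ORF table (see [annotate_orfs()]).
#' @param element_len element length in nt.
#' @param panel the role panel used for annotation (supplies categories).
#' @param size_threshold maximum GTA-like element size in nt.
#' @param eam_orf_threshold ORFs longer than this many nt count as EAM-class
#'   content.
#' @param head_roles role names whose joint presence defines the packaging/
#'   capsid core of the head-tail module.
#' @return an object of class `gta_element_call`: `label`, `length_nt`,
#'   per-criterion `criteria` flags, and a `rationale` string.
#' @export
classify_element <- function(orfs, element_len, panel,
                             size_threshold = 25000L,
                             eam_orf_threshold = 2000L,
                             head_roles = c("terminase", "portal", "major_capsid_E")) {
  if (is.null(orfs) || nrow(orfs) == 0L)
    stop("classify_element requires at least one ORF", call. = FALSE)
  cat_of <- stats::setNames(panel$category, panel$role_name)
  assigned <- orfs[!is.na(orfs$role_name), , drop = FALSE]
  cats <- cat_of[assigned$role_name]
  strand_basis <- if (nrow(assigned) > 0L) assigned else orfs
  flags <- list(
    size_ok = element_len <= size_threshold,
    single_strand = strand_consistency(strand_basis) == 1,
    head_tail_complete = all(head_roles %in% assigned$role_name) &&
      sum(cats %in% c("tail", "baseplate")) >= 2L,
    eam_absent = !any(cats == "EAM") &&
      !any(orfs$nt_length > eam_orf_threshold),
    regulatory_absent = !any(cats == "regulatory"))
  label <- if (all(unlist(flags))) "GTA-like"
  else if (flags$head_tail_complete && (!flags$size_ok || !flags$eam_absent))
    "prophage-like"
  else "ambiguous"
  rationale <- paste(
    sprintf("%s=%s", names(flags), vapply(flags, isTRUE, logical(1))),
    collapse = ", ")
  structure(list(label = label, length_nt = element_len,
                 criteria = flags, rationale = rationale),
            class = "gta_element_call")
}

#' @export
print.gta_element_call <- function(x, ...) {
  cat(sprintf("Element call: %s (%d nt)\n  %s\n", x$label, x$length_nt,
              x$rationale))
  invisible(x)
}

#' Map contigs onto a host genome by exact k-mer matching
#'
#' Every length-`k` exact match between a query contig (either strand) and a
#' host contig increments a per-base depth counter over the matched host
#' interval; contiguous overlapping k-mer matches from the same query are
#' merged into one footprint first, so depth counts matching query
#' placements, not k-mer placements. Breadth-at-depth statistics (`>0` and
#' `>5`) summarise how much of the host genome is touched and how often —
#' the signature of random host-DNA packaging as opposed to element-only
#' packaging.
#'
#' @param contigs query contig table.
#' @param host host genome: a contig table or a named character vector.
#' @param k k-mer size; values below 11 are rejected.
#' @return class `gta_host_profile`: per host contig a list with `depth`
#'   (integer vector), `breadth_gt0` and `breadth_gt5`; plus length-weighted
#'   `overall_breadth_gt0`/`overall_breadth_gt5`.
#' @export
map_contigs_to_host <- function(contigs, host, k = 21L) {
  if (k < 11L) stop("k below 11 rejected", call. = FALSE)
  if (is.character(host)) {
    host <- data.frame(id = names(host), seq = unname(host),
                       stringsAsFactors = FALSE)
  }
  profiles <- list()
  for (h in seq_len(nrow(host))) {
    hs <- host$seq[h]
    L <- nchar(hs)
    depth <- integer(L)
    if (L >= k) {
      starts <- seq_len(L - k + 1L)
      hk <- substring(hs, starts, starts + k - 1L)
      valid <- !grepl("N", hk, fixed = TRUE)
      idx <- split(starts[valid], hk[valid])
      nm <- names(idx)
      inc <- integer(L + 1L); dec <- integer(L + 1L)
      for (q in seq_len(nrow(contigs))) {
        for (qs in c(contigs$seq[q], revcomp(contigs$seq[q]))) {
          nq <- nchar(qs)
          if (nq < k) next
          qst <- seq_len(nq - k + 1L)
          qk <- substring(qs, qst, qst + k - 1L)
          qk <- qk[!grepl("N", qk, fixed = TRUE)]
          mm <- match(qk, nm)
          mm <- mm[!is.na(mm)]
          if (!length(mm)) next
          hits <- sort(unique(unlist(idx[mm], use.names = FALSE)))
          # merge overlapping k-mer matches of this query into footprints
          new_run <- c(TRUE, diff(hits) > k)
          run_id <- cumsum(new_run)
          run_start <- hits[new_run]
          run_end <- vapply(split(hits, run_id), max, numeric(1)) + k
          inc <- inc + tabulate(run_start, nbins = L + 1L)
          dec <- dec + tabulate(run_end, nbins = L + 1L)
        }
      }
      depth <- cumsum(inc - dec)[seq_len(L)]
    }
    profiles[[host$id[h]]] <- list(depth = depth,
                                   breadth_gt0 = mean(depth > 0L),
                                   breadth_gt5 = mean(depth > 5L))
  }
  lens <- nchar(host$seq)
  structure(list(
    contigs = profiles,
    overall_breadth_gt0 = sum(vapply(profiles, `[[`, numeric(1), "breadth_gt0") * lens) / sum(lens),
    overall_breadth_gt5 = sum(vapply(profiles, `[[`, numeric(1), "breadth_gt5") * lens) / sum(lens)),
    class = "gta_host_profile")
}

#' @export
print.gta_host_profile <- function(x, ...) {
  cat("Host k-mer mapping profile\n")
  for (id in names(x$contigs)) {
    p <- x$contigs[[id]]
    cat(sprintf("  %s: breadth>0 = %.3f, breadth>5 = %.3f\n", id,
                p$breadth_gt0, p$breadth_gt5))
  }
  cat(sprintf("  overall: breadth>0 = %.3f, breadth>5 = %.3f\n",
              x$overall_breadth_gt0, x$overall_breadth_gt5))
  invisible(x)
}

#' Screen long contigs for large open reading frames
#'
#' For every contig of at least `min_contig` nt, every ORF of at least
#' `min_orf` nt is annotated against the panel and emitted — the screen used
#' to spot EAM-class proteins (ankyrins, AAA-ATPases, tape measure proteins)
#' on long low-coverage contigs.
#'
#' @param contigs contig table.
#' @param panel role panel.
#' @param min_contig minimum contig length (nt).
#' @param min_orf minimum ORF length (nt).
#' @param min_identity,min_panel_cov annotation thresholds.
#' @return `data.frame` with `contig_id`, `contig_len`, `orf_start`,
#'   `orf_end`, `strand`, `orf_len`, `role_name`, `role_class`,
#'   `identity_frac`, `panel_cov_frac` and `protein`, sorted by contig then
#'   position.
#' @export
screen_long_orfs <- function(contigs, panel, min_contig = 5000L,
                             min_orf = 2000L, min_identity = 0.35,
                             min_panel_cov = 0.5) {
  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    clen <- nchar(contigs$seq[i])
    if (clen < min_contig) next
    orfs <- find_orfs(contigs$seq[i], contigs$id[i], min_nt = min_orf)
    if (nrow(orfs) == 0L) next
    orfs <- annotate_orfs(orfs, panel, min_identity = min_identity,
                          min_panel_cov = min_panel_cov)
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = contigs$id[i], contig_len = clen,
      orf_start = orfs$start, orf_end = orfs$end, strand = orfs$strand,
      orf_len = orfs$nt_length, role_name = orfs$role_name,
      role_class = .eam_role_class(orfs$role_name),
      identity_frac = orfs$identity_frac, panel_cov_frac = orfs$panel_cov_frac,
      protein = orfs$protein, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(contig_id = character(), contig_len = integer(),
                      orf_start = integer(), orf_end = integer(),
                      strand = character(), orf_len = integer(),
                      role_name = character(), role_class = character(),
                      identity_frac = numeric(), panel_cov_frac = numeric(),
                      protein = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, out$orf_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.eam_role_class <- function(role_name) {
  map <- c(ankyrin = "ankyrin", AAA_ATPase = "AAA-ATPase",
           tape_measure = "tape measure")
  out <- unname(map[role_name])
  out[is.na(out)] <- "other"
  out
}

#' Count long ORFs whose best match is a foreign (decoy) protein
#'
#' Aligns each long-ORF protein against the union of the native panel and a
#' foreign decoy panel; counts the ORFs whose best-scoring match lies in the
#' foreign panel and passes the annotation thresholds. A clean particle prep
#' of a bacterial element is expected to return 0.
#'
#' @param long_orf_rows output of [screen_long_orfs()] (must carry `protein`).
#' @param foreign_panel decoy panel (e.g. [default_foreign_panel()]).
#' @param panel native role panel.
#' @param min_identity,min_panel_cov annotation thresholds.
#' @return integer count of foreign assignments.
#' @export
foreign_orf_check <- function(long_orf_rows, foreign_panel, panel,
                              min_identity = 0.35, min_panel_cov = 0.5,
                              min_score = 50) {
  if (is.null(foreign_panel) || nrow(foreign_panel) == 0L)
    stop("foreign_orf_check requires a non-empty foreign panel", call. = FALSE)
  if (nrow(long_orf_rows) == 0L) return(0L)
  combined <- rbind(panel[, c("role_name", "category", "protein_seq")],
                    foreign_panel[, c("role_name", "category", "protein_seq")])
  is_foreign <- c(rep(FALSE, nrow(panel)), rep(TRUE, nrow(foreign_panel)))
  submat <- substitution_table()
  targets <- Biostrings::AAStringSet(combined$protein_seq)
  count <- 0L
  for (i in seq_len(nrow(long_orf_rows))) {
    prot <- long_orf_rows$protein[i]
    scores <- Biostrings::pairwiseAlignment(
      targets, Biostrings::AAString(prot), type = "local",
      substitutionMatrix = submat, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    best <- which.max(scores)
    if (!is_foreign[best]) next
    res <- local_align(prot, combined$protein_seq[best], substitution = submat)
    if (res$identity_frac >= min_identity &&
        res$target_cov_frac >= min_panel_cov && res$score >= min_score)
      count <- count + 1L
  }
  count
}

## Reverse complement of an IUPAC-degenerate primer.
.revcomp_iupac <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  paste(rev(.chars(comp)), collapse = "")
}

## Per-position IUPAC compatibility of a primer with a concrete template
## window; template N never matches.
.iupac_mismatches <- function(primer_chars, template_chars) {
  !mapply(function(p, t) t %in% .IUPAC_SETS[[p]], primer_chars, template_chars,
          USE.NAMES = FALSE)
}

#' In-silico PCR with degenerate primers
#'
#' Finds all template sites where the forward primer matches the forward
#' strand and the reverse primer matches the reverse strand downstream,
#' under IUPAC-compatible base matching with at most `max_mm` mismatches per
#' primer and the 3'-terminal `three_prime_exact` bases matching exactly.
#' Primer sites may not overlap, and products span the primers' outer ends.
#'
#' @param template DNA template (concrete bases; `N` never matches).
#' @param fwd_primer,rev_primer primers over the IUPAC alphabet, written 5'
#'   to 3'.
#' @param max_product maximum product length (nt).
#' @param max_mm maximum mismatches allowed per primer.
#' @param three_prime_exact number of 3'-terminal primer bases that must
#'   match without mismatch.
#' @return `data.frame` with 0-based half-open `start`, `end`, `length`,
#'   `fwd_mismatches`, `rev_mismatches`.
#' @export
insilico_pcr <- function(template, fwd_primer, rev_primer,
                         max_product = 2000L, max_mm = 2L,
                         three_prime_exact = 3L) {
  .check_dna_alphabet(template, "<template>")
  for (p in c(fwd_primer, rev_primer)) {
    if (nchar(p) <= three_prime_exact)
      stop("primer shorter than the 3'-exact requirement", call. = FALSE)
    if (grepl("[^ACGTRYSWKMBDHVN]", p))
      stop("primer contains a non-IUPAC character", call. = FALSE)
  }
  fwd_sites <- .primer_sites(template, fwd_primer, max_mm, three_prime_exact,
                             three_prime_at_end = TRUE)
  rev_sites <- .primer_sites(template, .revcomp_iupac(rev_primer), max_mm,
                             three_prime_exact, three_prime_at_end = FALSE)
  out <- list()
  for (i in seq_len(nrow(fwd_sites))) {
    for (j in seq_len(nrow(rev_sites))) {
      if (rev_sites$start[j] < fwd_sites$end[i]) next
      len <- rev_sites$end[j] - fwd_sites$start[i]
      if (len > max_product) next
      out[[length(out) + 1L]] <- data.frame(
        start = fwd_sites$start[i], end = rev_sites$end[j], length = len,
        fwd_mismatches = fwd_sites$mismatches[i],
        rev_mismatches = rev_sites$mismatches[j])
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      fwd_mismatches = integer(), rev_mismatches = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

## Candidate primer sites on the forward strand of the template (pattern is
## already oriented). 3'-exact bases sit at the site end for a forward
## primer, at the site start for a reverse-complemented reverse primer.
.primer_sites <- function(template, pattern, max_mm, three_prime_exact,
                          three_prime_at_end) {
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern), Biostrings::DNAString(template),
    max.mismatch = max_mm, with.indels = FALSE,
    fixed = c(pattern = FALSE, subject = TRUE))
  pc <- .chars(pattern)
  plen <- length(pc)
  out <- list()
  for (i in seq_len(length(hits))) {
    s0 <- Biostrings::start(hits)[i] - 1L       # 0-based
    window <- .chars(substr(template, s0 + 1L, s0 + plen))
    mm <- .iupac_mismatches(pc, window)
    if (sum(mm) > max_mm) next
    tp <- if (three_prime_at_end) (plen - three_prime_exact + 1L):plen
          else seq_len(three_prime_exact)
    if (any(mm[tp])) next
    out[[length(out) + 1L]] <- data.frame(start = s0, end = s0 + plen,
                                          mismatches = sum(mm))
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), mismatches = integer()))
  do.call(rbind, out)
}

#' The degenerate hydrolase-gene primer pair used for enrichment QC
#'
#' The classic WO-phage "orf7" degenerate primer pair used to confirm phage
#' enrichment in particle preparations.
#'
#' @return list with `fwd` and `rev` IUPAC primer strings.
#' @export
orf7_qc_primers <- function() {
  list(fwd = "CTGSCTTCAAGKTGCTTTATTGC",
       rev = "TCAAGAGAYCARATAACAGTAGC")
}

#' Consolidate stage outputs into a single report
#'
#' @param sweep,core,annotation,classification,frameshift,repeats,host_profile,long_orfs,foreign_count,pcr
#'   stage outputs; any subset may be supplied but at least one must be.
#' @param config the effective configuration to embed.
#' @return class `gta_report` (a named list).
#' @export
build_report <- function(sweep = NULL, core = NULL, annotation = NULL,
                         classification = NULL, frameshift = NULL,
                         repeats = NULL, host_profile = NULL, long_orfs = NULL,
                         foreign_count = NULL, pcr = NULL, config = list()) {
  sections <- list(sweep = sweep, core = core, annotation = annotation,
                   classification = classification, frameshift = frameshift,
                   repeats = repeats, host_profile = host_profile,
                   long_orfs = long_orfs, foreign_count = foreign_count,
                   pcr = pcr)
  sections <- sections[!vapply(sections, is.null, logical(1))]
  if (!length(sections))
    stop("build_report requires at least one stage output", call. = FALSE)
  structure(c(sections, list(config = config)), class = "gta_report")
}

#' Validate the structure of a consolidated report
#'
#' @param report a `gta_report`.
#' @return `TRUE` (invisibly) or an error describing the defect.
#' @export
validate_report <- function(report) {
  if (!inherits(report, "gta_report")) stop("not a gta_report", call. = FALSE)
  if (!"config" %in% names(report)) stop("report lacks config", call. = FALSE)
  known <- c("sweep", "core", "annotation", "classification", "frameshift",
             "repeats", "host_profile", "long_orfs", "foreign_count", "pcr",
             "config")
  extra <- setdiff(names(report), known)
  if (length(extra))
    stop(sprintf("unknown report section(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  if (length(setdiff(names(report), "config")) == 0L)
    stop("report has no stage sections", call. = FALSE)
  invisible(TRUE)
}

#' Serialise a report to JSON
#'
#' Stage objects are reduced to plain lists/tables; host depth vectors are
#' summarised as breadth statistics. Identical reports serialise to
#' byte-identical JSON.
#'
#' @param report a `gta_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  validate_report(report)
  x <- unclass(report)
  if (!is.null(x$host_profile) && inherits(report$host_profile, "gta_host_profile")) {
    hp <- report$host_profile
    x$host_profile <- list(
      per_contig = lapply(hp$contigs, function(p)
        list(breadth_gt0 = p$breadth_gt0, breadth_gt5 = p$breadth_gt5)),
      overall_breadth_gt0 = hp$overall_breadth_gt0,
      overall_breadth_gt5 = hp$overall_breadth_gt5)
  }
  if (!is.null(x$sweep) && inherits(report$sweep, "gta_sweep")) {
    sw <- report$sweep
    x$sweep <- list(cutoff_schedule = sw$cutoff_schedule,
                    survivors_A = unname(sw$survivors_per_cutoff["A", ]),
                    survivors_B = unname(sw$survivors_per_cutoff["B", ]),
                    stop_cutoff = sw$stop_cutoff, converged = sw$converged)
  }
  if (!is.null(x$frameshift) && inherits(report$frameshift, "gta_frameshift_set")) {
    x$frameshift <- lapply(unclass(report$frameshift), function(cand) {
      list(shift = cand$shift, junction = cand$junction, strand = cand$strand,
           window = as.list(cand$window),
           slippery = cand$slippery, palindromes = cand$palindromes,
           repeats = cand$repeats, fusion_length = nchar(cand$fusion_protein),
           evidence_score = cand$evidence_score)
    })
  }
  x <- rapply(x, unclass, how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(path)
}
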