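#' Run the full GTA screening pipeline on a particle prep
#'
#' Orchestrates every stage over a pair of contig sets: coverage-stringency
#' convergence to the shared core, ORF calling and role annotation of the
#' core, element classification, frameshift-evidence detection, shared-repeat
#' analysis against the host genome (when given), host packaging assessment
#' by k-mer mapping, the long-ORF EAM screen and foreign-ORF check, and the
#' degenerate-primer PCR QC.
#'
#' @param setA,setB contig tables (e.g. from [read_fasta()] or a
#'   [simulate_particle_prep()] object's `sets`).
#' @param host_genome optional host genome contig table.
#' @param panel,foreign_panel role panels.
#' @param schedule,max_survivors,min_core convergence parameters
#'   (see [sweep_convergence()]).
#' @param min_orf_nt,start_codons,min_identity,min_panel_cov annotation
#'   parameters.
#' @param primers QC primer pair (list with `fwd`, `rev`).
#' @return a `gta_report` consolidating all stage outputs, with the
#'   effective configuration embedded.
#' @export
run_pipeline <- function(setA, setB, host_genome = NULL,
                         panel = default_role_panel(),
                         foreign_panel = default_foreign_panel(),
                         schedule = c(0, 5, 10, 50, 100, 500, 1000, 2000, 3000),
                         max_survivors = 3L, min_core = 5000L,
                         min_orf_nt = 150L,
                         start_codons = c("ATG", "GTG", "TTG"),
                         min_identity = 0.35, min_panel_cov = 0.5,
                         primers = orf7_qc_primers()) {
  config <- list(schedule = schedule, max_survivors = max_survivors,
                 min_core = min_core, min_orf_nt = min_orf_nt,
                 start_codons = start_codons, min_identity = min_identity,
                 min_panel_cov = min_panel_cov, primers = primers)
  sweep <- sweep_convergence(setA, setB, schedule = schedule,
                             max_survivors = max_survivors, min_core = min_core)
  annotation <- NULL; classification <- NULL; frameshift <- NULL
  repeats <- NULL; pcr <- NULL
  if (sweep$converged) {
    core <- sweep$core
    orfs <- find_orfs(core$core_seq, "core", min_nt = min_orf_nt,
                      start_codons = start_codons)
    annotation <- annotate_orfs(orfs, panel, min_identity = min_identity,
                                min_panel_cov = min_panel_cov)
    classification <- classify_element(annotation, core$length, panel)
    # candidate search over the annotated gene set: overlap architectures
    # between spurious unannotated calls are not biologically meaningful
    genes <- annotation[!is.na(annotation$role_name), , drop = FALSE]
    frameshift <- detect_fusion_candidates(genes, core$core_seq)
    pcr <- insilico_pcr(core$core_seq, primers$fwd, primers$rev)
  }
  host_profile <- NULL; long_orfs <- NULL; foreign_count <- NULL
  long_orfs <- screen_long_orfs(setA, panel, min_identity = min_identity,
                                min_panel_cov = min_panel_cov)
  foreign_count <- foreign_orf_check(long_orfs, foreign_panel, panel,
                                     min_identity = min_identity,
                                     min_panel_cov = min_panel_cov)
  if (!is.null(host_genome)) {
    host_profile <- map_contigs_to_host(rbind(setA[, c("id", "seq")],
                                              setB[, c("id", "seq")]),
                                        host_genome)
    if (sweep$converged) {
      repeats <- shared_exact_repeats(sweep$core$core_seq,
                                      host_genome$seq[1], min_len = 50L)
    }
  }
  build_report(sweep = sweep, core = sweep$core, annotation = annotation,
               classification = classification, frameshift = frameshift,
               repeats = repeats, host_profile = host_profile,
               long_orfs = long_orfs, foreign_count = foreign_count,
               pcr = pcr, config = config)
}
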