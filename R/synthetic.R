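## ---------------------------------------------------------------------------
## Synthetic particle-prep generator.
##
## The generator emulates the situation the pipeline is built for: a compact
## (~15.6 kb) phage-like element packaged at very high assembler coverage,
## recovered independently in two contig sets that agree on the element and
## differ only in their flanks; a background of low-coverage random fragments
## of the host genome; rare long contigs carrying single giant EAM-class
## ORFs; and a hydrolase locus split by a +1 programmed ribosomal frameshift
## with planted junction evidence (slippery heptamer, 10 bp palindrome,
## duplicated 9 bp repeat).
## ---------------------------------------------------------------------------

## Role vocabulary of the synthetic core, in gene order. aa_len values are a
## modeling choice (per-role plausible sizes); the hydrolase pair sizes
## (64 aa and 175 aa) are fixed by the frameshift architecture.
.CORE_ROLE_TABLE <- data.frame(
  role_name = c("methylase", "hypothetical_2", "ankyrin_repeat_small",
                "terminase", "gpW", "hydrolase_orf6", "hydrolase_orf7",
                "portal", "s49_peptidase", "head_decoration",
                "major_capsid_E", "hypothetical_12", "tail_Z",
                "hypothetical_14", "baseplate_V", "PAAR", "baseplate_W",
                "baseplate_J", "tail_I", "hypothetical_20", "hypothetical_21",
                "DUF2924"),
  category = c("other", "other", "other", "packaging", "head", "lysis",
               "lysis", "head", "head", "head", "head", "other", "tail",
               "other", "baseplate", "baseplate", "baseplate", "baseplate",
               "tail", "other", "other", "other"),
  aa_len = c(410L, 180L, 220L, 433L, 120L, 64L, 175L, 450L, 300L, 190L,
             360L, 150L, 200L, 160L, 210L, 95L, 180L, 310L, 240L, 140L,
             130L, 230L),
  stringsAsFactors = FALSE)

## Fixed codons that realise the frameshift junction architecture and the
## planted evidence motifs inside the hydrolase coding regions.
## hydrolase_orf6 (64 aa): 9-bp repeat copy GCTGAAGAT at codons 52-54; a +1
## frame stop (TAA) via codons 58-59; slippery heptamer AAATTTT via codons
## 60-62; codons 63-64 place the downstream ATG in the +1 frame overlapping
## the stop codon.
.HYD6_CODONS <- c(`52` = "GCT", `53` = "GAA", `54` = "GAT",
                  `58` = "CTA", `59` = "AAT", `60` = "AAA", `61` = "TTT",
                  `62` = "TAC", `63` = "CAT", `64` = "GGT")
## hydrolase_orf7 (175 aa): codons 2-3 are dictated by the overlap with the
## orf6 stop; codons 5-8 plant the 10 bp palindrome ACGAATTCGT; codons 10-12
## plant the second 9-bp repeat copy; codons 30-37 and 150-157 plant one
## concrete resolution of each degenerate QC primer (forward site and
## reverse-complemented reverse site).
.HYD7_CODONS <- c(`2` = "GTT", `3` = "AAG", `4` = "GAA",
                  `5` = "ACG", `6` = "AAT", `7` = "TCG", `8` = "TGG",
                  `10` = "GCT", `11` = "GAA", `12` = "GAT",
                  `30` = "CTG", `31` = "GCT", `32` = "TCA", `33` = "AGG",
                  `34` = "TGC", `35` = "TTT", `36` = "ATT", `37` = "GCA",
                  `150` = "GCT", `151` = "ACT", `152` = "GTT", `153` = "ATT",
                  `154` = "TGG", `155` = "TCT", `156` = "CTT", `157` = "GAA")

.EAM_ROLES <- c("ankyrin", "AAA_ATPase", "tape_measure")

#' Parameters of the synthetic particle-prep simulation
#'
#' Defaults encode the study conditions the generator emulates: a 15,638 nt
#' core carrying 22 same-strand genes with a frameshift-split hydrolase
#' locus, core coverage three orders of magnitude above the host-fragment
#' background, GC content 0.36, and three EAM-class long-ORF loci.
#'
#' @param seed integer RNG seed; fixed seed implies identical output.
#' @param core_length core element length (nt).
#' @param n_core_genes number of core genes (first `n` roles of the packaged
#'   vocabulary).
#' @param frameshift_locus plant the +1 frameshift hydrolase locus (requires
#'   `n_core_genes >= 7`).
#' @param flank_len length (nt) of the dataset-specific random flank.
#' @param host_contig_lengths lengths of the two host-genome contigs.
#' @param n_host_fragments random host fragments per dataset.
#' @param host_fragment_cov_range,core_cov_range,eam_cov_range coverage
#'   ranges (uniform draws).
#' @param n_eam_contigs number of EAM-class long-ORF loci (roles cycle
#'   through ankyrin, AAA-ATPase, tape measure).
#' @param eam_orf_min_len minimum EAM ORF length (nt).
#' @param gc background GC fraction.
#' @return class `gta_sim_params` (a validated list).
#' @export
simulation_params <- function(seed = 1L, core_length = 15638L,
                              n_core_genes = 22L, frameshift_locus = TRUE,
                              flank_len = 500L,
                              host_contig_lengths = c(60000L, 40000L),
                              n_host_fragments = 40L,
                              host_fragment_cov_range = c(1, 5),
                              core_cov_range = c(1000, 4500),
                              eam_cov_range = c(2, 30),
                              n_eam_contigs = 3L, eam_orf_min_len = 2001L,
                              gc = 0.36) {
  p <- list(seed = as.integer(seed), core_length = as.integer(core_length),
            n_core_genes = as.integer(n_core_genes),
            frameshift_locus = isTRUE(frameshift_locus),
            flank_len = as.integer(flank_len),
            host_contig_lengths = as.integer(host_contig_lengths),
            n_host_fragments = as.integer(n_host_fragments),
            host_fragment_cov_range = as.numeric(host_fragment_cov_range),
            core_cov_range = as.numeric(core_cov_range),
            eam_cov_range = as.numeric(eam_cov_range),
            n_eam_contigs = as.integer(n_eam_contigs),
            eam_orf_min_len = as.integer(eam_orf_min_len),
            gc = as.numeric(gc))
  stopifnot(p$n_core_genes >= 1L, p$n_core_genes <= nrow(.CORE_ROLE_TABLE),
            p$n_host_fragments >= 0L, p$n_eam_contigs >= 0L,
            p$flank_len >= 0L, length(p$host_contig_lengths) == 2L,
            p$gc > 0, p$gc < 1,
            diff(p$host_fragment_cov_range) >= 0,
            diff(p$core_cov_range) >= 0, diff(p$eam_cov_range) >= 0)
  if (p$core_length < 3L * p$n_core_genes * 50L)
    stop("core_length must be at least 3 * n_core_genes * 50 nt", call. = FALSE)
  structure(p, class = "gta_sim_params")
}

## Build the frameshift-split hydrolase locus from panel proteins p6/p7.
## Returns the 715 nt locus sequence plus relative truth coordinates.
.build_hydrolase_locus <- function(p6, p7) {
  stopifnot(nchar(p6) == 64L, nchar(p7) == 175L)
  orf6_nt <- .reverse_translate(p6, as.list(.HYD6_CODONS))   # 195 nt incl stop
  tail_cods <- as.list(.HYD7_CODONS[as.integer(names(.HYD7_CODONS)) >= 4L])
  aa7 <- .chars(p7)
  cba <- .codons_by_aa()
  cods <- vapply(aa7[4:175], function(a) {
    opts <- cba[[a]]; opts[sample.int(length(opts), 1)]
  }, character(1), USE.NAMES = FALSE)
  for (nm in names(tail_cods)) cods[as.integer(nm) - 3L] <- tail_cods[[nm]]
  locus <- paste0(orf6_nt, "G", paste(cods, collapse = ""), "TAA")
  stopifnot(nchar(locus) == 715L)
  # self-checks: the planted architecture must be readable back
  stopifnot(substr(locus, 188L, 190L) == "ATG",
            translate_orf(substr(locus, 188L, 715L)) == p7,
            translate_orf(substr(locus, 1L, 195L)) == p6,
            substr(locus, 178L, 184L) == "AAATTTT",
            substr(locus, 200L, 209L) == revcomp(substr(locus, 200L, 209L)),
            substr(locus, 154L, 162L) == substr(locus, 215L, 223L))
  list(seq = locus,
       orf6 = c(0L, 195L), orf7 = c(187L, 715L),
       junction = 187L, slippery_pos = 177L,
       palindrome = c(pos = 199L, length = 10L),
       repeat_pos = c(153L, 214L), repeat_len = 9L)
}

#' Generate the synthetic core element
#'
#' Builds a single-strand core of `core_length` nt carrying
#' `n_core_genes` non-overlapping genes in the packaged role order, each
#' starting with ATG and ending with a stop, separated by stop-rich frame
#' insulators and GC-0.36 random filler. With `frameshift_locus`, genes 6
#' and 7 form the hydrolase locus whose downstream ORF starts in the +1
#' frame inside the upstream ORF, with a slippery heptamer, a 10 bp
#' palindrome and two copies of a 9 bp repeat planted within +/-60 nt of the
#' junction.
#'
#' @param params a [simulation_params()] object.
#' @param panel role panel supplying the gene products
#'   (default [default_role_panel()]).
#' @return list with `core_seq`, `orf_table` (role, category, 0-based
#'   half-open coordinates, strand, aa_len) and `frameshift` truth (or
#'   `NULL`).
#' @export
generate_core_element <- function(params, panel = default_role_panel()) {
  stopifnot(inherits(params, "gta_sim_params"))
  .with_seed(params$seed, .generate_core_element_impl(params, panel))
}

.generate_core_element_impl <- function(params, panel) {
  roles <- .CORE_ROLE_TABLE[seq_len(params$n_core_genes), ]
  prot_of <- stats::setNames(panel$protein_seq, panel$role_name)
  missing <- setdiff(roles$role_name, names(prot_of))
  if (length(missing))
    stop(sprintf("panel lacks core role(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  use_locus <- params$frameshift_locus && params$n_core_genes >= 7L
  ins <- nchar(.FRAME_INSULATOR)

  unit_roles <- if (use_locus) {
    c(roles$role_name[seq_len(5L)], "hydrolase_locus",
      roles$role_name[-seq_len(7L)])
  } else roles$role_name
  n_units <- length(unit_roles)

  aa_len <- stats::setNames(roles$aa_len, roles$role_name)
  unit_len <- function(aa) {
    vapply(unit_roles, function(u) {
      if (u == "hydrolase_locus") 715L else 3L * (aa[[u]] + 1L)
    }, integer(1))
  }
  total <- sum(unit_len(aa_len)) + ins * (n_units + 1L)
  if (total > params$core_length) {
    # scale ordinary gene sizes down to fit (hydrolase locus is fixed)
    fixed_nt <- (if (use_locus) 715L else 0L) + ins * (n_units + 1L)
    ord <- setdiff(unit_roles, "hydrolase_locus")
    budget <- params$core_length - fixed_nt - 3L * length(ord)
    f <- budget / (3 * sum(aa_len[ord]))
    aa_len[ord] <- pmax(50L, as.integer(floor(aa_len[ord] * f)))
    total <- sum(unit_len(aa_len)) + ins * (n_units + 1L)
    if (total > params$core_length)
      stop("core_length too small to host the gene set", call. = FALSE)
  }
  leftover <- params$core_length - total
  filler <- as.integer(stats::rmultinom(1, leftover, rep(1, n_units + 1L)))

  parts <- character(0)
  pos <- 0L
  orf_rows <- list()
  fs_truth <- NULL
  cat_of <- stats::setNames(roles$category, roles$role_name)
  for (u in seq_len(n_units)) {
    fill <- .random_dna(filler[u], params$gc)
    parts <- c(parts, fill, .FRAME_INSULATOR)
    pos <- pos + filler[u] + ins
    role <- unit_roles[u]
    if (role == "hydrolase_locus") {
      loc <- .build_hydrolase_locus(prot_of[["hydrolase_orf6"]],
                                    prot_of[["hydrolase_orf7"]])
      parts <- c(parts, loc$seq)
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        role_name = c("hydrolase_orf6", "hydrolase_orf7"),
        category = "lysis",
        start = pos + c(loc$orf6[1], loc$orf7[1]),
        end = pos + c(loc$orf6[2], loc$orf7[2]),
        strand = "+", aa_len = c(64L, 175L), stringsAsFactors = FALSE)
      fs_truth <- list(
        junction = pos + loc$junction,
        shift = "+1",
        slippery_pos = pos + loc$slippery_pos,
        palindrome_pos = pos + unname(loc$palindrome["pos"]),
        palindrome_len = unname(loc$palindrome["length"]),
        repeat_pos = pos + loc$repeat_pos,
        repeat_len = loc$repeat_len)
      pos <- pos + 715L
    } else {
      prot <- substr(prot_of[[role]], 1L, aa_len[[role]])
      gene <- .reverse_translate(prot)
      parts <- c(parts, gene)
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        role_name = role, category = unname(cat_of[role]),
        start = pos, end = pos + nchar(gene), strand = "+",
        aa_len = nchar(prot), stringsAsFactors = FALSE)
      pos <- pos + nchar(gene)
    }
  }
  parts <- c(parts, .FRAME_INSULATOR, .random_dna(filler[n_units + 1L], params$gc))
  core_seq <- paste(parts, collapse = "")
  stopifnot(nchar(core_seq) == params$core_length)
  orf_table <- do.call(rbind, orf_rows)
  rownames(orf_table) <- NULL
  list(core_seq = core_seq, orf_table = orf_table, frameshift = fs_truth)
}

#' Generate a synthetic host genome with embedded element copies
#'
#' Two random-background contigs: the first embeds one exact copy of the
#' core (the resident prophage region) and the EAM-class long-ORF loci; the
#' second embeds a rearranged partial copy with a duplicated baseplate block,
#' two IS110-family transposase genes and a recombinase.
#'
#' @param params a [simulation_params()] object.
#' @param core output of [generate_core_element()].
#' @param panel role panel (must contain the EAM roles, `IS110_transposase`
#'   and `recombinase`).
#' @return list with `contigs` (table `id`, `seq`), `prophage_interval`,
#'   `partial_interval`, `eam_loci` (table of gene intervals and roles) and
#'   `reserved` (per-contig list of embedded intervals, used to sample clean
#'   background fragments).
#' @export
generate_host_genome <- function(params, core, panel = default_role_panel()) {
  stopifnot(inherits(params, "gta_sim_params"))
  .with_seed(params$seed + 1L, .generate_host_genome_impl(params, core, panel))
}

.generate_host_genome_impl <- function(params, core, panel) {
  prot_of <- stats::setNames(panel$protein_seq, panel$role_name)
  need <- c(.EAM_ROLES, "IS110_transposase", "recombinase")
  if (length(setdiff(need, names(prot_of))))
    stop("panel lacks EAM/transposase/recombinase roles", call. = FALSE)
  ins <- .FRAME_INSULATOR
  L1 <- params$host_contig_lengths[1]
  L2 <- params$host_contig_lengths[2]

  eam_roles <- if (params$n_eam_contigs > 0L)
    .EAM_ROLES[(seq_len(params$n_eam_contigs) - 1L) %% 3L + 1L] else character(0)
  eam_units <- lapply(eam_roles, function(r) {
    gene <- .reverse_translate(prot_of[[r]])
    if (nchar(gene) < params$eam_orf_min_len)
      stop(sprintf("EAM role %s is shorter than eam_orf_min_len", r), call. = FALSE)
    list(role = r, gene = gene, unit = paste0(ins, gene, ins))
  })

  # contig 1: [bg] core [bg] eam1 [bg] eam2 ... [bg]
  embeds1 <- c(list(list(role = "core", unit = core$core_seq)), eam_units)
  used1 <- sum(vapply(embeds1, function(e) nchar(e$unit), integer(1)))
  n_gap1 <- length(embeds1) + 1L
  if (used1 + n_gap1 * 200L > L1)
    stop("embeddings exceed host contig 1 capacity", call. = FALSE)
  gaps1 <- 200L + as.integer(stats::rmultinom(1, L1 - used1 - n_gap1 * 200L,
                                              rep(1, n_gap1)))
  # contig 2: [bg] partial copy [bg]
  ot <- core$orf_table
  span <- function(r1, r2) {
    i <- match(r1, ot$role_name); j <- match(r2, ot$role_name)
    substr(core$core_seq, ot$start[i] + 1L, ot$end[j])
  }
  partial <- paste0(
    span("terminase", "portal"),
    span("baseplate_V", "baseplate_W"),
    ins, .reverse_translate(prot_of[["IS110_transposase"]]), ins,
    span("tail_Z", ot$role_name[nrow(ot)]),
    span("baseplate_V", "baseplate_W"),
    ins, .reverse_translate(prot_of[["recombinase"]]), ins,
    .reverse_translate(prot_of[["IS110_transposase"]]), ins)
  if (nchar(partial) + 3L * 200L > L2)
    stop("embeddings exceed host contig 2 capacity", call. = FALSE)
  gaps2 <- 200L + as.integer(stats::rmultinom(1, L2 - nchar(partial) - 2L * 200L,
                                              rep(1, 2L)))

  build <- function(gaps, units, gc) {
    parts <- character(0); pos <- 0L; ivals <- list()
    for (i in seq_along(units)) {
      parts <- c(parts, .random_dna(gaps[i], gc))
      pos <- pos + gaps[i]
      parts <- c(parts, units[[i]]$unit)
      ivals[[i]] <- list(role = units[[i]]$role, start = pos,
                         end = pos + nchar(units[[i]]$unit))
      pos <- pos + nchar(units[[i]]$unit)
    }
    parts <- c(parts, .random_dna(gaps[length(gaps)], gc))
    list(seq = paste(parts, collapse = ""), ivals = ivals)
  }
  b1 <- build(gaps1, embeds1, params$gc)
  b2 <- build(gaps2, list(list(role = "partial_copy", unit = partial)), params$gc)
  stopifnot(nchar(b1$seq) == L1, nchar(b2$seq) == L2)

  eam_loci <- if (length(eam_units)) do.call(rbind, lapply(
    seq_along(eam_units), function(i) {
      iv <- b1$ivals[[i + 1L]]
      data.frame(contig = "host_1", role = iv$role,
                 start = iv$start, end = iv$end,
                 orf_start = iv$start + nchar(ins),
                 orf_end = iv$end - nchar(ins), stringsAsFactors = FALSE)
    })) else data.frame()
  list(
    contigs = data.frame(id = c("host_1", "host_2"),
                         seq = c(b1$seq, b2$seq), stringsAsFactors = FALSE),
    prophage_interval = list(contig = "host_1", start = b1$ivals[[1]]$start,
                             end = b1$ivals[[1]]$end),
    partial_interval = list(contig = "host_2", start = b2$ivals[[1]]$start,
                            end = b2$ivals[[1]]$end),
    eam_loci = eam_loci,
    reserved = list(
      host_1 = lapply(b1$ivals, function(x) c(x$start, x$end)),
      host_2 = lapply(b2$ivals, function(x) c(x$start, x$end))))
}

#' Generate the two particle-prep contig sets
#'
#' Dataset A carries the full core with an A-specific random 3' flank;
#' dataset B carries it with a B-specific 5' flank (so the core is the exact
#' sequence shared by the two sets). Each dataset further contains the
#' EAM-locus windows at low-to-moderate coverage and `n_host_fragments`
#' random host background fragments (0.5-8 kb) at low coverage. Contig
#' headers follow the SPAdes `NODE_i_length_L_cov_C` dialect.
#'
#' @param params a [simulation_params()] object.
#' @param core output of [generate_core_element()].
#' @param host output of [generate_host_genome()].
#' @return list with contig tables `A` and `B` and per-dataset `truth`
#'   tables recording every contig's origin.
#' @export
generate_particle_contig_sets <- function(params, core, host) {
  stopifnot(inherits(params, "gta_sim_params"))
  .with_seed(params$seed + 2L,
             .generate_particle_sets_impl(params, core, host))
}

.generate_particle_sets_impl <- function(params, core, host) {
  one_dataset <- function(label, flank_side) {
    seqs <- character(0); covs <- numeric(0)
    origin <- character(0); h_contig <- character(0)
    h_start <- integer(0); h_end <- integer(0)
    flank <- .random_dna(params$flank_len, params$gc)
    core_contig <- if (flank_side == "3prime") paste0(core$core_seq, flank)
                   else paste0(flank, core$core_seq)
    seqs <- c(seqs, core_contig)
    covs <- c(covs, stats::runif(1, params$core_cov_range[1], params$core_cov_range[2]))
    origin <- c(origin, "core")
    h_contig <- c(h_contig, NA); h_start <- c(h_start, NA); h_end <- c(h_end, NA)
    if (nrow(host$eam_loci)) {
      for (i in seq_len(nrow(host$eam_loci))) {
        locus <- host$eam_loci[i, ]
        hs <- host$contigs$seq[host$contigs$id == locus$contig]
        w5 <- sample(1500:1700, 1); w3 <- sample(1500:1700, 1)
        ws <- max(0L, locus$start - w5); we <- min(nchar(hs), locus$end + w3)
        seqs <- c(seqs, substr(hs, ws + 1L, we))
        covs <- c(covs, stats::runif(1, params$eam_cov_range[1], params$eam_cov_range[2]))
        origin <- c(origin, paste0("eam_", locus$role))
        h_contig <- c(h_contig, locus$contig)
        h_start <- c(h_start, ws); h_end <- c(h_end, we)
      }
    }
    if (params$n_host_fragments > 0L) {
      lens <- nchar(host$contigs$seq)
      for (i in seq_len(params$n_host_fragments)) {
        repeat {
          ci <- sample.int(nrow(host$contigs), 1, prob = lens)
          flen <- sample(500:8000, 1)
          if (flen > lens[ci]) next
          fs <- sample.int(lens[ci] - flen + 1L, 1) - 1L
          resv <- host$reserved[[host$contigs$id[ci]]]
          clash <- any(vapply(resv, function(iv)
            fs < iv[2] && (fs + flen) > iv[1], logical(1)))
          if (!clash) break
        }
        seqs <- c(seqs, substr(host$contigs$seq[ci], fs + 1L, fs + flen))
        covs <- c(covs, stats::runif(1, params$host_fragment_cov_range[1],
                                     params$host_fragment_cov_range[2]))
        origin <- c(origin, "host_fragment")
        h_contig <- c(h_contig, host$contigs$id[ci])
        h_start <- c(h_start, fs); h_end <- c(h_end, fs + flen)
      }
    }
    covs <- round(covs, 1)
    ids <- sprintf("NODE_%d_length_%d_cov_%s", seq_along(seqs), nchar(seqs),
                   format(covs, trim = TRUE, nsmall = 1, scientific = FALSE))
    list(contigs = data.frame(id = ids, seq = seqs, coverage = covs,
                              dataset_label = label, stringsAsFactors = FALSE),
         truth = data.frame(id = ids, origin = origin, host_contig = h_contig,
                            host_start = h_start, host_end = h_end,
                            stringsAsFactors = FALSE))
  }
  a <- one_dataset("A", "3prime")
  b <- one_dataset("B", "5prime")
  list(A = a$contigs, B = b$contigs,
       truth = list(A = a$truth, B = b$truth))
}

#' Simulate a full particle-prep experiment
#'
#' Runs the three generator stages under a single parameter set and,
#' optionally, writes the artifacts to disk: `datasetA.fasta`,
#' `datasetB.fasta` (coverage-carrying headers), `host_genome.fasta`,
#' `truth.gff3` (core gene and frameshift features) and `truth.json`.
#'
#' @param params a [simulation_params()] object.
#' @param out_dir optional output directory (created if missing).
#' @param panel role panel.
#' @return class `gta_prep`: list with `params`, `core`, `host`, `sets`.
#' @export
simulate_particle_prep <- function(params = simulation_params(),
                                   out_dir = NULL,
                                   panel = default_role_panel()) {
  core <- generate_core_element(params, panel)
  host <- generate_host_genome(params, core, panel)
  sets <- generate_particle_contig_sets(params, core, host)
  prep <- structure(list(params = params, core = core, host = host,
                         sets = sets), class = "gta_prep")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(sets$A, file.path(out_dir, "datasetA.fasta"))
    write_fasta(sets$B, file.path(out_dir, "datasetB.fasta"))
    write_fasta(host$contigs, file.path(out_dir, "host_genome.fasta"))
    feats <- data.frame(
      seq_id = "core", start = core$orf_table$start, end = core$orf_table$end,
      strand = core$orf_table$strand, feature_type = "gene",
      stringsAsFactors = FALSE)
    feats$attributes <- lapply(core$orf_table$role_name, function(r) c(ID = r))
    if (!is.null(core$frameshift)) {
      fs <- data.frame(seq_id = "core", start = core$frameshift$junction,
                       end = core$frameshift$junction + 3L, strand = "+",
                       feature_type = "frameshift_junction",
                       stringsAsFactors = FALSE)
      fs$attributes <- list(c(ID = "plus1_frameshift"))
      feats <- rbind(feats, fs)
    }
    write_gff3(feats, file.path(out_dir, "truth.gff3"),
               seq_lengths = c(core = nchar(core$core_seq)))
    truth <- list(params = unclass(params),
                  core_seq = core$core_seq,
                  orf_table = core$orf_table,
                  frameshift = core$frameshift,
                  prophage_interval = host$prophage_interval,
                  partial_interval = host$partial_interval,
                  eam_loci = host$eam_loci,
                  dataset_truth = sets$truth)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  prep
}

#' @export
print.gta_prep <- function(x, ...) {
  cat(sprintf("Synthetic particle prep (seed %d)\n", x$params$seed))
  cat(sprintf("  core: %d nt, %d genes%s\n", nchar(x$core$core_seq),
              nrow(x$core$orf_table),
              if (!is.null(x$core$frameshift)) " (+1 frameshift locus)" else ""))
  cat(sprintf("  host: %s nt in 2 contigs\n",
              paste(nchar(x$host$contigs$seq), collapse = " + ")))
  cat(sprintf("  datasets: A = %d contigs, B = %d contigs\n",
              nrow(x$sets$A), nrow(x$sets$B)))
  invisible(x)
}

#' Build a synthetic prophage-scale reference element
#'
#' A 65,653 bp stand-in for a full lambda-like WO-phage genome: the proximal
#' head-tail core followed by an EAM-like module (giant ankyrin, AAA-ATPase
#' and tape measure genes), a recombinase, and random distal filler. Used to
#' exercise the prophage-like branch of [classify_element()] and as a
#' synthetic reference record of the canonical packaged-phage size.
#'
#' @param seed RNG seed.
#' @param length_nt total element length.
#' @param panel role panel.
#' @return list with `seq` and `length`.
#' @export
generate_prophage_element <- function(seed = 1L, length_nt = 65653L,
                                      panel = default_role_panel()) {
  params <- simulation_params(seed = seed)
  core <- generate_core_element(params, panel)
  .with_seed(seed + 3L, {
    prot_of <- stats::setNames(panel$protein_seq, panel$role_name)
    ins <- .FRAME_INSULATOR
    genes <- paste0(ins, vapply(c("recombinase", .EAM_ROLES), function(r)
      .reverse_translate(prot_of[[r]]), character(1)), collapse = "")
    body <- paste0(core$core_seq, genes, ins)
    if (nchar(body) > length_nt)
      stop("length_nt too small for the prophage stand-in", call. = FALSE)
    seq <- paste0(body, .random_dna(length_nt - nchar(body), params$gc))
    list(seq = seq, length = nchar(seq))
  })
}
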