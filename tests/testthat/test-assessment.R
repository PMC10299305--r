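panel <- default_role_panel()

mk_orfs <- function(roles, nt = 900L, strand = "+") {
  data.frame(seq_id = "e", start = seq_along(roles) * 1000L,
             end = seq_along(roles) * 1000L + nt,
             strand = strand, frame = 0L, nt_length = nt,
             protein = "MKT", role_name = roles,
             align_score = 100, identity_frac = 1, panel_cov_frac = 1,
             stringsAsFactors = FALSE)
}

test_that("a compact single-strand head-tail element is called GTA-like", {
  core <- generate_core_element(simulation_params(seed = 1))
  ann <- annotate_orfs(find_orfs(core$core_seq, "core"), panel)
  call <- classify_element(ann, nchar(core$core_seq), panel)
  expect_equal(call$label, "GTA-like")
  expect_true(all(unlist(call$criteria)))
})

test_that("a phage-scale element with EAM content and recombinase is prophage-like", {
  pw <- generate_prophage_element(seed = 2)
  ann <- annotate_orfs(find_orfs(pw$seq, "pw"), panel)
  call <- classify_element(ann, pw$length, panel)
  expect_equal(call$label, "prophage-like")
  expect_false(call$criteria$size_ok)
  expect_false(call$criteria$eam_absent)
  expect_false(call$criteria$regulatory_absent)
  expect_true(call$criteria$head_tail_complete)
})

test_that("the label is a pure, total function of the five criteria", {
  # portal alone: incomplete head-tail module -> ambiguous
  call <- classify_element(mk_orfs("portal"), 15000L, panel)
  expect_equal(call$label, "ambiguous")
  # complete module but oversized -> prophage-like
  roles <- c("terminase", "portal", "major_capsid_E", "tail_Z", "baseplate_V")
  expect_equal(classify_element(mk_orfs(roles), 40000L, panel)$label,
               "prophage-like")
  # complete module, compact, clean -> GTA-like
  expect_equal(classify_element(mk_orfs(roles), 15638L, panel)$label,
               "GTA-like")
  # compact but with an EAM role -> ambiguous (module present, size ok)
  withEAM <- mk_orfs(c(roles, "ankyrin"))
  expect_equal(classify_element(withEAM, 15638L, panel)$label, "prophage-like")
  # a long ORF alone breaks eam_absent even without an EAM role
  long <- mk_orfs(roles)
  long$nt_length[1] <- 2500L
  expect_equal(classify_element(long, 15638L, panel)$criteria$eam_absent, FALSE)
  # a regulatory role blocks GTA-like but does not make it prophage-like
  withReg <- mk_orfs(c(roles, "recombinase"))
  expect_equal(classify_element(withReg, 15638L, panel)$label, "ambiguous")
  expect_error(classify_element(mk_orfs("portal")[0, ], 1000L, panel),
               "at least one")
})

test_that("host mapping: identity query covers the host, copies stack depth", {
  withr::with_seed(3, {
    host <- data.frame(id = "h", seq = random_dna_str(4000),
                       stringsAsFactors = FALSE)
    q <- data.frame(id = "q", seq = host$seq, stringsAsFactors = FALSE)
    prof <- map_contigs_to_host(q, host)
    expect_equal(prof$contigs$h$breadth_gt0, 1.0)

    frag <- substr(host$seq, 1001, 1800)
    q6 <- data.frame(id = paste0("q", 1:6), seq = frag,
                     stringsAsFactors = FALSE)
    p6 <- map_contigs_to_host(q6, host)
    expect_true(all(p6$contigs$h$depth[1001:1800] >= 6))
    expect_equal(p6$contigs$h$breadth_gt5, 800 / 4000)
    expect_lte(p6$contigs$h$breadth_gt5, p6$contigs$h$breadth_gt0)
  })
  expect_error(map_contigs_to_host(data.frame(id = "q", seq = "ACGT"),
                                   data.frame(id = "h", seq = "ACGT"), k = 9L),
               "rejected")
})

test_that("host mapping breadth matches the planted fragment footprint", {
  prep <- simulate_particle_prep(simulation_params(seed = 23, n_host_fragments = 12,
                                                   host_contig_lengths = c(45000L, 35000L)))
  tr <- prep$sets$truth$A
  fr <- prep$sets$A[tr$origin == "host_fragment", ]
  prof <- map_contigs_to_host(fr, prep$host$contigs)
  for (hid in prep$host$contigs$id) {
    L <- nchar(prep$host$contigs$seq[prep$host$contigs$id == hid])
    covered <- logical(L)
    tt <- tr[tr$origin == "host_fragment" & tr$host_contig == hid, ]
    for (i in seq_len(nrow(tt)))
      covered[(tt$host_start[i] + 1):tt$host_end[i]] <- TRUE
    expect_equal(prof$contigs[[hid]]$breadth_gt0, mean(covered),
                 tolerance = 1e-6)
    expect_lte(prof$contigs[[hid]]$breadth_gt5, prof$contigs[[hid]]$breadth_gt0)
  }
})

test_that("the long-ORF screen applies both thresholds and recovers EAM truth", {
  prep <- simulate_particle_prep(simulation_params(seed = 29, n_host_fragments = 4,
                                                   host_contig_lengths = c(45000L, 35000L)))
  rows <- screen_long_orfs(prep$sets$A, panel)
  expect_equal(nrow(rows), 3L)
  expect_setequal(rows$role_class, c("ankyrin", "AAA-ATPase", "tape measure"))
  truth <- prep$sets$truth$A
  for (i in seq_len(nrow(rows))) {
    want <- sub("^eam_", "", truth$origin[truth$id == rows$contig_id[i]])
    expect_equal(rows$role_name[i], want)
  }
  # threshold edges: short contig / short ORFs are excluded
  short_contig <- data.frame(id = "s", seq = substr(prep$sets$A$seq[2], 1, 4999),
                             stringsAsFactors = FALSE)
  expect_equal(nrow(screen_long_orfs(short_contig, panel)), 0L)
  bg <- data.frame(id = "bg", seq = gtasieve:::.with_seed(5, gtasieve:::.random_dna(6000)),
                   stringsAsFactors = FALSE)
  expect_equal(nrow(screen_long_orfs(bg, panel)), 0L)
})

test_that("the foreign-ORF check counts decoy best-matches and nothing else", {
  foreign <- default_foreign_panel()
  prep <- simulate_particle_prep(simulation_params(seed = 31, n_host_fragments = 0L,
                                                   host_contig_lengths = c(45000L, 35000L)))
  rows <- screen_long_orfs(prep$sets$A, panel)
  expect_equal(foreign_orf_check(rows, foreign, panel), 0L)
  # plant a decoy-derived long ORF: it must be counted
  withr::with_seed(55, {
    decoy_prot <- foreign$protein_seq[foreign$role_name == "mosquito_vitellogenin"]
    gene <- gtasieve:::.reverse_translate(decoy_prot)
    contig <- paste0(gtasieve:::.random_dna(2000), gtasieve:::.FRAME_INSULATOR,
                     gene, gtasieve:::.FRAME_INSULATOR, gtasieve:::.random_dna(2000))
  })
  planted <- screen_long_orfs(data.frame(id = "x", seq = contig,
                                         stringsAsFactors = FALSE), panel,
                              min_orf = 1200L)
  expect_equal(nrow(planted), 1L)
  expect_equal(foreign_orf_check(planted, foreign, panel), 1L)
  expect_error(foreign_orf_check(rows, foreign[0, ], panel), "non-empty")
})

test_that("in-silico PCR finds degenerate-primer products under the mismatch policy", {
  primers <- orf7_qc_primers()
  withr::with_seed(71, {
    fwd_site <- "CTGGCTTCAAGGTGCTTTATTGC"   # one resolution of the fwd primer
    rev_site <- revcomp("TCAAGAGACCAAATAACAGTAGC")  # resolved rev primer, bottom strand
    tmpl <- paste0(random_dna_str(200), fwd_site, random_dna_str(300),
                   rev_site, random_dna_str(150))
    prod <- insilico_pcr(tmpl, primers$fwd, primers$rev)
    expect_equal(nrow(prod), 1L)
    expect_equal(prod$start, 200L)
    expect_equal(prod$length, 23L + 300L + 23L)
    expect_equal(prod$fwd_mismatches, 0L)
    expect_equal(prod$rev_mismatches, 0L)
    # no sites -> no products
    expect_equal(nrow(insilico_pcr(random_dna_str(800), primers$fwd,
                                   primers$rev)), 0L)
    # span guard
    far <- paste0(random_dna_str(100), fwd_site, random_dna_str(5000),
                  rev_site, random_dna_str(100))
    expect_equal(nrow(insilico_pcr(far, primers$fwd, primers$rev,
                                   max_product = 2000L)), 0L)
    # a 3'-terminal mismatch kills the site even within the mismatch budget
    bad3 <- sub("TTGC$", "TTGA", fwd_site)
    tmpl2 <- paste0(random_dna_str(100), bad3, random_dna_str(200), rev_site,
                    random_dna_str(50))
    expect_equal(nrow(insilico_pcr(tmpl2, primers$fwd, primers$rev)), 0L)
  })
  expect_error(insilico_pcr("ACGT", "AC", "ACGTT"), "shorter")
})

test_that("the synthetic core is PCR-positive for the hydrolase QC primers", {
  core <- generate_core_element(simulation_params(seed = 37))
  primers <- orf7_qc_primers()
  prod <- insilico_pcr(core$core_seq, primers$fwd, primers$rev)
  expect_gte(nrow(prod), 1L)
  expect_true(all(prod$fwd_mismatches == 0L))
  i7 <- match("hydrolase_orf7", core$orf_table$role_name)
  expect_gte(prod$start[1], core$orf_table$start[i7])
  expect_lte(prod$end[1], core$orf_table$end[i7])
})

test_that("reports consolidate sections, validate, and serialise deterministically", {
  core <- generate_core_element(simulation_params(seed = 2))
  ann <- annotate_orfs(find_orfs(core$core_seq, "core"), panel)
  call <- classify_element(ann, nchar(core$core_seq), panel)
  rep1 <- build_report(classification = call, config = list(seed = 2))
  expect_true(validate_report(rep1))
  expect_named(rep1, c("classification", "config"))
  expect_error(build_report(config = list()), "at least one")

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, f1)
  write_report(rep1, f2)
  expect_identical(readLines(f1), readLines(f2))
  parsed <- jsonlite::read_json(f1)
  expect_equal(parsed$classification$label, "GTA-like")
})
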