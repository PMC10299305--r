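params_small <- simulation_params(seed = 11, n_host_fragments = 6,
                                  host_contig_lengths = c(45000L, 35000L))

test_that("the generator is deterministic: one seed, identical artifacts", {
  a <- simulate_particle_prep(params_small)
  b <- simulate_particle_prep(params_small)
  expect_identical(a$core$core_seq, b$core$core_seq)
  expect_identical(a$host$contigs$seq, b$host$contigs$seq)
  expect_identical(a$sets$A, b$sets$A)
  expect_identical(a$sets$B, b$sets$B)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_particle_prep(params_small, out_dir = d1)
  simulate_particle_prep(params_small, out_dir = d2)
  for (f in c("datasetA.fasta", "datasetB.fasta", "host_genome.fasta",
              "truth.gff3", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("core truth is self-consistent: ORFs translate cleanly, motifs sit where recorded", {
  core <- generate_core_element(simulation_params(seed = 3))
  expect_equal(nchar(core$core_seq), 15638L)
  expect_equal(nrow(core$orf_table), 22L)
  expect_true(all(core$orf_table$strand == "+"))
  for (i in seq_len(nrow(core$orf_table))) {
    nt <- substr(core$core_seq, core$orf_table$start[i] + 1L,
                 core$orf_table$end[i])
    prot <- translate_orf(nt)  # errors on any internal stop
    expect_equal(nchar(prot), core$orf_table$aa_len[i])
  }
  fs <- core$frameshift
  expect_equal(substr(core$core_seq, fs$slippery_pos + 1L, fs$slippery_pos + 7L),
               "AAATTTT")
  pal <- substr(core$core_seq, fs$palindrome_pos + 1L,
                fs$palindrome_pos + fs$palindrome_len)
  expect_identical(pal, revcomp(pal))
  r1 <- substr(core$core_seq, fs$repeat_pos[1] + 1L, fs$repeat_pos[1] + fs$repeat_len)
  r2 <- substr(core$core_seq, fs$repeat_pos[2] + 1L, fs$repeat_pos[2] + fs$repeat_len)
  expect_identical(r1, r2)
  # all planted evidence lies within +/-60 nt of the junction
  expect_true(all(abs(c(fs$slippery_pos, fs$palindrome_pos, fs$repeat_pos) -
                        fs$junction) <= 60L))
  # the downstream start codon sits in the +1 frame inside the upstream ORF
  i6 <- match("hydrolase_orf6", core$orf_table$role_name)
  expect_lt(fs$junction, core$orf_table$end[i6] - 3L)
  expect_equal((fs$junction - core$orf_table$start[i6]) %% 3L, 1L)
})

test_that("six-frame calling on the synthetic core recovers exactly the 22 planted genes", {
  core <- generate_core_element(simulation_params(seed = 5))
  called <- find_orfs(core$core_seq, "core")
  key <- function(d) paste(d$start, d$end, d$strand)
  expect_true(all(key(core$orf_table) %in% key(called)))
  # and no called ORF crosses the EAM length threshold
  expect_lt(max(called$nt_length), 2000L)
})

test_that("a single-gene core scales the gene down but keeps a real ORF", {
  p <- simulation_params(seed = 2, core_length = 600L, n_core_genes = 1L,
                         frameshift_locus = FALSE)
  core <- generate_core_element(p)
  expect_equal(nchar(core$core_seq), 600L)
  expect_equal(nrow(core$orf_table), 1L)
  expect_gte(core$orf_table$end[1] - core$orf_table$start[1], 150L)
  called <- find_orfs(core$core_seq, "c", min_nt = 150L)
  expect_true(any(called$start == core$orf_table$start[1] &
                    called$end == core$orf_table$end[1]))
})

test_that("host genome embeds one exact core copy and the requested EAM loci", {
  core <- generate_core_element(params_small)
  host <- generate_host_genome(params_small, core)
  pi <- host$prophage_interval
  hseq <- host$contigs$seq[host$contigs$id == pi$contig]
  expect_identical(substr(hseq, pi$start + 1L, pi$end), core$core_seq)
  # exactly one exact copy in the whole host genome
  n_copies <- sum(vapply(host$contigs$seq, function(s)
    length(gregexpr(core$core_seq, s, fixed = TRUE)[[1]]) *
      (gregexpr(core$core_seq, s, fixed = TRUE)[[1]][1] != -1L), numeric(1)))
  expect_equal(n_copies, 1)
  expect_equal(nrow(host$eam_loci), 3L)
  for (i in seq_len(nrow(host$eam_loci))) {
    locus <- host$eam_loci[i, ]
    hs <- host$contigs$seq[host$contigs$id == locus$contig]
    gene <- substr(hs, locus$orf_start + 1L, locus$orf_end)
    expect_gte(nchar(gene), 2001L)
    expect_type(translate_orf(gene), "character")
  }
})

test_that("host contigs too small for the embeddings raise a capacity error", {
  p <- simulation_params(seed = 1, host_contig_lengths = c(20000L, 9000L))
  core <- generate_core_element(p)
  expect_error(generate_host_genome(p, core), "capacity")
})

test_that("datasets share exactly the planted core and differ only in their flanks", {
  prep <- simulate_particle_prep(params_small)
  a_core <- prep$sets$A$seq[prep$sets$truth$A$origin == "core"]
  b_core <- prep$sets$B$seq[prep$sets$truth$B$origin == "core"]
  r <- longest_common_exact(a_core, b_core)
  expect_equal(r$length, nchar(prep$core$core_seq))
  expect_identical(r$substring, prep$core$core_seq)
  expect_equal(r$posA, 0L)                      # A varies only 3'
  expect_equal(r$posB, nchar(b_core) - r$length) # B varies only 5'
})

test_that("n_host_fragments = 0 leaves only core and EAM contigs", {
  p <- simulation_params(seed = 4, n_host_fragments = 0L)
  prep <- simulate_particle_prep(p)
  expect_equal(nrow(prep$sets$A), 1L + 3L)
  expect_true(all(prep$sets$truth$A$origin %in%
                    c("core", "eam_ankyrin", "eam_AAA_ATPase", "eam_tape_measure")))
})

test_that("planted host fragments are true substrings of the host genome", {
  prep <- simulate_particle_prep(params_small)
  tr <- prep$sets$truth$A
  frag <- which(tr$origin == "host_fragment")
  for (i in frag) {
    hs <- prep$host$contigs$seq[prep$host$contigs$id == tr$host_contig[i]]
    expect_identical(prep$sets$A$seq[i],
                     substr(hs, tr$host_start[i] + 1L, tr$host_end[i]))
  }
})

test_that("the prophage-scale stand-in has the canonical packaged-phage length", {
  pw <- generate_prophage_element(seed = 2)
  expect_equal(pw$length, 65653L)
  expect_equal(nchar(pw$seq), 65653L)
})
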