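test_that("the planted hydrolase locus yields exactly one +1 candidate with full evidence", {
  prep_core <- generate_core_element(simulation_params(seed = 21))
  ann <- annotate_orfs(find_orfs(prep_core$core_seq, "core"), default_role_panel())
  genes <- ann[!is.na(ann$role_name), ]
  cands <- detect_fusion_candidates(genes, prep_core$core_seq)
  expect_length(cands, 1L)
  cand <- cands[[1]]
  expect_equal(cand$shift, "+1")
  expect_equal(cand$junction, prep_core$frameshift$junction)
  expect_equal(cand$upstream$role_name, "hydrolase_orf6")
  expect_equal(cand$downstream$role_name, "hydrolase_orf7")
  # fusion = upstream codons before the shift point + downstream product
  up_codons <- (cand$junction - cand$upstream$start) %/% 3L
  expect_equal(nchar(cand$fusion_protein), up_codons + 175L)
  expect_gte(nrow(cand$slippery), 1L)
  expect_gte(max(cand$palindromes$length), 10L)
  expect_gte(nrow(cand$repeats), 1L)
})

test_that("non-overlapping, in-frame or opposite-strand pairs yield no candidate", {
  # two ORFs in the same frame, no overlap
  s <- paste0("ATGAAACCCTAA", "ATGTTTGGGTAA")
  orfs <- find_orfs(s, min_nt = 9L)
  fwd <- orfs[orfs$strand == "+", ]
  expect_length(detect_fusion_candidates(fwd, s), 0L)
  # opposite strands never pair
  mixed <- data.frame(
    seq_id = "s", start = c(0L, 10L), end = c(30L, 25L),
    strand = c("+", "-"), frame = c(0L, 0L), nt_length = c(30L, 15L),
    protein = c("MKAYWDEPQ", "MKAY"), stringsAsFactors = FALSE)
  expect_length(detect_fusion_candidates(mixed, random_dna_str(40)), 0L)
})

test_that("slippery heptamer scanning implements the XXXYYYN class", {
  hits <- scan_slippery("GGGAAATTTTCCC")
  expect_true(any(hits$pos == 3 & hits$heptamer == "AAATTTT"))
  expect_equal(nrow(scan_slippery("ACACACACACAC")), 0L)
  expect_equal(nrow(scan_slippery("AAAAAAA")), 0L)  # X == Y forbidden
  expect_equal(nrow(scan_slippery("AAATTTN")), 0L)  # N never matches
})

test_that("palindrome finding returns maximal revcomp-invariant substrings", {
  p <- find_palindromes("AAGAATTCAA")
  expect_equal(nrow(p), 1L)
  expect_equal(p$pos, 2L)
  expect_equal(p$length, 6L)
  expect_equal(nrow(find_palindromes("AAAAAA")), 0L)
  expect_error(find_palindromes("ACGT", min_len = 5L), "even")
  withr::with_seed(12, {
    for (i in 1:25) {
      s <- random_dna_str(80, if (i %% 5 == 0) c("A", "T", "N") else c("A", "C", "G", "T"))
      got <- find_palindromes(s, min_len = 4L)
      want <- oracle_palindromes(s, min_len = 4L)
      expect_equal(paste(got$pos, got$length), paste(want$pos, want$length),
                   info = paste("case", i))
      for (r in seq_len(nrow(got))) {
        sub <- substr(s, got$pos[r] + 1, got$pos[r] + got$length[r])
        expect_identical(sub, revcomp(sub))
      }
    }
  })
})

test_that("short-repeat pairs match the all-pairs oracle, direct and inverted", {
  w <- paste0(random_dna_str(10), "ACGTACGTA", random_dna_str(21), "ACGTACGTA",
              random_dna_str(10))
  got <- find_short_repeats(w, k = 9L)
  expect_true(any(got$pos1 == 10 & got$pos2 == 40 & got$orientation == "direct"))
  w2 <- paste0("GATCCAGTT", random_dna_str(20), revcomp("GATCCAGTT"))
  got2 <- find_short_repeats(w2, k = 9L)
  expect_true(any(got2$pos1 == 0 & got2$pos2 == 29 & got2$orientation == "inverted"))
  expect_error(find_short_repeats(w, k = 4L), ">= 5")
  withr::with_seed(33, {
    for (i in 1:20) {
      s <- random_dna_str(70, c("A", "C"))  # low complexity forces repeats
      got <- find_short_repeats(s, k = 6L)
      want <- oracle_repeat_pairs(s, k = 6L)
      expect_equal(got, want, info = paste("case", i))
    }
  })
})

test_that("the evidence score is the stated weighted tally", {
  cand <- list(
    slippery = data.frame(pos = 1L, heptamer = "AAATTTT"),
    palindromes = data.frame(pos = 5L, length = 10L),
    repeats = data.frame(unit_length = 9L, pos1 = c(1L, 2L, 3L),
                         pos2 = c(11L, 12L, 13L),
                         orientation = c("inverted", "inverted", "direct")))
  cand$repeats <- cand$repeats[c(1, 2), ]
  expect_equal(score_evidence(cand), 4.0)  # 1 + 1 + 2 inverted
  empty <- list(slippery = data.frame(), palindromes = data.frame(),
                repeats = data.frame(orientation = character()))
  expect_equal(score_evidence(empty), 0.0)
  cand2 <- list(slippery = data.frame(pos = 1L),
                palindromes = data.frame(pos = 1L),
                repeats = data.frame(orientation = c(rep("inverted", 2),
                                                     rep("direct", 5))))
  expect_equal(score_evidence(cand2, c(slippery = 2, palindrome = 1,
                                       inverted = 1, direct = 0)), 5.0)
  expect_error(score_evidence(cand2, c(slippery = -1, palindrome = 1,
                                       inverted = 1, direct = 1)), "negative")
})

test_that("enlarging the evidence window never removes interior hits", {
  core <- generate_core_element(simulation_params(seed = 14))
  ann <- annotate_orfs(find_orfs(core$core_seq, "core"), default_role_panel())
  genes <- ann[!is.na(ann$role_name), ]
  small <- detect_fusion_candidates(genes, core$core_seq, window_w = 60L)[[1]]
  large <- detect_fusion_candidates(genes, core$core_seq, window_w = 100L)[[1]]
  shift <- small$window["start"] - large$window["start"]
  expect_true(all((small$slippery$pos + shift) %in% large$slippery$pos))
  expect_true(all((small$repeats$pos1 + shift) %in% large$repeats$pos1))
})
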