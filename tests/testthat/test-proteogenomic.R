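rule1 <- cleavage_rule(min_len = 1)

test_that("variant read-support filters are inclusive at both thresholds", {
  calls <- data.frame(
    protein_id = "P", pos = 2L, ref = "V", alt = "I",
    alt_reads = c(2L, 1L, 5L, 3L), coverage = c(10L, 50L, 9L, 30L),
    label = c("at_both", "low_alt", "low_cov", "pass"))
  out <- filter_variants(calls)
  expect_setequal(out$label, c("at_both", "pass"))
  calls$alt <- "V"
  expect_error(filter_variants(calls), "differ")
})

test_that("variant application substitutes exactly one residue", {
  expect_equal(apply_variant("AVK", 2, "V", "I"), "AIK")
  expect_error(apply_variant("AVK", 2, "A", "I"), "mismatch at position 2")
  expect_error(apply_variant("AVK", 9, "V", "I"), "outside")
  # applying then reverting returns the original
  expect_equal(apply_variant(apply_variant("AVK", 2, "V", "I"), 2, "I", "V"),
               "AVK")
})

test_that("an internal substitution yields exactly one identifying peptide", {
  ref <- "AAAKCVDEKGGGR"
  var <- apply_variant(ref, 6, "V", "W")
  peps <- saav_specific_peptides(ref, var, rule1)
  expect_equal(peps$peptide, "CWDEK")
  expect_equal(peps$start, 5L)
})

test_that("a K-creating substitution splits the peptide into two identifying peptides", {
  ref <- "AAAKCVDEGGGHR"
  var <- apply_variant(ref, 8, "E", "K")   # new cut site inside CVDEGGGHR
  peps <- saav_specific_peptides(ref, var, rule1)
  expect_equal(sort(peps$peptide), sort(c("CVDK", "GGGHR")))
  # digest-both oracle agrees
  want <- setdiff(oracle_digest(var)$peptide, oracle_digest(ref)$peptide)
  expect_setequal(peps$peptide, want)
})

test_that("a K-destroying substitution merges two peptides into one", {
  ref <- "AAAKCVDEKGGGR"
  var <- apply_variant(ref, 9, "K", "S")
  peps <- saav_specific_peptides(ref, var, rule1)
  expect_equal(peps$peptide, "CVDESGGGR")
  want <- setdiff(oracle_digest(var)$peptide, oracle_digest(ref)$peptide)
  expect_setequal(peps$peptide, want)
})

test_that("I/L equating suppresses mass-indistinguishable identifying peptides", {
  ref <- "AAAKCIDEKGGGR"
  var <- apply_variant(ref, 6, "I", "L")  # CIDEK -> CLDEK, same mass
  expect_equal(nrow(saav_specific_peptides(ref, var, rule1)), 1)
  expect_equal(nrow(saav_specific_peptides(ref, var, rule1,
                                           equate_il = TRUE)), 0)
})

test_that("SAAV library concatenates identifying peptides with exact sidecar coordinates", {
  proteome <- c(P1 = "AAAKCVDEGGGHR", P2 = "MMMKEEEKVVVR")
  calls <- data.frame(protein_id = c("P1", "P2"), pos = c(8L, 6L),
                      ref = c("E", "E"), alt = c("K", "W"),
                      alt_reads = 5L, coverage = 20L,
                      label = c("P1:E8K", "P2:E6W"), stringsAsFactors = FALSE)
  lib <- build_saav_library(proteome, calls, rule1)
  expect_length(lib$fasta, 2)
  rec <- "SAAV|P1|P1:E8K"
  side <- lib$sidecar[lib$sidecar$record_id == rec, ]
  # two identifying peptides; record is their in-order concatenation
  expect_equal(nchar(lib$fasta[[rec]]), sum(nchar(side$peptide)))
  for (i in seq_len(nrow(side))) {
    expect_equal(substr(lib$fasta[[rec]], side$start[i], side$end[i]),
                 side$peptide[i])
  }
  # an I->L SAAV is mass-silent: recorded as empty under I/L equating
  proteome3 <- c(P3 = "AAAKCIDEKGGGR")
  calls2 <- data.frame(protein_id = "P3", pos = 6L, ref = "I", alt = "L",
                       alt_reads = 5L, coverage = 20L, label = "P3:I6L",
                       stringsAsFactors = FALSE)
  lib2 <- build_saav_library(proteome3, calls2, rule1, equate_il = TRUE)
  expect_length(lib2$fasta, 0)
  expect_equal(lib2$empty, "P3:I6L")
})

test_that("identifying peptides never occur in the parent reference digest", {
  withr::with_seed(55, {
    for (rep in 1:40) {
      prot <- gen_proteome(n = 3, len_range = c(60, 150),
                           seed = sample.int(1e6, 1))
      calls <- gen_variants(prot$fasta, n = 4, seed = sample.int(1e6, 1))
      lib <- build_saav_library(prot$fasta, calls, rule1)
      for (i in seq_len(nrow(lib$sidecar))) {
        pid <- strsplit(lib$sidecar$record_id[i], "|", fixed = TRUE)[[1]][2]
        ref_peps <- oracle_digest(prot$fasta[[pid]])$peptide
        expect_false(lib$sidecar$peptide[i] %in% ref_peps)
      }
    }
  })
})

test_that("toy three-isoform gene yields the four expected groups", {
  shared <- "AAAAGGK"
  u1 <- "CCCDDK"; u2 <- "EEEFFK"; u3 <- "HHHMMK"
  isoforms <- c(I1 = paste0(shared, u1), I2 = paste0(shared, u2),
                I3 = paste0(shared, u3))
  lib <- build_isoform_library(isoforms, min_len = 5)
  sets <- lapply(lib$groups, `[[`, "isoforms")
  expect_setequal(
    vapply(sets, paste, "", collapse = ","),
    c("I1,I2,I3", "I1", "I2", "I3"))
  grp_all <- lib$groups[["ISOGRP|I1;I2;I3"]]
  expect_equal(grp_all$peptides, shared)
  expect_equal(lib$groups[["ISOGRP|I2"]]$peptides, u2)
})

test_that("peptides shorter than five residues are excluded", {
  isoforms <- c(I1 = "GGKAAAAAR", I2 = "GGKCCCCCR")  # GGK has length 3
  lib <- build_isoform_library(isoforms, min_len = 5)
  expect_false("GGK" %in% unlist(lapply(lib$groups, `[[`, "peptides")))
  lib4 <- build_isoform_library(isoforms, min_len = 3)
  expect_true("GGK" %in% unlist(lapply(lib4$groups, `[[`, "peptides")))
})

test_that("identical isoforms collapse into a single two-id group", {
  isoforms <- c(A = "AAAAKGGGGR", B = "AAAAKGGGGR")
  lib <- build_isoform_library(isoforms, min_len = 5)
  expect_length(lib$groups, 1)
  expect_equal(lib$groups[[1]]$isoforms, c("A", "B"))
  expect_error(build_isoform_library(c(A = "AAAAK", A = "CCCCK")),
               "duplicate")
})

test_that("isoform grouping partitions the retained peptide universe", {
  withr::with_seed(23, {
    for (rep in 1:30) {
      fam <- gen_isoform_family(n_iso = sample(2:4, 1),
                                n_shared = sample(2:4, 1),
                                n_unique = sample(1:3, 1),
                                seed = sample.int(1e6, 1))
      lib <- build_isoform_library(fam, min_len = 5)
      all_peps <- unlist(lapply(lib$groups, `[[`, "peptides"))
      expect_false(any(duplicated(all_peps)))      # disjoint
      universe <- unique(unlist(lapply(fam, function(s) {
        p <- oracle_digest(s)$peptide
        p[nchar(p) >= 5 & nchar(p) <= 50]
      })))
      expect_setequal(all_peps, universe)          # exhaustive
      # every peptide's group matches its true isoform membership
      for (g in lib$groups) {
        for (p in g$peptides) {
          member <- names(fam)[vapply(fam, function(s) {
            p %in% oracle_digest(s)$peptide
          }, TRUE)]
          expect_setequal(g$isoforms, member)
        }
      }
    }
  })
})
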