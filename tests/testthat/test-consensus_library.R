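make_spectrum <- function(id, mz, intensity, rt = 100, pmz = 500, charge = 2L) {
  ord <- order(mz)
  list(id = id, precursor_mz = pmz, charge = charge, rt = rt,
       peaks = cbind(mz = mz[ord], intensity = intensity[ord]))
}

test_that("singleton clusters pass through consensus unchanged", {
  sp <- make_spectrum("s1", c(100, 200), c(5, 10), rt = 123)
  cs <- build_consensus(list(sp), data.frame(spectrum_id = "s1",
                                             cluster_id = "c1"))
  expect_length(cs, 1)
  expect_equal(cs[[1]]$n_members, 1L)
  expect_equal(cs[[1]]$rt, 123)
  expect_equal(cs[[1]]$peaks, sp$peaks)
})

test_that("consensus merges peaks within tolerance, splits beyond it", {
  s1 <- make_spectrum("s1", 500.000, 10)
  s2 <- make_spectrum("s2", 500.010, 10)
  asg <- data.frame(spectrum_id = c("s1", "s2"), cluster_id = "c1")
  merged <- build_consensus(list(s1, s2), asg,
                            transition_config(merge_tol = 0.02))[[1]]
  expect_equal(nrow(merged$peaks), 1)
  expect_equal(unname(merged$peaks[1, "mz"]), 500.005)   # equal-weight mean
  expect_equal(unname(merged$peaks[1, "intensity"]), 10) # mean of equal values
  split <- build_consensus(list(s1, s2), asg,
                           transition_config(merge_tol = 0.005))[[1]]
  expect_equal(nrow(split$peaks), 2)
})

test_that("identical members give a consensus equal to either member", {
  s1 <- make_spectrum("s1", c(100, 300), c(4, 8), rt = 50)
  s2 <- make_spectrum("s2", c(100, 300), c(4, 8), rt = 70)
  cs <- build_consensus(list(s1, s2),
                        data.frame(spectrum_id = c("s1", "s2"),
                                   cluster_id = "c1"))[[1]]
  expect_equal(unname(cs$peaks[, "mz"]), c(100, 300))
  expect_equal(unname(cs$peaks[, "intensity"]), c(4, 8))
  expect_equal(cs$rt, 60)  # median member RT
})

test_that("consensus rejects assignments to unknown spectra", {
  sp <- make_spectrum("s1", 100, 1)
  expect_error(
    build_consensus(list(sp), data.frame(spectrum_id = "nope",
                                         cluster_id = "c1")),
    "unknown spectra")
})

test_that("best-PSM selection keeps the minimum q-value per peptide group", {
  psms <- data.frame(
    spectrum_id = c("a", "b", "c", "d", "e", "f"),
    peptide = c("PEPTIDEK", "PEPTIDEK", "BADQK", "TIEK", "TIEK", "PEPTIDEK"),
    charge = c(2L, 2L, 2L, 2L, 2L, 3L),
    score = c(1, 5, 9, 2, 7, 4),
    pvalue = rep(0.001, 6),
    qvalue = c(0.05, 0.02, 0.15, 0.02, 0.02, 0.01),
    stringsAsFactors = FALSE)
  best <- select_best_psms(psms, transition_config())
  # argmin q within (PEPTIDEK, 2)
  expect_equal(best$spectrum_id[best$peptide == "PEPTIDEK" & best$charge == 2], "b")
  # group with only q >= 0.10 is absent
  expect_false("BADQK" %in% best$peptide)
  # q tie within (TIEK, 2): higher score wins
  expect_equal(best$spectrum_id[best$peptide == "TIEK"], "e")
  # same sequence, different charge is a distinct group
  expect_equal(nrow(best), 3)
  expect_true(all(best$qvalue < 0.10))
})

test_that("transition extraction respects the ppm boundary exactly", {
  pep <- "ACDEFGHIK"
  theo <- theoretical_fragments(pep, "y", 1L)
  target <- theo$mz[theo$ordinal == 3]
  mz <- c(target * (1 + 0.5e-6),   # inside 1 ppm
          theo$mz[theo$ordinal == 5] * (1 + 2e-6))  # outside
  cs <- list(cluster_id = "c1", n_members = 1L, precursor_mz = 500,
             charge = 2L, rt = 100,
             peaks = cbind(mz = sort(mz), intensity = c(10, 10)))
  psm <- list(peptide = pep, charge = 2L)
  tr <- extract_transitions(cs, psm,
                            transition_config(series = "y", frag_charges = 1L))
  expect_equal(tr$FragmentSeriesNumber, 3L)
  expect_false(5L %in% tr$FragmentSeriesNumber)
  expect_equal(tr$NormalizedRetentionTime, 100)
  expect_equal(tr$transition_group_id, paste0(pep, "/2"))
})

test_that("a spectrum of all theoretical ions yields the full transition count", {
  pep <- "LNCDEFGHK"
  cfg <- transition_config()
  theo <- theoretical_fragments(pep, cfg$series, cfg$frag_charges)
  cs <- list(cluster_id = "c1", n_members = 1L, precursor_mz = 500,
             charge = 2L, rt = 50,
             peaks = cbind(mz = sort(theo$mz),
                           intensity = rep(1, nrow(theo))))
  tr <- extract_transitions(cs, list(peptide = pep, charge = 2L), cfg)
  expect_equal(nrow(tr), (nchar(pep) - 1) * 2 * 2)
  # every emitted transition satisfies its ppm invariant
  for (i in seq_len(nrow(tr))) {
    t_mz <- fragment_mz(pep, tr$FragmentType[i], tr$FragmentSeriesNumber[i],
                        tr$FragmentCharge[i])
    expect_lte(abs(tr$ProductMz[i] - t_mz) / t_mz, cfg$ppm_tol * 1e-6)
  }
})

test_that("top-N keeps the most intense transitions", {
  pep <- "ACDEFGHIK"
  theo <- theoretical_fragments(pep, "y", 1L)
  cs <- list(cluster_id = "c1", n_members = 1L, precursor_mz = 500,
             charge = 2L, rt = 50,
             peaks = cbind(mz = sort(theo$mz),
                           intensity = seq_len(nrow(theo))))
  tr <- extract_transitions(cs, list(peptide = pep, charge = 2L),
                            transition_config(series = "y",
                                              frag_charges = 1L, top_n = 3))
  expect_equal(nrow(tr), 3)
  expect_setequal(tr$LibraryIntensity,
                  sort(seq_len(nrow(theo)), decreasing = TRUE)[1:3])
})

test_that("end-to-end library build recovers fragments from jittered spectra", {
  peps <- c("ACDEFGHIK", "LMNPQSTVK", "WYVACDEGK")
  sim <- gen_spectra(peps, ppm_sd = 0.2, noise_frac = 0.2, seed = 99)
  gtl <- build_library(sim$spectra, sim$assignment, sim$psms)
  expect_true(all(peps %in% gtl$PeptideSequence))
  # recall over the known fragment sets
  total <- 0; found <- 0
  for (pep in peps) {
    truth <- sim$truth$fragments[[paste0("cl_", pep, "_2")]]
    got <- gtl[gtl$PeptideSequence == pep, ]
    key <- paste(got$FragmentType, got$FragmentSeriesNumber, got$FragmentCharge)
    tkey <- paste(truth$series, truth$ordinal, truth$charge)
    total <- total + length(tkey)
    found <- found + sum(tkey %in% key)
  }
  expect_gte(found / total, 0.95)
})

test_that("GTL write/read round-trips and maps shuffled columns by header", {
  withr::with_seed(5, {
    peps <- replicate(20, random_peptide(sample(6:12, 1)))
    rows <- lapply(peps, function(p) {
      ord <- sample(nchar(p) - 1, 1)
      data.frame(
        transition_group_id = paste0(p, "/2"), PeptideSequence = p,
        FullPeptideName = p, PrecursorCharge = 2L,
        PrecursorMz = round(precursor_mz(p, 2), 6),
        ProductMz = round(fragment_mz(p, "y", ord, 1), 6),
        FragmentType = "y", FragmentSeriesNumber = ord,
        FragmentCharge = 1L,
        LibraryIntensity = round(runif(1, 1, 1e5), 3),
        NormalizedRetentionTime = round(runif(1, 0, 5400), 3),
        ProteinName = "P1", decoy = 0L, stringsAsFactors = FALSE)
    })
    gtl <- do.call(rbind, rows)
  })
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gtl(gtl, f)
  expect_equal(strsplit(readLines(f, n = 1), "\t")[[1]], GTL_COLUMNS)
  back <- read_gtl(f)
  expect_equal(back, gtl, tolerance = 1e-9)

  # shuffled column order still reads via header mapping
  df <- utils::read.delim(f, check.names = FALSE)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df[, rev(names(df))], f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_gtl(f2)$PeptideSequence, gtl$PeptideSequence)

  # missing column errors
  f3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df[, -2], f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gtl(f3), "missing column")

  # empty list writes a header-only file
  f4 <- withr::local_tempfile(fileext = ".tsv")
  write_gtl(gtl[0, ], f4)
  expect_length(readLines(f4), 1)
  expect_equal(nrow(read_gtl(f4)), 0)
})
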