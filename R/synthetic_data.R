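# Seeded synthetic-data generators emulating every input the library,
# calibration, combination and summarization stages consume, with ground
# truth retained so downstream results can be scored exactly.

.AA20 <- names(residue_masses())

# Random residue string; uniform over the 20 standard residues.
.random_seq <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

#' Generate a random proteome with tryptic-friendly composition
#'
#' Sequences are uniform over the 20 standard residues, giving roughly one
#' K/R per ten residues and hence tryptic peptides mostly in the 5--30
#' residue range. Deterministic under the seed.
#'
#' @param n Number of proteins.
#' @param len_range Integer length-2: protein length bounds (uniform).
#' @param seed RNG seed.
#' @return List with `fasta` (named character, ids `PROT_0001`...) and
#'   `truth` (data.frame of protein id and length).
#' @export
gen_proteome <- function(n = 50L, len_range = c(80L, 300L), seed = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    seqs <- vapply(lens, .random_seq, "")
    ids <- sprintf("PROT_%04d", seq_len(n))
    names(seqs) <- ids
    list(fasta = seqs, truth = data.frame(protein_id = ids, length = lens,
                                          stringsAsFactors = FALSE))
  })
}

#' Generate clustered MS2 spectra, cluster assignments and PSMs
#'
#' Per peptide, `replicates` spectra are emitted containing every
#' theoretical y/b fragment peak perturbed by Gaussian ppm jitter, plus
#' uniform random noise peaks. All replicates of a peptide belong to one
#' cluster. The PSM table targets cluster ids: true PSMs draw q-values
#' below 0.10; a configurable fraction of additional decoy PSMs (shuffled
#' sequences) draw q-values above it.
#'
#' @param peptides Character vector of peptide sequences.
#' @param precursor_charge Precursor charge assigned to every peptide.
#' @param replicates Spectra per cluster.
#' @param ppm_sd Gaussian jitter SD on fragment m/z, in ppm.
#' @param noise_frac Noise peaks per spectrum as a fraction of the
#'   theoretical fragment count.
#' @param frag_charges Fragment charges simulated.
#' @param decoy_frac Decoy PSMs as a fraction of the true PSM count.
#' @param seed RNG seed.
#' @return List with `spectra` (list, MGF-shaped), `assignment`
#'   (data.frame `spectrum_id`, `cluster_id`), `psms` (data.frame) and
#'   `truth` (per-cluster theoretical fragments with series/ordinal/charge
#'   and the noise m/z values per spectrum).
#' @export
gen_spectra <- function(peptides, precursor_charge = 2L, replicates = 3L,
                        ppm_sd = 0.3, noise_frac = 0.2, frag_charges = c(1L, 2L),
                        decoy_frac = 0.1, seed = 1L) {
  with_seed(seed, {
    spectra <- list()
    assignment <- list()
    truth_frag <- list()
    truth_noise <- list()
    gradient_rt <- stats::runif(length(peptides), 100, 5000)
    for (k in seq_along(peptides)) {
      pep <- peptides[k]
      cluster <- paste0("cl_", pep, "_", precursor_charge)
      theo <- theoretical_fragments(pep, c("y", "b"), frag_charges)
      truth_frag[[cluster]] <- theo
      mz_lo <- min(theo$mz) * 0.9
      mz_hi <- max(theo$mz) * 1.1
      n_noise <- round(noise_frac * nrow(theo))
      for (r in seq_len(replicates)) {
        sid <- paste0(cluster, "_rep", r)
        jit <- theo$mz * (1 + stats::rnorm(nrow(theo), 0, ppm_sd * 1e-6))
        ints <- stats::rlnorm(nrow(theo), meanlog = log(1e4), sdlog = 1)
        noise_mz <- if (n_noise > 0) stats::runif(n_noise, mz_lo, mz_hi)
                    else numeric(0)
        noise_int <- if (n_noise > 0) {
          stats::rlnorm(n_noise, meanlog = log(2e3), sdlog = 1)
        } else numeric(0)
        pk <- cbind(mz = c(jit, noise_mz), intensity = c(ints, noise_int))
        pk <- pk[order(pk[, "mz"]), , drop = FALSE]
        spectra[[sid]] <- list(
          id = sid,
          precursor_mz = precursor_mz(pep, precursor_charge),
          charge = precursor_charge,
          rt = gradient_rt[k] + stats::rnorm(1, 0, 5),
          peaks = pk
        )
        assignment[[sid]] <- data.frame(spectrum_id = sid,
                                        cluster_id = cluster,
                                        stringsAsFactors = FALSE)
        truth_noise[[sid]] <- noise_mz
      }
    }
    psms <- data.frame(
      spectrum_id = paste0("cl_", peptides, "_", precursor_charge),
      peptide = peptides,
      charge = precursor_charge,
      score = stats::runif(length(peptides), 2, 6),
      pvalue = stats::runif(length(peptides), 1e-6, 0.01),
      qvalue = stats::runif(length(peptides), 1e-4, 0.09),
      stringsAsFactors = FALSE
    )
    n_decoy <- round(decoy_frac * length(peptides))
    if (n_decoy > 0) {
      idx <- sample(seq_along(peptides), n_decoy)
      decoy_pep <- vapply(peptides[idx], function(p) {
        paste(sample(strsplit(p, "")[[1]]), collapse = "")
      }, "")
      decoys <- data.frame(
        spectrum_id = paste0("cl_", peptides[idx], "_", precursor_charge),
        peptide = decoy_pep,
        charge = precursor_charge,
        score = stats::runif(n_decoy, 0, 2),
        pvalue = stats::runif(n_decoy, 0.2, 1),
        qvalue = stats::runif(n_decoy, 0.10, 1),
        stringsAsFactors = FALSE
      )
      psms <- rbind(psms, decoys)
    }
    list(
      spectra = unname(spectra),
      assignment = do.call(rbind, c(assignment, list(make.row.names = FALSE))),
      psms = psms,
      truth = list(fragments = truth_frag, noise = truth_noise,
                   peptides = peptides)
    )
  })
}

#' Generate per-run feature tables with a known RT drift
#'
#' Library RTs are uniform over the gradient; observed RT is an affine
#' drift of the library RT plus Gaussian noise. Designated peptide
#' fractions violate exactly one anchor-selection filter each (wide peak,
#' low intensity, large RT deviation, detected in few runs); all other
#' peptides pass every filter. Truth records each peptide's violation flag
#' and the per-run drift.
#'
#' @param n_peptides Number of peptides.
#' @param n_runs Number of runs/samples.
#' @param gradient Gradient span in seconds.
#' @param slope,intercept Affine drift: observed = slope * library +
#'   intercept + noise.
#' @param noise_sd RT noise SD (s).
#' @param frac_wide,frac_low,frac_far,frac_few Fractions of peptides
#'   violating, respectively, the peak-width, intensity, RT-deviation and
#'   run-count filters.
#' @param detect_prob Detection probability per (clean peptide, run).
#' @param peptides_per_protein Peptides mapped to each synthetic protein id.
#' @param seed RNG seed.
#' @return List with `features` (data.frame: peptide, protein, run,
#'   rt_obs, rt_lib, width, intensity) and `truth` (peptide flags and the
#'   drift parameters).
#' @export
gen_rt_runs <- function(n_peptides = 500L, n_runs = 25L,
                        gradient = c(0, 5400), slope = 1.05,
                        intercept = 180, noise_sd = 6,
                        frac_wide = 0.1, frac_low = 0.1, frac_far = 0.05,
                        frac_few = 0.05, detect_prob = 0.92,
                        peptides_per_protein = 5L, seed = 1L) {
  stopifnot(diff(gradient) > 0)
  with_seed(seed, {
    peps <- vapply(seq_len(n_peptides), function(i) {
      paste0(.random_seq(sample(7:14, 1)), sample(c("K", "R"), 1))
    }, "")
    peps <- make.unique(peps, sep = "x")
    prot <- sprintf("SPROT_%04d",
                    ceiling(seq_len(n_peptides) / peptides_per_protein))
    flag <- rep("none", n_peptides)
    n_flags <- floor(n_peptides * c(frac_wide, frac_low, frac_far, frac_few))
    pool <- sample(n_peptides)
    at <- 0L
    for (j in seq_along(n_flags)) {
      take <- pool[at + seq_len(n_flags[j])]
      flag[take] <- c("wide", "low_intensity", "far_rt", "few_runs")[j]
      at <- at + n_flags[j]
    }
    rt_lib <- stats::runif(n_peptides, gradient[1], gradient[2])
    rows <- list()
    for (r in seq_len(n_runs)) {
      p_det <- ifelse(flag == "few_runs", 0.5, detect_prob)
      det <- stats::runif(n_peptides) < p_det
      idx <- which(det)
      rt_obs <- slope * rt_lib[idx] + intercept +
        stats::rnorm(length(idx), 0, noise_sd)
      rt_obs[flag[idx] == "far_rt"] <- rt_obs[flag[idx] == "far_rt"] +
        sample(c(-1, 1), sum(flag[idx] == "far_rt"), replace = TRUE) *
          stats::runif(sum(flag[idx] == "far_rt"), 700, 2000)
      width <- ifelse(flag[idx] == "wide",
                      stats::runif(length(idx), 17, 40),
                      stats::runif(length(idx), 6, 16))
      intensity <- ifelse(flag[idx] == "low_intensity",
                          10^stats::runif(length(idx), 3, 4.9),
                          10^stats::runif(length(idx), 5.1, 7))
      rows[[r]] <- data.frame(
        peptide = peps[idx], protein = prot[idx],
        run = sprintf("run_%02d", r),
        rt_obs = rt_obs, rt_lib = rt_lib[idx],
        width = width, intensity = intensity,
        stringsAsFactors = FALSE
      )
    }
    list(
      features = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      truth = list(
        flags = data.frame(peptide = peps, protein = prot, flag = flag,
                           rt_lib = rt_lib, stringsAsFactors = FALSE),
        slope = slope, intercept = intercept, noise_sd = noise_sd,
        gradient = gradient
      )
    )
  })
}

#' Generate paired peptide and transcript quantification matrices
#'
#' Protein abundance per sample is log-normal (log2 SD `prot_sd`). True
#' peptides follow the protein profile plus Gaussian log2 noise `pep_sd`;
#' decoy peptides are independent draws at the same scale. Transcripts
#' follow the protein profile plus `trans_sd` noise, except a
#' `decouple_frac` fraction drawn independently so their transcript-protein
#' correlation is near zero. Missingness censors values below the given
#' intensity quantile of each matrix (missing-not-at-random, as in MS
#' data).
#'
#' @param n_proteins Number of proteins.
#' @param n_true True peptides per protein.
#' @param n_decoy Independent decoy peptides per protein.
#' @param n_samples Number of samples.
#' @param pep_sd Peptide-level log2 noise SD.
#' @param prot_sd Protein-abundance log2 SD across samples.
#' @param trans_sd Transcript-level log2 noise SD.
#' @param decouple_frac Fraction of transcript-protein pairs decoupled.
#' @param miss_quantile Censoring quantile (0 disables missingness).
#' @param seed RNG seed.
#' @return List with `peptides`, `transcripts` (raw-scale matrices), `map`
#'   (data.frame peptide, protein, decoy flag), `pairing` (transcript ids
#'   per protein) and `truth` (log2 protein profiles and decoupling
#'   flags).
#' @export
gen_quant_dataset <- function(n_proteins = 100L, n_true = 5L, n_decoy = 2L,
                              n_samples = 30L, pep_sd = 0.2, prot_sd = 1,
                              trans_sd = 0.3, decouple_frac = 0,
                              miss_quantile = 0.1, seed = 1L) {
  with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_samples))
    prot_ids <- sprintf("QPROT_%04d", seq_len(n_proteins))
    base <- stats::runif(n_proteins, 18, 24)
    profile <- base + matrix(stats::rnorm(n_proteins * n_samples, 0, prot_sd),
                             n_proteins, n_samples)
    dimnames(profile) <- list(prot_ids, samples)
    pep_rows <- list(); map <- list()
    for (i in seq_len(n_proteins)) {
      for (j in seq_len(n_true)) {
        id <- paste0(prot_ids[i], "_pep", j)
        pep_rows[[id]] <- profile[i, ] + stats::rnorm(1, 0, 0.5) +
          stats::rnorm(n_samples, 0, pep_sd)
        map[[id]] <- data.frame(peptide = id, protein = prot_ids[i],
                                decoy = FALSE, stringsAsFactors = FALSE)
      }
      for (j in seq_len(n_decoy)) {
        id <- paste0(prot_ids[i], "_decoy", j)
        pep_rows[[id]] <- base[i] + stats::rnorm(n_samples, 0, prot_sd)
        map[[id]] <- data.frame(peptide = id, protein = prot_ids[i],
                                decoy = TRUE, stringsAsFactors = FALSE)
      }
    }
    peptides_log2 <- do.call(rbind, pep_rows)
    colnames(peptides_log2) <- samples
    decoupled <- stats::runif(n_proteins) < decouple_frac
    trans <- profile + matrix(stats::rnorm(n_proteins * n_samples, 0, trans_sd),
                              n_proteins, n_samples)
    trans[decoupled, ] <- matrix(
      stats::runif(sum(decoupled), 18, 24) +
        stats::rnorm(sum(decoupled) * n_samples, 0, prot_sd),
      sum(decoupled), n_samples
    )
    trans_ids <- sub("QPROT", "TX", prot_ids)
    dimnames(trans) <- list(trans_ids, samples)
    censor <- function(m, q) {
      if (q <= 0) return(m)
      thr <- stats::quantile(m, q)
      m[m < thr] <- NA
      m
    }
    pep_raw <- censor(2^peptides_log2, miss_quantile)
    trans_raw <- censor(2^trans, miss_quantile)
    list(
      peptides = pep_raw,
      transcripts = trans_raw,
      map = do.call(rbind, c(unname(map), list(make.row.names = FALSE))),
      pairing = data.frame(x_id = trans_ids, y_id = prot_ids,
                           stringsAsFactors = FALSE),
      truth = list(profile = profile, decoupled = decoupled)
    )
  })
}

#' Generate variant calls against a proteome
#'
#' Draws single-amino-acid substitutions at random positions. A configurable
#' fraction is cleavage-site-altering: half of those create a new K site,
#' half destroy an existing K/R site. Read support is drawn so most calls
#' pass the 2-alt-read / 10x-coverage filters and a configurable fraction
#' fails them.
#'
#' @param proteome Named character vector of reference sequences.
#' @param n Number of variant calls.
#' @param site_altering_frac Fraction of calls creating or destroying a
#'   K/R cleavage site.
#' @param fail_frac Fraction of calls drawn below the read-support
#'   thresholds.
#' @param seed RNG seed.
#' @return data.frame: protein_id, pos, ref, alt, alt_reads, coverage,
#'   label, with a `site_effect` truth column (none/create/destroy).
#' @export
gen_variants <- function(proteome, n = 20L, site_altering_frac = 0.3,
                         fail_frac = 0.1, seed = 1L) {
  with_seed(seed, {
    non_kr <- setdiff(.AA20, c("K", "R"))
    out <- vector("list", n)
    n_alter <- round(n * site_altering_frac)
    effects <- c(rep(c("create", "destroy"), length.out = n_alter),
                 rep("none", n - n_alter))
    for (i in seq_len(n)) {
      repeat {
        pid <- sample(names(proteome), 1)
        s <- proteome[[pid]]
        res <- strsplit(s, "")[[1]]
        eff <- effects[i]
        pos <- switch(eff,
          create = { cand <- which(!(res %in% c("K", "R")))
                     if (!length(cand)) next
                     sample(cand, 1) },
          destroy = { cand <- which(res %in% c("K", "R"))
                      if (!length(cand)) next
                      sample(cand, 1) },
          none = { cand <- which(!(res %in% c("K", "R")))
                   if (!length(cand)) next
                   sample(cand, 1) }
        )
        ref <- res[pos]
        alt <- switch(eff,
          create = "K",
          destroy = sample(non_kr, 1),
          none = sample(setdiff(non_kr, ref), 1)
        )
        if (alt == ref) next
        fails <- stats::runif(1) < fail_frac
        alt_reads <- if (fails) sample(0:1, 1) else sample(2:60, 1)
        coverage <- max(alt_reads + sample(0:80, 1), if (fails) 0 else 10)
        if (!fails && coverage < 10) coverage <- 10
        out[[i]] <- data.frame(
          protein_id = pid, pos = pos, ref = ref, alt = alt,
          alt_reads = alt_reads, coverage = coverage,
          label = paste0(pid, ":", ref, pos, alt),
          site_effect = eff, stringsAsFactors = FALSE
        )
        break
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Generate a family of protein isoforms sharing tryptic blocks
#'
#' Builds tryptic "blocks" (random peptides ending in K or R) and assembles
#' isoforms as the shared blocks plus each isoform's unique blocks, so
#' peptide-to-isoform-set mapping has a known structure.
#'
#' @param n_iso Number of isoforms.
#' @param n_shared Blocks common to all isoforms.
#' @param n_unique Blocks unique to each isoform.
#' @param block_len Range of residues per block before the terminal K/R.
#' @param seed RNG seed.
#' @return Named character vector of isoform sequences (`ISO_01`...).
#' @export
gen_isoform_family <- function(n_iso = 3L, n_shared = 4L, n_unique = 2L,
                               block_len = c(6L, 12L), seed = 1L) {
  with_seed(seed, {
    non_krp <- setdiff(.AA20, c("K", "R", "P"))
    block <- function() {
      len <- sample(block_len[1]:block_len[2], 1)
      paste0(paste(sample(non_krp, len, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1))
    }
    shared <- replicate(n_shared, block())
    seqs <- vapply(seq_len(n_iso), function(i) {
      uniq <- replicate(n_unique, block())
      paste(c(shared, uniq), collapse = "")
    }, "")
    names(seqs) <- sprintf("ISO_%02d", seq_len(n_iso))
    seqs
  })
}
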