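# Consensus-spectrum construction, best-PSM selection and transition
# extraction into an OpenSWATH-compatible generic transition list (GTL).

#' Canonical GTL column set
#'
#' Column names, in order, of the OpenSWATH-compatible generic transition
#' list written by [write_gtl()].
#' @export
GTL_COLUMNS <- c(
  "transition_group_id", "PeptideSequence", "FullPeptideName",
  "PrecursorCharge", "PrecursorMz", "ProductMz", "FragmentType",
  "FragmentSeriesNumber", "FragmentCharge", "LibraryIntensity",
  "NormalizedRetentionTime", "ProteinName", "decoy"
)

#' Transition-extraction configuration
#'
#' @param ppm_tol Fragment match tolerance in ppm (default 1.0): an observed
#'   peak matches a theoretical ion when |obs - theo| / theo <= ppm_tol*1e-6.
#' @param series Ion series considered (y and b, the most commonly observed).
#' @param frag_charges Fragment charge states enumerated.
#' @param q_max q-value ceiling for PSM selection; groups whose best q-value
#'   is not below this are dropped (default 0.10).
#' @param merge_tol Peak-merge tolerance (Da) for consensus construction.
#' @param top_n Keep at most this many transitions per peptide group, by
#'   library intensity (default Inf: keep all matched transitions).
#' @return List of class `transition_config`.
#' @export
transition_config <- function(ppm_tol = 1.0, series = c("y", "b"),
                              frag_charges = c(1L, 2L), q_max = 0.10,
                              merge_tol = 0.02, top_n = Inf) {
  if (ppm_tol <= 0) stop("ppm_tol must be positive")
  if (q_max <= 0 || q_max > 1) stop("q_max must be in (0, 1]")
  structure(
    list(ppm_tol = ppm_tol, series = series,
         frag_charges = as.integer(frag_charges), q_max = q_max,
         merge_tol = merge_tol, top_n = top_n),
    class = "transition_config"
  )
}

.merge_peaks <- function(peaks, tol) {
  if (nrow(peaks) <= 1) return(peaks)
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  # greedy left-to-right: start a new group when the gap to the current
  # group's running weighted mean exceeds tol
  grp <- integer(nrow(peaks))
  g <- 1L
  grp[1] <- g
  mean_mz <- peaks[1, "mz"]
  wsum <- peaks[1, "intensity"]
  for (i in 2:nrow(peaks)) {
    if (peaks[i, "mz"] - mean_mz <= tol) {
      grp[i] <- g
      w <- peaks[i, "intensity"]
      if (wsum + w > 0) {
        mean_mz <- (mean_mz * wsum + peaks[i, "mz"] * w) / (wsum + w)
      } else {
        mean_mz <- (mean_mz + peaks[i, "mz"]) / 2
      }
      wsum <- wsum + w
    } else {
      g <- g + 1L
      grp[i] <- g
      mean_mz <- peaks[i, "mz"]
      wsum <- peaks[i, "intensity"]
    }
  }
  mz <- vapply(split(seq_len(nrow(peaks)), grp), function(idx) {
    w <- peaks[idx, "intensity"]
    if (sum(w) > 0) sum(peaks[idx, "mz"] * w) / sum(w)
    else mean(peaks[idx, "mz"])
  }, 0)
  intensity <- vapply(split(peaks[, "intensity"], grp), mean, 0)
  out <- cbind(mz = unname(mz), intensity = unname(intensity))
  out[order(out[, "mz"]), , drop = FALSE]
}

#' Build consensus spectra from clustered MS2 spectra
#'
#' Clustering itself (e.g. MaRaCluster) happens upstream; this consumes the
#' spectrum-to-cluster assignment and merges member spectra. Within a
#' cluster, peaks falling within `cfg$merge_tol` Da (greedy left-to-right)
#' are merged to one peak with intensity-weighted mean m/z and mean
#' intensity; the consensus retention time is the median member RT.
#'
#' @param spectra List of spectra (see [read_mgf()]).
#' @param assignment data.frame with columns `spectrum_id`, `cluster_id`.
#' @param cfg A [transition_config()].
#' @return List of consensus spectra: each has `cluster_id`, `n_members`,
#'   `precursor_mz`, `charge`, `rt` and merged `peaks`.
#' @export
build_consensus <- function(spectra, assignment, cfg = transition_config()) {
  ids <- vapply(spectra, `[[`, "", "id")
  unknown <- setdiff(assignment$spectrum_id, ids)
  if (length(unknown)) {
    stop("assignment references unknown spectra: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  by_cluster <- split(assignment$spectrum_id, assignment$cluster_id)
  lapply(names(by_cluster), function(cl) {
    members <- spectra[match(by_cluster[[cl]], ids)]
    if (length(members) == 1L) {
      sp <- members[[1]]
      return(list(cluster_id = cl, n_members = 1L,
                  precursor_mz = sp$precursor_mz, charge = sp$charge,
                  rt = sp$rt, peaks = sp$peaks))
    }
    all_peaks <- do.call(rbind, lapply(members, `[[`, "peaks"))
    list(
      cluster_id = cl,
      n_members = length(members),
      precursor_mz = stats::median(vapply(members, `[[`, 0, "precursor_mz")),
      charge = members[[1]]$charge,
      rt = stats::median(vapply(members, `[[`, 0, "rt")),
      peaks = .merge_peaks(all_peaks, cfg$merge_tol)
    )
  })
}

#' Select the best PSM per peptide group
#'
#' A peptide group is a (sequence, charge) pair -- the library counting
#' unit. Each group keeps its minimum-q-value PSM; groups whose best
#' q-value is not below `cfg$q_max` are dropped. Ties on q-value break by
#' higher search score, then lexicographic spectrum id, so output is
#' deterministic.
#'
#' @param psms data.frame with columns `spectrum_id`, `peptide`, `charge`,
#'   `score`, `pvalue`, `qvalue`.
#' @param cfg A [transition_config()].
#' @return data.frame, one row per retained peptide group.
#' @export
select_best_psms <- function(psms, cfg = transition_config()) {
  if (!nrow(psms)) return(psms)
  if (anyNA(psms$qvalue)) stop("q-values must be populated before selection")
  ord <- order(psms$peptide, psms$charge, psms$qvalue, -psms$score,
               psms$spectrum_id)
  psms <- psms[ord, , drop = FALSE]
  key <- paste(psms$peptide, psms$charge, sep = "/")
  best <- psms[!duplicated(key), , drop = FALSE]
  best <- best[best$qvalue < cfg$q_max, , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Extract transitions from a consensus spectrum
#'
#' For every theoretical y/b ion of the PSM's peptide (all ordinals, the
#' configured fragment charges), the observed peak list is searched within
#' the ppm tolerance; if one or more peaks match, one transition is emitted
#' using the closest peak (tie: higher intensity). The consensus retention
#' time becomes the transition's normalized RT.
#'
#' @param consensus One consensus spectrum from [build_consensus()].
#' @param psm One-row data.frame (or list) with `peptide`, `charge` and the
#'   target `spectrum_id`/`cluster_id` equal to the consensus cluster.
#' @param cfg A [transition_config()].
#' @param protein Protein id written to the `ProteinName` column.
#' @param masses Residue mass table.
#' @return data.frame in GTL column layout (possibly zero rows).
#' @export
extract_transitions <- function(consensus, psm, cfg = transition_config(),
                                protein = "", masses = residue_masses()) {
  peptide <- psm$peptide
  charge <- as.integer(psm$charge)
  theo <- theoretical_fragments(peptide, cfg$series, cfg$frag_charges, masses)
  peaks <- consensus$peaks
  hit <- lapply(seq_len(nrow(theo)), function(i) {
    tmz <- theo$mz[i]
    tol <- tmz * cfg$ppm_tol * 1e-6
    d <- abs(peaks[, "mz"] - tmz)
    in_tol <- which(d <= tol)
    if (!length(in_tol)) return(NULL)
    best <- in_tol[order(d[in_tol], -peaks[in_tol, "intensity"])][1]
    c(i, peaks[best, "mz"], peaks[best, "intensity"])
  })
  hit <- do.call(rbind, hit)
  if (is.null(hit)) {
    out <- empty_gtl()
  } else {
    i <- hit[, 1]
    out <- data.frame(
      transition_group_id = paste0(peptide, "/", charge),
      PeptideSequence = peptide,
      FullPeptideName = peptide,
      PrecursorCharge = charge,
      PrecursorMz = precursor_mz(peptide, charge, masses),
      ProductMz = hit[, 2],
      FragmentType = theo$series[i],
      FragmentSeriesNumber = theo$ordinal[i],
      FragmentCharge = theo$charge[i],
      LibraryIntensity = hit[, 3],
      NormalizedRetentionTime = consensus$rt,
      ProteinName = protein,
      decoy = 0L,
      stringsAsFactors = FALSE
    )
    out <- out[out$LibraryIntensity > 0, , drop = FALSE]
    if (is.finite(cfg$top_n) && nrow(out) > cfg$top_n) {
      out <- out[order(-out$LibraryIntensity), , drop = FALSE][seq_len(cfg$top_n), ]
      out <- out[order(out$FragmentType, out$FragmentSeriesNumber), , drop = FALSE]
    }
    rownames(out) <- NULL
  }
  out
}

empty_gtl <- function() {
  out <- data.frame(
    transition_group_id = character(0), PeptideSequence = character(0),
    FullPeptideName = character(0), PrecursorCharge = integer(0),
    PrecursorMz = numeric(0), ProductMz = numeric(0),
    FragmentType = character(0), FragmentSeriesNumber = integer(0),
    FragmentCharge = integer(0), LibraryIntensity = numeric(0),
    NormalizedRetentionTime = numeric(0), ProteinName = character(0),
    decoy = integer(0), stringsAsFactors = FALSE
  )
  out
}

#' Build a spectral library (GTL) from spectra, clusters and PSMs
#'
#' End-to-end: consensus spectra from the cluster assignment, best-PSM
#' selection per peptide group at the q-value ceiling, transition
#' extraction at the ppm tolerance.
#'
#' @param spectra List of spectra.
#' @param assignment Spectrum-to-cluster assignment data.frame.
#' @param psms PSM data.frame; `spectrum_id` refers to cluster ids of the
#'   consensus spectra (searches run on consensus spectra).
#' @param cfg A [transition_config()].
#' @param protein_map Optional named character vector: peptide -> protein id.
#' @param masses Residue mass table.
#' @return GTL data.frame of all extracted transitions.
#' @export
build_library <- function(spectra, assignment, psms,
                          cfg = transition_config(), protein_map = NULL,
                          masses = residue_masses()) {
  consensus <- build_consensus(spectra, assignment, cfg)
  names(consensus) <- vapply(consensus, `[[`, "", "cluster_id")
  best <- select_best_psms(psms, cfg)
  if (!nrow(best)) return(empty_gtl())
  pieces <- lapply(seq_len(nrow(best)), function(i) {
    psm <- best[i, ]
    cs <- consensus[[as.character(psm$spectrum_id)]]
    if (is.null(cs)) stop("PSM targets unknown cluster: ", psm$spectrum_id)
    prot <- if (!is.null(protein_map)) {
      p <- protein_map[[psm$peptide]]
      if (is.null(p) || is.na(p)) "" else p
    } else ""
    extract_transitions(cs, psm, cfg, protein = prot, masses = masses)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write a generic transition list to tsv
#'
#' Fixed column set and order (OpenSWATH-compatible), tab-separated,
#' header row, '.' decimal separator, m/z values to 6 decimals.
#'
#' @param transitions GTL data.frame.
#' @param path Output path.
#' @export
write_gtl <- function(transitions, path) {
  missing_cols <- setdiff(GTL_COLUMNS, names(transitions))
  if (length(missing_cols)) {
    stop("transitions missing GTL column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- transitions[, GTL_COLUMNS, drop = FALSE]
  for (col in c("PrecursorMz", "ProductMz")) {
    df[[col]] <- sprintf("%.6f", df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic transition list from tsv
#'
#' Columns are located by header name, so column order in the file is
#' free; all GTL columns must be present.
#'
#' @param path Path to a GTL tsv.
#' @return GTL data.frame in canonical column order.
#' @export
read_gtl <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(GTL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("GTL file ", path, " missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, GTL_COLUMNS, drop = FALSE]
  num <- c("PrecursorMz", "ProductMz", "LibraryIntensity",
           "NormalizedRetentionTime")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !anyNA(df[[col]])) {
      bad <- which(is.na(v) & !is.na(df[[col]]))[1]
      stop("malformed numeric value in column ", col, " at data line ", bad)
    }
    df[[col]] <- v
  }
  for (col in c("PrecursorCharge", "FragmentSeriesNumber", "FragmentCharge",
                "decoy")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("ProteinName", "transition_group_id", "PeptideSequence",
                "FullPeptideName", "FragmentType")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}
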