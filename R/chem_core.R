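# Amino-acid masses, proteolytic digestion and peptide/fragment m/z.

.PROTON <- 1.007276466
.WATER  <- 18.0105646

# Monoisotopic residue masses (Da) for the 20 standard amino acids.
.RESIDUE_MONO <- c(
  G = 57.021464,  A = 71.037114,  S = 87.032028,  P = 97.052764,
  V = 99.068414,  T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Fundamental mass constants
#'
#' @return Named numeric vector with the proton and water monoisotopic
#'   masses (Da) used throughout the package.
#' @export
mass_constants <- function() {
  c(proton = .PROTON, water = .WATER)
}

#' Monoisotopic residue mass table
#'
#' Returns the residue mass lookup used for all peptide and fragment mass
#' computations. Fixed modifications are applied as additive deltas; the
#' default carries carbamidomethylation of cysteine (+57.021464 Da), the
#' standard fixed modification for iodoacetamide-alkylated samples.
#'
#' @param fixed_mods Named numeric vector of mass deltas (Da) keyed by
#'   residue letter, added to the corresponding residue mass. Use
#'   `fixed_mods = NULL` for unmodified residues.
#' @return Named numeric vector of 20 residue masses (Da).
#' @examples
#' residue_masses()[["C"]]            # carbamidomethylated Cys
#' residue_masses(NULL)[["C"]]        # plain Cys
#' @export
residue_masses <- function(fixed_mods = c(C = 57.021464)) {
  tab <- .RESIDUE_MONO
  if (length(fixed_mods)) {
    bad <- setdiff(names(fixed_mods), names(tab))
    if (length(bad)) {
      stop("fixed_mods refer to unknown residues: ", paste(bad, collapse = ", "))
    }
    tab[names(fixed_mods)] <- tab[names(fixed_mods)] + fixed_mods
  }
  stopifnot(all(tab > 0))
  tab
}

#' Read a residue-table override from a key=value file
#'
#' Each non-empty, non-comment line is `RESIDUE=mass` (Da). Residues listed
#' replace the default (modified) masses.
#'
#' @param path Path to a flat text file.
#' @param base Base table to override, default [residue_masses()].
#' @return Named numeric residue mass vector.
#' @export
read_residue_table <- function(path, base = residue_masses()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed residue-table line: ", ln)
    res <- trimws(kv[1])
    if (!res %in% names(base)) stop("unknown residue in override: ", res)
    base[[res]] <- as.numeric(kv[2])
  }
  stopifnot(all(base > 0))
  base
}

#' Proteolytic cleavage rule
#'
#' Describes a protease as a cut-after residue set with suppressor residues
#' (no cut when the following residue is a suppressor). The default is the
#' dominant trypsin convention: cut C-terminal to K or R unless followed by
#' proline.
#'
#' @param cut_after Character vector of residues after which cleavage occurs.
#' @param suppress Residues that, when immediately following a candidate cut
#'   site, suppress the cut.
#' @param missed Maximum number of missed cleavages (0--5).
#' @param min_len,max_len Peptide length bounds applied after digestion.
#' @return An object of class `cleavage_rule`.
#' @export
cleavage_rule <- function(cut_after = c("K", "R"), suppress = "P",
                          missed = 0L, min_len = 5L, max_len = 50L) {
  cut_after <- unique(toupper(cut_after))
  suppress <- unique(toupper(suppress))
  if (length(intersect(cut_after, suppress))) {
    stop("cut_after and suppress residue sets must be disjoint")
  }
  if (missed < 0 || missed > 5) stop("missed cleavages must be in 0..5")
  if (min_len > max_len) stop("min_len must not exceed max_len")
  structure(
    list(cut_after = cut_after, suppress = suppress,
         missed = as.integer(missed),
         min_len = as.integer(min_len), max_len = as.integer(max_len)),
    class = "cleavage_rule"
  )
}

.check_sequence <- function(sequence, masses, skip_nonstandard = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("sequence must be a nonempty character scalar")
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- !(res %in% names(masses))
  if (any(bad)) {
    if (skip_nonstandard) res <- res[!bad]
    else stop("non-standard residue(s) in sequence: ",
              paste(unique(res[bad]), collapse = ", "))
  }
  if (!length(res)) stop("sequence empty after removing non-standard residues")
  res
}

#' In-silico proteolytic digestion
#'
#' Cleaves a protein sequence with a [cleavage_rule()]. Base fragments are
#' maximal runs between allowed cut sites; peptides with up to
#' `rule$missed` missed cleavages are formed by joining adjacent base
#' fragments. Length filters are applied last, so position bookkeeping is
#' exact: concatenating the 0-missed-cleavage peptides (before length
#' filtering) reconstructs the input.
#'
#' @param sequence Protein sequence (character scalar).
#' @param rule A [cleavage_rule()].
#' @param skip_nonstandard Drop non-standard residues instead of erroring.
#' @param masses Residue table defining the valid alphabet.
#' @return data.frame with columns `peptide`, `start`, `end` (1-based
#'   inclusive) and `missed_cleavages`, ordered by start position then
#'   missed-cleavage count.
#' @examples
#' digest("ACDKRPEK", cleavage_rule(min_len = 1))
#' @export
digest <- function(sequence, rule = cleavage_rule(), skip_nonstandard = FALSE,
                   masses = residue_masses()) {
  res <- .check_sequence(sequence, masses, skip_nonstandard)
  n <- length(res)
  # cut after position i iff res[i] in cut_after and res[i+1] not a suppressor
  cuts <- which(res %in% rule$cut_after)
  cuts <- cuts[cuts == n | !(res[pmin(cuts + 1L, n)] %in% rule$suppress)]
  bounds <- unique(c(0L, cuts[cuts < n], n))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  out <- vector("list", (rule$missed + 1L) * length(starts))
  k <- 0L
  for (mc in 0:rule$missed) {
    i_last <- length(starts) - mc
    if (i_last < 1) break
    for (i in seq_len(i_last)) {
      s <- starts[i]; e <- ends[i + mc]
      k <- k + 1L
      out[[k]] <- list(peptide = paste(res[s:e], collapse = ""),
                       start = s, end = e, missed_cleavages = mc)
    }
  }
  out <- out[seq_len(k)]
  df <- data.frame(
    peptide = vapply(out, `[[`, "", "peptide"),
    start = vapply(out, `[[`, 0L, "start"),
    end = vapply(out, `[[`, 0L, "end"),
    missed_cleavages = vapply(out, `[[`, 0L, "missed_cleavages"),
    stringsAsFactors = FALSE
  )
  len <- df$end - df$start + 1L
  df <- df[len >= rule$min_len & len <= rule$max_len, , drop = FALSE]
  df <- df[order(df$start, df$missed_cleavages), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.residue_mass_sum <- function(res, masses) {
  m <- masses[res]
  if (anyNA(m)) {
    stop("residue(s) absent from mass table: ",
         paste(unique(res[is.na(m)]), collapse = ", "))
  }
  sum(m)
}

#' Neutral monoisotopic peptide mass
#'
#' @param peptide Peptide sequence.
#' @param masses Residue mass table (fixed modifications already applied).
#' @return Neutral mass in Da: sum of residue masses plus one water.
#' @export
peptide_mass <- function(peptide, masses = residue_masses()) {
  res <- .check_sequence(peptide, masses)
  .residue_mass_sum(res, masses) + .WATER
}

#' Theoretical fragment-ion m/z
#'
#' b ions are N-terminal prefixes (sum of the first `ordinal` residues plus
#' `charge` protons); y ions are C-terminal suffixes (last `ordinal`
#' residues plus water plus protons).
#'
#' @param peptide Peptide sequence.
#' @param series `"y"` or `"b"`.
#' @param ordinal Fragment ordinal, 1 to `nchar(peptide) - 1`. Vectorized.
#' @param charge Fragment charge, >= 1.
#' @param masses Residue mass table.
#' @return Fragment m/z (Th), same length as `ordinal`.
#' @export
fragment_mz <- function(peptide, series = c("y", "b"), ordinal, charge = 1L,
                        masses = residue_masses()) {
  series <- match.arg(series)
  res <- .check_sequence(peptide, masses)
  n <- length(res)
  if (any(ordinal < 1L | ordinal > n - 1L)) {
    stop("fragment ordinal out of range 1..", n - 1L)
  }
  if (charge < 1) stop("fragment charge must be >= 1")
  m <- masses[res]
  csum <- cumsum(m)
  neutral <- if (series == "b") csum[ordinal]
             else (csum[n] - csum[n - ordinal]) + .WATER
  unname((neutral + charge * .PROTON) / charge)
}

#' Precursor m/z
#'
#' @inheritParams fragment_mz
#' @param charge Precursor charge, >= 1.
#' @return (neutral mass + charge protons) / charge, in Th.
#' @export
precursor_mz <- function(peptide, charge, masses = residue_masses()) {
  if (charge < 1) stop("precursor charge must be >= 1")
  (peptide_mass(peptide, masses) + charge * .PROTON) / charge
}

#' Enumerate all theoretical y/b fragments of a peptide
#'
#' @param peptide Peptide sequence.
#' @param series Ion series to enumerate (subset of y, b).
#' @param charges Fragment charge states.
#' @param masses Residue mass table.
#' @return data.frame with columns `series`, `ordinal`, `charge`, `mz`.
#' @export
theoretical_fragments <- function(peptide, series = c("y", "b"),
                                  charges = c(1L, 2L),
                                  masses = residue_masses()) {
  n <- nchar(peptide)
  if (n < 2) stop("peptide must have length >= 2 to fragment")
  grid <- expand.grid(series = series, ordinal = seq_len(n - 1L),
                      charge = charges, stringsAsFactors = FALSE)
  grid$mz <- vapply(seq_len(nrow(grid)), function(i) {
    fragment_mz(peptide, grid$series[i], grid$ordinal[i], grid$charge[i],
                masses)
  }, 0)
  grid
}

#' Collapse isoleucine and leucine for mass-based peptide comparison
#'
#' I and L are isobaric; this maps both to "L" so peptides indistinguishable
#' by mass compare equal.
#'
#' @param peptides Character vector of peptide sequences.
#' @return Character vector with every I replaced by L.
#' @export
equate_il <- function(peptides) {
  gsub("I", "L", peptides, fixed = TRUE)
}
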