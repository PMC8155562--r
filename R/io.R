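# FASTA and MGF readers/writers shared by the library-building stages.

#' Read a protein FASTA file
#'
#' Thin wrapper over Biostrings returning a named character vector
#' (header line without ">" as name, sequence as value), the container the
#' digestion and library builders work with.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped sequence lines).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- names(ss)
  out
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector; names become headers.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read an MGF peak-list file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS, CHARGE and
#' RTINSECONDS headers followed by "m/z intensity" peak lines. No installed
#' package reads MGF, so the (simple, line-oriented) format is parsed here.
#'
#' @param path Path to an MGF file.
#' @return List of spectra; each spectrum is a list with elements `id`,
#'   `precursor_mz`, `charge`, `rt` (seconds) and `peaks` (two-column
#'   matrix, `mz` ascending, `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS / END IONS")
  }
  lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    is_hdr <- grepl("^[A-Z]+=", block)
    hdr <- block[is_hdr]
    kv <- strsplit(hdr, "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, "", 1L)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    names(vals) <- keys
    pk_lines <- block[!is_hdr & nzchar(trimws(block))]
    peaks <- if (length(pk_lines)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk_lines), "[ \t]+"),
                                 function(x) as.numeric(x[1:2])))
      colnames(m) <- c("mz", "intensity")
      m[order(m[, "mz"]), , drop = FALSE]
    } else {
      matrix(numeric(0), 0, 2, dimnames = list(NULL, c("mz", "intensity")))
    }
    chg <- vals["CHARGE"]
    charge <- if (is.na(chg)) NA_integer_
              else as.integer(sub("\\+$", "", chg))
    list(
      id = unname(if (!is.na(vals["TITLE"])) vals["TITLE"] else paste0("spectrum_", i)),
      precursor_mz = as.numeric(strsplit(unname(vals["PEPMASS"]), "[ \t]+")[[1]][1]),
      charge = charge,
      rt = as.numeric(unname(vals["RTINSECONDS"])),
      peaks = peaks
    )
  })
}

#' Write spectra to MGF
#'
#' @param spectra List of spectra as produced by [read_mgf()].
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$id), con)
    writeLines(paste0("PEPMASS=", format(sp$precursor_mz, digits = 10)), con)
    if (!is.null(sp$charge) && !is.na(sp$charge)) {
      writeLines(paste0("CHARGE=", sp$charge, "+"), con)
    }
    if (!is.null(sp$rt) && !is.na(sp$rt)) {
      writeLines(paste0("RTINSECONDS=", format(sp$rt, digits = 10)), con)
    }
    if (nrow(sp$peaks)) {
      writeLines(paste(format(sp$peaks[, "mz"], digits = 10, trim = TRUE),
                       format(sp$peaks[, "intensity"], digits = 10, trim = TRUE)),
                 con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Path to a tsv with a header row.
#' @return data.frame, strings kept as character, empty cells as NA.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param df data.frame to write.
#' @param path Output path; missing values become empty cells.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
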