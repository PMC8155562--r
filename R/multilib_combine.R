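# Combination of peptide quantifications searched against multiple
# spectral libraries.

#' Combine peptide quantifications from multiple library searches
#'
#' Each library search yields one table of peptide groups (peptide +
#' charge) with a p-value and per-sample quantities. For each group in the
#' union, the combined record is chosen by precedence: (1) if the group is
#' quantified in the own library, its record is used; (2) if it is
#' quantified in only one library, that record is used; (3) if it is
#' quantified in two or more external libraries but not the own one, the
#' record with the lower p-value is used. The chosen library's quantities
#' are carried; other libraries' quantities for the same group are not
#' merged.
#'
#' @param results Named list of data.frames, one per library, each with
#'   columns `peptide`, `charge`, `pvalue` and any number of sample
#'   columns. Names are the library ids.
#' @param own_id Name of the own library within `results`.
#' @return data.frame with `peptide`, `charge`, `pvalue`, `source_library`
#'   and the sample columns of the chosen record, one row per peptide
#'   group; `qvalue` left unset (see [bh_qvalues()]).
#' @export
combine_results <- function(results, own_id) {
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    stop("results must be a named list of library tables")
  }
  if (!own_id %in% names(results)) {
    stop("own_id '", own_id, "' not among library ids: ",
         paste(names(results), collapse = ", "))
  }
  for (id in names(results)) {
    df <- results[[id]]
    need <- c("peptide", "charge", "pvalue")
    if (!all(need %in% names(df))) {
      stop("library '", id, "' missing column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    }
    key <- paste(df$peptide, df$charge, sep = "/")
    if (anyDuplicated(key)) {
      stop("duplicate peptide group within library '", id, "': ",
           key[duplicated(key)][1])
    }
    if (any(df$pvalue <= 0 | df$pvalue > 1)) {
      stop("p-values in library '", id, "' must lie in (0, 1]")
    }
  }
  long <- do.call(rbind, lapply(names(results), function(id) {
    df <- results[[id]]
    df$source_library <- id
    df
  }))
  key <- paste(long$peptide, long$charge, sep = "/")
  chosen <- unlist(lapply(split(seq_len(nrow(long)), key), function(idx) {
    own <- idx[long$source_library[idx] == own_id]
    if (length(own)) return(own)
    if (length(idx) == 1L) return(idx)
    idx[order(long$pvalue[idx], long$source_library[idx])][1]
  }), use.names = FALSE)
  out <- long[chosen, , drop = FALSE]
  out <- out[order(out$peptide, out$charge), , drop = FALSE]
  front <- c("peptide", "charge", "pvalue", "source_library")
  out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: the q-value of a p-value is the
#' smallest adjusted level at which it would be accepted. Input order is
#' preserved. Delegates to `stats::p.adjust(method = "BH")` after
#' validating the p-values.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as input.
#' @export
bh_qvalues <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Combine library tsv files and append q-values
#'
#' Convenience wrapper: reads per-library tsv tables (columns `peptide`,
#' `charge`, `pvalue`, samples), applies [combine_results()] and
#' [bh_qvalues()].
#'
#' @param own_path Path to the own library's tsv.
#' @param ext_paths Character vector of external library tsv paths.
#' @param own_id,ext_ids Library ids; defaults derived from file names.
#' @return Combined data.frame with a `qvalue` column.
#' @export
combine_library_files <- function(own_path, ext_paths,
                                  own_id = "own",
                                  ext_ids = paste0("external-",
                                                   seq_along(ext_paths))) {
  results <- c(
    stats::setNames(list(read_tsv(own_path)), own_id),
    stats::setNames(lapply(ext_paths, read_tsv), ext_ids)
  )
  out <- combine_results(results, own_id)
  out$qvalue <- bh_qvalues(out$pvalue)
  out
}
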