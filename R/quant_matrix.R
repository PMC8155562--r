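# Scaling, missingness filtering, correlation-clique protein summarization
# and transcript-protein correlation for quantification matrices.
#
# Quantification matrices are base numeric matrices: rows = features
# (peptides, proteins or transcripts), columns = samples, NA = missing.

#' Read a quantification matrix from tsv
#'
#' First column holds feature ids, remaining columns are samples; empty
#' cells are missing values.
#'
#' @param path Path to a tsv file.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_quant_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a quantification matrix to tsv
#'
#' @param m Numeric matrix (feature rownames, sample colnames).
#' @param path Output path.
#' @param id_col Name for the feature-id column.
#' @export
write_quant_matrix <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Scale each sample by its median intensity
#'
#' Divides every column by its median over observed values, removing
#' sample-level intensity differences; missing values stay missing. After
#' scaling, every column's median is 1.
#'
#' @param m Raw-level quantification matrix (values >= 0 or NA).
#' @return Scaled matrix of the same shape.
#' @export
median_scale <- function(m) {
  if (any(m < 0, na.rm = TRUE)) stop("raw matrix must be non-negative")
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  if (anyNA(med)) {
    stop("all-missing sample column(s): ",
         paste(colnames(m)[is.na(med)], collapse = ", "))
  }
  if (any(med == 0)) {
    stop("zero median in sample column(s): ",
         paste(colnames(m)[med == 0], collapse = ", "))
  }
  sweep(m, 2, med, `/`)
}

#' Log2-transform, mean-center and SD-scale each row
#'
#' Per row over observed values: log2, subtract the mean, divide by the
#' standard deviation. Constant rows (SD 0) become centered zeros with a
#' warning.
#'
#' @param m Quantification matrix with strictly positive observed values.
#' @return Row-standardized log2 matrix.
#' @export
log2_center_scale <- function(m) {
  if (any(m <= 0, na.rm = TRUE)) {
    stop("observed values must be strictly positive for log2 transform")
  }
  lg <- log2(m)
  mu <- rowMeans(lg, na.rm = TRUE)
  sd <- apply(lg, 1, stats::sd, na.rm = TRUE)
  out <- sweep(lg, 1, mu, `-`)
  zero_sd <- !is.na(sd) & sd == 0
  if (any(zero_sd)) {
    warning(sum(zero_sd), " constant row(s) left as centered zeros")
    sd[zero_sd] <- 1
  }
  sd[is.na(sd)] <- 1  # rows with a single observation: centered zero
  sweep(out, 1, sd, `/`)
}

#' Drop rows with too many missing observations
#'
#' @param m Quantification matrix.
#' @param max_frac Strict upper bound on the per-row missing fraction
#'   (default 0.30: rows with less than 30 percent missing are kept).
#' @return Filtered matrix.
#' @export
filter_missingness <- function(m, max_frac = 0.30) {
  frac <- rowMeans(is.na(m))
  m[frac < max_frac, , drop = FALSE]
}

#' Configuration for correlation-clique protein summarization
#'
#' @param min_size Minimum subgroup size (default 3 peptides).
#' @param rho_min Minimum pairwise Spearman correlation within the
#'   subgroup (default 0.7, inclusive).
#' @param min_overlap Minimum number of pairwise complete sample
#'   observations for a correlation to count (default 6).
#' @param clique_cap Up to this many peptides the maximum clique is found
#'   exactly; beyond it a greedy degeneracy-ordered search is used
#'   (default 30).
#' @param fallback What to do when no qualifying clique exists: `"drop"`
#'   the protein (default) or `"sum_all"` peptides.
#' @return List of class `summarization_config`.
#' @export
summarization_config <- function(min_size = 3L, rho_min = 0.7,
                                 min_overlap = 6L, clique_cap = 30L,
                                 fallback = c("drop", "sum_all")) {
  fallback <- match.arg(fallback)
  if (min_size < 2) stop("min_size must be >= 2")
  if (rho_min <= -1 || rho_min >= 1) stop("rho_min must be in (-1, 1)")
  structure(
    list(min_size = as.integer(min_size), rho_min = rho_min,
         min_overlap = as.integer(min_overlap),
         clique_cap = as.integer(clique_cap), fallback = fallback),
    class = "summarization_config"
  )
}

# Pairwise Spearman among matrix rows with a minimum-overlap requirement;
# returns adjacency (TRUE where rho >= rho_min on >= min_overlap pairs).
.peptide_adjacency <- function(m, cfg) {
  n <- nrow(m)
  adj <- matrix(FALSE, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (sum(ok) < cfg$min_overlap) next
      rho <- stats::cor(m[i, ok], m[j, ok], method = "spearman")
      if (!is.na(rho) && rho >= cfg$rho_min) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  adj
}

# Greedy degeneracy-ordered max-clique heuristic for large peptide sets.
.greedy_clique <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  best <- integer(0)
  for (seed_v in order(-deg)) {
    clique <- seed_v
    cand <- which(adj[seed_v, ])
    cand <- cand[order(-deg[cand])]
    for (v in cand) {
      if (all(adj[v, clique])) clique <- c(clique, v)
    }
    if (length(clique) > length(best)) best <- clique
  }
  sort(best)
}

# All maximum cliques of the adjacency graph (exact when small, greedy
# beyond cfg$clique_cap); returns a list of integer index vectors.
.max_cliques <- function(adj, cfg) {
  n <- nrow(adj)
  if (n <= cfg$clique_cap) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cl <- igraph::largest_cliques(g)
    lapply(cl, function(v) sort(as.integer(v)))
  } else {
    list(.greedy_clique(adj))
  }
}

#' Summarize one protein's peptides by their largest correlated subgroup
#'
#' Builds a graph over the protein's peptides with an edge where the
#' pairwise Spearman correlation is at least `cfg$rho_min` (computed on at
#' least `cfg$min_overlap` shared samples), selects the largest clique of
#' at least `cfg$min_size` peptides (ties broken toward larger total raw
#' intensity), sums the members' raw intensities per sample (observed
#' members only; a sample with no observed member stays missing), and
#' standardizes the summed profile with [log2_center_scale()].
#'
#' @param m Raw-level matrix of this protein's peptides (rows) by samples.
#' @param cfg A [summarization_config()].
#' @return List with `peptides` (clique members), `summed` (raw per-sample
#'   sums) and `scaled` (log2/centered/scaled vector), or NULL when no
#'   qualifying subgroup exists and `cfg$fallback` is `"drop"`.
#' @export
summarize_protein <- function(m, cfg = summarization_config()) {
  if (is.null(dim(m))) stop("m must be a matrix of peptide rows")
  clique <- integer(0)
  if (nrow(m) >= cfg$min_size) {
    adj <- .peptide_adjacency(m, cfg)
    cliques <- .max_cliques(adj, cfg)
    cliques <- Filter(function(v) length(v) >= cfg$min_size, cliques)
    if (length(cliques)) {
      tot <- vapply(cliques, function(v) sum(m[v, ], na.rm = TRUE), 0)
      clique <- cliques[[order(-lengths(cliques), -tot)[1]]]
    }
  }
  if (!length(clique)) {
    if (cfg$fallback == "drop") return(NULL)
    clique <- seq_len(nrow(m))
  }
  sub <- m[clique, , drop = FALSE]
  observed <- colSums(!is.na(sub)) > 0
  summed <- colSums(sub, na.rm = TRUE)
  summed[!observed] <- NA_real_
  scaled <- as.numeric(log2_center_scale(matrix(summed, nrow = 1)))
  names(scaled) <- names(summed)
  list(peptides = rownames(m)[clique], summed = summed, scaled = scaled)
}

#' Summarize all proteins of a peptide quantification matrix
#'
#' @param m Raw-level peptide matrix (peptide rownames).
#' @param map data.frame with columns `peptide`, `protein`.
#' @param cfg A [summarization_config()].
#' @return List with `raw` (protein x sample matrix of summed intensities),
#'   `scaled` (row-standardized log2 version) and `members` (named list of
#'   clique peptides per protein). Dropped proteins are absent.
#' @export
summarize_proteins <- function(m, map, cfg = summarization_config()) {
  if (!all(c("peptide", "protein") %in% names(map))) {
    stop("map must have columns peptide, protein")
  }
  map <- map[map$peptide %in% rownames(m), , drop = FALSE]
  by_prot <- split(map$peptide, map$protein)
  summaries <- lapply(by_prot, function(peps) {
    summarize_protein(m[peps, , drop = FALSE], cfg)
  })
  keep <- !vapply(summaries, is.null, TRUE)
  summaries <- summaries[keep]
  if (!length(summaries)) {
    return(list(raw = matrix(numeric(0), 0, ncol(m),
                             dimnames = list(NULL, colnames(m))),
                scaled = matrix(numeric(0), 0, ncol(m),
                                dimnames = list(NULL, colnames(m))),
                members = list()))
  }
  raw <- do.call(rbind, lapply(summaries, `[[`, "summed"))
  scaled <- do.call(rbind, lapply(summaries, `[[`, "scaled"))
  rownames(raw) <- rownames(scaled) <- names(summaries)
  colnames(raw) <- colnames(scaled) <- colnames(m)
  list(raw = raw, scaled = scaled,
       members = lapply(summaries, `[[`, "peptides"))
}

#' Spearman correlation between paired features of two matrices
#'
#' For each requested pair (for example transcript and protein of the same
#' gene), computes the Spearman correlation over shared samples with
#' pairwise-complete observations, average ranks for ties, and a p-value
#' from the t-approximation on rho with n - 2 degrees of freedom. Pairs
#' with fewer than 3 complete observations are reported with NA rho and a
#' note.
#'
#' @param x,y Quantification matrices sharing (some) sample columns.
#' @param pairing data.frame with columns `x_id`, `y_id` naming rows of
#'   `x` and `y` to correlate.
#' @return data.frame: `x_id`, `y_id`, `rho`, `pvalue`, `n`, `note`.
#' @export
spearman_pairs <- function(x, y, pairing) {
  shared <- intersect(colnames(x), colnames(y))
  if (!length(shared)) stop("x and y share no sample columns")
  if (!all(c("x_id", "y_id") %in% names(pairing))) {
    stop("pairing must have columns x_id, y_id")
  }
  res <- lapply(seq_len(nrow(pairing)), function(i) {
    xi <- pairing$x_id[i]; yi <- pairing$y_id[i]
    if (!xi %in% rownames(x) || !yi %in% rownames(y)) {
      return(data.frame(x_id = xi, y_id = yi, rho = NA_real_,
                        pvalue = NA_real_, n = 0L, note = "feature absent"))
    }
    a <- x[xi, shared]; b <- y[yi, shared]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    if (n < 3) {
      return(data.frame(x_id = xi, y_id = yi, rho = NA_real_,
                        pvalue = NA_real_, n = n,
                        note = "fewer than 3 complete pairs"))
    }
    rho <- stats::cor(a[ok], b[ok], method = "spearman")
    p <- if (is.na(rho)) NA_real_
         else if (abs(rho) >= 1) 0
         else {
           tval <- rho * sqrt((n - 2) / (1 - rho^2))
           2 * stats::pt(-abs(tval), df = n - 2)
         }
    data.frame(x_id = xi, y_id = yi, rho = rho, pvalue = p, n = n, note = "")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
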