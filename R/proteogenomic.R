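# RNA-guided library builders: SAAV-specific peptide FASTA and
# isoform-combination mock-protein FASTA, both inputs to the transition
# library stage.

#' Filter RNA-derived variant calls by read support
#'
#' Keeps calls with at least `min_alt` reads supporting the variant and at
#' least `min_cov` reads total coverage (both inclusive).
#'
#' @param calls data.frame with columns `protein_id`, `pos`, `ref`, `alt`,
#'   `alt_reads`, `coverage` and optional `label`.
#' @param min_alt Minimum alternate-allele read count (default 2).
#' @param min_cov Minimum total coverage (default 10).
#' @return Filtered data.frame.
#' @export
filter_variants <- function(calls, min_alt = 2L, min_cov = 10L) {
  need <- c("protein_id", "pos", "ref", "alt", "alt_reads", "coverage")
  if (!all(need %in% names(calls))) {
    stop("variant table missing column(s): ",
         paste(setdiff(need, names(calls)), collapse = ", "))
  }
  if (any(calls$coverage < calls$alt_reads)) {
    stop("coverage must be >= alt_reads")
  }
  if (any(calls$ref == calls$alt)) stop("ref and alt residues must differ")
  out <- calls[calls$alt_reads >= min_alt & calls$coverage >= min_cov, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply a single-amino-acid variant to a protein sequence
#'
#' @param sequence Protein sequence.
#' @param pos 1-based substitution position.
#' @param ref Expected reference residue at `pos` (checked).
#' @param alt Alternate residue.
#' @return Variant sequence, same length.
#' @export
apply_variant <- function(sequence, pos, ref, alt) {
  n <- nchar(sequence)
  if (pos < 1 || pos > n) {
    stop("variant position ", pos, " outside sequence of length ", n)
  }
  have <- substr(sequence, pos, pos)
  if (have != ref) {
    stop("reference mismatch at position ", pos, ": sequence has '", have,
         "', variant expects '", ref, "'")
  }
  substr(sequence, pos, pos) <- alt
  sequence
}

#' Peptides that specifically identify a SAAV
#'
#' Digests the reference and the variant sequence with the same cleavage
#' rule and returns the variant peptides absent from the reference digest.
#' Typically this is a single peptide; a substitution that creates a K/R
#' cleavage site yields two specific peptides, one that destroys a site
#' yields a single merged peptide.
#'
#' @param ref_seq,var_seq Reference and variant protein sequences (equal
#'   length).
#' @param rule A [cleavage_rule()].
#' @param equate_il Compare peptides with I and L collapsed (isobaric), so
#'   variant peptides indistinguishable by mass from a reference peptide
#'   are not reported as identifying.
#' @return data.frame of identifying peptides with `peptide`, `start`,
#'   `end` (positions in the variant protein), ordered by position; zero
#'   rows when the variant yields no identifying peptide.
#' @export
saav_specific_peptides <- function(ref_seq, var_seq, rule = cleavage_rule(),
                                   equate_il = FALSE) {
  if (nchar(ref_seq) != nchar(var_seq)) {
    stop("reference and variant sequences must have equal length")
  }
  ref_dig <- digest(ref_seq, rule)
  var_dig <- digest(var_seq, rule)
  ref_set <- if (equate_il) equate_il(ref_dig$peptide) else ref_dig$peptide
  var_cmp <- if (equate_il) equate_il(var_dig$peptide) else var_dig$peptide
  out <- var_dig[!(var_cmp %in% ref_set), c("peptide", "start", "end")]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a SAAV peptide library from variant calls
#'
#' For each filtered variant call: derive the variant protein sequence,
#' digest reference and variant, keep the variant-specific peptides
#' ([saav_specific_peptides()]), and emit one FASTA record per SAAV whose
#' sequence is the identifying peptides concatenated in order of position
#' in the variant protein. A sidecar table records every member peptide
#' with its coordinates inside the concatenated record, so downstream
#' transition building always uses real peptides, never artifacts spanning
#' concatenation junctions. SAAVs with no identifying peptide are recorded
#' in `empty` and not emitted.
#'
#' @param proteome Named character vector: protein id -> reference
#'   sequence.
#' @param calls Variant table (see [filter_variants()]); applied as-is, so
#'   filter first if read-support thresholds should apply.
#' @param rule A [cleavage_rule()].
#' @param equate_il Collapse I/L when testing peptide specificity.
#' @param whole_proteome If TRUE, identifying peptides must also be absent
#'   from the digest of every other reference protein (stricter
#'   uniqueness); default compares against the parent protein only.
#' @return List with `fasta` (named character, header
#'   `SAAV|<protein id>|<label>`), `sidecar` (data.frame: `record_id`,
#'   `peptide`, `start`, `end` within the record) and `empty` (labels of
#'   SAAVs with no identifying peptide).
#' @export
build_saav_library <- function(proteome, calls, rule = cleavage_rule(),
                               equate_il = FALSE, whole_proteome = FALSE) {
  missing_prot <- setdiff(calls$protein_id, names(proteome))
  if (length(missing_prot)) {
    stop("variant calls reference unknown protein(s): ",
         paste(utils::head(missing_prot, 5), collapse = ", "))
  }
  bg <- NULL
  if (whole_proteome) {
    bg <- unlist(lapply(proteome, function(s) digest(s, rule)$peptide),
                 use.names = FALSE)
    if (equate_il) bg <- equate_il(bg)
  }
  fasta <- character(0)
  sidecar <- list()
  empty <- character(0)
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    label <- if ("label" %in% names(calls) && !is.na(call$label)) call$label
             else paste0(call$protein_id, ":", call$ref, call$pos, call$alt)
    ref_seq <- proteome[[call$protein_id]]
    var_seq <- apply_variant(ref_seq, call$pos, call$ref, call$alt)
    peps <- saav_specific_peptides(ref_seq, var_seq, rule, equate_il)
    if (!is.null(bg) && nrow(peps)) {
      cmp <- if (equate_il) equate_il(peps$peptide) else peps$peptide
      peps <- peps[!(cmp %in% bg), , drop = FALSE]
    }
    if (!nrow(peps)) {
      empty <- c(empty, label)
      next
    }
    rec_id <- paste("SAAV", call$protein_id, label, sep = "|")
    fasta[[rec_id]] <- paste(peps$peptide, collapse = "")
    len <- nchar(peps$peptide)
    ends <- cumsum(len)
    sidecar[[length(sidecar) + 1L]] <- data.frame(
      record_id = rec_id, peptide = peps$peptide,
      start = ends - len + 1L, end = ends, stringsAsFactors = FALSE
    )
  }
  list(
    fasta = fasta,
    sidecar = if (length(sidecar)) do.call(rbind, sidecar)
              else data.frame(record_id = character(0), peptide = character(0),
                              start = integer(0), end = integer(0)),
    empty = empty
  )
}

#' Build an isoform-combination (mock protein) library
#'
#' Digests every protein isoform, maps each distinct peptide of at least
#' `min_len` residues to the exact set of isoform ids whose digest
#' contains it, and groups peptides sharing the same isoform set. Each
#' group becomes one mock protein: its peptides concatenated (ordered by
#' position in the group's lexicographically smallest isoform), with a
#' header encoding the sorted isoform ids. Every retained peptide belongs
#' to exactly one group, so the groups partition the peptide universe.
#'
#' @param isoforms Named character vector: protein isoform id -> sequence
#'   (ids unique).
#' @param rule A [cleavage_rule()]; its length bounds are replaced by
#'   `min_len` and the rule's `max_len`.
#' @param min_len Minimum peptide length retained (default 5).
#' @return List with `groups` (list: each has `isoforms`, `peptides`,
#'   `mock_id`, `mock_seq`), `fasta` (named character of mock proteins)
#'   and `sidecar` (data.frame: `record_id`, `peptide`, `start`, `end`).
#' @export
build_isoform_library <- function(isoforms, rule = cleavage_rule(),
                                  min_len = 5L) {
  if (anyDuplicated(names(isoforms))) {
    stop("duplicate protein isoform ids")
  }
  rule2 <- rule
  rule2$min_len <- as.integer(min_len)
  digests <- lapply(isoforms, function(s) unique(digest(s, rule2)$peptide))
  # peptide -> sorted set of isoform ids containing it
  pep2iso <- list()
  for (id in names(digests)) {
    for (p in digests[[id]]) pep2iso[[p]] <- c(pep2iso[[p]], id)
  }
  if (!length(pep2iso)) {
    return(list(groups = list(), fasta = character(0),
                sidecar = data.frame(record_id = character(0),
                                     peptide = character(0),
                                     start = integer(0), end = integer(0))))
  }
  set_key <- vapply(pep2iso, function(ids) paste(sort(ids), collapse = ";"), "")
  groups <- lapply(split(names(pep2iso), set_key), function(peps) {
    iso_ids <- sort(pep2iso[[peps[1]]])
    # order member peptides by position in the smallest-id isoform
    anchor <- isoforms[[iso_ids[1]]]
    pos <- vapply(peps, function(p) as.integer(regexpr(p, anchor, fixed = TRUE)),
                  0L)
    peps <- peps[order(pos, peps)]
    mock_id <- paste0("ISOGRP|", paste(iso_ids, collapse = ";"))
    list(isoforms = iso_ids, peptides = peps, mock_id = mock_id,
         mock_seq = paste(peps, collapse = ""))
  })
  names(groups) <- vapply(groups, `[[`, "", "mock_id")
  fasta <- vapply(groups, `[[`, "", "mock_seq")
  names(fasta) <- names(groups)
  sidecar <- do.call(rbind, lapply(groups, function(g) {
    len <- nchar(g$peptides)
    ends <- cumsum(len)
    data.frame(record_id = g$mock_id, peptide = g$peptides,
               start = ends - len + 1L, end = ends,
               stringsAsFactors = FALSE)
  }))
  rownames(sidecar) <- NULL
  list(groups = groups, fasta = fasta, sidecar = sidecar)
}
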