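#' Peptide reporter-intensity matrix
#'
#' Container for a peptide x sample matrix of TMT reporter intensities with a
#' group label (e.g. `"Wt"` / `"Hom"`) per sample channel. Missing intensities
#' are `NA`; a reported intensity of 0 means "not observed" and is converted to
#' missing on construction.
#'
#' @param intensities Numeric matrix, rows = peptides (rownames = peptide IDs),
#'   columns = samples (colnames = sample IDs). Values >= 0 or `NA`.
#' @param groups Character vector of group labels, one per sample column.
#' @return An object of class `peptide_matrix`: the matrix with a `groups`
#'   attribute (named by sample ID).
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("PEP1", "PEP2"), c("S1", "S2", "S3")))
#' peptide_matrix(rbind(m, m + 1)[1:2, ], groups = c("Wt", "Wt", "Hom"))
#' @export
peptide_matrix <- function(intensities, groups) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("`intensities` must have peptide rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate peptide ID: ",
         rownames(intensities)[anyDuplicated(rownames(intensities))],
         call. = FALSE)
  if (length(groups) != ncol(intensities))
    stop("one group label per sample column required", call. = FALSE)
  if (any(intensities < 0, na.rm = TRUE)) {
    bad <- which(intensities < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative intensity at peptide '%s', sample '%s'",
                 rownames(intensities)[bad[1L]],
                 colnames(intensities)[bad[2L]]), call. = FALSE)
  }
  intensities[!is.na(intensities) & intensities == 0] <- NA_real_
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 2L))
    stop("fewer than 2 samples in group: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  structure(intensities, groups = setNames(groups, colnames(intensities)),
            class = c("peptide_matrix", "matrix", "array"))
}

#' @export
print.peptide_matrix <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("peptide_matrix: %d peptides x %d samples (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s:%d", names(table(g)), table(g)),
                    collapse = ", ")))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x)),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Sample group labels
#'
#' @param x A `peptide_matrix` or `protein_quant` object.
#' @return Named character vector of group labels, one per sample.
#' @export
sample_groups <- function(x) attr(x, "groups")

#' Read a peptide reporter-intensity table
#'
#' Expects a TSV whose first line is a header (`peptide_id` followed by sample
#' IDs) and whose second line starts with `#group:` and carries one group
#' label per sample; remaining lines are one peptide per row. Empty cells are
#' missing; a 0 intensity is treated as missing. Group labels may instead be
#' supplied via `groups` (vector or path to a two-column sidecar TSV
#' `sample_id TAB group`).
#'
#' @param path Path to the TSV file.
#' @param groups Optional group labels overriding the `#group:` line: either a
#'   character vector (one per sample) or the path of a sidecar TSV.
#' @return A [peptide_matrix()].
#' @export
read_peptide_table <- function(path, groups = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty peptide table: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 2L)
    stop("peptide table must have at least 2 sample columns", call. = FALSE)
  body_start <- 2L
  file_groups <- NULL
  if (length(lines) >= 2L && startsWith(lines[[2L]], "#group:")) {
    gfields <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    file_groups <- gfields[-1L]
    if (length(file_groups) != length(sample_ids))
      stop("#group: line must carry one label per sample", call. = FALSE)
    body_start <- 3L
  }
  if (!is.null(groups)) {
    if (length(groups) == 1L && file.exists(groups)) {
      sidecar <- read.delim(groups, header = FALSE, stringsAsFactors = FALSE)
      groups <- setNames(as.character(sidecar[[2L]]),
                         as.character(sidecar[[1L]]))[sample_ids]
      if (anyNA(groups))
        stop("sidecar group file missing labels for some samples",
             call. = FALSE)
    }
  } else {
    if (is.null(file_groups))
      stop("no #group: line in file and no `groups` supplied", call. = FALSE)
    groups <- file_groups
  }
  body <- lines[seq.int(body_start, length.out = length(lines) - body_start + 1L)]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    stop("peptide table has no peptide rows", call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate peptide ID: ", ids[anyDuplicated(ids)], call. = FALSE)
  nc <- length(sample_ids)
  vals <- matrix(NA_real_, nrow = length(ids), ncol = nc,
                 dimnames = list(ids, sample_ids))
  for (r in seq_along(fields)) {
    f <- fields[[r]]
    length(f) <- nc + 1L          # right-pad short rows (trailing empties)
    cells <- f[-1L]
    empty <- is.na(cells) | !nzchar(cells)
    x <- suppressWarnings(as.numeric(cells))
    bad <- which(!empty & is.na(x))
    if (length(bad))
      stop(sprintf("non-numeric intensity '%s' at peptide '%s', sample '%s'",
                   cells[bad[1L]], ids[r], sample_ids[bad[1L]]),
           call. = FALSE)
    neg <- which(!is.na(x) & x < 0)
    if (length(neg))
      stop(sprintf("negative intensity at peptide '%s', sample '%s'",
                   ids[r], sample_ids[neg[1L]]), call. = FALSE)
    vals[r, ] <- x
  }
  peptide_matrix(vals, groups)
}

#' Write a peptide reporter-intensity table
#'
#' Inverse of [read_peptide_table()]: writes the header line, the `#group:`
#' line and one row per peptide, with missing intensities as empty cells.
#' Intensities are written with full precision so the pair round-trips
#' losslessly.
#'
#' @param x A [peptide_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(x, path) {
  stopifnot(inherits(x, "peptide_matrix"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- c(
    paste(c("peptide_id", colnames(x)), collapse = "\t"),
    paste(c("#group:", attr(x, "groups")), collapse = "\t"),
    vapply(seq_len(nrow(x)), function(r)
      paste(c(rownames(x)[r], fmt(x[r, ])), collapse = "\t"), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a peptide-to-protein mapping table
#'
#' A two-column TSV (`peptide_id`, `protein_id`) with a header line; a shared
#' peptide appears on one row per owner protein. A peptide is *unique* when it
#' maps to exactly one protein.
#'
#' @param path Path to the TSV.
#' @return `read_protein_map()`: a data.frame with columns `peptide_id` and
#'   `protein_id`.
#' @export
read_protein_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("peptide_id", "protein_id") %in% names(df)))
    stop("map must have columns peptide_id, protein_id", call. = FALSE)
  df[c("peptide_id", "protein_id")]
}

#' @rdname read_protein_map
#' @param map Data.frame with columns `peptide_id`, `protein_id`.
#' @export
write_protein_map <- function(map, path) {
  write.table(map[c("peptide_id", "protein_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT annotation file
#'
#' Standard GMT: one term per line, `term_id TAB description TAB member TAB
#' member ...`. Member sets are de-duplicated; terms left with no members are
#' dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @param category Annotation category label attached to every term read from
#'   this file (e.g. `"BP"`, `"pathway"`, `"domain"`). Default `"pathway"`.
#' @return A list of terms, each a list with elements `term_id`, `name`,
#'   `category` and `members` (character vector).
#' @export
read_annotation_gmt <- function(path, category = "pathway") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  terms <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    terms[[i]] <- list(term_id = f[[1L]], name = f[[2L]],
                       category = category, members = members)
  }
  empty <- vapply(terms, function(t) length(t$members) == 0L, TRUE)
  if (any(empty)) {
    warning(sum(empty), " empty term(s) dropped: ",
            paste(vapply(terms[empty], `[[`, "", "term_id"), collapse = ", "),
            call. = FALSE)
    terms <- terms[!empty]
  }
  terms
}

#' @rdname read_annotation_gmt
#' @param terms List of terms as returned by [read_annotation_gmt()] or
#'   [simulate_annotations()].
#' @export
write_annotation_gmt <- function(terms, path) {
  lines <- vapply(terms, function(t)
    paste(c(t$term_id, t$name, t$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PRM ratio table
#'
#' A TSV with header columns `protein_id`, `protein_name`, `gene_name`,
#' `peptides` (semicolon-separated sequences), `prm_ratio`, `tmt_ratio`,
#' `regulated_type` (`Up`/`Down`). Both ratios are Hom/Wt and must be
#' positive.
#'
#' @param path Path to the TSV.
#' @return A data.frame of class `prm_records` with one row per protein.
#' @seealso [load_table1_fixture()] for the packaged 20-protein validation
#'   table.
#' @export
read_prm_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    out <- data.frame(protein_id = character(), protein_name = character(),
                      gene_name = character(), peptides = character(),
                      prm_ratio = numeric(), tmt_ratio = numeric(),
                      regulated_type = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("prm_records", "data.frame")
    return(out)
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "protein_name", "gene_name", "peptides",
            "prm_ratio", "tmt_ratio", "regulated_type")
  if (!all(need %in% names(df)))
    stop("PRM table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df <- df[need]
  if (any(!is.finite(df$prm_ratio)) || any(!is.finite(df$tmt_ratio)) ||
      any(df$prm_ratio <= 0) || any(df$tmt_ratio <= 0))
    stop("PRM and TMT ratios must be positive", call. = FALSE)
  if (!all(df$regulated_type %in% c("Up", "Down")))
    stop("regulated_type must be 'Up' or 'Down'", call. = FALSE)
  class(df) <- c("prm_records", "data.frame")
  df
}
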