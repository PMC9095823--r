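#' Centralize peptide intensities
#'
#' First step of relative quantification: each peptide's intensities are
#' divided by their across-sample mean, \eqn{U_{ij} = I_{ij} /
#' \mathrm{mean}(I_j)}, making peptides of very different ionization
#' efficiency comparable. Means are taken over observed values only; missing
#' cells stay missing. Peptides missing in every sample are dropped with a
#' warning.
#'
#' @param x A [peptide_matrix()] of raw reporter intensities.
#' @return A `peptide_matrix` of centralized relative values `U`.
#' @export
centralize <- function(x) {
  stopifnot(inherits(x, "peptide_matrix"))
  g <- attr(x, "groups")
  X <- unclass(x)
  m <- apply(X, 1L, mean_obs)
  dead <- is.na(m)
  if (any(dead)) {
    warning(sum(dead), " peptide(s) with no observed intensity dropped",
            call. = FALSE)
    X <- X[!dead, , drop = FALSE]
    m <- m[!dead]
  }
  structure(X / m, groups = g, dropped_peptides = sum(dead),
            class = c("peptide_matrix", "matrix", "array"))
}

#' Median-correct centralized values
#'
#' Second step: each sample channel's centralized values are divided by that
#' channel's median, \eqn{NR_{ij} = U_{ij} / \mathrm{median}(U_i)}, removing
#' the systematic per-channel loading/detection bias. Medians are over
#' observed values; after correction every channel's observed median is
#' exactly 1.
#'
#' @param x A `peptide_matrix` of centralized values from [centralize()].
#' @return A `peptide_matrix` of corrected values `NR`.
#' @export
median_correct <- function(x) {
  stopifnot(inherits(x, "peptide_matrix"))
  med <- apply(unclass(x), 2L, median_obs)
  if (anyNA(med))
    stop("sample with no observed value: ",
         paste(colnames(x)[is.na(med)], collapse = ", "), call. = FALSE)
  if (any(med == 0))
    stop("degenerate input: sample median 0 in ",
         paste(colnames(x)[med == 0], collapse = ", "), call. = FALSE)
  nr <- sweep(unclass(x), 2L, med, `/`)
  structure(nr, groups = attr(x, "groups"),
            dropped_peptides = attr(x, "dropped_peptides"),
            class = class(x))
}

#' Roll peptides up to protein relative values
#'
#' Third step: the relative quantitative value of protein k in sample i is
#' the median of that sample's corrected values over the protein's *unique*
#' peptides, \eqn{R_{ik} = \mathrm{median}(NR_{ij}, j \in k)}. A peptide is
#' unique when the mapping assigns it exactly one protein; shared peptides
#' never contribute. A protein with no unique peptide observed in a sample is
#' missing there; proteins with no unique peptides at all are absent from the
#' output. A protein is *quantifiable* when at least one of its unique
#' peptides is observed in at least 2 samples of each group.
#'
#' @param x A `peptide_matrix` of corrected values from [median_correct()].
#' @param map Peptide-to-protein mapping data.frame (`peptide_id`,
#'   `protein_id`); every peptide in `x` must appear.
#' @return A `protein_quant` object: protein x sample matrix of `R` values
#'   with attributes `groups`, `n_unique_peptides` (per protein) and
#'   `quantifiable` (logical per protein).
#' @export
rollup_protein <- function(x, map) {
  stopifnot(inherits(x, "peptide_matrix"), is.data.frame(map))
  absent <- setdiff(rownames(x), map$peptide_id)
  if (length(absent))
    stop("peptide(s) absent from map: ",
         paste(head(absent, 3L), collapse = ", "),
         if (length(absent) > 3L) ", ...", call. = FALSE)
  owners <- table(map$peptide_id)
  unique_pep <- names(owners)[owners == 1L]
  m <- map[map$peptide_id %in% unique_pep & map$peptide_id %in% rownames(x), ]
  groups <- attr(x, "groups")
  prot_ids <- sort(unique(m$protein_id))
  R <- matrix(NA_real_, nrow = length(prot_ids), ncol = ncol(x),
              dimnames = list(prot_ids, colnames(x)))
  n_unique <- integer(length(prot_ids))
  names(n_unique) <- prot_ids
  pep_by_prot <- split(m$peptide_id, m$protein_id)
  for (k in prot_ids) {
    peps <- pep_by_prot[[k]]
    n_unique[k] <- length(peps)
    sub <- unclass(x)[peps, , drop = FALSE]
    R[k, ] <- apply(sub, 2L, median_obs)
  }
  obs_per_group <- function(k) {
    peps <- pep_by_prot[[k]]
    sub <- !is.na(unclass(x)[peps, , drop = FALSE])
    # any single unique peptide observed in >=2 samples of each group?
    any(apply(sub, 1L, function(row)
      all(tapply(row, groups, sum) >= 2L)))
  }
  quantifiable <- vapply(prot_ids, obs_per_group, TRUE)
  structure(R, groups = groups, n_unique_peptides = n_unique,
            quantifiable = quantifiable,
            class = c("protein_quant", "matrix", "array"))
}

#' @export
print.protein_quant <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("protein_quant: %d proteins x %d samples (%s); %d quantifiable\n",
              nrow(x), ncol(x),
              paste(sprintf("%s:%d", names(table(g)), table(g)),
                    collapse = ", "),
              sum(attr(x, "quantifiable"))))
  invisible(x)
}

#' Replicate-reproducibility QC
#'
#' For each sample channel, computes the median of its pairwise Spearman
#' correlations (on log-transformed protein values, pairwise complete) with
#' the other channels of the same group, and flags channels whose median
#' correlation falls below `floor`. A group of fewer than 3 channels is
#' skipped with a warning, since the outlier cannot be isolated from a single
#' pair.
#'
#' Reproducibility must be judged on a scale that carries cross-protein
#' dynamic range: [protein_quant()] therefore applies this check to the
#' *raw-intensity* protein rollup (medians of unique-peptide reporter
#' intensities), where genuine replicates correlate strongly, not to the
#' final relative values, whose cross-protein structure is removed by
#' construction.
#'
#' @param quant A `protein_quant`-shaped matrix from [rollup_protein()]
#'   (raw-intensity or relative values).
#' @param floor Correlation floor in \[-1, 1\]. Default 0.8.
#' @return A list with `flagged` (character vector of sample IDs),
#'   `median_correlation` (named numeric per sample) and `correlations`
#'   (full sample x sample Spearman matrix, NA across groups).
#' @export
replicate_qc <- function(quant, floor = 0.8) {
  stopifnot(inherits(quant, "protein_quant"), floor >= -1, floor <= 1)
  groups <- attr(quant, "groups")
  logR <- log(unclass(quant))
  n <- ncol(quant)
  cmat <- matrix(NA_real_, n, n, dimnames = list(colnames(quant),
                                                 colnames(quant)))
  med_cor <- setNames(rep(NA_real_, n), colnames(quant))
  flagged <- character()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3L) {
      warning("group '", g, "' has fewer than 3 samples; QC skipped",
              call. = FALSE)
      next
    }
    sub <- suppressWarnings(
      cor(logR[, idx, drop = FALSE], method = "spearman",
          use = "pairwise.complete.obs"))
    cmat[idx, idx] <- sub
    for (j in seq_along(idx)) {
      med_cor[idx[j]] <- median(sub[j, -j], na.rm = TRUE)
      if (!is.na(med_cor[idx[j]]) && med_cor[idx[j]] < floor)
        flagged <- c(flagged, colnames(quant)[idx[j]])
    }
  }
  list(flagged = flagged, median_correlation = med_cor, correlations = cmat)
}

#' Full peptide-to-protein quantification with QC
#'
#' Runs [replicate_qc()] on the raw-intensity protein rollup, excludes any
#' flagged channels, then chains [centralize()], [median_correct()] and
#' [rollup_protein()] over the retained channels only (normalization is
#' computed after QC exclusion, so a bad channel cannot distort the retained
#' ones).
#'
#' @param peptides A [peptide_matrix()] of raw reporter intensities.
#' @param map Peptide-to-protein mapping data.frame.
#' @param qc Logical; run replicate QC and exclude flagged channels.
#'   Default `TRUE`.
#' @param qc_floor Correlation floor passed to [replicate_qc()]. Default 0.8.
#' @return A `protein_quant` matrix (flagged channels removed) with extra
#'   attributes `qc` (the [replicate_qc()] result from the first pass) and
#'   `excluded_samples`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 30, seed = 2))
#' q <- protein_quant(sim$peptides, sim$map)
#' q
#' @export
protein_quant <- function(peptides, map, qc = TRUE, qc_floor = 0.8) {
  qc_res <- NULL
  excluded <- character()
  pep <- peptides
  if (qc) {
    raw_abundance <- rollup_protein(peptides, map)
    qc_res <- replicate_qc(raw_abundance, floor = qc_floor)
    excluded <- qc_res$flagged
    if (length(excluded)) {
      keep <- setdiff(colnames(peptides), excluded)
      groups <- attr(peptides, "groups")[keep]
      pep <- peptide_matrix(unclass(peptides)[, keep, drop = FALSE], groups)
    }
  }
  quant <- rollup_protein(median_correct(centralize(pep)), map)
  attr(quant, "qc") <- qc_res
  attr(quant, "excluded_samples") <- excluded
  quant
}

#' Spectra accounting and utilization rate
#'
#' Bookkeeping for the MS/MS search funnel: total acquired secondary spectra,
#' effective (identified) spectra, identified peptides, specific (unique)
#' peptides, identified proteins and quantifiable proteins. The utilization
#' rate is the percentage of acquired spectra that were effective.
#'
#' @param total_spectra,effective_spectra,identified_peptides,
#'   specific_peptides,identified_proteins,quantifiable_proteins Counts.
#' @return `spectra_accounting()`: a validated list of class
#'   `spectra_accounting`.
#' @examples
#' acc <- spectra_accounting(247627, 67318, 38475, 37221, 5874, 5010)
#' spectra_utilization(acc)
#' @export
spectra_accounting <- function(total_spectra, effective_spectra,
                               identified_peptides = NA,
                               specific_peptides = NA,
                               identified_proteins = NA,
                               quantifiable_proteins = NA) {
  stopifnot(is_count(total_spectra), total_spectra > 0,
            is_count(effective_spectra))
  if (effective_spectra > total_spectra)
    stop("effective spectra exceed total spectra", call. = FALSE)
  if (!is.na(specific_peptides) && !is.na(identified_peptides) &&
      specific_peptides > identified_peptides)
    stop("specific peptides exceed identified peptides", call. = FALSE)
  if (!is.na(quantifiable_proteins) && !is.na(identified_proteins) &&
      quantifiable_proteins > identified_proteins)
    stop("quantifiable proteins exceed identified proteins", call. = FALSE)
  structure(list(total_spectra = total_spectra,
                 effective_spectra = effective_spectra,
                 identified_peptides = identified_peptides,
                 specific_peptides = specific_peptides,
                 identified_proteins = identified_proteins,
                 quantifiable_proteins = quantifiable_proteins),
            class = "spectra_accounting")
}

#' @rdname spectra_accounting
#' @param acc A `spectra_accounting` object.
#' @return `spectra_utilization()`: the utilization rate as a percentage
#'   rounded to 1 decimal place.
#' @export
spectra_utilization <- function(acc) {
  stopifnot(inherits(acc, "spectra_accounting"))
  round(100 * acc$effective_spectra / acc$total_spectra, 1)
}
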