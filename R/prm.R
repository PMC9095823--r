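#' Load the packaged 20-protein PRM validation table
#'
#' Ships with the package: the 20 candidate proteins quantified by parallel
#' reaction monitoring, each with its discovery-stage TMT Hom/Wt ratio, the
#' targeted PRM Hom/Wt ratio and the regulation direction (16 Down, 4 Up).
#' The file's checksum is verified on load.
#'
#' @return A `prm_records` data.frame with 20 rows (see [read_prm_table()]).
#' @examples
#' prm <- load_table1_fixture()
#' table(prm$regulated_type)
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_prm.tsv", package = "tmtdep",
                      mustWork = TRUE)
  sum_ <- unname(tools::md5sum(path))
  if (!identical(sum_, "2039ccb95b720da9bdddd4da12f912a0"))
    stop("PRM fixture is corrupted (checksum mismatch)", call. = FALSE)
  read_prm_table(path)
}

#' PRM-vs-TMT concordance
#'
#' Quantifies agreement between targeted (PRM) and discovery (TMT) ratios:
#' how many records have both ratios on the same side of 1 (strict; a ratio
#' of exactly 1 is logged and counted for neither side), the Spearman
#' correlation of the log2 ratios, the regulation call obtained by applying
#' the discovery fold-change bounds to the TMT ratio, and how many records
#' pass those bounds.
#'
#' @param records A `prm_records` data.frame (e.g. [load_table1_fixture()]).
#' @param up,down Discovery fold-change bounds. Defaults 1.30 and 0.77.
#' @return A list of class `concordance_report`: `n_records`,
#'   `n_sign_concordant`, `spearman_log_ratio`, `tmt_call` (per record),
#'   `n_pass_threshold`, `n_type_match` (calls equal to the recorded
#'   `regulated_type`), `ties` (records with a ratio exactly 1).
#' @examples
#' concordance(load_table1_fixture())
#' @export
concordance <- function(records, up = 1.30, down = 0.77) {
  stopifnot(nrow(records) >= 1L)
  ties <- records$protein_id[records$prm_ratio == 1 | records$tmt_ratio == 1]
  if (length(ties))
    message("ratio exactly 1 for: ", paste(ties, collapse = ", "))
  conc <- (records$prm_ratio > 1 & records$tmt_ratio > 1) |
          (records$prm_ratio < 1 & records$tmt_ratio < 1)
  rho <- suppressWarnings(cor(log2(records$prm_ratio),
                              log2(records$tmt_ratio),
                              method = "spearman"))
  call_ <- ifelse(records$tmt_ratio > up, "Up",
                  ifelse(records$tmt_ratio < down, "Down", "NS"))
  structure(list(
    n_records = nrow(records),
    n_sign_concordant = sum(conc),
    spearman_log_ratio = rho,
    tmt_call = setNames(call_, records$protein_id),
    n_pass_threshold = sum(call_ != "NS"),
    n_type_match = sum(call_ == records$regulated_type),
    ties = ties
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("PRM/TMT concordance: %d records\n", x$n_records))
  cat(sprintf("  sign-concordant (both sides of 1): %d/%d\n",
              x$n_sign_concordant, x$n_records))
  cat(sprintf("  Spearman(log2 PRM, log2 TMT): %.3f\n", x$spearman_log_ratio))
  cat(sprintf("  passing discovery FC bounds: %d; call matches type: %d\n",
              x$n_pass_threshold, x$n_type_match))
  invisible(x)
}

#' Two-group summary statistics with a Student t-test
#'
#' Per-group mean and standard error of the mean, a two-sided equal-variance
#' t-test p-value and the conventional significance stars (\code{*} p < 0.05,
#' \code{**} p < 0.01, \code{***} p < 0.001).
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return A list: `mean_a`, `sem_a`, `mean_b`, `sem_b`, `p`, `stars`.
#' @examples
#' group_stats(c(1.0, 1.1, 0.9, 1.0), c(2.1, 1.9, 2.0, 2.2, 2.0))
#' @export
group_stats <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  na_ <- length(a); nb <- length(b)
  sp2 <- ((na_ - 1L) * stats::var(a) + (nb - 1L) * stats::var(b)) /
    (na_ + nb - 2L)
  se <- sqrt(sp2 * (1 / na_ + 1 / nb))
  p <- if (se == 0) {
    if (mean(a) == mean(b)) 1 else 0
  } else {
    2 * pt(abs((mean(a) - mean(b)) / se), na_ + nb - 2L, lower.tail = FALSE)
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(mean_a = mean(a), sem_a = sd(a) / sqrt(na_),
       mean_b = mean(b), sem_b = sd(b) / sqrt(nb),
       p = p, stars = stars)
}
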