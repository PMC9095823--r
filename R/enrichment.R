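#' Fisher exact term over-representation
#'
#' For each term, builds the 2x2 table (k DEPs in the term, n-k DEPs outside,
#' K-k background in the term, N-K-n+k outside) over the annotated universe
#' and computes the one-sided (over-representation) Fisher exact p-value —
#' the hypergeometric upper-tail probability of drawing at least k term
#' members in n draws from a background of N containing K. Within each
#' annotation category, n is the number of foreground proteins carrying any
#' annotation of that category and N the annotated background; BH adjustment
#' is applied per category. Terms are intersected with the background first;
#' empty terms (K = 0) are skipped.
#'
#' @param foreground Character vector of interesting proteins (e.g. DEPs);
#'   must be a subset of `background`.
#' @param background Character vector of all eligible proteins (e.g. all
#'   quantifiable proteins).
#' @param terms List of terms (see [read_annotation_gmt()]).
#' @return A data.frame of class `enrich_result`, sorted by p-value:
#'   `term_id`, `term_name`, `category`, `k`, `n`, `K`, `N`, `p_value`,
#'   `bh_adjusted_p`, `fold_enrichment`, `log2_fold_enrichment`.
#' @examples
#' bg <- sprintf("P%02d", 1:40)
#' terms <- list(list(term_id = "T1", name = "t", category = "BP",
#'                    members = bg[1:10]))
#' fisher_enrich(bg[1:8], bg, terms)
#' @export
fisher_enrich <- function(foreground, background, terms) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background", call. = FALSE)
  empty <- data.frame(term_id = character(), term_name = character(),
                      category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      bh_adjusted_p = numeric(), fold_enrichment = numeric(),
                      log2_fold_enrichment = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("enrich_result", "data.frame")
  if (length(foreground) == 0L) {
    warning("empty foreground: no enrichment computed", call. = FALSE)
    return(empty)
  }
  if (length(terms) == 0L) return(empty)
  cats <- vapply(terms, function(t) t$category %||% "pathway", "")
  rows <- list()
  for (cat_ in unique(cats)) {
    tt <- terms[cats == cat_]
    members <- lapply(tt, function(t) intersect(t$members, background))
    annotated <- unique(unlist(members))
    N <- length(annotated)
    fg <- intersect(foreground, annotated)
    n <- length(fg)
    K <- vapply(members, length, 1L)
    k <- vapply(members, function(m) length(intersect(m, fg)), 1L)
    keep <- K > 0L
    if (!any(keep)) next
    K <- K[keep]; k <- k[keep]; tt <- tt[keep]
    p <- fisher_overrep_p(k, n, K, N)
    fe <- ifelse(n > 0, (k / n) / (K / N), NA_real_)
    rows[[cat_]] <- data.frame(
      term_id = vapply(tt, `[[`, "", "term_id"),
      term_name = vapply(tt, function(t) t$name %||% "", ""),
      category = cat_, k = k, n = n, K = K, N = N, p_value = p,
      bh_adjusted_p = bh_adjust(p),
      fold_enrichment = fe, log2_fold_enrichment = log2(fe),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$p_value, -out$fold_enrichment, out$term_id), ]
  rownames(out) <- NULL
  class(out) <- c("enrich_result", "data.frame")
  out
}

#' @export
print.enrich_result <- function(x, n = 10L, ...) {
  cat(sprintf("enrich_result: %d terms (%d with BH-adjusted p < 0.05)\n",
              nrow(x), sum(x$bh_adjusted_p < 0.05)))
  if (nrow(x))
    print(head(as.data.frame(x)[c("term_id", "category", "k", "K",
                                  "p_value", "bh_adjusted_p",
                                  "fold_enrichment")], n),
          digits = 3, row.names = FALSE)
  invisible(x)
}

#' One-sided over-representation p-value
#'
#' The probability of observing at least `k` term members among `n` draws
#' from a universe of `N` proteins of which `K` belong to the term — the
#' upper tail of the hypergeometric distribution, identical to the one-sided
#' Fisher exact test on the 2x2 table `(k, n-k, K-k, N-K-n+k)`. Vectorized
#' over parallel table vectors.
#'
#' @param k,n,K,N Table margins: overlap, foreground size, term size,
#'   universe size. Must satisfy `k <= min(n, K)` and `max(n, K) <= N`.
#' @return Numeric vector of p-values in (0, 1\].
#' @export
fisher_overrep_p <- function(k, n, K, N) {
  stopifnot(all(k <= pmin(n, K)), all(pmax(n, K) <= N))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: p-values are ranked ascending,
#' scaled by m/rank, made monotone non-decreasing from the largest down and
#' capped at 1; results are returned in the input order.
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Select the top enriched terms
#'
#' First `n` terms by ascending p-value; ties are broken by larger fold
#' enrichment, then lexicographic term ID, so the selection is deterministic.
#'
#' @param results An `enrich_result` data.frame.
#' @param n Number of terms to keep (>= 1).
#' @return The subset, same class.
#' @export
top_terms <- function(results, n = 20L) {
  if (!is_count(n) || n <= 0) stop("n must be a positive count", call. = FALSE)
  ord <- order(results$p_value, -results$fold_enrichment, results$term_id)
  out <- results[ord, ][seq_len(min(n, nrow(results))), ]
  rownames(out) <- NULL
  class(out) <- class(results)
  out
}

#' Q-group enrichment matrix
#'
#' For each fold-change severity bin Q1..Q4 as foreground (against the common
#' background), computes per-term one-sided Fisher p-values, and assembles a
#' terms x 4 matrix of -log10 p (capped at `cap` to keep downstream z-scores
#' finite). Only terms significant (BH-adjusted p < `bh_alpha`) in at least
#' one bin are kept. An empty bin contributes a zero column with a warning.
#'
#' @param fit A `dep_fit` object with Q categories assigned.
#' @param background Character vector of background proteins.
#' @param terms List of terms.
#' @param bh_alpha Significance threshold for keeping a term. Default 0.05.
#' @param cap Ceiling for -log10 p. Default 16.
#' @return Numeric matrix (possibly 0-row) with columns `Q1..Q4` and one row
#'   per retained term.
#' @export
q_group_matrix <- function(fit, background, terms, bh_alpha = 0.05,
                           cap = 16) {
  stopifnot(inherits(fit, "dep_fit"))
  qs <- c("Q1", "Q2", "Q3", "Q4")
  r <- fit$records
  ids <- vapply(terms, `[[`, "", "term_id")
  pmat <- matrix(NA_real_, nrow = length(terms), ncol = 4L,
                 dimnames = list(ids, qs))
  keep_term <- rep(FALSE, length(terms))
  for (j in seq_along(qs)) {
    fg <- r$protein_id[!is.na(r$q_category) & r$q_category == qs[j]]
    fg <- intersect(fg, background)
    if (length(fg) == 0L) {
      warning("empty Q group: ", qs[j], call. = FALSE)
      pmat[, j] <- 1
      next
    }
    res <- fisher_enrich(fg, background, terms)
    pmat[res$term_id, j] <- res$p_value
    keep_term[match(res$term_id[res$bh_adjusted_p < bh_alpha], ids)] <- TRUE
  }
  pmat[is.na(pmat)] <- 1
  out <- -log10(pmat)
  out[out > cap] <- cap
  out[keep_term, , drop = FALSE]
}

#' Hierarchically cluster enrichment-matrix rows
#'
#' Rows are z-scored (a constant row becomes all zeros, with a warning),
#' distances are Euclidean and the linkage is average, mirroring the
#' conventions of heatmap-style enrichment displays. The result is
#' deterministic for a fixed input.
#'
#' @param mat Numeric matrix with >= 2 rows (e.g. from [q_group_matrix()]).
#' @return A list with `order` (row indices in leaf order), `labels`
#'   (rownames in leaf order), `heights` (merge heights) and `hclust`
#'   (the underlying [stats::hclust] object).
#' @export
cluster_rows <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 2L)
    stop("need a matrix with at least 2 rows", call. = FALSE)
  sds <- apply(mat, 1L, sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " constant row(s) z-scored to zeros",
            call. = FALSE)
  z <- (mat - rowMeans(mat)) / ifelse(sds == 0, 1, sds)
  hc <- hclust(dist(z, method = "euclidean"), method = "average")
  list(order = hc$order,
       labels = if (!is.null(rownames(mat))) rownames(mat)[hc$order],
       heights = hc$height, hclust = hc)
}
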