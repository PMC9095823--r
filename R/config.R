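#' Pipeline configuration
#'
#' Bundles the thresholds and options used by [run_pipeline()] and the
#' individual stages. Defaults are the discovery-stage conventions of the
#' analysis: a protein is differentially expressed when its Hom/Wt fold change
#' exceeds 1.30 or falls below 0.77 with a t-test p-value under 0.05, and DEPs
#' are binned into severity categories Q1 (FC <= 0.667), Q2 (0.667 < FC <=
#' 0.769), Q3 (1.3 < FC <= 1.5) and Q4 (FC > 1.5).
#'
#' @param up_threshold Fold-change threshold above which a significant protein
#'   is called Up (strict inequality). Default 1.30.
#' @param down_threshold Fold-change threshold below which a significant
#'   protein is called Down (strict). Default 0.77.
#' @param alpha p-value threshold for DEP calling (strict). Default 0.05.
#' @param q_edges Four strictly increasing fold-change edges defining the
#'   severity bins. Default `c(0.667, 0.769, 1.3, 1.5)`.
#' @param qc_correlation_floor Within-group median pairwise Spearman
#'   correlation below which a replicate channel is flagged. Default 0.8.
#' @param enrichment_top_n Number of top terms reported per annotation
#'   category. Default 20.
#' @param test_method `"student"` (equal-variance, default) or `"welch"`.
#' @param log_transform Logical; run the t-test on log2 of the relative
#'   quantitative values. Default `FALSE`.
#' @param bh_alpha BH-adjusted p threshold used when selecting terms for the
#'   Q-group matrix. Default 0.05.
#' @param seed Integer seed recorded in the run summary and used for any
#'   stochastic stage. Default 1.
#'
#' @return An object of class `pipeline_config` (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$up_threshold
#' @export
pipeline_config <- function(up_threshold = 1.30,
                            down_threshold = 0.77,
                            alpha = 0.05,
                            q_edges = c(0.667, 0.769, 1.3, 1.5),
                            qc_correlation_floor = 0.8,
                            enrichment_top_n = 20L,
                            test_method = c("student", "welch"),
                            log_transform = FALSE,
                            bh_alpha = 0.05,
                            seed = 1L) {
  test_method <- match.arg(test_method)
  stopifnot(
    is.numeric(up_threshold), is.numeric(down_threshold),
    down_threshold < 1, up_threshold > 1,
    is.numeric(alpha), alpha >= 0, alpha < 1,
    length(q_edges) == 4L, !is.unsorted(q_edges, strictly = TRUE),
    qc_correlation_floor >= -1, qc_correlation_floor <= 1,
    is_count(enrichment_top_n), enrichment_top_n >= 1,
    is.logical(log_transform), length(log_transform) == 1L,
    bh_alpha > 0, bh_alpha <= 1
  )
  structure(list(
    up_threshold = up_threshold, down_threshold = down_threshold,
    alpha = alpha, q_edges = q_edges,
    qc_correlation_floor = qc_correlation_floor,
    enrichment_top_n = as.integer(enrichment_top_n),
    test_method = test_method, log_transform = log_transform,
    bh_alpha = bh_alpha, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("TMT pipeline configuration\n")
  cat(sprintf("  DEP thresholds : FC > %.2f or FC < %.2f, p < %g (%s t%s)\n",
              x$up_threshold, x$down_threshold, x$alpha, x$test_method,
              if (x$log_transform) ", log2" else ""))
  cat(sprintf("  Q edges        : %s\n", paste(x$q_edges, collapse = ", ")))
  cat(sprintf("  QC corr floor  : %.2f   BH alpha: %g   top terms: %d   seed: %d\n",
              x$qc_correlation_floor, x$bh_alpha, x$enrichment_top_n, x$seed))
  invisible(x)
}
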