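#' Per-protein Hom/Wt fold change
#'
#' Fold change of each protein is the ratio of the arithmetic means of its
#' relative quantitative values over the two groups (mean over Hom channels /
#' mean over Wt channels, observed values only). Proteins observed in fewer
#' than 2 samples of either group, or with a zero Wt mean, are excluded with
#' a warning.
#'
#' @param quant A `protein_quant` matrix.
#' @param numerator,denominator Group labels forming the ratio. Defaults
#'   `"Hom"` / `"Wt"`.
#' @return Named numeric vector of fold changes (excluded proteins absent).
#' @export
fold_change <- function(quant, numerator = "Hom", denominator = "Wt") {
  stopifnot(inherits(quant, "protein_quant"))
  groups <- attr(quant, "groups")
  num <- unclass(quant)[, groups == numerator, drop = FALSE]
  den <- unclass(quant)[, groups == denominator, drop = FALSE]
  n_num <- rowSums(!is.na(num))
  n_den <- rowSums(!is.na(den))
  ok <- n_num >= 2L & n_den >= 2L
  m_num <- rowMeans(num, na.rm = TRUE)
  m_den <- rowMeans(den, na.rm = TRUE)
  zero <- ok & m_den == 0
  if (any(zero))
    warning(sum(zero), " protein(s) with zero ", denominator,
            " mean excluded", call. = FALSE)
  ok <- ok & !zero
  fc <- m_num[ok] / m_den[ok]
  names(fc) <- rownames(quant)[ok]
  fc
}

#' Per-protein two-sample t-test p-values
#'
#' Two-sided two-sample t-test on each protein's per-channel relative values,
#' equal-variance (Student) by default or Welch, optionally on log2 values.
#' Computed in closed form over all proteins at once. Degenerate proteins
#' (zero variance in both groups) get p = 1 when the group means are equal
#' and p = 0 when they differ; their IDs are returned in the `degenerate`
#' attribute.
#'
#' @param quant A `protein_quant` matrix.
#' @param method `"student"` (default) or `"welch"`.
#' @param log2_transform Logical; test on log2 of the values. Default `FALSE`.
#' @param group_a,group_b Group labels. Defaults `"Wt"`, `"Hom"`.
#' @return Named numeric vector of p-values for proteins with >= 2 observed
#'   values per group, with attribute `degenerate` naming zero-variance
#'   proteins with unequal means.
#' @export
dep_test <- function(quant, method = c("student", "welch"),
                     log2_transform = FALSE,
                     group_a = "Wt", group_b = "Hom") {
  stopifnot(inherits(quant, "protein_quant"))
  method <- match.arg(method)
  groups <- attr(quant, "groups")
  X <- unclass(quant)
  if (log2_transform) X <- log2(X)
  a <- X[, groups == group_a, drop = FALSE]
  b <- X[, groups == group_b, drop = FALSE]
  na_ <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ok <- na_ >= 2L & nb >= 2L
  a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
  na_ <- na_[ok]; nb <- nb[ok]
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / (na_ - 1L)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / (nb - 1L)
  if (method == "student") {
    sp2 <- ((na_ - 1L) * va + (nb - 1L) * vb) / (na_ + nb - 2L)
    se <- sqrt(sp2 * (1 / na_ + 1 / nb))
    df <- na_ + nb - 2L
  } else {
    se <- sqrt(va / na_ + vb / nb)
    df <- (va / na_ + vb / nb)^2 /
      ((va / na_)^2 / (na_ - 1L) + (vb / nb)^2 / (nb - 1L))
  }
  tstat <- (mb - ma) / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se == 0 | !is.finite(se)
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  names(p) <- rownames(quant)[which(ok)]
  attr(p, "degenerate") <- names(p)[degen & ma != mb]
  p
}

#' Classify regulation from fold change and p-value
#'
#' A protein is `Up` when FC > `up` and p < `alpha`, `Down` when FC < `down`
#' and p < `alpha`, otherwise `NS`. All comparisons are strict, so a protein
#' sitting exactly on a threshold is not significant.
#'
#' @param fc Numeric vector of fold changes (> 0).
#' @param p Numeric vector of p-values, recycled against `fc`.
#' @param up,down,alpha Thresholds; defaults 1.30, 0.77, 0.05.
#' @return Character vector in `{"Up", "Down", "NS"}`.
#' @examples
#' classify_dep(c(0.66, 1.98, 1.30), c(0.01, 0.01, 0.001))
#' @export
classify_dep <- function(fc, p, up = 1.30, down = 0.77, alpha = 0.05) {
  stopifnot(all(fc > 0, na.rm = TRUE), all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("NS", length(fc))
  out[fc > up & p < alpha] <- "Up"
  out[fc < down & p < alpha] <- "Down"
  out[is.na(fc) | is.na(p)] <- NA_character_
  out
}

#' Assign fold-change severity categories
#'
#' DEPs are binned by fold change: Q1 (FC <= 0.667, severely down), Q2
#' (0.667 < FC, mildly down), Q3 (1.3 < FC <= 1.5, mildly up), Q4 (FC > 1.5,
#' severely up); non-significant proteins get `"none"`. Down calls with FC in
#' (0.769, 0.77) fall in Q2 so the four bins partition the DEPs even though
#' the nominal Q2 upper edge (0.769) sits just below the Down threshold
#' (0.77).
#'
#' @param fc Numeric vector of fold changes.
#' @param regulation Character vector from [classify_dep()].
#' @param edges Four increasing bin edges. Default `c(0.667, 0.769, 1.3,
#'   1.5)`.
#' @return Character vector in `{"Q1", "Q2", "Q3", "Q4", "none"}`.
#' @export
assign_q <- function(fc, regulation, edges = c(0.667, 0.769, 1.3, 1.5)) {
  stopifnot(length(edges) == 4L, !is.unsorted(edges, strictly = TRUE))
  out <- rep("none", length(fc))
  down <- regulation == "Down"
  up <- regulation == "Up"
  out[down & fc <= edges[1L]] <- "Q1"
  out[down & fc > edges[1L]] <- "Q2"
  out[up & fc <= edges[4L]] <- "Q3"
  out[up & fc > edges[4L]] <- "Q4"
  out[is.na(regulation)] <- NA_character_
  out
}

#' Fit the differential-expression model
#'
#' The package's central estimator: for every quantifiable protein with at
#' least 2 observed relative values per group it computes the Hom/Wt fold
#' change ([fold_change()]), a two-sample t p-value ([dep_test()]), the
#' regulation call ([classify_dep()]) and the severity bin ([assign_q()]).
#'
#' @param quant A `protein_quant` matrix from [protein_quant()].
#' @param config A [pipeline_config()] carrying the thresholds, test method
#'   and transform flag.
#' @return An object of class `dep_fit` with components
#'   \describe{
#'     \item{records}{data.frame: `protein_id`, `fc`, `log2fc`, `p`,
#'       `regulation`, `q_category`}
#'     \item{counts}{named counts of Up / Down / NS and the DEP total}
#'     \item{config}{the configuration used}
#'   }
#'   Methods: `print`, `summary`, `coef` (named log2 fold changes),
#'   `plot` (volcano), `as.data.frame`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 50, seed = 3))
#' fit <- dep_fit(protein_quant(sim$peptides, sim$map))
#' fit
#' head(coef(fit))
#' @export
dep_fit <- function(quant, config = pipeline_config()) {
  stopifnot(inherits(quant, "protein_quant"),
            inherits(config, "pipeline_config"))
  keep <- attr(quant, "quantifiable")
  q2 <- structure(unclass(quant)[keep, , drop = FALSE],
                  groups = attr(quant, "groups"),
                  n_unique_peptides = attr(quant, "n_unique_peptides")[keep],
                  quantifiable = rep(TRUE, sum(keep)),
                  class = c("protein_quant", "matrix", "array"))
  fc <- fold_change(q2)
  p <- dep_test(q2, method = config$test_method,
                log2_transform = config$log_transform)
  ids <- intersect(names(fc), names(p))
  fc <- fc[ids]; pv <- p[ids]
  reg <- classify_dep(fc, pv, up = config$up_threshold,
                      down = config$down_threshold, alpha = config$alpha)
  qcat <- assign_q(fc, reg, edges = config$q_edges)
  records <- data.frame(protein_id = ids, fc = fc, log2fc = log2(fc),
                        p = pv, regulation = reg, q_category = qcat,
                        stringsAsFactors = FALSE, row.names = NULL)
  counts <- c(Up = sum(reg == "Up"), Down = sum(reg == "Down"),
              NS = sum(reg == "NS"))
  counts <- c(counts, total_dep = unname(counts["Up"] + counts["Down"]))
  structure(list(records = records, counts = counts, config = config,
                 degenerate = attr(p, "degenerate"),
                 n_tested = length(ids)),
            class = "dep_fit")
}

#' @export
print.dep_fit <- function(x, ...) {
  cat(sprintf("dep_fit: %d proteins tested, %d DEPs (%d up, %d down)\n",
              x$n_tested, x$counts["total_dep"], x$counts["Up"],
              x$counts["Down"]))
  cat(sprintf("  thresholds: FC > %.2f or < %.2f, p < %g (%s t-test%s)\n",
              x$config$up_threshold, x$config$down_threshold,
              x$config$alpha, x$config$test_method,
              if (x$config$log_transform) ", log2 values" else ""))
  invisible(x)
}

#' @export
summary.dep_fit <- function(object, ...) {
  qtab <- table(factor(object$records$q_category,
                       levels = c("Q1", "Q2", "Q3", "Q4", "none")))
  out <- list(counts = object$counts, q_table = qtab,
              config = object$config,
              top = head(object$records[order(object$records$p), ], 10L))
  class(out) <- "summary.dep_fit"
  out
}

#' @export
print.summary.dep_fit <- function(x, ...) {
  cat(sprintf("DEPs: %d (up %d / down %d), NS %d\n", x$counts["total_dep"],
              x$counts["Up"], x$counts["Down"], x$counts["NS"]))
  cat("Severity bins: ",
      paste(sprintf("%s=%d", names(x$q_table), x$q_table), collapse = "  "),
      "\n")
  cat("Top proteins by p-value:\n")
  print(x$top, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
coef.dep_fit <- function(object, ...) {
  setNames(object$records$log2fc, object$records$protein_id)
}

#' @export
as.data.frame.dep_fit <- function(x, ...) x$records

#' Volcano-plot table
#'
#' Plot-ready table of log2 fold change vs -log10 p with the regulation call
#' per protein. p-values of 0 (degenerate zero-variance proteins) are capped
#' at `-log10 p = cap`.
#'
#' @param fit A `dep_fit` object.
#' @param cap Ceiling for `-log10(p)`. Default 300 (around the smallest
#'   representable double).
#' @return Data.frame with columns `protein_id`, `log2fc`, `neg_log10_p`,
#'   `regulation` and attribute `counts`.
#' @export
volcano_table <- function(fit, cap = 300) {
  stopifnot(inherits(fit, "dep_fit"))
  r <- fit$records
  nlp <- -log10(r$p)
  nlp[!is.finite(nlp) | nlp > cap] <- cap
  out <- data.frame(protein_id = r$protein_id, log2fc = r$log2fc,
                    neg_log10_p = nlp, regulation = r$regulation,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- fit$counts
  out
}

#' @export
#' @rdname dep_fit
#' @param x,... For `plot.dep_fit`: the fit and further arguments passed to
#'   [graphics::plot()].
plot.dep_fit <- function(x, ...) {
  v <- volcano_table(x)
  col <- c(Up = "firebrick", Down = "steelblue", NS = "grey60")[v$regulation]
  plot(v$log2fc, v$neg_log10_p, pch = 16, cex = 0.6, col = col,
       xlab = expression(log[2] ~ "fold change (Hom/Wt)"),
       ylab = expression(-log[10] ~ "p"), ...)
  abline(v = log2(c(x$config$down_threshold, x$config$up_threshold)),
         lty = 2, col = "grey40")
  abline(h = -log10(x$config$alpha), lty = 2, col = "grey40")
  legend("topright", legend = c("Up", "Down", "NS"), pch = 16,
         col = c("firebrick", "steelblue", "grey60"), bty = "n")
  invisible(v)
}
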