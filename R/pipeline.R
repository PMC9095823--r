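#' Run the full TMT differential-expression pipeline
#'
#' Chains every stage — ingest, QC + quantification, differential calling,
#' per-category enrichment, the Q-group enrichment matrix with clustering,
#' and (optionally) PRM concordance — and writes one artifact per stage plus
#' a JSON run summary. The run is a pure function of the inputs and the
#' configuration: repeated runs produce identical outputs.
#'
#' Artifacts written to `out_dir`:
#' \describe{
#'   \item{protein_quant.tsv}{protein x sample relative values (4 decimals),
#'     with a `#group:` line and a unique-peptide count column}
#'   \item{dep_table.tsv}{per-protein fc, log2fc, p, regulation, q_category}
#'   \item{enrichment_<category>.tsv}{one per annotation category}
#'   \item{q_group_matrix.tsv}{-log10 p per term x Q bin, rows in clustered
#'     leaf order (when >= 2 terms survive)}
#'   \item{prm_report.json}{concordance report (when `prm` is given)}
#'   \item{run_summary.json}{counts, thresholds, seed, QC exclusions}
#' }
#'
#' @param config A [pipeline_config()].
#' @param peptides Path to a peptide intensity TSV or a [peptide_matrix()].
#' @param map Path to a mapping TSV or a data.frame.
#' @param gmt Path(s) to GMT file(s) or a list of term lists; file names (or
#'   list names) give the category labels. Optional.
#' @param prm Path to a PRM table or a `prm_records` data.frame. Optional.
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress progress messages. Default `FALSE`.
#' @return Invisibly, a list with the in-memory stage results (`quant`,
#'   `fit`, `enrichment`, `q_matrix`, `prm_report`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), peptides, map,
                         gmt = NULL, prm = NULL, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[tmtdep] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_stage(stage, conditionMessage(e)))
  }

  say("reading inputs")
  pep <- run_stage("read", if (inherits(peptides, "peptide_matrix")) peptides
                   else read_peptide_table(peptides))
  pmap <- run_stage("read", if (is.data.frame(map)) map
                    else read_protein_map(map))

  say("quantifying (", nrow(pep), " peptides, ", ncol(pep), " samples)")
  quant <- run_stage("quantify",
                     protein_quant(pep, pmap,
                                   qc_floor = config$qc_correlation_floor))
  excluded <- attr(quant, "excluded_samples")
  if (length(excluded)) say("QC excluded sample(s): ",
                            paste(excluded, collapse = ", "))
  write_protein_quant(quant, file.path(out_dir, "protein_quant.tsv"))

  say("differential expression")
  fit <- run_stage("differential", dep_fit(quant, config))
  dep_path <- file.path(out_dir, "dep_table.tsv")
  r <- fit$records
  dep_out <- data.frame(protein_id = r$protein_id,
                        fc = fmt_ratio(r$fc), log2fc = fmt_ratio(r$log2fc),
                        p = sprintf("%.6g", r$p),
                        regulation = r$regulation,
                        q_category = r$q_category,
                        stringsAsFactors = FALSE)
  write.table(dep_out, dep_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  enr <- list(); qmat <- NULL; leaf <- NULL
  if (!is.null(gmt)) {
    terms <- run_stage("enrich", {
      if (is.character(gmt)) {
        cats <- if (!is.null(names(gmt))) names(gmt) else
          sub("\\.gmt$", "", basename(gmt))
        unlist(lapply(seq_along(gmt), function(i)
          read_annotation_gmt(gmt[[i]], category = cats[[i]])),
          recursive = FALSE)
      } else gmt
    })
    bg_ids <- r$protein_id
    deps <- r$protein_id[r$regulation != "NS"]
    say("enrichment (", length(deps), " DEPs vs ", length(bg_ids),
        " background)")
    res <- run_stage("enrich", fisher_enrich(deps, bg_ids, terms))
    for (cat_ in unique(res$category)) {
      sub <- res[res$category == cat_, ]
      enr[[cat_]] <- sub
      out <- sub
      out$fold_enrichment <- fmt_ratio(out$fold_enrichment)
      out$log2_fold_enrichment <- fmt_ratio(out$log2_fold_enrichment)
      out$p_value <- sprintf("%.6g", out$p_value)
      out$bh_adjusted_p <- sprintf("%.6g", out$bh_adjusted_p)
      write.table(out, file.path(out_dir,
                                 paste0("enrichment_", cat_, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    qmat <- run_stage("q_matrix",
                      suppressWarnings(
                        q_group_matrix(fit, bg_ids, terms,
                                       bh_alpha = config$bh_alpha)))
    if (nrow(qmat) >= 2L) {
      leaf <- cluster_rows(qmat)
      qmat_out <- qmat[leaf$order, , drop = FALSE]
    } else qmat_out <- qmat
    qdf <- data.frame(term_id = rownames(qmat_out),
                      apply(qmat_out, 2L, fmt_ratio),
                      stringsAsFactors = FALSE, check.names = FALSE)
    write.table(qdf, file.path(out_dir, "q_group_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  prm_report <- NULL
  if (!is.null(prm)) {
    say("PRM concordance")
    recs <- run_stage("prm", if (is.data.frame(prm)) prm
                      else read_prm_table(prm))
    prm_report <- run_stage("prm",
                            concordance(recs, up = config$up_threshold,
                                        down = config$down_threshold))
    jsonlite::write_json(
      prm_report[c("n_records", "n_sign_concordant", "spearman_log_ratio",
                   "n_pass_threshold", "n_type_match")],
      file.path(out_dir, "prm_report.json"), auto_unbox = TRUE, digits = NA)
  }

  summary_ <- list(
    seed = config$seed,
    thresholds = list(up = config$up_threshold, down = config$down_threshold,
                      alpha = config$alpha, q_edges = config$q_edges),
    n_peptides = nrow(pep), n_samples_input = ncol(pep),
    excluded_samples = as.list(excluded),
    n_proteins = nrow(quant),
    n_quantifiable = sum(attr(quant, "quantifiable")),
    n_tested = fit$n_tested,
    n_up = unname(fit$counts["Up"]), n_down = unname(fit$counts["Down"]),
    n_dep = unname(fit$counts["Up"] + fit$counts["Down"]),
    n_terms_significant = if (length(enr))
      sum(do.call(rbind, enr)$bh_adjusted_p < config$bh_alpha) else 0L
  )
  jsonlite::write_json(summary_, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", out_dir)
  invisible(list(quant = quant, fit = fit, enrichment = enr, q_matrix = qmat,
                 leaf_order = leaf, prm_report = prm_report,
                 summary = summary_))
}

#' Write / read a protein relative-quantification table
#'
#' TSV with a header (`protein_id`, `n_unique_peptides`, sample IDs), a
#' `#group:` line and one row per protein; relative values are written with
#' 4 decimal places, missing values as empty cells.
#'
#' @param quant A `protein_quant` matrix.
#' @param path Output path.
#' @return `path` (write) or a `protein_quant` matrix (read).
#' @export
write_protein_quant <- function(quant, path) {
  stopifnot(inherits(quant, "protein_quant"))
  nup <- attr(quant, "n_unique_peptides")
  fmt <- function(v) ifelse(is.na(v), "", fmt_ratio(v))
  lines <- c(
    paste(c("protein_id", "n_unique_peptides", colnames(quant)),
          collapse = "\t"),
    paste(c("#group:", "", attr(quant, "groups")), collapse = "\t"),
    vapply(seq_len(nrow(quant)), function(r)
      paste(c(rownames(quant)[r], nup[r], fmt(quant[r, ])), collapse = "\t"),
      "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_protein_quant
#' @export
read_protein_quant <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-(1:2)]
  stopifnot(startsWith(lines[[2L]], "#group:"))
  groups <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]][-(1:2)]
  body <- lines[-(1:2)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  nup <- as.integer(vapply(fields, `[[`, "", 2L))
  vals <- t(vapply(fields, function(f) {
    length(f) <- length(sample_ids) + 2L
    x <- f[-(1:2)]
    suppressWarnings(as.numeric(ifelse(is.na(x) | !nzchar(x), NA, x)))
  }, numeric(length(sample_ids))))
  dimnames(vals) <- list(ids, sample_ids)
  groups <- setNames(groups, sample_ids)
  obs <- !is.na(vals)
  quantifiable <- apply(obs, 1L, function(row)
    all(tapply(row, groups, sum) >= 2L))
  structure(vals, groups = groups,
            n_unique_peptides = setNames(nup, ids),
            quantifiable = quantifiable,
            class = c("protein_quant", "matrix", "array"))
}
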