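# small in-code fixtures

# bare numeric matrix: strip class and bookkeeping attributes
as_plain <- function(m) {
  m <- unclass(m)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

tiny_peptide_matrix <- function() {
  m <- matrix(c(100, 110, 90, 105, 200, 210, 190, 205, 195,
                55, 60, 50, 52, 30, 28, 31, 29, 30,
                1000, 900, 1100, 950, 1000, 1050, 980, 1020, 990),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("PEP1", "PEP2", "PEP3"),
                              c(paste0("Wt", 1:4), paste0("Hom", 1:5))))
  peptide_matrix(m, groups = c(rep("Wt", 4), rep("Hom", 5)))
}

tiny_peptide_tsv <- function(path = tempfile(fileext = ".tsv")) {
  write_peptide_table(tiny_peptide_matrix(), path)
  path
}

# protein_quant with given per-group R rows (list of per-sample value vectors)
manual_quant <- function(rows, n_wt = 4, n_hom = 5) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- c(paste0("Wt", seq_len(n_wt)), paste0("Hom", seq_len(n_hom)))
  groups <- setNames(c(rep("Wt", n_wt), rep("Hom", n_hom)), colnames(m))
  structure(m, groups = groups,
            n_unique_peptides = setNames(rep(1L, nrow(m)), rownames(m)),
            quantifiable = setNames(rep(TRUE, nrow(m)), rownames(m)),
            class = c("protein_quant", "matrix", "array"))
}

# a dep_fit-shaped object from explicit records (for enrichment-stage tests)
manual_fit <- function(records, config = pipeline_config()) {
  structure(list(records = records,
                 counts = c(Up = sum(records$regulation == "Up"),
                            Down = sum(records$regulation == "Down"),
                            NS = sum(records$regulation == "NS"),
                            total_dep = sum(records$regulation != "NS")),
                 config = config, n_tested = nrow(records)),
            class = "dep_fit")
}
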