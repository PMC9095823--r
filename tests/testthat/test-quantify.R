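test_that("centralize divides each peptide by its observed across-sample mean", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5,
                4, NA, 8),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("S1", "S2", "S3")))
  # need >= 2 samples per group: use 2 groups over 3 samples? groups need >=2 each
  m <- cbind(m, S4 = c(4, 5, NA))
  pm <- peptide_matrix(m, groups = c("Wt", "Wt", "Hom", "Hom"))
  u <- centralize(pm)
  expect_equal(unname(u["A", ]), c(1, 2, 3, 4) / 2.5)
  expect_equal(unname(u["B", ]), rep(1, 4))
  expect_equal(unname(u["C", ]), c(4, NA, 8, NA) / 6)
})

test_that("fully missing peptides are dropped with a warning", {
  m <- unclass(tiny_peptide_matrix())
  m["PEP2", ] <- NA
  pm <- peptide_matrix(m, groups = c(rep("Wt", 4), rep("Hom", 5)))
  expect_warning(u <- centralize(pm), "dropped")
  expect_equal(nrow(u), 2L)
  expect_equal(attr(u, "dropped_peptides"), 1L)
})

test_that("median_correct forces every sample's observed median to 1", {
  u <- centralize(tiny_peptide_matrix())
  nr <- median_correct(u)
  med <- apply(unclass(nr), 2, median, na.rm = TRUE)
  expect_equal(unname(med), rep(1, 9), tolerance = 1e-12)
  # forced example: a column (2, 4, 6) has median 4
  m <- matrix(c(2, 2, 2, 2,
                4, 4, 4, 4,
                6, 6, 6, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("S1", "S2", "S3", "S4")))
  pm <- peptide_matrix(m, groups = c("Wt", "Wt", "Hom", "Hom"))
  nr2 <- median_correct(structure(unclass(pm),
                                  groups = attr(pm, "groups"),
                                  class = class(pm)))
  expect_equal(unname(nr2[, 1]), c(0.5, 1, 1.5))
})

test_that("normalization invariants hold on simulated matrices", {
  for (s in 1:10) {
    sim <- simulate_dataset(sim_config(n_proteins = 30, seed = 100 + s))
    u <- suppressWarnings(centralize(sim$peptides))
    full <- rowSums(is.na(u)) == 0
    expect_lt(max(abs(rowMeans(u[full, , drop = FALSE]) - 1)), 1e-12)
    nr <- median_correct(u)
    med <- apply(unclass(nr), 2, median, na.rm = TRUE)
    expect_lt(max(abs(med - 1)), 1e-12)
  }
})

test_that("the pipeline is invariant to global rescaling of intensities", {
  sim <- simulate_dataset(sim_config(n_proteins = 25, seed = 6))
  q1 <- protein_quant(sim$peptides, sim$map, qc = FALSE)
  scaled <- peptide_matrix(unclass(sim$peptides) * 3.7,
                           groups = sample_groups(sim$peptides))
  q2 <- protein_quant(scaled, sim$map, qc = FALSE)
  expect_equal(unclass(q1), unclass(q2), tolerance = 1e-12)
})

test_that("rank-one input collapses to all-unit relative values", {
  a <- 10 ^ runif(9, -1, 1)                   # per-sample loading
  b <- 10 ^ runif(40, 4, 7)                   # per-peptide signal
  m <- outer(b, a)
  dimnames(m) <- list(sprintf("P%02d", 1:40),
                      c(paste0("Wt", 1:4), paste0("Hom", 1:5)))
  pm <- peptide_matrix(m, groups = c(rep("Wt", 4), rep("Hom", 5)))
  map <- data.frame(peptide_id = rownames(m),
                    protein_id = rep(sprintf("PR%02d", 1:10), each = 4))
  q <- protein_quant(pm, map, qc = FALSE)
  expect_lt(max(abs(unclass(q) - 1)), 1e-12)
})

test_that("rollup takes medians over unique peptides only", {
  m <- matrix(rep(c(0.8, 1.0, 1.4, 0.8, 1.2, 99), each = 4),
              nrow = 6, byrow = TRUE,
              dimnames = list(sprintf("PEP%d", 1:6),
                              c("Wt1", "Wt2", "Hom1", "Hom2")))
  pm <- structure(m, groups = setNames(c("Wt", "Wt", "Hom", "Hom"),
                                       colnames(m)),
                  class = c("peptide_matrix", "matrix", "array"))
  map <- data.frame(
    peptide_id = c("PEP1", "PEP2", "PEP3", "PEP4", "PEP5", "PEP6", "PEP6"),
    protein_id = c("A", "A", "A", "B", "B", "A", "B"))
  q <- rollup_protein(pm, map)
  expect_equal(unname(q["A", ]), rep(1.0, 4))   # odd count: exact median
  expect_equal(unname(q["B", ]), rep(1.0, 4))   # even count: midpoint
  # shared PEP6 (two owners) contributed to neither protein
  map2 <- map[map$peptide_id != "PEP6", ]
  q2 <- rollup_protein(structure(m[1:5, ], groups = attr(pm, "groups"),
                                 class = class(pm)), map2)
  expect_equal(unclass(q)[c("A", "B"), ], unclass(q2)[c("A", "B"), ])
  # a protein carrying only shared peptides is absent
  map3 <- rbind(map, data.frame(peptide_id = "PEP6", protein_id = "C"))
  q3 <- rollup_protein(pm, map3)
  expect_false("C" %in% rownames(q3))
  # unmapped peptide is a hard error
  expect_error(rollup_protein(pm, map[map$peptide_id != "PEP1", ]),
               "absent from map")
})

test_that("rollup ignores shared peptides entirely", {
  sim <- simulate_dataset(sim_config(n_proteins = 30,
                                     frac_shared_peptides = 0, seed = 14))
  nr <- median_correct(centralize(sim$peptides))
  q1 <- rollup_protein(nr, sim$map)
  # append many new two-owner peptides to the corrected matrix and map:
  # no R value may move
  set.seed(15)
  extra_vals <- matrix(rlnorm(20 * ncol(nr)), nrow = 20,
                       dimnames = list(sprintf("SHARED%02d", 1:20),
                                       colnames(nr)))
  nr_ext <- structure(rbind(unclass(nr), extra_vals),
                      groups = attr(nr, "groups"), class = class(nr))
  map_ext <- rbind(sim$map,
                   data.frame(peptide_id = rep(rownames(extra_vals), 2),
                              protein_id = rep(c("PROT0001", "PROT0002"),
                                               each = 20)))
  q2 <- rollup_protein(nr_ext, map_ext)
  expect_equal(as_plain(q1), as_plain(q2)[rownames(q1), ])
})

test_that("implementation matches the brute-force three-formula oracle", {
  set.seed(99)
  for (trial in 1:20) {
    nr_ <- sample(2:6, 1); nc_ <- sample(4:6, 1)
    m <- matrix(rlnorm(nr_ * nc_, 10, 1), nr_, nc_,
                dimnames = list(sprintf("PEP%d", seq_len(nr_)),
                                sprintf("S%d", seq_len(nc_))))
    m[runif(length(m)) < 0.15] <- NA
    m[rowSums(!is.na(m)) == 0, 1] <- 1     # keep every peptide observed once
    groups <- rep(c("Wt", "Hom"), length.out = nc_)
    groups[1:2] <- "Wt"; groups[3:4] <- "Hom"
    pm <- peptide_matrix(m, groups)
    owners <- sample(c(1, 1, 1, 2), nr_, replace = TRUE)
    map <- data.frame(peptide_id = rownames(m),
                      protein_id = sprintf("PR%d", owners))
    shared <- sample(nr_, 1)
    map <- rbind(map, data.frame(peptide_id = rownames(m)[shared],
                                 protein_id = "PR9"))
    impl <- rollup_protein(median_correct(centralize(pm)), map)
    oracle <- quant_oracle(unclass(pm), map)
    expect_equal(as_plain(impl)[rownames(oracle), , drop = FALSE], oracle,
                 tolerance = 1e-12)
  }
})

test_that("replicate QC flags a fully decorrelated channel and only it", {
  sim <- simulate_dataset(sim_config(n_proteins = 100, seed = 7))
  raw <- rollup_protein(sim$peptides, sim$map)
  clean <- replicate_qc(raw, floor = 0.8)
  expect_length(clean$flagged, 0L)
  expect_true(all(clean$median_correlation > 0.9))

  deg <- degrade_sample(sim$peptides, "Wt3", 1, seed = 2)
  flagged <- replicate_qc(rollup_protein(deg, sim$map), floor = 0.8)$flagged
  expect_identical(flagged, "Wt3")

  # floor = -1 never flags
  expect_length(replicate_qc(rollup_protein(deg, sim$map), floor = -1)$flagged,
                0L)
  # downstream exclusion via protein_quant
  q <- protein_quant(deg, sim$map)
  expect_identical(attr(q, "excluded_samples"), "Wt3")
  expect_false("Wt3" %in% colnames(q))
})

test_that("QC skips groups too small to isolate an outlier", {
  sim <- simulate_dataset(sim_config(n_proteins = 30, n_wt = 2, seed = 4))
  raw <- rollup_protein(sim$peptides, sim$map)
  expect_warning(res <- replicate_qc(raw), "fewer than 3")
  expect_false(any(startsWith(res$flagged, "Wt")))
})

test_that("spectra accounting reproduces the utilization arithmetic", {
  acc <- spectra_accounting(247627, 67318, 38475, 37221, 5874, 5010)
  expect_identical(spectra_utilization(acc), 27.2)
  expect_identical(spectra_utilization(spectra_accounting(1000, 1000)), 100.0)
  expect_identical(spectra_utilization(spectra_accounting(1000, 0)), 0.0)
  expect_error(spectra_accounting(100, 101), "exceed")
  expect_error(spectra_accounting(100, 50, identified_peptides = 10,
                                  specific_peptides = 11), "exceed")
})
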