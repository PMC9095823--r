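test_that("fisher_enrich builds the 2x2 table and matches tail enumeration", {
  bg <- sprintf("P%03d", 1:100)
  fg <- bg[1:10]
  terms <- list(
    list(term_id = "T1", name = "t1", category = "BP",
         members = c(bg[1:5], bg[96:100])),   # 5 of fg, 10 of bg
    list(term_id = "CATCHALL", name = "t2", category = "BP",
         members = bg))                       # annotates the whole universe
  res <- fisher_enrich(fg, bg, terms)
  t1 <- res[res$term_id == "T1", ]
  expect_equal(t1$k, 5L)
  expect_equal(t1$n, 10L)
  expect_equal(t1$K, 10L)
  expect_equal(t1$N, 100L)
  expect_equal(t1$p_value, hyper_tail_oracle(5L, 10L, 10L, 100L),
               tolerance = 1e-12)
  expect_equal(t1$fold_enrichment, (5 / 10) / (10 / 100))
  # independent cross-check against the R Fisher test
  ref <- fisher.test(matrix(c(5, 5, 5, 85), 2), alternative = "greater")
  expect_equal(t1$p_value, ref$p.value, tolerance = 1e-9)
  # the catch-all term is never enriched
  expect_equal(res$p_value[res$term_id == "CATCHALL"], 1)
})

test_that("degenerate universes give p = 1", {
  bg <- sprintf("P%02d", 1:12)
  terms <- list(list(term_id = "ALL", name = "a", category = "BP",
                     members = bg))
  res <- fisher_enrich(bg, bg, terms)   # k = n = K = N
  expect_equal(res$p_value, 1)
  expect_equal(res$fold_enrichment, 1)
  # full background against itself: p = 1 for every term
  terms2 <- lapply(1:4, function(i)
    list(term_id = paste0("T", i), name = "t", category = "BP",
         members = sample(bg, 6)))
  res2 <- fisher_enrich(bg, bg, terms2)
  expect_true(all(res2$p_value == 1))
})

test_that("enrichment p is monotone non-increasing in the overlap k", {
  impl <- fisher_overrep_p(0:8, 8L, 20L, 60L)
  oracle <- hyper_tail_oracle(0:8, rep(8L, 9), rep(20L, 9), rep(60L, 9))
  expect_equal(impl, oracle, tolerance = 1e-12)
  expect_true(all(diff(impl) <= 1e-15))
})

test_that("empty foreground warns and K = 0 terms are skipped", {
  bg <- sprintf("P%02d", 1:10)
  terms <- list(list(term_id = "T1", name = "t", category = "BP",
                     members = bg[1:3]),
                list(term_id = "T2", name = "t", category = "BP",
                     members = "NOT_IN_BG"))
  expect_warning(res0 <- fisher_enrich(character(), bg, terms), "empty")
  expect_equal(nrow(res0), 0L)
  res <- fisher_enrich(bg[1:2], bg, terms)
  expect_identical(res$term_id, "T1")
  expect_error(fisher_enrich(c(bg[1], "STRANGER"), bg, terms), "subset")
})

test_that("BH adjustment matches the hand step-up oracle and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bh_adjust(numeric()), numeric())
  set.seed(11)
  for (trial in 1:10) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # order invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-14)
  }
})

test_that("BH is applied within each annotation category separately", {
  bg <- sprintf("P%02d", 1:40)
  fg <- bg[1:8]
  mk <- function(id, cat, members) list(term_id = id, name = id,
                                        category = cat, members = members)
  terms <- list(mk("B1", "BP", bg[1:10]), mk("B2", "BP", bg[11:20]),
                mk("C1", "CC", bg[1:10]))
  res <- fisher_enrich(fg, bg, terms)
  for (cat_ in c("BP", "CC")) {
    sub <- res[res$category == cat_, ]
    expect_equal(sub$bh_adjusted_p, bh_oracle(sub$p_value),
                 tolerance = 1e-14)
  }
  # n and N are computed per category universe
  expect_true(all(res$N[res$category == "CC"] == 10L))
})

test_that("top_terms selects deterministically with the stated tie-breaks", {
  res <- data.frame(term_id = c("B", "A", "C", "D"),
                    p_value = c(0.01, 0.01, 0.001, 0.5),
                    fold_enrichment = c(2, 2, 5, 1))
  top <- top_terms(res, 2)
  expect_identical(top$term_id, c("C", "A"))   # tie at p=0.01 -> lexicographic
  expect_identical(top_terms(res, 10)$term_id, c("C", "A", "B", "D"))
  expect_error(top_terms(res, 0), "positive")
  res2 <- data.frame(term_id = c("A", "B"), p_value = c(0.5, 0.5),
                     fold_enrichment = c(1, 3))
  expect_identical(top_terms(res2, 1)$term_id, "B")  # larger FE wins the tie
})

test_that("q_group_matrix localizes a planted severely-down term to Q1", {
  prot <- sprintf("P%03d", 1:120)
  records <- data.frame(
    protein_id = prot,
    fc = 1, log2fc = 0, p = 0.5,
    regulation = "NS", q_category = "none", stringsAsFactors = FALSE)
  q1 <- 1:15; q2 <- 16:25; q3 <- 26:35; q4 <- 36:45
  records$regulation[c(q1, q2)] <- "Down"
  records$regulation[c(q3, q4)] <- "Up"
  records$q_category[q1] <- "Q1"; records$q_category[q2] <- "Q2"
  records$q_category[q3] <- "Q3"; records$q_category[q4] <- "Q4"
  terms <- list(
    list(term_id = "DOWN_TERM", name = "t", category = "pathway",
         members = prot[c(q1, 110:119)]),
    list(term_id = "FLAT", name = "t", category = "pathway",
         members = prot[50:109]))
  fit <- manual_fit(records)
  m <- q_group_matrix(fit, prot, terms)
  expect_true("DOWN_TERM" %in% rownames(m))
  expect_equal(colnames(m), c("Q1", "Q2", "Q3", "Q4"))
  expect_identical(which.max(m["DOWN_TERM", ]), c(Q1 = 1L))
  expect_true(all(m >= 0))
})

test_that("q_group_matrix handles empty bins and no DEPs", {
  prot <- sprintf("P%02d", 1:30)
  records <- data.frame(protein_id = prot, fc = 1, log2fc = 0, p = 0.5,
                        regulation = "NS", q_category = "none",
                        stringsAsFactors = FALSE)
  terms <- list(list(term_id = "T", name = "t", category = "pathway",
                     members = prot[1:10]))
  warns <- capture_warnings(m <- q_group_matrix(manual_fit(records), prot,
                                                terms))
  expect_true(all(grepl("empty Q group", warns)))
  expect_length(warns, 4L)
  expect_equal(nrow(m), 0L)
})

test_that("identical Q-group memberships give identical columns", {
  prot <- sprintf("P%02d", 1:40)
  base <- data.frame(protein_id = prot[1:8], fc = 0.5, log2fc = -1,
                     p = 0.001, regulation = "Down",
                     stringsAsFactors = FALSE)
  records <- do.call(rbind, lapply(c("Q1", "Q2", "Q3", "Q4"), function(qq)
    transform(base, q_category = qq)))
  terms <- list(list(term_id = "T", name = "t", category = "pathway",
                     members = prot[1:10]))
  m <- q_group_matrix(manual_fit(records), prot, terms)
  expect_equal(m[, "Q1"], m[, "Q2"])
  expect_equal(m[, "Q1"], m[, "Q3"])
  expect_equal(m[, "Q1"], m[, "Q4"])
})

test_that("row clustering is deterministic and groups duplicates", {
  m <- rbind(A = c(5, 1, 1, 1), B = c(1, 5, 1, 1),
             A2 = c(5, 1, 1, 1), C = c(1, 1, 5, 5))
  res <- cluster_rows(m)
  # identical rows merge first at height 0 and sit adjacently
  expect_equal(res$heights[1], 0)
  pos <- match(c("A", "A2"), res$labels)
  expect_equal(abs(diff(pos)), 1L)
  expect_identical(res$labels, cluster_rows(m)$labels)
  expect_error(cluster_rows(m[1, , drop = FALSE]), "at least 2 rows")
  expect_warning(cluster_rows(rbind(m, D = c(2, 2, 2, 2))), "constant")
})
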