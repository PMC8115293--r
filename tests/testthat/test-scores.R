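# Expression-level scoring: qPCR relative expression, signature scores,
# median splits, histology binarisation, and survival comparison.

test_that("relative expression follows 2^-dCt against the housekeeper mean", {
  expect_equal(relative_expression(23, c(23, 23)), 1)
  expect_equal(relative_expression(20, c(22, 24)), 8)
  re <- relative_expression(21, c(22, 24))
  expect_equal(relative_expression(22, c(22, 24)), re / 2)
  expect_error(relative_expression(20, numeric(0)), "housekeeper")
})

test_that("fold change is a quotient with anti-symmetry", {
  expect_equal(fold_change(2, 2), 1)
  expect_equal(fold_change(4, 2), 2)
  expect_equal(fold_change(3, 7), 1 / fold_change(7, 3))
  expect_error(fold_change(1, 0), "positive")
})

test_that("maf_score equals the exp-mean-log oracle and is scale-consistent", {
  m <- matrix(c(1, 2, 4), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
  expect_equal(unname(maf_score(m, c("A", "B", "C"))), 2)
  mv <- matrix(3.7, 4, 2, dimnames = list(letters[1:4], c("s1", "s2")))
  expect_equal(unname(maf_score(mv, letters[1:4])), c(3.7, 3.7))

  set.seed(8)
  for (i in 1:10) {
    v <- matrix(runif(60, 0.5, 8), 6, 10,
                dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:10)))
    got <- maf_score(v, sprintf("g%d", 1:6))
    oracle <- exp(colMeans(log(v)))
    expect_lt(max(abs(got - oracle)), 1e-9)
    # multiplying one sample's signature values by c scales its score by c
    v2 <- v; v2[, 3] <- v2[, 3] * 2.5
    expect_equal(unname(maf_score(v2, sprintf("g%d", 1:6))[3]),
                 unname(2.5 * got[3]))
  }

  expect_warning(maf_score(mv, c("a", "b", "NOTHERE")), "absent")
  expect_error(maf_score(mv, c("X", "Y")), "no signature gene")
  mz <- mv; mz["a", 1] <- 0
  expect_warning(maf_score(mz, letters[1:4]), "floored")
})

test_that("median split uses the <=-median-low tie rule and is monotone-invariant", {
  expect_equal(unname(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_true(all(median_split(rep(5, 6)) == "low"))
  expect_equal(unname(median_split(3)), "low")
  s <- c(a = 0.2, b = 1.5, c = 0.9, d = 4, e = 2.2)
  expect_identical(median_split(s), median_split(log(s)))
  expect_identical(median_split(s), median_split(rank(s)))
})

test_that("collagen genes are stripped by pattern", {
  r <- strip_collagen_genes(c("COL1A1", "ACTA2"))
  expect_equal(r$kept, "ACTA2")
  expect_equal(r$removed, "COL1A1")
  r2 <- strip_collagen_genes(c("MMP1", "FAP"))
  expect_equal(r2$kept, c("MMP1", "FAP"))
  expect_warning(r3 <- strip_collagen_genes(c("COL1A2", "COL3A1")), "empty")
  expect_length(r3$kept, 0)
  # COLEC-type symbols are not collagen chains
  expect_equal(strip_collagen_genes("COLEC12")$kept, "COLEC12")
})

test_that("histology scores binarise at the documented cuts", {
  expect_equal(binarize_histology("invasion", 2), "low")
  expect_equal(binarize_histology("invasion", 3), "high")
  expect_equal(binarize_histology("invasion", c(0, 2, 3, 4)),
               c("low", "low", "high", "high"))
  expect_error(binarize_histology("invasion", 5), "0..4")

  expect_equal(binarize_histology("elastosis", "3+"), "CSD")
  expect_equal(binarize_histology("elastosis", "2-"), "noCSD")
  expect_equal(binarize_histology("elastosis", "2"), "CSD")
  expect_equal(binarize_histology("elastosis", 0:10),
               c(rep("noCSD", 6), rep("CSD", 5)))
  expect_error(binarize_histology("elastosis", "4+"), "label")
})

test_that("log-rank matches a hand-computed risk table and detects no sham effect", {
  # duplicated identical groups: statistic exactly 0
  r0 <- km_logrank(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(r0$chisq, 0)

  # toy two-group case, no censoring: brute-force risk-table oracle
  time <- 1:6; event <- rep(1, 6); grp <- rep(c("A", "B"), each = 3)
  o <- 0; e <- 0; v <- 0
  for (t in sort(time)) {
    at_risk <- time >= t
    n <- sum(at_risk); na <- sum(at_risk & grp == "A")
    d <- sum(time == t & event == 1)
    o <- o + sum(time == t & event == 1 & grp == "A")
    e <- e + d * na / n
    if (n > 1) v <- v + d * (n - d) / (n - 1) * na * (n - na) / n^2
  }
  oracle_chisq <- (o - e)^2 / v
  r <- km_logrank(time, event, grp)
  expect_equal(r$chisq, oracle_chisq, tolerance = 1e-9)
  expect_equal(r$p, stats::pchisq(oracle_chisq, 1, lower.tail = FALSE))
})

test_that("median-split groups recover planted survival structure", {
  es <- make_expression_dataset(survival_sim_spec(seed = 99))
  sc <- score_and_compare_survival(es, sig_genes)
  expect_gte(mean(sc$groups == es$truth$group[names(sc$groups)]), 0.9)
  expect_true(sc$logrank$p < 0.05)
  # stripping collagen genes from a non-collagen signature changes nothing
  sc2 <- score_and_compare_survival(es, sig_genes, drop_collagen = TRUE)
  expect_identical(sc$scores, sc2$scores)
})
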