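test_that("Welch's t handles the standard and the degenerate cases", {
  same <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  res <- welchT(c(10, 11, 12), c(20, 21, 22))
  expect_equal(res$t, -10 / sqrt(2 / 3), tolerance = 1e-12)   # -12.247
  expect_equal(res$df, 4)
  expect_lt(res$p, 0.01)

  # antisymmetry under group swap
  swp <- welchT(c(20, 21, 22), c(10, 11, 12))
  expect_equal(swp$t, -res$t)
  expect_equal(swp$p, res$p)

  # both constant: equal -> p = 1; different -> untestable
  expect_equal(welchT(c(5, 5), c(5, 5))$p, 1)
  expect_true(welchT(c(5, 5), c(7, 7))$untestable)
  expect_true(welchT(3, c(1, 2))$untestable)
})

test_that("BH adjustment matches the hand step-up oracle and its order properties", {
  expect_equal(bhFDR(0.03), 0.03)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(88)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bhFDR(p)
    expect_equal(q, bhOracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_equal(order(q[order(p)]), seq_along(p))  # significance order kept
  }
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold change puts the cultivar of interest in the numerator", {
  expect_equal(foldChange(136.4, 225.8), 225.8 / 136.4)   # indole, ~1.655
  expect_equal(foldChange(7, 7), 1)
  expect_equal(foldChange(0, 5), Inf)                     # present/absent
  expect_true(is.nan(foldChange(0, 0)))                   # untestable
  expect_error(foldChange(-1, 2), ">= 0")
})

test_that("volcano classification applies all three thresholds strictly", {
  cfg <- screenConfig()
  expect_equal(volcanoClassify(0.01, 1.5, 1.2, cfg), "up")
  expect_equal(volcanoClassify(0.01, 1.2, 1.2, cfg), "not_significant")
  expect_equal(volcanoClassify(0.2, 3.0, 2.0, cfg), "not_significant")
  expect_equal(volcanoClassify(0.01, 0.5, 1.5, cfg), "down")
  expect_equal(volcanoClassify(0.01, 0.8, 1.5, cfg), "not_significant")
  expect_equal(volcanoClassify(0.01, 1.5, 1.0, cfg), "not_significant")
  expect_equal(volcanoClassify(0.05, 1.5, 1.5, cfg), "not_significant")
  expect_equal(volcanoClassify(0.01, Inf, 1.5, cfg), "up")
  expect_equal(volcanoClassify(NA, 1.5, 1.5, cfg), "untestable")
  expect_equal(volcanoClassify(0.01, NaN, 1.5, cfg), "untestable")
})

test_that("the pairwise screen recovers a planted fold change and only it", {
  spec <- plantEffect(nullTwoGroupSpec(seed = 901), "F5", "B", 2.0)
  vs <- generateReplicates(spec)
  tab <- discriminatingScreen(vs, ref = "A", target = "B")
  expect_equal(discriminating(tab), "F5")
  expect_equal(tab["F5", "status"], "up")
  # every called compound satisfies all three strict thresholds
  called <- tab[tab$status %in% c("up", "down"), ]
  expect_true(all(called$q_value < 0.05))
  expect_true(all(called$vip > 1))
  expect_true(all(called$fc > 1.2 | called$fc < 0.8))
  # compounds n.d. everywhere in both groups are untestable
  absent <- rownames(tab)[tab$mean_ref == 0 & tab$mean_int == 0]
  expect_true(length(absent) > 0)
  expect_true(all(tab[absent, "status"] == "untestable"))
})

test_that("a knocked-out compound surfaces as a present/absent 'down' call", {
  spec <- plantEffect(nullTwoGroupSpec(seed = 902), "F9", "B", 0)
  vs <- generateReplicates(spec)
  tab <- discriminatingScreen(vs, ref = "A", target = "B")
  expect_equal(tab["F9", "fc"], 0)
  expect_equal(tab["F9", "status"], "down")
  expect_error(discriminatingScreen(vs, ref = "A", target = "Z"),
               "not present")
})

test_that("Venn intersections partition the union of discriminating sets", {
  mk <- function(ids, status_ids) {
    df <- data.frame(compound_id = ids,
                     status = ifelse(ids %in% status_ids, "up",
                                     "not_significant"),
                     stringsAsFactors = FALSE)
    class(df) <- c("DiffTable", "data.frame")
    df
  }
  ids <- paste0("C", 1:6)
  tabs <- list(A = mk(ids, c("C1", "C2")),
               B = mk(ids, c("C2", "C3")),
               C = mk(ids, c("C2", "C4")))
  venn <- vennIntersections(tabs)
  expect_equal(sort(names(venn$membership)), c("C1", "C2", "C3", "C4"))
  expect_equal(venn$membership$C2, c("A", "B", "C"))
  expect_equal(sum(venn$counts), 4)     # regions partition the union
  expect_equal(unname(venn$counts["A&B&C"]), 1L)

  # disjoint sets have an empty triple region; identical sets fill it
  disj <- vennIntersections(list(A = mk(ids, "C1"), B = mk(ids, "C2"),
                                 C = mk(ids, "C3")))
  expect_false("A&B&C" %in% names(disj$counts))
  same <- vennIntersections(list(A = mk(ids, "C5"), B = mk(ids, "C5"),
                                 C = mk(ids, "C5")))
  expect_equal(names(same$counts), "A&B&C")

  expect_equal(discriminatingKeyOdorants(tabs, c("C2", "C6")), "C2")
  expect_equal(discriminatingKeyOdorants(tabs, character(0)), character(0))
})

test_that("ROC/AUC equals the concordant-pair statistic and its symmetries", {
  # perfect separation and pure ties
  expect_equal(rocCurve(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1.0)
  expect_equal(rocCurve(rep(4, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)

  set.seed(19)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    scores <- sample(1:8, n, replace = TRUE)   # ties guaranteed
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || !any(pos)) next
    r <- rocCurve(scores, pos)
    expect_equal(r$auc, aucOracle(scores, pos), tolerance = 1e-12)
    # curve runs monotonically from (0,0) to (1,1)
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    # label flip and monotone transform symmetries
    expect_equal(rocCurve(scores, !pos)$auc, 1 - r$auc, tolerance = 1e-12)
    expect_equal(rocCurve(exp(scores / 2), pos)$auc, r$auc,
                 tolerance = 1e-12)
  }
  expect_error(rocCurve(1:4, rep(TRUE, 4)), "non-empty")
})

test_that("AUC agrees with the pROC reference implementation", {
  set.seed(23)
  scores <- rnorm(30)
  pos <- rep(c(TRUE, FALSE), 15)
  mine <- rocCurve(scores, pos)$auc
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(pos, scores, direction = "<",
                                   quiet = TRUE))))
  expect_equal(mine, ref, tolerance = 1e-12)
})
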