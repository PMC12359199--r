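test_that("win/tie/loss counting honors the margin and the substantial filter", {
  errA <- c(t1 = 3, t2 = 6, t3 = 6.4)
  errB <- c(t1 = 3.4, t2 = 5, t3 = 7.0)
  cmp <- compare_methods(errA, errB, substantial = NULL)
  expect_equal(cmp$unfiltered$tie, 1)     # |3 - 3.4| = 0.4 < 0.5
  expect_equal(cmp$unfiltered$win_b, 1)   # 6 vs 5
  expect_equal(cmp$unfiltered$win_a, 1)   # 6.4 vs 7.0
  cmp2 <- compare_methods(errA, errB, substantial = 5.0)
  expect_equal(cmp2$filtered$n, 2)        # t1 excluded: both errors <= 5
  expect_equal(cmp2$filtered$win_a, 1)
  expect_equal(cmp2$filtered$win_b, 1)
  expect_equal(cmp2$filtered$tie, 0)
  # identical errors are all ties
  cmp3 <- compare_methods(errA, errA)
  expect_equal(cmp3$unfiltered$tie, 3)
  expect_error(compare_methods(errA, c(x = 1, y = 2, z = 3)), "differ")
})

test_that("swapping the methods swaps wins and losses", {
  set.seed(17)
  for (k in 1:10) {
    a <- setNames(runif(20, 0, 12), paste0("t", 1:20))
    b <- setNames(a + rnorm(20), names(a))
    ab <- compare_methods(a, b)
    ba <- compare_methods(b, a)
    expect_equal(ab$unfiltered$win_a, ba$unfiltered$win_b)
    expect_equal(ab$unfiltered$win_b, ba$unfiltered$win_a)
    expect_equal(ab$unfiltered$tie, ba$unfiltered$tie)
    expect_equal(ab$filtered$win_a, ba$filtered$win_b)
    expect_equal(ab$unfiltered$win_a + ab$unfiltered$tie +
                   ab$unfiltered$win_b, 20)
  }
})

test_that("the confusion matrix bins residues by true and predicted category", {
  # perfect prediction gives the identity on supported rows
  v <- c(95, 80, 60, 40)
  m <- confusion_matrix(v, v)
  expect_equal(unname(diag(m)), rep(1, 4))
  # all mass in one off-diagonal cell
  m2 <- confusion_matrix(rep(40, 5), rep(95, 5))
  expect_equal(unname(m2["<50", ]), c(1, 0, 0, 0))
  expect_true(all(is.na(m2[">90", ])))  # unsupported rows absent
  # hand-binned mixed case
  m3 <- confusion_matrix(c(95, 80, 60, 40), c(95, 95, 60, 40))
  expect_equal(unname(m3[">90", ]), c(1, 0, 0, 0))
  expect_equal(unname(m3["70-90", ]), c(1, 0, 0, 0))
  expect_equal(unname(m3["50-70", ]), c(0, 0, 1, 0))
  expect_equal(unname(m3["<50", ]), c(0, 0, 0, 1))
  expect_equal(unname(attr(m3, "support")), rep(1L, 4), ignore_attr = TRUE)
})

test_that("confusion rows always sum to one where supported", {
  set.seed(23)
  for (k in 1:10) {
    true <- runif(100, 0, 100)
    pred <- pmin(100, pmax(0, true + rnorm(100, sd = 15)))
    m <- confusion_matrix(true, pred)
    sums <- rowSums(m)
    expect_equal(unname(sums[!is.na(sums)]),
                 rep(1, sum(!is.na(sums))), tolerance = 1e-12)
  }
})

test_that("the 2x2 category chi-squared matches the direct formula", {
  direct <- function(cA, tA, cB, tB) {
    O <- rbind(c(cA, tA - cA), c(cB, tB - cB))
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    sum((O - E)^2 / E)
  }
  r1 <- category_chi2(10, 20, 10, 20)
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p.value, 1)
  r2 <- category_chi2(15, 20, 5, 20)
  expect_equal(r2$statistic, direct(15, 20, 5, 20))
  expect_equal(r2$statistic, 10)
  expect_equal(r2$p.value, 1.565e-3, tolerance = 1e-3)
  r3 <- category_chi2(0, 10, 10, 10)
  expect_equal(r3$statistic, direct(0, 10, 10, 10))
  expect_equal(r3$statistic, 20)
  expect_equal(r3$p.value, 7.7e-6, tolerance = 1e-2)
  expect_error(category_chi2(0, 10, 0, 10), "degenerate")
})

test_that("chi-squared p-values agree with a permutation null", {
  # permutation null conditioned on both margins: correct counts for A
  # follow a hypergeometric, so 1e5 shuffles are drawn directly from it
  mc_p <- function(cA, tA, cB, tB, n = 1e5) {
    obs <- category_chi2(cA, tA, cB, tB)$statistic
    tot_correct <- cA + cB
    draws <- stats::rhyper(n, tot_correct, tA + tB - tot_correct, tA)
    stat <- vapply(draws, function(d) {
      O <- rbind(c(d, tA - d), c(tot_correct - d, tB - (tot_correct - d)))
      E <- outer(rowSums(O), colSums(O)) / sum(O)
      sum((O - E)^2 / E)
    }, numeric(1))
    mean(stat >= obs - 1e-9)
  }
  set.seed(29)
  for (tab in list(c(10, 20, 10, 20), c(15, 20, 5, 20), c(0, 10, 10, 10))) {
    p_exact <- category_chi2(tab[1], tab[2], tab[3], tab[4])$p.value
    p_mc <- mc_p(tab[1], tab[2], tab[3], tab[4])
    se <- sqrt(max(p_mc, 1e-6) * (1 - min(p_mc, 1 - 1e-6)) / 1e5)
    # the asymptotic p agrees with the discrete conditional-exact null up
    # to MC error on the diffuse tables and to order of magnitude on the
    # small ones, where the null's atoms are comparable to p itself
    agree_abs <- abs(p_exact - p_mc) < 3 * se + 5e-5
    agree_ratio <- p_mc > 0 && p_exact / p_mc < 3 && p_mc / p_exact < 3
    expect_true(agree_abs || agree_ratio)
  }
})

test_that("ablation deltas subtract full-model errors from variant errors", {
  full <- c(a = 4, b = 5)
  expect_equal(unname(ablation_delta(full, full)$delta), c(0, 0))
  up <- ablation_delta(full, full + 0.3)
  expect_equal(unname(up$delta), c(0.3, 0.3))
  expect_equal(unname(up$quantiles[2]), 0.3)
  mixed <- ablation_delta(c(a = 4, b = 5), c(a = 5, b = 4))
  expect_equal(unname(mixed$delta), c(1, -1))
  expect_equal(unname(mixed$quantiles[2]), 0)
  expect_error(ablation_delta(full, c(z = 1, w = 2)), "differ")
})

test_that("the report wrapper ties the protocol together", {
  set.seed(31)
  truth <- list()
  predA <- list()
  predB <- list()
  for (k in 1:4) {
    v <- setNames(runif(25, 20, 100), 1:25)
    truth[[paste0("t", k)]] <- egnnqa:::new_lddt_profile(v)
    predA[[paste0("t", k)]] <- egnnqa:::new_lddt_profile(
      setNames(pmin(100, pmax(0, v + rnorm(25, sd = 4))), names(v)))
    predB[[paste0("t", k)]] <- egnnqa:::new_lddt_profile(
      setNames(pmin(100, pmax(0, v + rnorm(25, sd = 12))), names(v)))
  }
  rep <- evaluate_predictions(truth, list(A = predA, B = predB))
  expect_equal(nrow(rep$per_model), 4)
  expect_true(all(rep$per_model$model_error_A < rep$per_model$model_error_B))
  expect_equal(nrow(rep$per_residue), 2 * 4 * 25)
  expect_named(rep$confusion, c("A", "B"))
  expect_equal(rep$comparison$unfiltered$n, 4)
})
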