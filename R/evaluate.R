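#' Win/tie/loss comparison of two methods' per-target errors
#'
#' Compares two methods target by target on their model-level LDDT errors.
#' Targets whose errors differ by less than the tie margin are ties;
#' otherwise the method with the smaller error wins. The comparison is also
#' reported restricted to targets where either method makes a substantial
#' error (error strictly above the threshold), the subset where the methods
#' genuinely disagree.
#'
#' @param errA,errB named numeric vectors of per-target errors (same
#'   target set).
#' @param tie_margin absolute error difference below which a target is a
#'   tie (default 0.5 LDDT units).
#' @param substantial substantial-error threshold (default 5.0); set to
#'   `NULL` to skip the filtered comparison.
#' @return object of class `qa_comparison`: for each of `unfiltered` and
#'   `filtered`, counts and fractions of A-wins, ties, B-wins.
#' @export
compare_methods <- function(errA, errB, tie_margin = 0.5, substantial = 5.0) {
  if (!is.null(names(errA)) && !is.null(names(errB))) {
    if (!setequal(names(errA), names(errB))) {
      stop("target sets differ: ",
           paste(union(setdiff(names(errA), names(errB)),
                       setdiff(names(errB), names(errA))), collapse = ", "))
    }
    errB <- errB[names(errA)]
  } else if (length(errA) != length(errB)) {
    stop("per-target error vectors differ in length")
  }
  tally <- function(a, b) {
    d <- a - b
    win_a <- sum(d <= -tie_margin)
    win_b <- sum(d >= tie_margin)
    tie <- sum(abs(d) < tie_margin)
    n <- length(a)
    list(n = n, win_a = win_a, tie = tie, win_b = win_b,
         frac = if (n) c(win_a = win_a, tie = tie, win_b = win_b) / n
                else c(win_a = NA, tie = NA, win_b = NA))
  }
  out <- list(unfiltered = tally(errA, errB),
              tie_margin = tie_margin, substantial = substantial)
  if (!is.null(substantial)) {
    keep <- pmax(errA, errB) > substantial
    out$filtered <- tally(errA[keep], errB[keep])
  }
  structure(out, class = "qa_comparison")
}

#' @export
print.qa_comparison <- function(x, ...) {
  show <- function(tag, t) {
    cat(sprintf("%s (n = %d): A wins %d (%.1f%%), ties %d (%.1f%%), B wins %d (%.1f%%)\n",
                tag, t$n, t$win_a, 100 * t$frac["win_a"],
                t$tie, 100 * t$frac["tie"], t$win_b, 100 * t$frac["win_b"]))
  }
  show("all targets", x$unfiltered)
  if (!is.null(x$filtered)) {
    show(sprintf("error > %.1f subset", x$substantial), x$filtered)
  }
  invisible(x)
}

#' Row-normalized 4x4 LDDT category confusion matrix
#'
#' Entry (r, c) is the fraction of residues whose true LDDT falls in
#' category r and whose predicted LDDT falls in category c, over the four
#' confidence bands >90, 70-90, 50-70, <50. Rows with no residues in the
#' true category are NA (reported absent, not zero-filled); row support
#' counts are attached as the `"support"` attribute.
#'
#' @param true,pred paired numeric vectors of per-residue LDDT values.
#' @return 4 x 4 matrix with dimnames over [lddt_categories()].
#' @export
confusion_matrix <- function(true, pred) {
  stopifnot(length(true) == length(pred), length(true) > 0)
  ok <- !is.na(true) & !is.na(pred)
  lev <- lddt_categories()
  tc <- factor(lddt_category(true[ok]), levels = lev)
  pc <- factor(lddt_category(pred[ok]), levels = lev)
  tab <- table(tc, pc)
  support <- rowSums(tab)
  m <- sweep(unclass(tab), 1, support, "/")
  m[support == 0, ] <- NA_real_
  dimnames(m) <- list(true = lev, predicted = lev)
  attr(m, "support") <- support
  m
}

#' Chi-squared test on category-correctness counts of two methods
#'
#' Pearson chi-squared (1 degree of freedom, no continuity correction) on
#' the 2x2 table of correctly vs incorrectly categorized residues for
#' methods A and B, testing whether the two correct fractions differ.
#'
#' @param correctA,totalA correct and total residue counts for method A.
#' @param correctB,totalB same for method B.
#' @return list with `statistic`, `p.value`, `table`.
#' @export
category_chi2 <- function(correctA, totalA, correctB, totalB) {
  stopifnot(totalA > 0, totalB > 0, correctA <= totalA, correctB <= totalB)
  tab <- rbind(A = c(correct = correctA, incorrect = totalA - correctA),
               B = c(correct = correctB, incorrect = totalB - correctB))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("degenerate margin: an expected count is 0")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p.value = unname(ct$p.value),
       table = tab)
}

#' Per-target error deltas of an ablated model variant
#'
#' Subtracts the full model's per-target error from the variant's, so a
#' positive delta means the variant is worse (the removed feature helped).
#'
#' @param full_errors,variant_errors named numeric vectors over the same
#'   targets.
#' @return list with `delta` (variant - full, per target) and `quantiles`
#'   (25/50/75%).
#' @export
ablation_delta <- function(full_errors, variant_errors) {
  if (!is.null(names(full_errors)) && !is.null(names(variant_errors))) {
    if (!setequal(names(full_errors), names(variant_errors))) {
      stop("target sets differ")
    }
    variant_errors <- variant_errors[names(full_errors)]
  } else if (length(full_errors) != length(variant_errors)) {
    stop("per-target error vectors differ in length")
  }
  delta <- variant_errors - full_errors
  list(delta = delta,
       quantiles = stats::quantile(delta, c(0.25, 0.5, 0.75), names = TRUE))
}

#' Evaluate one or more prediction methods against true profiles
#'
#' Convenience wrapper producing the standard report: per-model errors,
#' a long per-residue table, per-method confusion matrices, and (with two
#' methods) the win/tie/loss comparison.
#'
#' @param truth named list of true `lddt_profile`s (names = target ids).
#' @param predictions named list of methods, each a named list of predicted
#'   `lddt_profile`s over the same targets.
#' @param tie_margin,substantial see [compare_methods()].
#' @return object of class `eval_report` with fields `per_model`,
#'   `per_residue`, `confusion`, `comparison` (NULL unless exactly two
#'   methods).
#' @export
evaluate_predictions <- function(truth, predictions, tie_margin = 0.5,
                                 substantial = 5.0) {
  stopifnot(length(predictions) >= 1, !is.null(names(predictions)))
  targets <- names(truth)
  per_model <- data.frame(target_id = targets, stringsAsFactors = FALSE)
  long <- list()
  confusion <- list()
  for (m in names(predictions)) {
    preds <- predictions[[m]]
    if (!setequal(names(preds), targets)) {
      stop("method '", m, "' is missing targets: ",
           paste(setdiff(targets, names(preds)), collapse = ", "))
    }
    per_model[[paste0("model_error_", m)]] <- vapply(
      targets, function(tg) model_error(preds[[tg]], truth[[tg]]), numeric(1))
    rows <- lapply(targets, function(tg) {
      tv <- truth[[tg]]$per_residue
      pv <- preds[[tg]]$per_residue[names(tv)]
      ok <- !is.na(tv) & !is.na(pv)
      data.frame(target_id = tg, residue_index = as.integer(names(tv)[ok]),
                 true_lddt = unname(tv[ok]), method = m,
                 pred_lddt = unname(pv[ok]), stringsAsFactors = FALSE)
    })
    long[[m]] <- do.call(rbind, rows)
    confusion[[m]] <- confusion_matrix(long[[m]]$true_lddt, long[[m]]$pred_lddt)
  }
  comparison <- NULL
  if (length(predictions) == 2) {
    nm <- names(predictions)
    ea <- setNames(per_model[[paste0("model_error_", nm[1])]], targets)
    eb <- setNames(per_model[[paste0("model_error_", nm[2])]], targets)
    comparison <- compare_methods(ea, eb, tie_margin, substantial)
  }
  structure(list(per_model = per_model,
                 per_residue = do.call(rbind, long),
                 confusion = confusion, comparison = comparison),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  err_cols <- grep("^model_error_", names(x$per_model), value = TRUE)
  for (cc in err_cols) {
    cat(sprintf("  %s: mean %.3f\n", sub("model_error_", "", cc),
                mean(x$per_model[[cc]])))
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
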