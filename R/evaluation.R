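#' Confusion matrix
#'
#' Tallies `(true, predicted)` label pairs into a `K x K` count matrix,
#' rows = true class, columns = predicted class.
#'
#' @param y_true,y_pred integer labels in `1..K`.
#' @param K number of classes (default: largest label seen).
#' @return Integer `K x K` matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, K = max(c(y_true, y_pred))) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  assert_that(length(y_true) == length(y_pred),
              "y_true and y_pred must have equal length")
  assert_that(all(y_true >= 1 & y_true <= K) && all(y_pred >= 1 & y_pred <= K),
              "labels must lie in 1..%d", K)
  cm <- matrix(0L, K, K)
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

# One-vs-rest collapse of a confusion matrix for class k.
ovr_counts <- function(cm, k) {
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from a confusion matrix
#'
#' Per class, the matrix is collapsed one-vs-rest to (TP, TN, FP, FN) and
#' the standard binary metrics are computed: accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 `2PR/(P+R)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Macro values are
#' unweighted class means; overall accuracy is `trace/total`. Any `0/0`
#' term (including a zero MCC denominator) is defined as 0.
#'
#' @param cm a [confusion()] matrix (or plain `K x K` count matrix).
#' @return Object of class `metrics_report`: list with scalar `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `macro_mcc` and a
#'   tibble `per_class`.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  K <- nrow(cm)
  assert_that(K == ncol(cm) && sum(cm) > 0, "cm must be square with total > 0")
  per <- lapply(seq_len(K), function(k) {
    ct <- ovr_counts(cm, k)
    tp <- unname(ct["TP"]); tn <- unname(ct["TN"])
    fp <- unname(ct["FP"]); fn <- unname(ct["FN"])
    prec <- safe_div(tp, tp + fp)
    rec <- safe_div(tp, tp + fn)
    den_mcc <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    tibble::tibble(
      class = k,
      accuracy = (tp + tn) / sum(ct),
      precision = prec,
      recall = rec,
      f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
      mcc = if (den_mcc == 0) 0 else (tp * tn - fp * fn) / den_mcc)
  })
  per <- dplyr::bind_rows(per)
  structure(list(accuracy = sum(diag(cm)) / sum(cm),
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1),
                 macro_mcc = mean(per$mcc),
                 per_class = per),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> accuracy %.4f | macro P %.4f ",
                     "R %.4f F1 %.4f MCC %.4f\n"),
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              x$macro_mcc))
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return Tibble with one row per class plus macro/overall rows.
#' @export
tidy.metrics_report <- function(x, ...) {
  dplyr::bind_rows(
    x$per_class,
    tibble::tibble(class = NA_integer_, accuracy = x$accuracy,
                   precision = x$macro_precision, recall = x$macro_recall,
                   f1 = x$macro_f1, mcc = x$macro_mcc))
}

# Midrank one-vs-rest AUC: the Mann-Whitney statistic.
auc_binary <- function(scores, positive) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro one-vs-rest ROC AUC
#'
#' Per-class one-vs-rest AUC by the rank (Mann-Whitney) statistic with
#' midranks for ties, averaged over the classes present in `y_true`.
#' Classes absent from `y_true` are excluded with a warning. The statistic
#' is invariant under any strictly increasing transform of the scores.
#'
#' @param scores numeric `n x K` score matrix (columns = classes).
#' @param y_true integer labels in `1..K`.
#' @return Macro AUC, a scalar in `[0, 1]`.
#' @export
roc_auc_ovr_macro <- function(scores, y_true) {
  scores <- as.matrix(scores)
  assert_that(all(is.finite(scores)), "scores must be finite")
  K <- ncol(scores)
  present <- sort(unique(y_true))
  if (length(present) < K)
    warning(sprintf("class(es) %s absent from y_true; excluded from macro AUC",
                    paste(setdiff(seq_len(K), present), collapse = ", ")))
  aucs <- vapply(present, function(k)
    auc_binary(scores[, k], y_true == k), numeric(1))
  mean(aucs)
}

#' Dunn's test with Bonferroni correction
#'
#' Kruskal-Wallis rank test on the pooled values followed by Dunn's
#' pairwise z statistics (with tie correction); p-values are multiplied by
#' the number of pairs (capped at 1). A compact letter display summarises
#' the pairwise pattern: groups are sorted by decreasing median and groups
#' that are not significantly different share a letter.
#'
#' @param samples_by_group named list mapping group name to a numeric
#'   vector of metric values (e.g. the 5-repeat accuracies).
#' @param alpha significance level for the letter display.
#' @return List with `kruskal_p`, tibble `pairs` (`group1`, `group2`, `z`,
#'   `p_raw`, `p_adj`) and tibble `letters` (`group`, `median`, `letters`).
#' @export
dunn_bonferroni <- function(samples_by_group, alpha = 0.05) {
  assert_that(length(samples_by_group) >= 2, "need >= 2 groups")
  assert_that(all(vapply(samples_by_group, length, 1L) >= 3),
              "need >= 3 values per group")
  g <- names(samples_by_group) %||% as.character(seq_along(samples_by_group))
  names(samples_by_group) <- g
  x <- unlist(samples_by_group, use.names = FALSE)
  grp <- rep(g, vapply(samples_by_group, length, 1L))
  n <- length(x)

  if (length(unique(x)) == 1L) {
    pairs <- utils::combn(g, 2)
    tab <- tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                          z = 0, p_raw = 1, p_adj = 1)
    letters_tbl <- tibble::tibble(
      group = g,
      median = vapply(samples_by_group, stats::median, 1),
      letters = "a")
    return(list(kruskal_p = 1, pairs = tab, letters = letters_tbl))
  }

  kw <- stats::kruskal.test(x, factor(grp))
  r <- rank(x, ties.method = "average")
  rbar <- tapply(r, grp, mean)
  ni <- tapply(r, grp, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(g, 2)
  np <- ncol(pairs)
  z <- p_raw <- numeric(np)
  for (i in seq_len(np)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[[a]] + 1 / ni[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / se
    p_raw[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  p_adj <- pmin(1, p_raw * np)
  tab <- tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                        z = z, p_raw = p_raw, p_adj = p_adj)

  meds <- vapply(samples_by_group, stats::median, 1)
  ord <- names(sort(meds, decreasing = TRUE))
  sig <- function(a, b) {
    hit <- (tab$group1 == a & tab$group2 == b) |
      (tab$group1 == b & tab$group2 == a)
    any(tab$p_adj[hit] < alpha)
  }
  # Greedy letter assignment in median order: join the first letter class
  # whose members are all non-significant with the group, else a new letter.
  classes <- list()
  for (gname in ord) {
    joined <- FALSE
    for (ci in seq_along(classes)) {
      if (!any(vapply(classes[[ci]], sig, TRUE, b = gname))) {
        classes[[ci]] <- c(classes[[ci]], gname)
        joined <- TRUE
      }
    }
    if (!joined) classes[[length(classes) + 1L]] <- gname
  }
  letter_of <- vapply(g, function(gname)
    paste(letters[which(vapply(classes, function(cl) gname %in% cl, TRUE))],
          collapse = ""), "")
  letters_tbl <- tibble::tibble(group = g, median = unname(meds[g]),
                                letters = unname(letter_of))
  list(kruskal_p = kw$p.value, pairs = tab, letters = letters_tbl)
}

#' Generic tidiers
#'
#' `tidy()` returns a one-row-per-term tibble; `glance()` a one-row model
#' summary. Methods are provided for the fitted objects in this package.
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
glance.plsda_model <- function(x, ...)
  tibble::tibble(ncomp = x$ncomp, val_accuracy = x$val_accuracy)

#' @export
glance.svm_model <- function(x, ...)
  tibble::tibble(C = x$C, gamma = x$gamma, val_accuracy = x$val_accuracy)

#' @export
tidy.selection_result <- function(x, ...)
  tibble::tibble(method = x$method,
                 index = x$selected_indices,
                 wavelength_nm = x$selected_nm)

#' @export
glance.selection_result <- function(x, ...)
  tibble::tibble(method = x$method,
                 n_selected = length(x$selected_indices),
                 criterion_min = min(x$criterion_curve, na.rm = TRUE))
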