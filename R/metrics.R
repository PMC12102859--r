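#' 3-class confusion matrix
#'
#' Tallies truth-by-prediction counts for the three ear labels
#' (0 healthy, 1 lesion, 2 artefact). Rows are truth, columns are
#' prediction.
#'
#' @param truth,pred Equal-length vectors of labels in `{0, 1, 2}`.
#' @return A 3 x 3 integer matrix of class `confusion3` with dimnames
#'   `truth`/`pred`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred))
    abort_input("'truth' and 'pred' must have equal length")
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (anyNA(truth) || anyNA(pred) ||
      !all(truth %in% 0:2) || !all(pred %in% 0:2))
    abort_input("labels must be integers in {0, 1, 2}")
  cm <- table(truth = factor(truth, levels = 0:2),
              pred = factor(pred, levels = 0:2))
  cm <- matrix(as.integer(cm), 3L, 3L,
               dimnames = list(truth = 0:2, pred = 0:2))
  structure(cm, class = c("confusion3", "matrix"))
}

#' @export
print.confusion3 <- function(x, ...) {
  cat("3-class confusion matrix (rows = truth, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Screening metrics from a 3-class confusion matrix
#'
#' Accuracy is 3-class (`trace/total`). Sensitivity and specificity use
#' the screening binarization healthy (0) vs defect (1 or 2):
#' sensitivity is the fraction of truth-defect ears predicted as any
#' defect; specificity is the fraction of truth-healthy ears predicted
#' healthy. All values are exact fractions; rounding happens only at
#' presentation. A metric whose denominator is zero is reported as `NA`
#' (undefined), never silently as 0.
#'
#' @param cm A [confusion] matrix.
#' @return A list of class `metrics_report`: `accuracy`, `sensitivity`,
#'   `specificity`, `per_class_recall` (length 3), `n`.
#' @export
screening_metrics <- function(cm) {
  if (!inherits(cm, "confusion3")) {
    if (is.matrix(cm) && all(dim(cm) == 3L) && all(cm >= 0)) {
      cm <- structure(cm, class = c("confusion3", "matrix"))
    } else abort_input("'cm' must be a 3 x 3 confusion matrix")
  }
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0L) abort_input("confusion matrix is empty")
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  per_class <- vapply(1:3, function(i) frac(m[i, i], sum(m[i, ])), 0)
  structure(list(
    accuracy = sum(diag(m)) / total,
    sensitivity = frac(sum(m[2:3, 2:3]), sum(m[2:3, ])),
    specificity = frac(m[1, 1], sum(m[1, ])),
    per_class_recall = setNames(per_class, c("healthy", "lesion", "artefact")),
    n = total
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format_metrics_table(x), sep = "\n")
  invisible(x)
}

#' Format a metrics report as a small text table
#'
#' @param report A [screening_metrics] report (or a named list of them,
#'   one row each).
#' @return Character vector of lines.
#' @export
format_metrics_table <- function(report) {
  rows <- if (inherits(report, "metrics_report")) list(report = report)
          else report
  fmt <- function(v) ifelse(is.na(v), "undefined",
                            sprintf("%.2f", round_half_up(v, 2)))
  out <- c(sprintf("%-28s %9s %12s %12s", "Screening performance",
                   "Accuracy", "Sensitivity", "Specificity"))
  for (nm in names(rows)) {
    r <- rows[[nm]]
    out <- c(out, sprintf("%-28s %9s %12s %12s",
                          sprintf("%s (%d ears)", nm, r$n),
                          fmt(r$accuracy), fmt(r$sensitivity),
                          fmt(r$specificity)))
  }
  out
}

#' Per-class percentage shares
#'
#' Converts class counts to percentages of the total, rounded half-up
#' to `digits` decimals (the presentation convention used throughout).
#'
#' @param counts Non-negative counts (optionally named).
#' @param total Denominator; defaults to `sum(counts)`.
#' @param digits Decimal places (half-up).
#' @return Numeric vector of percentages.
#' @export
class_shares <- function(counts, total = sum(counts), digits = 2) {
  if (total <= 0) abort_input("'total' must be positive")
  if (any(counts < 0)) abort_input("'counts' must be non-negative")
  round_half_up(100 * counts / total, digits)
}

#' Cohen's kappa between two raters
#'
#' Unweighted kappa on the 3-class label scale, computed in exact
#' integer arithmetic: with `n` paired ratings, observed agreement `a`
#' and marginal products `e = sum(row_i * col_i)`,
#' `kappa = (n*a - e) / (n^2 - e)`. When both raters are identical and
#' concentrated on one class (expected agreement 1), kappa is 1 by
#' convention.
#'
#' @param a,b Equal-length label vectors in `{0, 1, 2}`, length >= 2.
#' @return A list of class `kappa_result`: `kappa`, `p_observed`,
#'   `p_expected`, `n`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) abort_input("'a' and 'b' lengths differ")
  n <- length(a)
  if (n < 2L) abort_input("need at least 2 paired ratings")
  a <- as.integer(a); b <- as.integer(b)
  if (!all(a %in% 0:2) || !all(b %in% 0:2))
    abort_input("labels must be integers in {0, 1, 2}")
  tab <- table(factor(a, levels = 0:2), factor(b, levels = 0:2))
  agree <- sum(diag(tab))
  e <- sum(as.numeric(rowSums(tab)) * as.numeric(colSums(tab)))
  kappa <- if (n * n == e) {
    if (agree == n) 1 else NA_real_  # degenerate: pe = 1
  } else {
    (n * agree - e) / (n * n - e)
  }
  structure(list(kappa = kappa, p_observed = agree / n,
                 p_expected = e / (n * n), n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.2f (po = %.3f, pe = %.3f, n = %d)\n",
              round_half_up(x$kappa, 2), x$p_observed, x$p_expected, x$n))
  invisible(x)
}

#' Construct a rater table
#'
#' An ears x raters matrix of labels, the input to agreement
#' statistics. No missing cells are allowed.
#'
#' @param labels Matrix (ears x raters) of labels in `{0, 1, 2}`, or a
#'   long data frame with columns `ear_id`, `rater`, `label`.
#' @param rater_ids,ear_ids Optional identifier vectors (default from
#'   dimnames or sequence).
#' @return A list of class `rater_table`: `labels` (integer matrix),
#'   `rater_ids`, `ear_ids`.
#' @export
rater_table <- function(labels, rater_ids = NULL, ear_ids = NULL) {
  if (is.data.frame(labels)) {
    need <- c("ear_id", "rater", "label")
    if (!all(need %in% names(labels)))
      abort_input("long rater table needs columns ear_id, rater, label")
    wide <- tapply(labels$label, list(labels$ear_id, labels$rater),
                   function(v) v[1])
    labels <- matrix(as.integer(wide), nrow(wide), ncol(wide))
    ear_ids <- rownames(wide); rater_ids <- colnames(wide)
  }
  labels <- as.matrix(labels)
  if (anyNA(labels)) abort_input("rater table has missing cells")
  if (!all(labels %in% 0:2))
    abort_input("labels must be integers in {0, 1, 2}")
  storage.mode(labels) <- "integer"
  if (is.null(rater_ids))
    rater_ids <- colnames(labels) %||% paste0("R", seq_len(ncol(labels)))
  if (is.null(ear_ids))
    ear_ids <- rownames(labels) %||% paste0("ear", seq_len(nrow(labels)))
  structure(list(labels = unname(labels),
                 rater_ids = as.character(rater_ids),
                 ear_ids = as.character(ear_ids)),
            class = "rater_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise Cohen's kappa among raters
#'
#' @param table A [rater_table] with at least two raters.
#' @return Symmetric numeric matrix (raters x raters) of kappas,
#'   diagonal 1.
#' @export
pairwise_kappa <- function(table) {
  if (!inherits(table, "rater_table")) table <- rater_table(table)
  k <- ncol(table$labels)
  if (k < 2L) abort_input("need at least 2 raters")
  out <- diag(1, k)
  dimnames(out) <- list(table$rater_ids, table$rater_ids)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      kp <- cohens_kappa(table$labels[, i], table$labels[, j])$kappa
      out[i, j] <- out[j, i] <- kp
    }
  }
  out
}

#' Unanimity and dissent accounting
#'
#' An ear is unanimous when every rater assigns the same label. For
#' three raters, each inconsistent ear with a 2-vs-1 split is
#' attributed to its lone dissenter; three-way splits (possible with
#' three classes) are counted under `no_majority`.
#'
#' @param table A [rater_table] with at least two raters.
#' @return A list of class `unanimity_report`: `unanimous` (per-class
#'   counts, names `0`,`1`,`2`), `inconsistent` (count),
#'   `minority` (per-rater lone-dissent counts; all `NA` unless exactly
#'   3 raters), `no_majority`, `n`.
#' @export
unanimity <- function(table) {
  if (!inherits(table, "rater_table")) table <- rater_table(table)
  lab <- table$labels
  k <- ncol(lab)
  if (k < 2L) abort_input("need at least 2 raters")
  all_same <- apply(lab, 1L, function(r) all(r == r[1]))
  unan <- vapply(0:2, function(cl)
    sum(all_same & lab[, 1] == cl), 0L)
  names(unan) <- as.character(0:2)
  minority <- setNames(rep(NA_integer_, k), table$rater_ids)
  no_majority <- 0L
  if (k == 3L) {
    minority[] <- 0L
    for (i in which(!all_same)) {
      r <- lab[i, ]
      tabr <- table(r)
      if (max(tabr) == 2L) {
        lone <- which(r == as.integer(names(tabr)[tabr == 1L]))
        minority[lone] <- minority[lone] + 1L
      } else {
        no_majority <- no_majority + 1L
      }
    }
  }
  structure(list(unanimous = unan, inconsistent = sum(!all_same),
                 minority = minority, no_majority = no_majority,
                 n = nrow(lab)),
            class = "unanimity_report")
}

#' @export
print.unanimity_report <- function(x, ...) {
  cat(sprintf(
    "Unanimity over %d ears: healthy %d, lesion %d, artefact %d; inconsistent %d\n",
    x$n, x$unanimous[["0"]], x$unanimous[["1"]], x$unanimous[["2"]],
    x$inconsistent))
  if (!anyNA(x$minority))
    cat("Lone dissents:",
        paste(sprintf("%s: %d", names(x$minority), x$minority),
              collapse = ", "),
        if (x$no_majority > 0)
          sprintf("(three-way splits: %d)", x$no_majority) else "",
        "\n")
  invisible(x)
}

#' Write a metrics report (plus optional agreement results) as JSON
#'
#' @param report A [screening_metrics] report.
#' @param path Output path.
#' @param kappa Optional [pairwise_kappa] matrix to embed.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path, kappa = NULL, extra = NULL) {
  payload <- list(
    n = report$n,
    accuracy = report$accuracy,
    sensitivity = report$sensitivity,
    specificity = report$specificity,
    per_class_recall = as.list(report$per_class_recall))
  if (!is.null(kappa)) {
    payload$pairwise_kappa <- as.data.frame(as.table(kappa),
                                            stringsAsFactors = FALSE)
    names(payload$pairwise_kappa) <- c("rater_a", "rater_b", "kappa")
  }
  if (!is.null(extra)) payload <- c(payload, extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
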