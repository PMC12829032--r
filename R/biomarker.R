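#' Mann-Whitney U test (pair-counting form)
#'
#' U is the number of (x_i, y_j) pairs with x_i > y_j plus half the tied
#' pairs — the statistic whose normalisation by n1*n2 is the ROC AUC. The
#' two-sided p-value is exact (via the null permutation distribution) when
#' n1 + n2 <= 16 and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric score vectors (both non-empty).
#' @return list with `U`, `p`, `n1`, `n2`, `exact`.
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("scores must not contain NA")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2 <= 16L) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  if (is.nan(p)) p <- 1   # fully tied data carry no evidence
  list(U = U, p = min(p, 1), n1 = n1, n2 = n2, exact = exact)
}

#' ROC curve and AUC
#'
#' AUC by pair counting, AUC = U / (n_pos * n_neg) with ties contributing
#' one half, plus the explicit ROC polyline from a threshold sweep over
#' the observed scores. The trapezoid area under the sweep equals the
#' pair-counting AUC exactly; both are returned so the identity can be
#' asserted.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels logical (or coercible) class labels, `TRUE` = positive.
#' @return list with `auc` (pair-counting), `auc_trapezoid`, `roc`
#'   (data.frame `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present")
  U <- mann_whitney(scores[labels], scores[!labels])$U
  auc <- U / (n_pos * n_neg)
  # threshold sweep: predict positive when score >= t, for t descending
  # through the unique scores (plus a sentinel above all of them)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t) / n_neg,
                numeric(1))
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, auc_trapezoid = auc_trap,
       roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       n_pos = n_pos, n_neg = n_neg)
}

#' Two-group biomarker comparison
#'
#' Mann-Whitney U test plus ROC/AUC for one clinicopathological dichotomy,
#' with the orientation "higher score = positive class".
#'
#' @param scores per-sample biomarker scores.
#' @param positive logical vector marking the positive class.
#' @param feature feature name carried into the result.
#' @return one-row data.frame: `feature`, `n_neg`, `n_pos`, `U`, `p`,
#'   `auc`.
#' @export
biomarker_compare <- function(scores, positive, feature = "feature") {
  positive <- as.logical(positive)
  keep <- !is.na(scores) & !is.na(positive)
  scores <- scores[keep]; positive <- positive[keep]
  mw <- mann_whitney(scores[positive], scores[!positive])
  roc <- roc_auc(scores, positive)
  data.frame(feature = feature, n_neg = sum(!positive),
             n_pos = sum(positive), U = mw$U, p = mw$p, auc = roc$auc,
             stringsAsFactors = FALSE)
}

#' Biomarker panel over the cohort dichotomies
#'
#' Runs [biomarker_compare()] for the six dichotomies of the biopsy
#' analysis: lesion (adjacent-normal vs cancer, all cores) and, among
#' cancer cores only, Gleason grade group (1-2 vs 3-5), T stage (T2 vs
#' T3), extraprostatic extension, seminal-vesicle invasion, and lymph-node
#' metastasis (each negative vs positive).
#'
#' @param scores_df data.frame with `sample_id` and `score`.
#' @param metadata cohort metadata (columns `sample_id`, `lesion`,
#'   `gleason_group`, `t_stage`, `epe`, `sv`, `ln`).
#' @return data.frame, one row per feature.
#' @export
cohort_biomarkers <- function(scores_df, metadata) {
  stopifnot(all(c("sample_id", "score") %in% names(scores_df)))
  md <- merge(scores_df, metadata, by = "sample_id")
  cancer <- md[md$lesion == "cancer", ]
  rows <- list(
    biomarker_compare(md$score, md$lesion == "cancer", "lesion"),
    biomarker_compare(cancer$score, cancer$gleason_group >= 3,
                      "gleason_group"),
    biomarker_compare(cancer$score, cancer$t_stage == "T3", "t_stage"),
    biomarker_compare(cancer$score, cancer$epe, "epe"),
    biomarker_compare(cancer$score, cancer$sv, "sv"),
    biomarker_compare(cancer$score, cancer$ln, "ln"))
  do.call(rbind, rows)
}
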