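# Expression- and score-level computations: qPCR relative expression,
# fold changes, geometric-mean signature scores with median split,
# collagen-gene filtering, histology-score binarisation, and Kaplan-Meier /
# log-rank comparison of score groups.

#' qPCR relative expression (2^-dCt)
#'
#' Relative expression normalised to the geometric mean of the housekeeping
#' genes: `RE = 2^-(ct_target - mean(ct_housekeepers))`. Averaging Ct
#' values arithmetically corresponds to the geometric mean of housekeeper
#' expression levels.
#'
#' @param ct_target Target-gene Ct value (cycles), finite and positive.
#' @param ct_housekeepers Numeric vector (length >= 1) of housekeeper Ct
#'   values.
#' @return Relative expression (dimensionless).
#' @export
relative_expression <- function(ct_target, ct_housekeepers) {
  if (length(ct_housekeepers) == 0L) stop("at least one housekeeper Ct required")
  stopifnot(is.finite(ct_target), ct_target > 0,
            all(is.finite(ct_housekeepers)), all(ct_housekeepers > 0))
  2^-(ct_target - mean(ct_housekeepers))
}

#' Fold change between two relative expressions
#'
#' @param re_treated,re_control Relative expression of the treated and
#'   control condition; `re_control` must be positive.
#' @return `re_treated / re_control`.
#' @export
fold_change <- function(re_treated, re_control) {
  stopifnot(is.finite(re_treated), is.finite(re_control))
  if (re_control <= 0) stop("control relative expression must be positive")
  re_treated / re_control
}

#' Geometric-mean signature score per sample
#'
#' For each sample, the geometric mean of the log2(x+1)-scale expression
#' values of the signature genes present in the dataset. Signature genes
#' absent from the matrix are dropped with a warning; zero values are
#' floored at `epsilon` (with a warning) so the geometric mean stays
#' defined.
#'
#' @param dataset An `expression_dataset` (see [make_expression_dataset()])
#'   or a numeric genes x samples matrix with gene ids as row names.
#' @param signature_genes Character vector of signature gene ids.
#' @param epsilon Floor applied to zero values.
#' @return Named numeric vector of per-sample scores.
#' @export
maf_score <- function(dataset, signature_genes, epsilon = 0.01) {
  values <- if (inherits(dataset, "expression_dataset")) dataset$values
            else dataset
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            length(signature_genes) >= 1)
  present <- intersect(signature_genes, rownames(values))
  missing <- setdiff(signature_genes, rownames(values))
  if (length(present) == 0L)
    stop("no signature gene present in the expression matrix")
  if (length(missing) > 0L)
    warning(sprintf("%d signature gene(s) absent and dropped: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")))
  v <- values[present, , drop = FALSE]
  if (any(v < 0)) stop("expression values must be >= 0 (log2(x+1) scale)")
  if (any(v == 0)) {
    warning(sprintf("%d zero value(s) floored at epsilon = %g",
                    sum(v == 0), epsilon))
    v[v == 0] <- epsilon
  }
  exp(colMeans(log(v)))
}

#' Median split into high and low groups
#'
#' Samples with score strictly above the cohort median are `"high"`; scores
#' at or below the median are `"low"` (deterministic tie rule).
#'
#' @param scores Numeric vector (optionally named).
#' @return Character vector of `"high"`/`"low"`, same names as `scores`.
#' @export
median_split <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 1, all(is.finite(scores)))
  med <- stats::median(scores)
  out <- ifelse(scores > med, "high", "low")
  names(out) <- names(scores)
  out
}

#' Remove collagen genes from a signature
#'
#' Drops gene identifiers matching the collagen-gene pattern (by default,
#' symbols beginning `COL` followed by a digit), returning both the reduced
#' set and the removed genes for audit.
#'
#' @param signature_genes Character vector of gene ids.
#' @param pattern Regular expression identifying collagen genes.
#' @return List with `kept` and `removed` character vectors.
#' @export
strip_collagen_genes <- function(signature_genes, pattern = "^COL[0-9]") {
  stopifnot(is.character(signature_genes))
  removed <- grep(pattern, signature_genes, value = TRUE)
  kept <- setdiff(signature_genes, removed)
  if (length(kept) == 0L)
    warning("all signature genes are collagen genes; reduced signature is empty")
  list(kept = kept, removed = removed)
}

# the 11-point solar-elastosis ladder, indices 0..10
elastosis_ladder <- c("0", "0+", "1-", "1", "1+", "2-", "2", "2+", "3-", "3", "3+")

#' Binarise ordinal histology scores
#'
#' Solar elastosis is scored on an 11-point ladder from 0 to 3+; scores from
#' 0 to 2- map to `"noCSD"` (no chronic sun damage) and scores from 2 to 3+
#' to `"CSD"`. Melanoma invasion at the invasive front is scored 0-4;
#' scores 0-2 map to `"low"` and 3-4 to `"high"`.
#'
#' @param score_kind `"elastosis"` or `"invasion"`.
#' @param raw_score For elastosis: ladder labels (`"0"`, `"0+"`, ...,
#'   `"3+"`) or integer indices 0-10; for invasion: integers 0-4.
#'   Vectorised.
#' @return Character vector of binary labels.
#' @export
binarize_histology <- function(score_kind = c("elastosis", "invasion"),
                               raw_score) {
  score_kind <- match.arg(score_kind)
  if (score_kind == "elastosis") {
    if (is.character(raw_score)) {
      idx <- match(raw_score, elastosis_ladder) - 1L
      if (anyNA(idx)) stop("unknown elastosis score label")
    } else {
      idx <- as.integer(raw_score)
      if (any(idx < 0 | idx > 10)) stop("elastosis index must be in 0..10")
    }
    ifelse(idx <= 5L, "noCSD", "CSD")  # cut between 2- (5) and 2 (6)
  } else {
    s <- as.integer(raw_score)
    if (any(s < 0 | s > 4)) stop("invasion score must be in 0..4")
    ifelse(s <= 2L, "low", "high")
  }
}

#' Kaplan-Meier curves and log-rank test between score groups
#'
#' Product-limit survival estimates per group and the two-sided log-rank
#' test, via the survival package.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored); at least one
#'   event required.
#' @param group Group labels; at least two distinct groups.
#' @return List with `fit` (a `survfit` object), `chisq`, `df`, and `p`.
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group),
            all(time > 0), all(event %in% c(0, 1)))
  if (length(unique(group)) < 2L) stop("at least two groups required")
  if (sum(event) < 1) stop("at least one event required")
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(fit = fit, chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Score an expression dataset and compare survival of score groups
#'
#' Convenience wrapper: computes the geometric-mean signature score,
#' median-splits the cohort, and (if survival data are present) runs the
#' log-rank comparison between the high and low groups.
#'
#' @param dataset An `expression_dataset`.
#' @param signature_genes Signature gene ids; defaults to the dataset's
#'   planted signature when generated synthetically.
#' @param drop_collagen If `TRUE`, collagen genes are removed from the
#'   signature before scoring.
#' @return List with `scores`, `groups`, and `logrank` (or `NULL` when no
#'   survival table is attached).
#' @export
score_and_compare_survival <- function(dataset, signature_genes,
                                       drop_collagen = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (drop_collagen)
    signature_genes <- strip_collagen_genes(signature_genes)$kept
  scores <- maf_score(dataset, signature_genes)
  groups <- median_split(scores)
  lr <- NULL
  if (!is.null(dataset$survival) && length(unique(groups)) == 2L) {
    surv <- dataset$survival
    lr <- km_logrank(surv$time, surv$event, groups[surv$sample_id])
  }
  list(scores = scores, groups = groups, logrank = lr)
}
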