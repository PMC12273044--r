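## CpG-panel biomarker evaluation: logistic scoring, first-principles
## ROC/AUC, stratified bootstrap CI, random-forest robustness check.

#' Build a panel matrix for a two-group contrast
#'
#' Assembles a samples x loci matrix of methylation values at the panel CpGs
#' for a binary contrast. In `matched_delta` mode (default) the value is the
#' tumour-minus-matched-normal percent per pair; in `raw_tumor` mode it is
#' the tumour percent. Samples missing any panel locus are dropped (logged
#' via message).
#'
#' @param calls cohort call table.
#' @param metadata sample metadata.
#' @param panel_loci `data.frame` with `chrom`, `pos` (1-based).
#' @param contrast length-2 character: class-0 and class-1 labels. Group
#'   labels (`PMOL`, `TN0`, `TN0plus`) or histology labels are accepted.
#' @param mode `"matched_delta"` or `"raw_tumor"`.
#' @return list of class `panel_matrix`: `x` (numeric matrix), `labels`
#'   (0/1 integer), `sample_id`, `contrast`, `mode`.
#' @export
build_panel <- function(calls, metadata, panel_loci,
                        contrast = c("PMOL", "TN0plus"),
                        mode = c("matched_delta", "raw_tumor")) {
  mode <- match.arg(mode)
  stopifnot(length(contrast) == 2L)
  pairs <- .matched_pairs(metadata)
  lab_of <- function(cls) {
    hit <- pairs$group == cls |
      metadata$histology[match(pairs$tumor_id, metadata$sample_id)] == cls
    if (!any(hit)) stop("empty class in contrast: ", cls)
    pairs[hit, , drop = FALSE]
  }
  p0 <- lab_of(contrast[1]); p1 <- lab_of(contrast[2])
  sel <- rbind(p0, p1)
  labels <- c(rep(0L, nrow(p0)), rep(1L, nrow(p1)))
  loci_key <- paste(panel_loci$chrom, panel_loci$pos)
  call_key <- paste(calls$chrom, calls$pos)
  x <- matrix(NA_real_, nrow(sel), nrow(panel_loci),
              dimnames = list(sel$tumor_id, loci_key))
  for (j in seq_len(nrow(panel_loci))) {
    at <- calls[call_key == loci_key[j], , drop = FALSE]
    vt <- at$pct[match(sel$tumor_id, at$sample_id)]
    if (mode == "matched_delta") {
      vn <- at$pct[match(sel$normal_id, at$sample_id)]
      x[, j] <- vt - vn
    } else x[, j] <- vt
  }
  keep <- complete.cases(x)
  if (!all(keep)) {
    message("dropped ", sum(!keep), " sample(s) missing panel loci")
  }
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  if (length(unique(labels)) < 2L) {
    stop("contrast ", paste(contrast, collapse = " vs "),
         " has an empty class after filtering")
  }
  structure(list(x = x, labels = labels, sample_id = rownames(x),
                 contrast = contrast, mode = mode), class = "panel_matrix")
}

#' Logistic scoring of a panel matrix
#'
#' Fits a maximum-likelihood logistic regression of class on the per-sample
#' mean panel methylation (the primary pooled-panel feature) or on the full
#' per-locus panel (`feature = "multivariate"`), returning in-sample
#' predicted probabilities as scores. On perfect separation or
#' non-convergence the likelihood diverges and scoring falls back to the
#' rank of the mean feature (ROC depends only on score order), with a
#' warning in the non-convergence case.
#'
#' @param panel a [build_panel()] object.
#' @param feature `"mean"` (default) or `"multivariate"`.
#' @return numeric scores, one per sample, in `[0, 1]`.
#' @export
fit_logistic <- function(panel, feature = c("mean", "multivariate")) {
  feature <- match.arg(feature)
  stopifnot(min(table(panel$labels)) >= 3L)
  f_mean <- rowMeans(panel$x)
  df <- if (feature == "mean") data.frame(y = panel$labels, f = f_mean)
  else data.frame(y = panel$labels, panel$x, check.names = TRUE)
  saturated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) saturated <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- fit$coefficients[-1]
  separated <- saturated || any(abs(coefs[!is.na(coefs)]) > 15)
  if (!fit$converged) {
    warning("logistic fit did not converge; falling back to rank scoring")
    separated <- TRUE
  }
  if (separated) {
    r <- rank(f_mean, ties.method = "average")
    return(r / (length(r) + 1))
  }
  as.numeric(fit$fitted.values)
}

## fast AUC via the Mann-Whitney rank statistic (ties count half)
.auc_mw <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' ROC curve and AUC from first principles
#'
#' Sweeps the unique score values as thresholds to produce the
#' (false-positive rate, true-positive rate) curve from (0,0) to (1,1), and
#' computes the AUC by trapezoid integration, which equals the Mann-Whitney
#' statistic P(score1 > score0) + 0.5 P(equal).
#'
#' @param scores numeric classifier scores (higher = more class-1).
#' @param labels 0/1 class labels.
#' @return list of class `roc_result`: `points` (data.frame `fpr`, `tpr`),
#'   `auc`, and unset CI fields `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- unique(pts)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, ci_low = NA_real_,
                 ci_high = NA_real_, n_boot = NA_integer_,
                 seed = NA_integer_), class = "roc_result")
}

## run fn with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Stratified bootstrap percentile CI for the AUC
#'
#' Resamples samples with replacement within each class (so both classes are
#' always represented), recomputes the AUC per replicate, and reports the
#' 2.5/97.5 percentile bounds. Deterministic given `seed`.
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the private RNG stream.
#' @return list `ci_low`, `ci_high`, `n_boot`, `seed`, `boot_auc` (the
#'   replicate AUCs).
#' @export
bootstrap_ci <- function(scores, labels, n_boot = 2000, seed = 1L) {
  labels <- as.integer(labels)
  i0 <- which(labels == 0); i1 <- which(labels == 1)
  if (length(i0) == 0L || length(i1) == 0L) stop("both classes required")
  boot <- .with_seed(seed, function() {
    vapply(seq_len(n_boot), function(b) {
      j <- c(sample(i0, length(i0), replace = TRUE),
             sample(i1, length(i1), replace = TRUE))
      .auc_mw(scores[j], labels[j])
    }, numeric(1))
  })
  ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  list(ci_low = ci[1], ci_high = ci[2], n_boot = n_boot, seed = seed,
       boot_auc = boot)
}

#' Evaluate a CpG panel end to end
#'
#' Convenience wrapper: logistic scoring, ROC/AUC and bootstrap CI.
#'
#' @param panel a [build_panel()] object.
#' @param n_boot,seed bootstrap settings, see [bootstrap_ci()].
#' @param feature scoring feature, see [fit_logistic()].
#' @return `roc_result` with CI fields set.
#' @export
evaluate_panel <- function(panel, n_boot = 2000, seed = 1L,
                           feature = "mean") {
  scores <- fit_logistic(panel, feature = feature)
  roc <- roc_auc(scores, panel$labels)
  ci <- bootstrap_ci(scores, panel$labels, n_boot = n_boot, seed = seed)
  roc$ci_low <- ci$ci_low; roc$ci_high <- ci$ci_high
  roc$n_boot <- ci$n_boot; roc$seed <- seed
  roc
}

#' Random-forest robustness check
#'
#' Bags randomized decision trees on the full per-locus panel and returns
#' the out-of-bag AUC, as a model-stringency check on the logistic/ROC
#' result.
#'
#' @param panel a [build_panel()] object.
#' @param n_trees number of trees.
#' @param seed RNG seed for the forest.
#' @return out-of-bag AUC.
#' @export
forest_check <- function(panel, n_trees = 500, seed = 1L) {
  stopifnot(min(table(panel$labels)) >= 3L)
  ## zero-variance features admit no split; with none left the OOB vote is
  ## the class prior for every sample and the AUC is 0.5 by definition
  keep <- apply(panel$x, 2, function(v) stats::var(v) > 0)
  if (!any(keep)) return(0.5)
  oob <- .with_seed(seed, function() {
    fit <- randomForest::randomForest(
      x = as.data.frame(panel$x[, keep, drop = FALSE]),
      y = factor(panel$labels), ntree = n_trees)
    fit$votes[, 2]  # vote share for the second level (class 1)
  })
  .auc_mw(oob, panel$labels)
}
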