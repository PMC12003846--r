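#' Prediction task specification
#'
#' Settings of the connectome-based prediction instrument: which per-scan
#' variable to predict from FC profiles, how features are selected inside
#' every training split, the repeated holdout scheme, and the permutation
#' null budget.
#'
#' @param target one of `"fd_ave"`, `"fd_max"`, `"ga"`, `"sex"`.
#' @param selection_alpha univariate p threshold for fold-internal feature
#'   selection (default 0.05).
#' @param n_repeats repeated random splits (default 50).
#' @param test_fraction held-out fraction per split (default 0.20).
#' @param n_permutations permutation sets for the null (default 50).
#' @param repeats_per_permutation CV repeats inside each permutation set
#'   (default 1 for desk-scale runtime; raise for the full budget).
#' @param model `"svr_linear"` or `"svc_linear"`; chosen from the target by
#'   default.
#' @param n_folds if set, use true k-fold CV instead of repeated 80/20 holdout.
#' @param seed master seed; every split, selection and permutation derives
#'   from it.
#' @return object of class `prediction_spec`.
#' @export
prediction_spec <- function(target = c("fd_ave", "fd_max", "ga", "sex"),
                            selection_alpha = 0.05, n_repeats = 50,
                            test_fraction = 0.20, n_permutations = 50,
                            repeats_per_permutation = 1, model = NULL,
                            n_folds = NULL, seed = 1) {
  target <- match.arg(target)
  if (test_fraction <= 0 || test_fraction >= 1) stopf("test_fraction must be in (0,1)")
  if (n_repeats < 1 || n_permutations < 1) stopf("n_repeats and n_permutations must be >= 1")
  if (is.null(model)) model <- if (target == "sex") "svc_linear" else "svr_linear"
  structure(list(target = target, selection_alpha = selection_alpha,
                 n_repeats = n_repeats, test_fraction = test_fraction,
                 n_permutations = n_permutations,
                 repeats_per_permutation = repeats_per_permutation,
                 model = model, n_folds = n_folds, seed = seed),
            class = "prediction_spec")
}

#' Univariate fold-internal feature selection
#'
#' Continuous targets: edges whose two-sided Pearson correlation p-value with
#' the target (training scans only) is below `alpha`. Binary targets: edges
#' whose two-sided pooled-variance two-sample t-test p-value is below `alpha`.
#' If nothing survives, the single smallest-p edge is selected with a warning.
#'
#' @param train_profiles training scans x edges matrix.
#' @param train_targets training target vector.
#' @param target_kind `"continuous"` or `"binary"`.
#' @param alpha selection threshold.
#' @return integer vector of selected edge indices.
#' @export
select_features <- function(train_profiles, train_targets,
                            target_kind = c("continuous", "binary"), alpha = 0.05) {
  target_kind <- match.arg(target_kind)
  P <- as.matrix(train_profiles)
  n <- nrow(P)
  p <- edgewise_pvalues(P, train_targets, target_kind)
  sel <- which(p < alpha)
  if (length(sel) == 0) {
    warnf("no edge passed selection at alpha = %g; falling back to the smallest-p edge", alpha)
    sel <- which.min(p)
  }
  sel
}

# vectorized univariate p-values across edges
edgewise_pvalues <- function(P, y, target_kind) {
  n <- nrow(P)
  sds <- apply(P, 2, sd)
  p <- rep(1, ncol(P))
  ok <- sds > 0
  if (target_kind == "continuous") {
    r <- as.vector(cor(as.numeric(y), P[, ok, drop = FALSE]))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    p[ok] <- 2 * pt(-abs(tstat), n - 2)
  } else {
    g <- as.factor(y)
    if (nlevels(g) != 2) stopf("binary selection needs exactly 2 classes")
    i1 <- g == levels(g)[1]
    n1 <- sum(i1); n2 <- sum(!i1)
    if (n1 < 2 || n2 < 2) stopf("need >= 2 scans per class")
    m1 <- colMeans(P[i1, ok, drop = FALSE]); m2 <- colMeans(P[!i1, ok, drop = FALSE])
    v1 <- apply(P[i1, ok, drop = FALSE], 2, var)
    v2 <- apply(P[!i1, ok, drop = FALSE], 2, var)
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    tstat <- (m1 - m2) / pmax(sp * sqrt(1 / n1 + 1 / n2), 1e-12)
    p[ok] <- 2 * pt(-abs(tstat), n1 + n2 - 2)
  }
  p
}

#' Connectome-based prediction with repeated holdout
#'
#' For each repeat: a random (sex-stratified for classification) 80/20 split;
#' feature selection and feature standardization computed on the training set
#' only; a linear SVR/SVC fit on the selected, standardized features;
#' evaluation on the held-out scans. Continuous performance is the Fisher z
#' of the predicted-vs-actual Pearson correlation; classification performance
#' is percent correct.
#'
#' @param profiles scans x edges matrix (or list of `fc_profile`s).
#' @param targets per-scan target vector (numeric, or labels for sex).
#' @param spec a [prediction_spec()].
#' @return object of class `prediction_result` with `per_repeat`, `mean`,
#'   `sd`, `selected_fraction` (mean per-repeat fraction of edges kept),
#'   `target`, `kind`, `n_scans`, `n_skipped`.
#' @export
run_prediction <- function(profiles, targets, spec) {
  P <- profiles_as_matrix(profiles)
  n <- nrow(P)
  if (n < 20) stopf("need >= 20 scans for prediction, got %d", n)
  kind <- if (spec$model == "svc_linear") "binary" else "continuous"
  if (anyNA(targets)) stopf("targets contain missing values")
  set.seed(spec$seed)
  repeat_seeds <- sample.int(2^31 - 2, spec$n_repeats)
  perfs <- rep(NA_real_, spec$n_repeats)
  fracs <- rep(NA_real_, spec$n_repeats)
  for (k in seq_len(spec$n_repeats)) {
    set.seed(repeat_seeds[k])
    test_idx <- draw_test_set(targets, spec$test_fraction, kind, spec$n_folds, k)
    train_idx <- setdiff(seq_len(n), test_idx)
    res <- fit_and_score(P, targets, train_idx, test_idx, spec, kind)
    perfs[k] <- res$perf
    fracs[k] <- res$frac
  }
  skipped <- sum(is.na(perfs))
  if (skipped > 0) log_info("prediction: %d/%d repeats skipped (degenerate test set)",
                            skipped, spec$n_repeats)
  ok <- !is.na(perfs)
  structure(list(per_repeat = perfs[ok], mean = mean(perfs[ok]), sd = sd(perfs[ok]),
                 selected_fraction = mean(fracs[ok]), target = spec$target,
                 kind = kind, n_scans = n, n_skipped = skipped),
            class = "prediction_result")
}

draw_test_set <- function(targets, test_fraction, kind, n_folds, k) {
  n <- length(targets)
  if (!is.null(n_folds)) {    # true k-fold option: fold (k-1) %% n_folds + 1
    folds <- sample(rep(seq_len(n_folds), length.out = n))
    return(which(folds == ((k - 1) %% n_folds) + 1))
  }
  if (kind == "binary") {     # stratified draw keeps small test sets balanced
    g <- as.factor(targets)
    unlist(lapply(levels(g), function(l) {
      idx <- which(g == l)
      sample(idx, max(1, round(test_fraction * length(idx))))
    }))
  } else {
    sample(n, max(2, round(test_fraction * n)))
  }
}

fit_and_score <- function(P, targets, train_idx, test_idx, spec, kind) {
  ytr <- targets[train_idx]; yte <- targets[test_idx]
  if (kind == "continuous" && sd(yte) == 0) return(list(perf = NA_real_, frac = NA_real_))
  if (kind == "binary" && length(unique(ytr)) < 2) return(list(perf = NA_real_, frac = NA_real_))
  sel <- select_features(P[train_idx, , drop = FALSE], ytr,
                         target_kind = kind, alpha = spec$selection_alpha)
  Xtr <- P[train_idx, sel, drop = FALSE]
  mu <- colMeans(Xtr)
  sg <- apply(Xtr, 2, sd); sg[sg == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
  Xte <- sweep(sweep(P[test_idx, sel, drop = FALSE], 2, mu), 2, sg, "/")
  if (kind == "binary") {
    fit <- linear_svm(Xtr, ytr, type = "svc")
    pred <- predict(fit, Xte)
    perf <- 100 * mean(pred == as.character(yte))
  } else {
    fit <- linear_svm(Xtr, as.numeric(ytr), type = "svr")
    pred <- predict(fit, Xte)
    if (sd(pred) == 0) {
      perf <- 0   # degenerate flat prediction carries no information
    } else {
      perf <- atanh_capped(cor(as.numeric(yte), pred))
    }
  }
  list(perf = perf, frac = length(sel) / ncol(P))
}

#' Permutation null for a prediction result
#'
#' Each permutation set shuffles the targets across scans once and reruns the
#' identical repeated-CV procedure (with `repeats_per_permutation` repeats);
#' the null distribution collects each set's mean performance. The p-value is
#' a one-tailed two-sample t-test (original repeats > null performances).
#'
#' @param result a `prediction_result` from [run_prediction()].
#' @param profiles,targets the same inputs given to [run_prediction()].
#' @param spec the same [prediction_spec()].
#' @return list with `null` (per-permutation mean performances), `p`
#'   (one-tailed), `observed_mean`.
#' @export
permutation_test <- function(result, profiles, targets, spec) {
  P <- profiles_as_matrix(profiles)
  set.seed(sub_seed(spec$seed, 0, salt = 77))
  perm_seeds <- sample.int(2^31 - 2, spec$n_permutations)
  null_perf <- rep(NA_real_, spec$n_permutations)
  pspec <- spec
  pspec$n_repeats <- spec$repeats_per_permutation
  pspec$n_permutations <- 1
  for (b in seq_len(spec$n_permutations)) {
    set.seed(perm_seeds[b])
    ytil <- sample(targets)
    pspec$seed <- perm_seeds[b]
    null_perf[b] <- suppressWarnings(run_prediction(P, ytil, pspec)$mean)
  }
  null_perf <- null_perf[!is.na(null_perf)]
  tt <- t.test(result$per_repeat, null_perf, alternative = "greater")
  list(null = null_perf, p = tt$p.value, observed_mean = result$mean)
}

#' Run prediction plus its permutation null in one call
#' @inheritParams permutation_test
#' @param profiles,targets inputs as for [run_prediction()].
#' @param spec a [prediction_spec()].
#' @return the `prediction_result` augmented with `null` and `p_perm`.
#' @export
run_prediction_with_null <- function(profiles, targets, spec) {
  res <- run_prediction(profiles, targets, spec)
  pt <- permutation_test(res, profiles, targets, spec)
  res$null <- pt$null
  res$p_perm <- pt$p
  res
}

#' Compare prediction performance across conditions
#'
#' Pairwise Welch two-sample t-tests between the per-repeat performance
#' distributions of the supplied conditions, Bonferroni-corrected over all
#' comparisons made.
#'
#' @param results named list of `prediction_result`s (>= 2).
#' @return data.frame with `condition_a`, `condition_b`, `mean_a`, `mean_b`,
#'   `t`, `p`, `p_bonferroni`, `note`.
#' @export
compare_conditions <- function(results) {
  if (length(results) < 2) stopf("need >= 2 conditions")
  if (is.null(names(results))) names(results) <- paste0("cond_", seq_along(results))
  cmb <- utils::combn(names(results), 2)
  m <- ncol(cmb)
  rows <- lapply(seq_len(m), function(k) {
    a <- results[[cmb[1, k]]]$per_repeat
    b <- results[[cmb[2, k]]]$per_repeat
    if (sd(a) == 0 && sd(b) == 0) {
      data.frame(condition_a = cmb[1, k], condition_b = cmb[2, k],
                 mean_a = mean(a), mean_b = mean(b), t = NA_real_,
                 p = if (mean(a) == mean(b)) 1 else 0, note = "zero variance (exact tie check)")
    } else {
      tt <- t.test(a, b)      # Welch: unequal repeat counts allowed
      data.frame(condition_a = cmb[1, k], condition_b = cmb[2, k],
                 mean_a = mean(a), mean_b = mean(b), t = unname(tt$statistic),
                 p = tt$p.value, note = "")
    }
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * m, 1)
  out
}

#' @export
print.prediction_result <- function(x, ...) {
  unit <- if (x$kind == "binary") "% correct" else "Fisher z(r)"
  cat(sprintf("<prediction_result> target=%s  %0.3f +/- %0.3f %s over %d repeats",
              x$target, x$mean, x$sd, unit, length(x$per_repeat)))
  if (!is.null(x$p_perm)) cat(sprintf("  (perm p = %0.4g)", x$p_perm))
  cat(sprintf("\n  selected fraction: %0.3f; scans: %d\n", x$selected_fraction, x$n_scans))
  invisible(x)
}
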