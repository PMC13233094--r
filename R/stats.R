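#' Pooled-standard-deviation Cohen's d
#'
#' \eqn{d = |m_A - m_B| / s_p} with
#' \eqn{s_p = \sqrt{((n_A-1)s_A^2 + (n_B-1)s_B^2)/(n_A+n_B-2)}}.
#' With zero pooled SD the effect is 0 for equal means and `Inf` otherwise.
#'
#' @param acc_A,acc_B Numeric vectors (length \eqn{\ge 2} each).
#' @return An object of class `"effect_size"`: list with `d_value`, `n_A`,
#'   `n_B`, `mean_A`, `mean_B`, `pooled_sd`.
#' @examples
#' cohens_d(c(1, 2, 3), c(3, 4, 5))$d_value  # 2
#' @export
cohens_d <- function(acc_A, acc_B) {
  n_A <- length(acc_A); n_B <- length(acc_B)
  if (n_A < 2 || n_B < 2) stop("each group needs at least 2 observations")
  m_A <- mean(acc_A); m_B <- mean(acc_B)
  sp <- sqrt(((n_A - 1) * stats::var(acc_A) + (n_B - 1) * stats::var(acc_B)) /
             (n_A + n_B - 2))
  d <- if (sp > 0) abs(m_A - m_B) / sp else if (m_A == m_B) 0 else Inf
  structure(list(d_value = d, n_A = n_A, n_B = n_B, mean_A = m_A,
                 mean_B = m_B, pooled_sd = sp),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f  (means %.4f vs %.4f, pooled sd %.4f, n = %d/%d)\n",
              x$d_value, x$mean_A, x$mean_B, x$pooled_sd, x$n_A, x$n_B))
  invisible(x)
}

#' Split a population at an accuracy threshold
#'
#' Units strictly above the threshold in their final training accuracy form
#' the high-achieving group (the comparison is strict: exactly hitting the
#' threshold counts as low). Proportions above threshold are reported for both
#' the final training and the test accuracies.
#'
#' @param final_train_acc,test_acc Equal-length accuracy vectors.
#' @param threshold Threshold in (0, 1); default 0.65.
#' @return An object of class `"achiever_split"`: list with `threshold`,
#'   `prop_above_train`, `prop_above_test`, `group` (factor `"high"`/`"low"`
#'   by final training accuracy).
#' @export
achiever_split <- function(final_train_acc, test_acc, threshold = 0.65) {
  if (length(final_train_acc) != length(test_acc))
    stop("final_train_acc and test_acc lengths differ")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(threshold = threshold,
                 prop_above_train = mean(final_train_acc > threshold),
                 prop_above_test = mean(test_acc > threshold),
                 group = factor(ifelse(final_train_acc > threshold,
                                       "high", "low"),
                                levels = c("high", "low"))),
            class = "achiever_split")
}

#' @export
print.achiever_split <- function(x, ...) {
  cat(sprintf("achiever split at %.0f%%: %.2f%% above in final training, %.2f%% in test\n",
              100 * x$threshold, 100 * x$prop_above_train,
              100 * x$prop_above_test))
  invisible(x)
}

#' Bin a per-trial correctness sequence
#'
#' Means of consecutive bins of `bin_size` trials; a trailing partial bin is
#' dropped.
#'
#' @param trial_correct Vector of 0/1 correctness values.
#' @param bin_size Positive bin width.
#' @return Numeric vector of bin accuracies.
#' @export
bin_trajectory <- function(trial_correct, bin_size = 20L) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  n_bins <- length(trial_correct) %/% bin_size
  if (n_bins == 0L) return(numeric(0))
  m <- matrix(trial_correct[seq_len(n_bins * bin_size)], nrow = bin_size)
  colMeans(m)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Plain Newton/IRLS on the Bernoulli log-likelihood. If the fit is unstable
#' (non-finite steps, or coefficients diverging as with perfect separation),
#' the fit is repeated with a small ridge penalty and flagged.
#'
#' @param X Model matrix.
#' @param y 0/1 response.
#' @param max_iter,tol Iteration controls.
#' @param ridge Ridge penalty used by the fallback.
#' @return List with `coefficients`, `vcov`, `converged`, `separation`,
#'   `iterations`.
#' @export
logistic_irls <- function(X, y, max_iter = 50L, tol = 1e-10, ridge = 1e-4) {
  X <- as.matrix(X)
  fit_once <- function(lambda) {
    beta <- numeric(ncol(X))
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      p <- 1 / (1 + exp(-eta))
      w <- p * (1 - p)
      w <- pmax(w, 1e-12)
      H <- crossprod(X, X * w) + diag(lambda, ncol(X))
      g <- crossprod(X, y - p) - lambda * beta
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step)))
        return(list(beta = beta, H = H, ok = FALSE, it = it))
      beta <- beta + drop(step)
      if (max(abs(step)) < tol)
        return(list(beta = beta, H = H, ok = TRUE, it = it))
    }
    list(beta = beta, H = H, ok = TRUE, it = max_iter)
  }
  f <- fit_once(0)
  separation <- !f$ok || any(abs(f$beta) > 15)
  if (separation) f <- fit_once(ridge)
  vc <- tryCatch(solve(f$H), error = function(e) {
    solve(f$H + diag(1e-8, ncol(X)))
  })
  list(coefficients = drop(f$beta), vcov = vc, converged = f$ok,
       separation = separation, iterations = f$it)
}

#' Pairwise curriculum contrasts from trial-level accuracy
#'
#' Fits a fixed-effects logistic model of trial correctness on curriculum
#' indicators (one log-odds parameter per curriculum, no intercept) by
#' [logistic_irls()], then reports every pairwise log-odds difference with its
#' Wald standard error, z statistic and two-sided p value. Raw p values are
#' reported (no multiplicity correction).
#'
#' @param trial_table Data frame with columns `participant`, `curriculum`,
#'   `correct` (0/1). Typically the test-phase rows of a study.
#' @return Data frame with columns `pair`, `curriculum_A`, `curriculum_B`,
#'   `beta`, `se`, `z`, `p`, `separation`.
#' @export
pairwise_logistic_contrasts <- function(trial_table) {
  stopifnot(all(c("participant", "curriculum", "correct") %in%
                names(trial_table)))
  cur <- factor(trial_table$curriculum)
  if (nlevels(cur) < 2) stop("need at least 2 curricula")
  counts <- table(unique(trial_table[, c("participant", "curriculum")])$curriculum)
  if (any(counts < 2)) stop("need at least 2 participants per curriculum")
  X <- stats::model.matrix(~ 0 + cur)
  colnames(X) <- levels(cur)
  fit <- logistic_irls(X, trial_table$correct)
  lev <- levels(cur)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    i <- match(pr[1], lev); j <- match(pr[2], lev)
    beta <- fit$coefficients[i] - fit$coefficients[j]
    se <- sqrt(fit$vcov[i, i] + fit$vcov[j, j] - 2 * fit$vcov[i, j])
    z <- beta / se
    data.frame(pair = paste(pr[1], "vs", pr[2]),
               curriculum_A = pr[1], curriculum_B = pr[2],
               beta = beta, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)),
               separation = fit$separation,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Effect-size table for a set of curriculum populations
#'
#' @param study A `"curriculum_study"` (list of populations) or a named list
#'   of numeric test-accuracy vectors.
#' @return Data frame with one row per curriculum pair: `pair`, `d`,
#'   `mean_A`, `mean_B`.
#' @export
effect_size_table <- function(study) {
  accs <- if (inherits(study, "curriculum_study"))
    lapply(study, function(p) p$records$test_acc) else study
  nm <- names(accs)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    es <- cohens_d(accs[[pr[1]]], accs[[pr[2]]])
    data.frame(pair = paste(pr[1], "vs", pr[2]),
               curriculum_A = pr[1], curriculum_B = pr[2],
               d = es$d_value, mean_A = es$mean_A, mean_B = es$mean_B,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
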