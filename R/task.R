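#' Define an XOR Gaussian-mixture discrimination task
#'
#' The task is a binary classification of points in \eqn{R^d}: stimuli with
#' label \eqn{y} are drawn from the two-component mixture
#' \eqn{x \sim \frac12 N(\mu_y, \sigma^2 I_d) + \frac12 N(-\mu_y, \sigma^2 I_d)}
#' with \eqn{\mu_0 \perp \mu_1} orthonormal, so diagonally opposite clusters
#' share a label and no linear classifier beats chance.
#'
#' @param d Input dimension (\eqn{\ge 2}).
#' @param seed Integer seed for the random orthonormal pair (ignored when
#'   `canonical = TRUE`).
#' @param canonical If `TRUE`, use the first two standard basis vectors as the
#'   class means.
#' @return An object of class `"xor_task"`: a list with elements `d`, `mu0`,
#'   `mu1`.
#' @examples
#' task <- make_task(2, canonical = TRUE)
#' task$mu0
#' @export
make_task <- function(d, seed = 1L, canonical = FALSE) {
  if (!is.numeric(d) || length(d) != 1L || d < 2)
    stop("d must be a single integer >= 2: two orthogonal unit vectors need d >= 2")
  d <- as.integer(d)
  if (canonical) {
    mu0 <- c(1, numeric(d - 1L))
    mu1 <- c(0, 1, numeric(d - 2L))
  } else {
    rng <- local_seed(seed)
    a <- stats::rnorm(d)
    b <- stats::rnorm(d)
    mu0 <- a / sqrt(sum(a^2))
    b <- b - sum(b * mu0) * mu0
    mu1 <- b / sqrt(sum(b^2))
  }
  structure(list(d = d, mu0 = mu0, mu1 = mu1), class = "xor_task")
}

#' @export
print.xor_task <- function(x, ...) {
  cat(sprintf("XOR Gaussian-mixture task: d = %d, |mu0| = %.6f, |mu1| = %.6f, mu0.mu1 = %.2e\n",
              x$d, sqrt(sum(x$mu0^2)), sqrt(sum(x$mu1^2)), sum(x$mu0 * x$mu1)))
  invisible(x)
}

#' Sample a batch of labelled XOR-GMM stimuli
#'
#' Each trial draws a label \eqn{y \sim Bern(1/2)} (unless constrained by
#' `subset`), a mixture-component sign \eqn{s \in \{+1,-1\}}, and
#' \eqn{x = s\,\mu_y + \sigma g}, \eqn{g \sim N(0, I_d)}.
#'
#' `subset` controls which of the four cluster centers may occur:
#' \describe{
#'   \item{`"both"`}{all four centers, fair coin for \eqn{s};}
#'   \item{`"plus"` / `"minus"`}{\eqn{s} forced to +1 / -1;}
#'   \item{`"mu0"` / `"mu1"`}{the label is forced (cluster pair
#'     \eqn{\pm\mu_0}, i.e. all label-0 trials, or \eqn{\pm\mu_1}); the sign
#'     stays a fair coin. These are the feature blocks of the bad curriculum.}
#' }
#'
#' @param task An `"xor_task"`.
#' @param sigma Noise standard deviation (\eqn{\ge 0}).
#' @param n Number of trials.
#' @param subset One of `"both"`, `"plus"`, `"minus"`, `"mu0"`, `"mu1"`.
#' @param seed Integer seed.
#' @return An object of class `"labeled_batch"`: list with `inputs`
#'   (`n x d`), `labels` (0/1), `center_signs` (+1/-1), `sigmas`.
#' @export
sample_batch <- function(task, sigma, n, subset = "both", seed = 1L) {
  stopifnot(inherits(task, "xor_task"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (n < 1) stop("n must be >= 1")
  subset <- match.arg(subset, c("both", "plus", "minus", "mu0", "mu1"))
  n <- as.integer(n)
  rng <- local_seed(seed)
  labels <- switch(subset,
    mu0 = rep(0L, n),
    mu1 = rep(1L, n),
    stats::rbinom(n, 1L, 0.5)
  )
  signs <- switch(subset,
    plus = rep(1, n),
    minus = rep(-1, n),
    sample(c(-1, 1), n, replace = TRUE)
  )
  G <- matrix(stats::rnorm(n * task$d, 0, sigma), n, task$d)
  centers <- outer(signs * (labels == 0), task$mu0) +
             outer(signs * (labels == 1), task$mu1)
  structure(list(inputs = G + centers,
                 labels = labels,
                 center_signs = signs,
                 sigmas = rep(sigma, n)),
            class = "labeled_batch")
}

#' @export
print.labeled_batch <- function(x, ...) {
  cat(sprintf("labeled_batch: %d trials, d = %d, sigma in [%g, %g]\n",
              length(x$labels), ncol(x$inputs), min(x$sigmas), max(x$sigmas)))
  invisible(x)
}

#' @export
as.data.frame.labeled_batch <- function(x, ...) {
  df <- data.frame(trial = seq_along(x$labels), label = x$labels,
                   center_sign = x$center_signs, sigma = x$sigmas)
  inp <- as.data.frame(x$inputs)
  names(inp) <- paste0("x_", seq_len(ncol(x$inputs)) - 1L)
  cbind(df, inp)
}

#' Write / read a labelled batch as CSV
#'
#' Columns: `trial, label, center_sign, sigma, x_0 ... x_{d-1}`.
#' @param batch A `"labeled_batch"`.
#' @param path File path.
#' @return `write_batch_csv` returns `path` invisibly; `read_batch_csv`
#'   returns a `"labeled_batch"`.
#' @export
write_batch_csv <- function(batch, path) {
  utils::write.csv(as.data.frame(batch), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_batch_csv
#' @export
read_batch_csv <- function(path) {
  df <- utils::read.csv(path)
  xcols <- grep("^x_", names(df))
  structure(list(inputs = as.matrix(df[, xcols, drop = FALSE]),
                 labels = as.integer(df$label),
                 center_signs = df$center_sign,
                 sigmas = df$sigma),
            class = "labeled_batch")
}

#' Bayes-optimal accuracy on the XOR-GMM task
#'
#' The Bayes rule classifies by the larger label-conditional mixture density;
#' for orthonormal means and isotropic noise it reduces to comparing
#' \eqn{|x\cdot\mu_1|} with \eqn{|x\cdot\mu_0|} (the rule is invariant under
#' \eqn{x \to -x}). The accuracy is estimated by Monte Carlo.
#'
#' @param task An `"xor_task"`.
#' @param sigma Noise standard deviation (> 0).
#' @param n_mc Number of Monte-Carlo trials.
#' @param seed Integer seed.
#' @return Estimated accuracy in `[0.5, 1]`.
#' @export
bayes_accuracy <- function(task, sigma, n_mc = 100000L, seed = 1L) {
  stopifnot(inherits(task, "xor_task"))
  if (sigma <= 0) stop("sigma must be positive")
  rng <- local_seed(seed)
  # only the projections onto mu0, mu1 matter
  y <- stats::rbinom(n_mc, 1L, 0.5)
  s <- sample(c(-1, 1), n_mc, replace = TRUE)
  p0 <- s * (y == 0) + sigma * stats::rnorm(n_mc)
  p1 <- s * (y == 1) + sigma * stats::rnorm(n_mc)
  mean((abs(p1) > abs(p0)) == (y == 1))
}

#' Bayes decision for explicit stimuli
#'
#' @param task An `"xor_task"`.
#' @param x A stimulus vector or an `n x d` matrix.
#' @return Predicted label(s) in \{0, 1\}.
#' @keywords internal
bayes_decision <- function(task, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  as.integer(abs(x %*% task$mu1) > abs(x %*% task$mu0))
}

# Seed the R RNG for the calling function, restoring the previous RNG state
# when that function exits.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  set.seed(seed)
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
  do.call(base::on.exit, list(as.call(list(restore)), TRUE, FALSE), envir = env)
  invisible(NULL)
}
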