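#' Curriculum schedules
#'
#' A curriculum schedule fixes, for every online training step
#' \eqn{t = 1 \dots T}, the stimulus noise level `sigma_t` and the probability
#' `p_first_t` that the trial is drawn from the curriculum's first feature
#' block (the cluster pair \eqn{\pm\mu_{first}}; only the bad curriculum uses
#' blocks, all other curricula have `p_first_t = 0.5` throughout, which
#' means unconstrained sampling from all four clusters).
#'
#' The four named curricula are:
#' \describe{
#'   \item{ascending}{difficulty rises from `sigma_easy` to `sigma_hard`;}
#'   \item{hard}{constant `sigma_hard`;}
#'   \item{random}{the ascending difficulty multiset in seeded random order;}
#'   \item{bad}{random difficulty order plus blocked feature exposure: the
#'     probability of the first cluster pair falls linearly from 1 to 0.}
#' }
#'
#' With `levels = L`, the schedule uses `L` discrete difficulty values held
#' constant over contiguous blocks of equal length (the difficulty staircase;
#' `random`/`bad` permute whole blocks). With `levels = NULL` the per-step
#' sequence is used (exact linear interpolation for `ascending`, a per-step
#' permutation for `random`/`bad`).
#'
#' @param T Number of online steps (\eqn{\ge 1}).
#' @param sigma_easy,sigma_hard Difficulty range, `sigma_easy <= sigma_hard`.
#' @param seed Integer seed for the permutation (`random`, `bad`).
#' @param levels Number of discrete difficulty levels, or `NULL`.
#' @return An object of class `"curriculum"`: list with `name`, `sigma_t`,
#'   `p_first_t`, `T`.
#' @examples
#' ascending_schedule(5, 0.1, 0.65)$sigma_t
#' bad_schedule(3, 0.1, 0.65, seed = 1)$p_first_t
#' @name schedules
NULL

new_curriculum <- function(name, sigma_t, p_first_t) {
  stopifnot(length(sigma_t) == length(p_first_t))
  structure(list(name = name, sigma_t = as.numeric(sigma_t),
                 p_first_t = as.numeric(p_first_t),
                 T = length(sigma_t)),
            class = "curriculum")
}

check_range <- function(T, sigma_easy, sigma_hard) {
  if (T < 1) stop("T must be >= 1")
  if (sigma_easy < 0) stop("sigma_easy must be non-negative")
  if (sigma_easy > sigma_hard) stop("sigma_easy must not exceed sigma_hard")
}

# the per-step ascending sequence, or the level staircase expanded to T steps
ascending_sigmas <- function(T, sigma_easy, sigma_hard, levels = NULL) {
  if (is.null(levels)) {
    if (T == 1L) return(sigma_hard)
    sigma_easy + (seq_len(T) - 1) / (T - 1) * (sigma_hard - sigma_easy)
  } else {
    levels <- as.integer(levels)
    stopifnot(levels >= 1, T %% levels == 0)
    vals <- if (levels == 1L) sigma_hard else
      sigma_easy + (seq_len(levels) - 1) / (levels - 1) * (sigma_hard - sigma_easy)
    rep(vals, each = T %/% levels)
  }
}

permuted_sigmas <- function(T, sigma_easy, sigma_hard, seed, levels = NULL) {
  base <- ascending_sigmas(T, sigma_easy, sigma_hard, levels)
  local_seed(seed)
  if (is.null(levels)) {
    base[sample.int(T)]
  } else {
    levels <- as.integer(levels)
    blk <- T %/% levels
    ord <- sample.int(levels)
    as.vector(vapply(ord, function(l) base[((l - 1) * blk + 1):(l * blk)],
                     numeric(blk)))
  }
}

#' @rdname schedules
#' @export
ascending_schedule <- function(T, sigma_easy = 0.1, sigma_hard = 0.65,
                               levels = NULL) {
  check_range(T, sigma_easy, sigma_hard)
  new_curriculum("ascending",
                 ascending_sigmas(as.integer(T), sigma_easy, sigma_hard, levels),
                 rep(0.5, T))
}

#' @rdname schedules
#' @export
hard_schedule <- function(T, sigma_hard = 0.65) {
  if (T < 1) stop("T must be >= 1")
  new_curriculum("hard", rep(sigma_hard, T), rep(0.5, T))
}

#' @rdname schedules
#' @export
random_schedule <- function(T, sigma_easy = 0.1, sigma_hard = 0.65,
                            seed = 1L, levels = NULL) {
  check_range(T, sigma_easy, sigma_hard)
  new_curriculum("random",
                 permuted_sigmas(as.integer(T), sigma_easy, sigma_hard, seed, levels),
                 rep(0.5, T))
}

#' @rdname schedules
#' @export
bad_schedule <- function(T, sigma_easy = 0.1, sigma_hard = 0.65,
                         seed = 1L, levels = NULL) {
  check_range(T, sigma_easy, sigma_hard)
  T <- as.integer(T)
  p <- if (T == 1L) 1 else 1 - (seq_len(T) - 1) / (T - 1)
  new_curriculum("bad",
                 permuted_sigmas(T, sigma_easy, sigma_hard, seed, levels),
                 p)
}

#' Build the schedule for a named curriculum
#'
#' Convenience dispatcher used by the population simulator: `T` is derived
#' from the training duration in time units (`T = round(time_units * d)`) and
#' `levels` defaults to one difficulty level per time unit.
#'
#' @param name One of `"ascending"`, `"hard"`, `"random"`, `"bad"`.
#' @param time_units Training duration in time units (steps / d).
#' @param d Input dimension.
#' @param sigma_easy,sigma_hard Difficulty range.
#' @param seed Seed for permuted schedules.
#' @param levels Number of difficulty levels (default: one per time unit).
#' @return A `"curriculum"`.
#' @export
build_schedule <- function(name, time_units, d, sigma_easy = 0.1,
                           sigma_hard = 0.65, seed = 1L,
                           levels = round(time_units)) {
  name <- match.arg(name, c("ascending", "hard", "random", "bad"))
  T <- as.integer(round(time_units * d))
  switch(name,
    ascending = ascending_schedule(T, sigma_easy, sigma_hard, levels),
    hard = hard_schedule(T, sigma_hard),
    random = random_schedule(T, sigma_easy, sigma_hard, seed, levels),
    bad = bad_schedule(T, sigma_easy, sigma_hard, seed, levels))
}

#' @export
print.curriculum <- function(x, ...) {
  cat(sprintf("%s curriculum: T = %d steps, sigma in [%g, %g]",
              x$name, x$T, min(x$sigma_t), max(x$sigma_t)))
  if (x$name == "bad")
    cat(sprintf(", block exposure ramp %g -> %g", x$p_first_t[1],
                x$p_first_t[x$T]))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.curriculum <- function(x, ...) {
  data.frame(step = seq_len(x$T), sigma = x$sigma_t, p_first = x$p_first_t)
}

#' Serialize a schedule to CSV (columns: step, sigma, p_first)
#' @param schedule A `"curriculum"`.
#' @param path File path.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.curriculum <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$sigma_t, type = "l", xlab = "step", ylab = "sigma",
                 main = paste(x$name, "curriculum"), ...)
  graphics::plot(x$p_first_t, type = "l", xlab = "step",
                 ylab = "P(first block)", ylim = c(0, 1))
  invisible(x)
}
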