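#' Simulation configuration for curriculum population runs
#'
#' Bundles the study conditions: network architecture, training schedule
#' parameters, evaluation sizes, and the integration engine.
#'
#' The `engine` selects how the online SGD dynamics are integrated (see the
#' package vignette for the derivation):
#' \describe{
#'   \item{`"meanfield"`}{deterministic order-parameter dynamics: per-step
#'     drift estimated from `gradient_samples` fresh stimuli, with the full
#'     second-order noise drift of the orthogonal weight Gram matrix.
#'     Stochasticity is confined to the initialization, matching an analytic
#'     population-dynamics treatment. Default.}
#'   \item{`"online"`}{the literal stochastic process: one stimulus per step.}
#' }
#'
#' `init_gram` chooses the geometry of the initial first-layer rows:
#' `"entrywise"` draws every weight entry N(0, `init_std`^2) (row norm
#' `init_std * sqrt(d)`); `"isotropic"` fixes the row component orthogonal to
#' the class means at norm `init_std` (the dimension-free reading, under
#' which the population statistics converge to a d-independent limit).
#'
#' @param curricula Character vector of curriculum names to simulate.
#' @param n_networks Networks per curriculum population.
#' @param d Input dimension.
#' @param K Hidden units.
#' @param init_std Weight initialization standard deviation.
#' @param eta Nominal learning rate; the per-step rate is `eta / d`.
#' @param time_units Training duration (time = steps / d).
#' @param sigma_easy,sigma_hard Difficulty range.
#' @param levels Number of discrete difficulty levels (default one per time
#'   unit; `NULL` for per-step schedules).
#' @param n_eval Fresh trials per per-unit training evaluation.
#' @param n_test Fresh hard test trials per network.
#' @param engine `"meanfield"` or `"online"`.
#' @param gradient_samples Stimuli per drift estimate (meanfield engine).
#' @param init_gram `"entrywise"` or `"isotropic"`.
#' @param bad_subsets `"cluster"` (feature blocks are the cluster pairs
#'   \eqn{\pm\mu_0} / \eqn{\pm\mu_1}) or `"sign"` (blocks are
#'   \eqn{\{+\mu_0,+\mu_1\}} / \eqn{\{-\mu_0,-\mu_1\}}).
#' @param per_network_order If `TRUE` (default), the random and bad curricula
#'   draw an independent difficulty-block order for every network (each
#'   network experiences its own random order, as when every simulation draws
#'   its own trial sequence); if `FALSE`, one shared permutation from the
#'   schedule seed is used for the whole population.
#' @param extension_units Checkpoints (in time units) for long-term hard
#'   training extensions.
#' @param master_seed Master seed; all per-network streams derive from it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(curricula = c("ascending", "hard", "random", "bad"),
                       n_networks = 10000L, d = 100L, K = 4L,
                       init_std = 0.05, eta = 10, time_units = 10,
                       sigma_easy = 0.1, sigma_hard = 0.65,
                       levels = round(time_units),
                       n_eval = 1000L, n_test = 10000L,
                       engine = c("meanfield", "online"),
                       gradient_samples = 128L,
                       init_gram = c("entrywise", "isotropic"),
                       bad_subsets = c("cluster", "sign"),
                       per_network_order = TRUE,
                       extension_units = c(100, 1000, 10000),
                       master_seed = 1L) {
  engine <- match.arg(engine)
  init_gram <- match.arg(init_gram)
  bad_subsets <- match.arg(bad_subsets)
  curricula <- match.arg(curricula, c("ascending", "hard", "random", "bad"),
                         several.ok = TRUE)
  cfg <- list(curricula = curricula, n_networks = as.integer(n_networks),
              d = as.integer(d), K = as.integer(K), init_std = init_std,
              eta = eta, time_units = time_units, sigma_easy = sigma_easy,
              sigma_hard = sigma_hard, levels = levels,
              n_eval = as.integer(n_eval), n_test = as.integer(n_test),
              engine = engine, gradient_samples = as.integer(gradient_samples),
              init_gram = init_gram, bad_subsets = bad_subsets,
              per_network_order = isTRUE(per_network_order),
              extension_units = extension_units,
              master_seed = as.numeric(master_seed))
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_networks < 1) stop("n_networks must be positive")
    if (d < K + 3) stop("d must be at least K + 3")
    if (init_std <= 0) stop("init_std must be positive")
    if (eta < 0) stop("eta must be non-negative")
    if (time_units <= 0) stop("time_units must be positive")
    if (round(time_units * d) < 1) stop("time_units * d must round to >= 1")
    if (sigma_easy < 0 || sigma_easy > sigma_hard)
      stop("need 0 <= sigma_easy <= sigma_hard")
    if (any(extension_units < 0)) stop("extension_units must be non-negative")
  })
  invisible(cfg)
}

# deterministic seed derivation (Lehmer step); exact in double arithmetic
derive_seed <- function(master, salt) {
  (master * 48271 + salt * 2246822519) %% 2147483647
}

curriculum_index <- function(name)
  match(name, c("ascending", "hard", "random", "bad"))

# build the schedule a config implies for one curriculum
config_schedule <- function(cfg, name) {
  build_schedule(name, cfg$time_units, cfg$d, cfg$sigma_easy, cfg$sigma_hard,
                 seed = derive_seed(cfg$master_seed, 101),
                 levels = cfg$levels)
}

#' Train one network through a curriculum (reference implementation)
#'
#' A plain-R online SGD loop: at every step one stimulus is drawn from the
#' schedule's current difficulty and feature-block distribution and a single
#' [sgd_step()] is applied. At the end of each time unit (every `d` steps) the
#' network is evaluated on `n_eval` fresh trials whose difficulty and block
#' membership are drawn from that unit's schedule entries; after training it
#' is evaluated on `n_test` fresh hard test trials.
#'
#' This is the exact object-level process; [run_population()] integrates the
#' same dynamics in reduced coordinates and is the production path.
#'
#' @param task An `"xor_task"`.
#' @param schedule A `"curriculum"` whose length matches
#'   `round(time_units * d)`.
#' @param config A `"sim_config"`.
#' @param seed Per-network seed.
#' @return A list of class `"trajectory_record"`: `seed_id`,
#'   `train_acc_per_unit`, `final_train_acc`, `test_acc`, `net`, `first`.
#' @export
train_network <- function(task, schedule, config, seed = 1L) {
  stopifnot(inherits(task, "xor_task"), inherits(schedule, "curriculum"))
  d <- task$d
  T <- schedule$T
  if (T != round(config$time_units * d))
    stop("schedule length does not match time_units * d")
  units <- T %/% d
  eta_step <- config$eta / d
  local_seed(seed)
  net <- list(W1 = matrix(stats::rnorm(config$K * d, 0, config$init_std),
                          config$K, d),
              w2 = stats::rnorm(config$K, 0, config$init_std),
              K = config$K, d = d)
  class(net) <- "xor_net"
  first <- if (stats::runif(1) < 0.5) 0L else 1L
  bad <- schedule$name == "bad"
  train_acc <- numeric(units)
  u <- 0L
  for (t in seq_len(T)) {
    tr <- draw_trial(task, schedule$sigma_t[t], schedule$p_first_t[t],
                     bad, config$bad_subsets, first)
    if (config$eta > 0)
      net <- sgd_step(net, tr$x, tr$y, eta_step)
    if (t %% d == 0L) {
      u <- u + 1L
      idx <- sample((t - d + 1L):t, config$n_eval, replace = TRUE)
      train_acc[u] <- eval_trials(net, task, schedule$sigma_t[idx],
                                  schedule$p_first_t[idx], bad,
                                  config$bad_subsets, first)
    }
  }
  test_acc <- eval_trials(net, task, rep(config$sigma_hard, config$n_test),
                          rep(0.5, config$n_test), FALSE, config$bad_subsets,
                          first)
  structure(list(seed_id = seed, train_acc_per_unit = train_acc,
                 final_train_acc = train_acc[units], test_acc = test_acc,
                 net = net, first = first),
            class = "trajectory_record")
}

# one training stimulus under the schedule's current conditions
draw_trial <- function(task, sigma, p_first, bad, bad_subsets, first) {
  if (bad && bad_subsets == "cluster") {
    y <- if (stats::runif(1) < p_first) first else 1L - first
    s <- sample(c(-1, 1), 1L)
  } else if (bad && bad_subsets == "sign") {
    y <- stats::rbinom(1L, 1L, 0.5)
    sf <- if (first == 0L) 1 else -1
    s <- if (stats::runif(1) < p_first) sf else -sf
  } else {
    y <- stats::rbinom(1L, 1L, 0.5)
    s <- sample(c(-1, 1), 1L)
  }
  mu <- if (y == 0L) task$mu0 else task$mu1
  list(x = s * mu + sigma * stats::rnorm(task$d), y = y)
}

eval_trials <- function(net, task, sigmas, p_firsts, bad, bad_subsets, first) {
  n <- length(sigmas)
  if (bad && bad_subsets == "cluster") {
    y <- ifelse(stats::runif(n) < p_firsts, first, 1L - first)
    s <- sample(c(-1, 1), n, replace = TRUE)
  } else if (bad && bad_subsets == "sign") {
    y <- stats::rbinom(n, 1L, 0.5)
    sf <- if (first == 0L) 1 else -1
    s <- ifelse(stats::runif(n) < p_firsts, sf, -sf)
  } else {
    y <- stats::rbinom(n, 1L, 0.5)
    s <- sample(c(-1, 1), n, replace = TRUE)
  }
  X <- matrix(stats::rnorm(n * task$d), n, task$d) * sigmas
  X <- X + outer(s * (y == 0), task$mu0) + outer(s * (y == 1), task$mu1)
  f <- net_logits(net, X)
  dec <- ifelse(f > 0, 1L, ifelse(f < 0, 0L, -1L))
  mean(dec == y)
}

#' Run a population of networks through one curriculum
#'
#' Trains `config$n_networks` independently initialized networks through the
#' curriculum's schedule using the reduced-coordinate engine (see
#' [sim_config()] for the engine choices), records per-time-unit training
#' accuracy and the final hard-test accuracy, and keeps the terminal network
#' state for long-term extensions.
#'
#' Per-network randomness derives from `(master seed, seed id)` streams, so
#' results are independent of execution order.
#'
#' @param config A `"sim_config"`.
#' @param curriculum Curriculum name, or a `"curriculum"` object whose length
#'   equals `round(time_units * d)`.
#' @return An object of class `"curriculum_population"`: list with
#'   `curriculum`, `config`, `schedule`, `records` (data frame with
#'   `seed_id`, per-unit training accuracies, `final_train_acc`, `test_acc`),
#'   and the terminal `state`.
#' @export
run_population <- function(config, curriculum = "ascending") {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(curriculum, "curriculum")) {
    schedule <- curriculum
    name <- schedule$name
  } else {
    name <- match.arg(curriculum, c("ascending", "hard", "random", "bad"))
    schedule <- config_schedule(config, name)
  }
  if (schedule$T != round(config$time_units * config$d))
    stop("schedule length does not match time_units * d")
  bmode <- if (name == "bad") {
    if (config$bad_subsets == "cluster") 1L else 2L
  } else 0L
  pop_seed <- derive_seed(config$master_seed, curriculum_index(name))
  ids <- seq_len(config$n_networks)
  # per-network difficulty orders permute the ascending staircase's blocks
  shuffle <- 0L
  sigma_base <- schedule$sigma_t
  if (config$per_network_order && name %in% c("random", "bad") &&
      !is.null(config$levels)) {
    shuffle <- as.integer(config$levels)
    sigma_base <- ascending_sigmas(schedule$T, config$sigma_easy,
                                   config$sigma_hard, config$levels)
  }
  res <- cpp_population(config$n_networks, config$d, config$K,
                        config$init_std, config$init_std, config$eta,
                        sigma_base, schedule$p_first_t, bmode,
                        config$n_eval, config$n_test, config$sigma_hard,
                        pop_seed, ids,
                        gram = if (config$init_gram == "entrywise") 0L else 1L,
                        B = if (config$engine == "online") 1L
                            else config$gradient_samples,
                        mf = config$engine == "meanfield",
                        shuffle_blocks = shuffle)
  units <- ncol(res$train_acc)
  rec <- data.frame(seed_id = ids, res$train_acc)
  names(rec)[-1L] <- paste0("train_acc_u", seq_len(units))
  rec$final_train_acc <- res$train_acc[, units]
  rec$test_acc <- res$test_acc
  structure(list(curriculum = name, config = config, schedule = schedule,
                 records = rec,
                 state = list(M = res$M, w2 = res$w2, Q = res$Q,
                              first = res$first, seed_ids = ids,
                              pop_seed = pop_seed)),
            class = "curriculum_population")
}

#' @export
print.curriculum_population <- function(x, ...) {
  cat(sprintf("curriculum population: %s, %d networks (engine %s, d = %d)\n",
              x$curriculum, nrow(x$records), x$config$engine, x$config$d))
  cat(sprintf("  mean final-unit training accuracy %.3f, mean test accuracy %.3f\n",
              mean(x$records$final_train_acc), mean(x$records$test_acc)))
  invisible(x)
}

#' @export
summary.curriculum_population <- function(object, threshold = 0.65, ...) {
  r <- object$records
  out <- list(curriculum = object$curriculum,
              n = nrow(r),
              mean_train = mean(r$final_train_acc),
              sd_train = stats::sd(r$final_train_acc),
              mean_test = mean(r$test_acc),
              sd_test = stats::sd(r$test_acc),
              prop_above_train = mean(r$final_train_acc > threshold),
              prop_above_test = mean(r$test_acc > threshold),
              threshold = threshold)
  class(out) <- "summary.curriculum_population"
  out
}

#' @export
print.summary.curriculum_population <- function(x, ...) {
  cat(sprintf("%s curriculum (n = %d)\n", x$curriculum, x$n))
  cat(sprintf("  final training: mean %.3f (sd %.3f), %.2f%% above %.0f%%\n",
              x$mean_train, x$sd_train, 100 * x$prop_above_train,
              100 * x$threshold))
  cat(sprintf("  hard test:      mean %.3f (sd %.3f), %.2f%% above %.0f%%\n",
              x$mean_test, x$sd_test, 100 * x$prop_above_test,
              100 * x$threshold))
  invisible(x)
}

#' @export
plot.curriculum_population <- function(x, threshold = 0.65, ...) {
  r <- x$records
  units <- sum(grepl("^train_acc_u", names(r)))
  tr <- as.matrix(r[, paste0("train_acc_u", seq_len(units))])
  hi <- r$final_train_acc > threshold
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  show <- sample(nrow(tr), min(100, nrow(tr)))
  graphics::matplot(t(tr[show, , drop = FALSE]),
                    type = "l", lty = 1,
                    col = grDevices::adjustcolor(
                      ifelse(hi[show], "darkcyan", "firebrick"), 0.3),
                    xlab = "time unit", ylab = "training accuracy",
                    main = paste(x$curriculum, "trajectories"), ylim = c(0, 1))
  graphics::abline(h = threshold, lty = 2)
  graphics::hist(r$test_acc, breaks = 30, xlab = "test accuracy",
                 main = "hard-test distribution", xlim = c(0, 1))
  graphics::abline(v = threshold, lty = 2)
  invisible(x)
}

#' Continue training a population on hard trials
#'
#' Resumes online SGD at `sigma_hard` with unconstrained cluster sampling
#' from the stored terminal state, evaluating fresh hard-test accuracy at each
#' checkpoint.
#'
#' @param pop A `"curriculum_population"`.
#' @param extra_units Non-negative checkpoints in time units (cumulative).
#' @param n_test Test trials per checkpoint (default from config).
#' @param stride Integration stride in steps (the per-step rate is scaled by
#'   `stride`, trading resolution for speed on very long extensions).
#' @param gradient_samples Stimuli per drift estimate; defaults to the
#'   config's value for the meanfield engine, 1 for online.
#' @return Matrix `n_networks x length(extra_units)` of test accuracies,
#'   with the checkpoints as column names.
#' @export
extend_on_hard <- function(pop, extra_units = pop$config$extension_units,
                           n_test = pop$config$n_test, stride = 1L,
                           gradient_samples = NULL) {
  stopifnot(inherits(pop, "curriculum_population"))
  if (any(extra_units < 0)) stop("extra_units must be non-negative")
  if (is.unsorted(extra_units)) stop("extra_units must be non-decreasing")
  cfg <- pop$config
  B <- if (!is.null(gradient_samples)) as.integer(gradient_samples)
       else if (cfg$engine == "online") 1L else cfg$gradient_samples
  st <- pop$state
  out <- cpp_extend(st$M, st$w2, st$Q, st$first, cfg$d, cfg$K, cfg$eta,
                    cfg$sigma_hard, as.numeric(extra_units),
                    as.integer(n_test), st$pop_seed, st$seed_ids,
                    B = B, mf = cfg$engine == "meanfield",
                    stride = as.integer(stride))
  colnames(out) <- paste0("plus_", extra_units)
  out
}

#' Run all configured curricula
#'
#' @param config A `"sim_config"`.
#' @return A named list of `"curriculum_population"` objects, class
#'   `"curriculum_study"`.
#' @export
run_study <- function(config) {
  pops <- lapply(config$curricula, function(cur) run_population(config, cur))
  names(pops) <- config$curricula
  structure(pops, class = "curriculum_study")
}

#' @export
print.curriculum_study <- function(x, ...) {
  for (p in x) print(p)
  invisible(x)
}

#' Write population records to CSV and a JSON run manifest
#'
#' @param pop A `"curriculum_population"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the CSV path.
#' @export
write_population_csv <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0("population_", pop$curriculum, ".csv"))
  utils::write.csv(pop$records, path, row.names = FALSE)
  invisible(path)
}
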