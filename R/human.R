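#' Counterbalanced RDK curriculum design for one synthetic participant
#'
#' Builds the trial table of the matched human experiment: a random-dot
#' kinematogram task in which the correct key depends on the conjunction of
#' majority motion direction (up/down) and majority color (blue/yellow)
#' through an XOR rule. 100 training trials are followed by 16 test trials.
#'
#' Difficulty is manipulated through motion coherence (0.40--1.00); color
#' coherence (0.66--1.00) is counterbalanced across trials but never
#' curriculum-structured. Curricula order the motion coherences: ascending
#' decreases linearly from 1.00 to 0.40, hard stays at 0.40, random permutes
#' the ascending values, and bad uses the permuted values while blocking the
#' feature pairings: trials come from a subset that holds one feature value
#' constant (e.g. yellow-up / yellow-down), with the probability of the first
#' subset falling linearly from 1 to 0 across training. The identity of the
#' first subset and the response-key mapping are counterbalanced across
#' participants. Test trials are all at motion coherence 0.40 with every
#' pairing crossed with every color-coherence level.
#'
#' @param curriculum One of `"ascending"`, `"hard"`, `"random"`, `"bad"`.
#' @param participant_id Positive integer; drives counterbalancing.
#' @param seed Integer seed for trial-order randomization.
#' @param n_train,n_test Trial counts.
#' @param coh_range Motion-coherence range.
#' @param color_levels Color-coherence levels (counterbalanced).
#' @return An object of class `"human_design"`: list with `curriculum`,
#'   `participant_id`, `response_mapping`, `subset_first`, `trials` (data
#'   frame with columns `phase`, `index`, `motion_coherence`, `motion_sign`,
#'   `color_coherence`, `color_sign`, `pairing`, `correct_response`), and
#'   `render_meta` (600 dots, radius 2 px, 1 px/frame).
#' @export
design_experiment <- function(curriculum, participant_id = 1L, seed = 1L,
                              n_train = 100L, n_test = 16L,
                              coh_range = c(0.40, 1.00),
                              color_levels = seq(0.66, 1.00, length.out = 4)) {
  curriculum <- match.arg(curriculum, c("ascending", "hard", "random", "bad"))
  stopifnot(participant_id >= 1, n_train >= 2, n_test >= 4)
  local_seed(seed)
  pairings <- data.frame(
    pairing = c("blue-up", "blue-down", "yellow-up", "yellow-down"),
    color_sign = c(1, 1, -1, -1),
    motion_sign = c(1, -1, 1, -1))
  # one-feature-constant subsets, rotated across participants
  subsets <- list(yellow = c("yellow-up", "yellow-down"),
                  blue = c("blue-up", "blue-down"),
                  up = c("blue-up", "yellow-up"),
                  down = c("blue-down", "yellow-down"))
  complement <- c(yellow = "blue", blue = "yellow", up = "down", down = "up")
  subset_first <- names(subsets)[(participant_id - 1L) %% 4L + 1L]
  # response mapping counterbalanced across participants:
  # XOR product +1 (blue-up, yellow-down) -> 'F' or 'J'
  mapping_F_positive <- (participant_id %% 2L) == 1L

  asc_coh <- seq(coh_range[2], coh_range[1], length.out = n_train)
  motion_coh <- switch(curriculum,
    ascending = asc_coh,
    hard = rep(coh_range[1], n_train),
    random = sample(asc_coh),
    bad = sample(asc_coh))
  if (curriculum == "bad") {
    p_first <- 1 - (seq_len(n_train) - 1) / (n_train - 1)
    from_first <- stats::runif(n_train) < p_first
    second <- complement[[subset_first]]
    pair_seq <- ifelse(from_first,
                       sample(subsets[[subset_first]], n_train, replace = TRUE),
                       sample(subsets[[second]], n_train, replace = TRUE))
  } else {
    pair_seq <- sample(rep(pairings$pairing, length.out = n_train))
  }
  color_coh <- sample(rep(color_levels, length.out = n_train))
  train <- data.frame(phase = "train", index = seq_len(n_train),
                      motion_coherence = motion_coh,
                      color_coherence = color_coh,
                      pairing = pair_seq, stringsAsFactors = FALSE)
  # test: hard motion coherence, pairings crossed with color levels
  grid <- expand.grid(pairing = pairings$pairing, color_coherence = color_levels,
                      stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), length.out = n_test), ]
  grid <- grid[sample(nrow(grid)), ]
  test <- data.frame(phase = "test", index = seq_len(n_test),
                     motion_coherence = coh_range[1],
                     color_coherence = grid$color_coherence,
                     pairing = grid$pairing, stringsAsFactors = FALSE)
  trials <- rbind(train, test)
  m <- match(trials$pairing, pairings$pairing)
  trials$color_sign <- pairings$color_sign[m]
  trials$motion_sign <- pairings$motion_sign[m]
  xor_positive <- trials$color_sign * trials$motion_sign > 0
  trials$correct_response <- ifelse(xor_positive == mapping_F_positive, "F", "J")
  structure(list(curriculum = curriculum,
                 participant_id = as.integer(participant_id),
                 response_mapping = if (mapping_F_positive) "F-positive"
                                    else "J-positive",
                 subset_first = subset_first,
                 trials = trials,
                 render_meta = list(n_dots = 600L, dot_radius_px = 2L,
                                    speed_px_per_frame = 1L),
                 seed = seed),
            class = "human_design")
}

#' @export
print.human_design <- function(x, ...) {
  cat(sprintf("RDK design: %s curriculum, participant %d, %d train + %d test trials\n",
              x$curriculum, x$participant_id,
              sum(x$trials$phase == "train"), sum(x$trials$phase == "test")))
  cat(sprintf("  response mapping %s; bad-curriculum first subset: %s\n",
              x$response_mapping, x$subset_first))
  invisible(x)
}

#' Default synthetic-responder parameters
#'
#' The responder is the package's own parsimonious network with a
#' two-dimensional input (signed motion and color evidence) plus perceptual
#' noise `nu` and a lapse rate `lapse`; `eta_step` is the per-trial learning
#' rate and `init_std` the weight initialization scale. The defaults are
#' chosen so that the four simulated arms reproduce the qualitative human
#' pattern (ascending best, bad worst, random and hard in between, with an
#' ascending-minus-bad test accuracy gap of roughly 0.09 at 50 participants
#' per arm).
#'
#' @return Named list of responder parameters.
#' @export
default_learner <- function() {
  list(nu = 0.15, lapse = 0.02, eta_step = 0.8, init_std = 0.02, K = 4L)
}

#' Simulate one synthetic participant on a design
#'
#' Each trial is encoded as the 2-d stimulus
#' `(motion_sign * motion_coherence, color_sign * color_coherence)` plus
#' isotropic Gaussian perceptual noise `nu`. The responder is a `K`-unit
#' bias-free ReLU network trained online (binary cross-entropy) on every
#' training trial; no updates occur during test. A zero logit (network
#' abstention) is resolved by a fair guess -- participants must answer.
#' The lapse rate `lapse` (in `[0, 0.5]`) sets the accuracy ceiling
#' `1 - lapse` in the standard psychometric parametrization: a trial lapses
#' with probability `2 * lapse` and receives a fair guess, so `lapse = 0.5`
#' yields chance responding on every trial regardless of the design.
#'
#' @param design A `"human_design"`.
#' @param learner Responder parameters, see [default_learner()]; optional
#'   elements `W1` (`K x 2`) and `w2` inject pre-trained weights.
#' @param seed Integer seed.
#' @return Integer 0/1 vector of per-trial correctness (train then test),
#'   with the trial table as attribute `"trials"`.
#' @export
simulate_participant <- function(design, learner = default_learner(),
                                 seed = 1L) {
  stopifnot(inherits(design, "human_design"))
  if (learner$lapse < 0 || learner$lapse > 0.5) stop("lapse must be in [0, 0.5]")
  if (learner$nu < 0) stop("nu must be non-negative")
  local_seed(seed)
  tr <- design$trials
  K <- learner$K
  if (!is.null(learner$W1)) {   # pre-trained weights injected
    W1 <- learner$W1
    w2 <- learner$w2
    K <- nrow(W1)
  } else {
    W1 <- matrix(stats::rnorm(K * 2, 0, learner$init_std), K, 2)
    w2 <- stats::rnorm(K, 0, learner$init_std)
  }
  n <- nrow(tr)
  # hoist trial columns and pre-draw the per-trial noise
  x1 <- tr$motion_sign * tr$motion_coherence
  x2 <- tr$color_sign * tr$color_coherence
  g1 <- learner$nu * stats::rnorm(n)
  g2 <- learner$nu * stats::rnorm(n)
  guesses <- sample(0:1, n, replace = TRUE)
  lapses <- stats::runif(n) < 2 * learner$lapse
  lapse_resp <- sample(0:1, n, replace = TRUE)
  is_train <- tr$phase == "train"
  y_all <- as.integer(tr$color_sign * tr$motion_sign > 0)
  eta <- learner$eta_step
  correct <- integer(n)
  for (i in seq_len(n)) {
    xa <- x1[i] + g1[i]; xb <- x2[i] + g2[i]
    pre <- W1[, 1L] * xa + W1[, 2L] * xb
    gate <- pre > 0
    h <- ifelse(gate, pre, 0)
    f <- sum(w2 * h)
    resp <- if (f > 0) 1L else if (f < 0) 0L else
      guesses[i]  # must answer: abstention becomes a guess
    if (lapses[i]) resp <- lapse_resp[i]
    y <- y_all[i]
    correct[i] <- as.integer(resp == y)
    if (is_train[i]) {
      delta <- 1 / (1 + exp(-f)) - y
      c_k <- eta * delta * w2 * gate
      W1[, 1L] <- W1[, 1L] - c_k * xa
      W1[, 2L] <- W1[, 2L] - c_k * xb
      w2 <- w2 - eta * delta * h
    }
  }
  attr(correct, "trials") <- tr
  correct
}

#' Generate a full synthetic four-arm study
#'
#' Participants are assigned to the four curricula in rotation
#' (`n_per_curriculum` each), with response mappings and bad-curriculum
#' subsets counterbalanced by participant number; every participant receives
#' an individually randomized design and an independent responder, all
#' deterministically derived from `master_seed`.
#'
#' @param n_per_curriculum Participants per curriculum.
#' @param learner Responder parameters ([default_learner()]).
#' @param master_seed Master seed.
#' @return An object of class `"human_study"`: list with `data` (data frame:
#'   `participant`, `curriculum`, `phase`, `trial`, `bin`, `correct`),
#'   `learner`, `master_seed`, and `n_per_curriculum`.
#' @export
generate_study <- function(n_per_curriculum = 50L,
                           learner = default_learner(), master_seed = 1L) {
  if (n_per_curriculum < 1) stop("n_per_curriculum must be >= 1")
  curricula <- c("ascending", "hard", "random", "bad")
  rows <- vector("list", 4L * n_per_curriculum)
  pid <- 0L
  for (i in seq_len(n_per_curriculum)) {
    for (cur in curricula) {
      pid <- pid + 1L
      dseed <- derive_seed(master_seed, 2L * pid)
      rseed <- derive_seed(master_seed, 2L * pid + 1L)
      des <- design_experiment(cur, participant_id = pid, seed = dseed)
      cr <- simulate_participant(des, learner, seed = rseed)
      tr <- attr(cr, "trials")
      rows[[pid]] <- data.frame(
        participant = pid, curriculum = cur, phase = tr$phase,
        trial = tr$index,
        bin = ifelse(tr$phase == "train", (tr$index - 1L) %/% 20L + 1L,
                     NA_integer_),
        correct = as.integer(cr), stringsAsFactors = FALSE)
    }
  }
  structure(list(data = do.call(rbind, rows), learner = learner,
                 master_seed = master_seed,
                 n_per_curriculum = as.integer(n_per_curriculum)),
            class = "human_study")
}

#' @export
print.human_study <- function(x, ...) {
  d <- x$data
  cat(sprintf("synthetic RDK study: %d participants (%d per curriculum), %d trials each\n",
              length(unique(d$participant)), x$n_per_curriculum,
              nrow(d) / length(unique(d$participant))))
  te <- d[d$phase == "test", ]
  agg <- tapply(te$correct, te$curriculum, mean)
  cat("  mean test accuracy by curriculum:\n")
  for (nm in names(agg)) cat(sprintf("    %-10s %.3f\n", nm, agg[[nm]]))
  invisible(x)
}

#' Analyze a human-format study
#'
#' Runs the human-side pipeline: per-participant test accuracy, binned
#' training trajectories (bins of `bin_size` trials), the 65%-threshold
#' achiever split per curriculum (final training bin vs test), and all
#' pairwise logistic contrasts on the test-phase trials.
#'
#' @param study A `"human_study"` or a data frame in the same per-trial
#'   format (`participant`, `curriculum`, `phase`, `trial`, `correct`).
#' @param bin_size Training bin width.
#' @param threshold Achiever threshold.
#' @return List with `participant_summary`, `binned` (mean accuracy per
#'   curriculum and bin), `achievers` (per curriculum), `contrasts`.
#' @export
analyze_human_study <- function(study, bin_size = 20L, threshold = 0.65) {
  d <- if (inherits(study, "human_study")) study$data else study
  stopifnot(all(c("participant", "curriculum", "phase", "trial", "correct")
                %in% names(d)))
  tr <- d[d$phase == "train", ]
  te <- d[d$phase == "test", ]
  ps <- do.call(rbind, lapply(split(d, d$participant), function(pd) {
    ptr <- pd[pd$phase == "train", ]
    ptr <- ptr[order(ptr$trial), ]
    bins <- bin_trajectory(ptr$correct, bin_size)
    data.frame(participant = pd$participant[1],
               curriculum = pd$curriculum[1],
               final_train_acc = bins[length(bins)],
               test_acc = mean(pd$correct[pd$phase == "test"]),
               stringsAsFactors = FALSE)
  }))
  rownames(ps) <- NULL
  binned <- do.call(rbind, lapply(split(tr, tr$curriculum), function(cd) {
    bybin <- tapply(cd$correct, (cd$trial - 1L) %/% bin_size + 1L, mean)
    data.frame(curriculum = cd$curriculum[1], bin = as.integer(names(bybin)),
               accuracy = as.numeric(bybin), stringsAsFactors = FALSE)
  }))
  rownames(binned) <- NULL
  achievers <- lapply(split(ps, ps$curriculum), function(g)
    achiever_split(g$final_train_acc, g$test_acc, threshold))
  contrasts <- pairwise_logistic_contrasts(te)
  list(participant_summary = ps, binned = binned, achievers = achievers,
       contrasts = contrasts)
}

#' Write a study to CSV with a JSON design sidecar
#'
#' @param study A `"human_study"`.
#' @param dir Output directory.
#' @return Invisibly, the CSV path.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "human_study.csv")
  utils::write.csv(study$data, path, row.names = FALSE)
  meta <- list(n_per_curriculum = study$n_per_curriculum,
               learner = study$learner, master_seed = study$master_seed)
  jsonlite::write_json(meta, file.path(dir, "human_study_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a participant-level trial CSV
#'
#' Optional loader for externally collected data in the same schema
#' (`participant`, `curriculum`, `phase`, `trial`, `correct`); the result can
#' be passed to [analyze_human_study()].
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_participant_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "curriculum", "phase", "trial", "correct")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  d
}
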