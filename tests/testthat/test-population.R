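test_that("the R reference trainer is deterministic and inert at eta = 0", {
  cfg <- small_config(n_networks = 1L, eta = 0)
  task <- make_task(cfg$d, canonical = TRUE)
  sch <- build_schedule("ascending", cfg$time_units, cfg$d)
  rec <- train_network(task, sch, cfg, seed = 5)
  # no learning: weights equal their initialization
  ref <- init_network(cfg$K, cfg$d, cfg$init_std, seed = 5)
  expect_identical(rec$net$W1, ref$W1)
  expect_identical(rec$net$w2, ref$w2)
  # chance level including abstentions
  expect_gt(rec$test_acc, 0.38)
  expect_lt(rec$test_acc, 0.56)

  cfg2 <- small_config(n_networks = 1L)
  r1 <- train_network(task, sch, cfg2, seed = 11)
  r2 <- train_network(task, sch, cfg2, seed = 11)
  expect_identical(r1$train_acc_per_unit, r2$train_acc_per_unit)
  expect_identical(r1$test_acc, r2$test_acc)
  expect_identical(r1$net$W1, r2$net$W1)
  expect_true(all(r1$train_acc_per_unit >= 0 & r1$train_acc_per_unit <= 1))
})

test_that("train_network rejects a schedule of the wrong length", {
  cfg <- small_config()
  task <- make_task(cfg$d, canonical = TRUE)
  expect_error(train_network(task, ascending_schedule(50), cfg), "length")
})

test_that("population runs are reproducible and order-independent", {
  cfg <- small_config(n_networks = 40L)
  p1 <- run_population(cfg, "ascending")
  p2 <- run_population(cfg, "ascending")
  expect_identical(p1$records, p2$records)
  expect_equal(nrow(p1$records), 40)
  expect_false(any(duplicated(p1$records$seed_id)))
  acc <- unlist(p1$records[, grep("acc", names(p1$records))])
  expect_true(all(acc >= 0 & acc <= 1))

  # a singleton population reproduces the first network of a larger one
  # (per-seed substreams are independent of population size)
  cfg1 <- small_config(n_networks = 1L)
  s1 <- run_population(cfg1, "ascending")
  expect_equal(s1$records$test_acc, p1$records$test_acc[1])
})

test_that("reduced-coordinate online engine matches the full-dimensional
           reference trainer in distribution", {
  cfg_r <- small_config(n_networks = 40L, engine = "online", n_test = 400L)
  task <- make_task(cfg_r$d, canonical = TRUE)
  sch <- build_schedule("ascending", cfg_r$time_units, cfg_r$d,
                        levels = cfg_r$levels)
  accs_R <- vapply(1:40, function(s)
    train_network(task, sch, cfg_r, seed = s)$test_acc, numeric(1))
  cfg_c <- small_config(n_networks = 400L, engine = "online", n_test = 400L)
  pop <- run_population(cfg_c, "ascending")
  accs_C <- pop$records$test_acc
  se <- sqrt(stats::var(accs_R) / 40 + stats::var(accs_C) / 400)
  expect_lt(abs(mean(accs_R) - mean(accs_C)), 3 * se + 1e-3)
})

test_that("exact replay of the update rule matches the R implementation", {
  net <- init_network(4, 12, 0.05, seed = 3)
  set.seed(4)
  X <- matrix(stats::rnorm(80 * 12), 80, 12)
  y <- stats::rbinom(80, 1, 0.5)
  netR <- net
  for (i in 1:80) netR <- sgd_step(netR, X[i, ], y[i], 0.25)
  cp <- curricsim:::cpp_sgd_path(net$W1, net$w2, X, y, 0.25)
  expect_equal(unname(netR$W1), unname(cp$W1), tolerance = 1e-13)
  expect_equal(unname(netR$w2), unname(cp$w2), tolerance = 1e-13)
})

test_that("hard training from scratch stays below the ascending curriculum", {
  cfg <- small_config(n_networks = 100L, d = 50L)
  a <- run_population(cfg, "ascending")
  h <- run_population(cfg, "hard")
  expect_gt(mean(a$records$test_acc), mean(h$records$test_acc))
})

test_that("no network beats the Bayes bound and extensions resume cleanly", {
  cfg <- small_config(n_networks = 60L, d = 50L, n_test = 2000L)
  task <- make_task(cfg$d, canonical = TRUE)
  bay <- bayes_accuracy(task, cfg$sigma_hard, 200000, seed = 1)
  pop <- run_population(cfg, "ascending")
  se <- binom_se(bay, cfg$n_test)
  expect_lt(max(pop$records$test_acc), bay + 3 * se + 0.01)

  # a zero-length extension re-measures the same accuracy on a fresh batch
  e0 <- extend_on_hard(pop, extra_units = 0, n_test = 2000L)
  diffs <- abs(e0[, 1] - pop$records$test_acc)
  tol <- 2 * sqrt(2 * 0.25 / 2000)
  expect_lt(mean(diffs > tol), 0.1)
  # continued hard training changes accuracy and stays in range
  e1 <- extend_on_hard(pop, extra_units = c(5, 10), n_test = 1000L)
  expect_equal(dim(e1), c(60L, 2L))
  expect_true(all(e1 >= 0 & e1 <= 1))
})

test_that("the bad curriculum dissociates training from test accuracy", {
  cfg <- small_config(n_networks = 300L, d = 50L, n_test = 1000L,
                      n_eval = 500L)
  bad <- run_population(cfg, "bad")
  asc <- run_population(cfg, "ascending")
  gap_bad <- mean(bad$records$final_train_acc) - mean(bad$records$test_acc)
  gap_asc <- abs(mean(asc$records$final_train_acc) -
                 mean(asc$records$test_acc))
  expect_gte(gap_bad, 0.2)
  expect_lte(gap_asc, 0.1)
})

test_that("config validation fails closed", {
  expect_error(sim_config(n_networks = 0), "positive")
  expect_error(sim_config(d = 5), "at least")
  expect_error(sim_config(sigma_easy = 0.9), "sigma_easy")
  expect_error(sim_config(init_std = -1), "positive")
})
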