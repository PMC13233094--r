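test_that("initialization is seeded and matches the Gaussian moments", {
  n1 <- init_network(4, 100, 0.05, seed = 42)
  n2 <- init_network(4, 100, 0.05, seed = 42)
  expect_identical(n1$W1, n2$W1)
  expect_identical(n1$w2, n2$w2)
  big <- init_network(8, 12500, 0.05, seed = 1)  # 1e5 entries
  w <- c(big$W1)
  expect_lt(abs(mean(w)), 3 * 0.05 / sqrt(1e5))
  expect_lt(abs(stats::sd(w) / 0.05 - 1), 0.02)
  expect_error(init_network(4, 100, 0), "positive")
})

test_that("forward pass evaluates the hand example and the abstention cases", {
  net <- structure(list(W1 = rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
                        w2 = c(1, 1, -1, -1), K = 4L, d = 2L),
                   class = "xor_net")
  out <- forward(net, c(2, 0))
  expect_equal(out$logit, 2)
  expect_equal(out$decision, "label1")

  zero_out <- net; zero_out$w2 <- rep(0, 4)
  expect_equal(forward(zero_out, c(0.3, -0.7))$decision, "abstain")

  # all units dead: W1 x <= 0 elementwise gives an exact zero logit
  dead <- structure(list(W1 = rbind(c(1, 0), c(0.5, 0.5)), w2 = c(1, 2),
                         K = 2L, d = 2L), class = "xor_net")
  out_dead <- forward(dead, c(-1, -1))
  expect_identical(out_dead$logit, 0)
  expect_equal(out_dead$decision, "abstain")
  expect_error(forward(net, c(1, 2, 3)), "length")
})

test_that("the ReLU layer is positively scale-covariant", {
  net <- init_network(4, 10, 0.05, seed = 3)
  x <- stats::rnorm(10)
  for (c in c(0.5, 2, 7)) {
    expect_equal(forward(net, c * x)$logit, c * forward(net, x)$logit,
                 tolerance = 1e-12)
  }
})

test_that("the analytic SGD gradient matches central finite differences", {
  set.seed(1)
  eps <- 1e-6
  worst <- 0
  for (trial in 1:100) {
    d <- sample(3:8, 1)
    K <- sample(2:5, 1)
    net <- init_network(K, d, 0.5, seed = trial)
    x <- stats::rnorm(d)
    y <- stats::rbinom(1, 1, 0.5)
    eta <- 0.01
    upd <- sgd_step(net, x, y, eta)
    gW1 <- (net$W1 - upd$W1) / eta
    gw2 <- (net$w2 - upd$w2) / eta
    num_grad <- function(get, set) {
      v0 <- get(net)
      g <- array(0, dim = dim(as.matrix(v0)))
      for (i in seq_along(v0)) {
        vp <- v0; vp[i] <- vp[i] + eps
        vm <- v0; vm[i] <- vm[i] - eps
        g[i] <- (curricsim:::bce_loss(set(net, vp), x, y) -
                 curricsim:::bce_loss(set(net, vm), x, y)) / (2 * eps)
      }
      g
    }
    nW1 <- num_grad(function(n) n$W1, function(n, v) { n$W1 <- matrix(v, K, d); n })
    nw2 <- num_grad(function(n) n$w2, function(n, v) { n$w2 <- c(v); n })
    denom <- max(1e-8, max(abs(nW1)), max(abs(nw2)))
    worst <- max(worst, max(abs(gW1 - nW1)) / denom,
                 max(abs(c(gw2) - c(nw2))) / denom)
  }
  expect_lt(worst, 1e-5)
})

test_that("closed ReLU gates freeze their rows and saturation freezes all", {
  net <- init_network(3, 4, 0.05, seed = 9)
  x <- c(1, 0, 0, 0)
  pre <- drop(net$W1 %*% x)
  upd <- sgd_step(net, x, 1, 0.1)
  for (k in which(pre < 0)) expect_identical(upd$W1[k, ], net$W1[k, ])

  # saturated loss: y = 1 with a very large positive logit
  sat <- structure(list(W1 = matrix(c(50, 0, 0, 50), 2, 2), w2 = c(5, 5),
                        K = 2L, d = 2L), class = "xor_net")
  x2 <- c(1, 1)
  upd2 <- sgd_step(sat, x2, 1, 0.1)
  delta_norm <- sqrt(sum((upd2$W1 - sat$W1)^2) + sum((upd2$w2 - sat$w2)^2))
  expect_lt(delta_norm, 1e-6 * 0.1 * sqrt(sum(x2^2)))
  expect_error(sgd_step(net, x, 2, 0.1), "0 or 1")
})

test_that("freezing the readout layer leaves it untouched", {
  net <- init_network(4, 6, 0.05, seed = 2)
  x <- stats::rnorm(6)
  upd <- sgd_step(net, x, 0, 0.5, freeze_w2 = TRUE)
  expect_identical(upd$w2, net$w2)
  expect_false(identical(upd$W1, net$W1))
})

test_that("accuracy counts abstentions as incorrect", {
  task <- make_task(6, canonical = TRUE)
  batch <- sample_batch(task, 0.3, 200, seed = 4)
  allzero <- init_network(4, 6, 0.05, seed = 1)
  allzero$w2 <- rep(0, 4)
  expect_equal(accuracy(allzero, batch), 0)

  sol <- xor_solution(task)
  easy <- sample_batch(task, 0.01, 2000, seed = 5)
  expect_gt(accuracy(sol, easy), 0.99)

  rnd <- init_network(4, 6, 0.05, seed = 8)
  hard <- sample_batch(task, 0.65, 10000, seed = 6)
  expect_lte(accuracy(rnd, hard), 0.55)
})

test_that("the hand-built solution implements the Bayes rule", {
  task <- make_task(30, seed = 5)
  sol <- xor_solution(task)
  batch <- sample_batch(task, 0.3, 20000, seed = 7)
  acc <- accuracy(sol, batch)
  bay <- bayes_accuracy(task, 0.3, 200000, seed = 8)
  se <- sqrt(acc * (1 - acc) * (1 / 20000 + 1 / 200000))
  expect_lt(abs(acc - bay), 2 * se + 1e-3)
  # decisions agree with the likelihood-ratio rule trial by trial
  pred <- predict(sol, batch)
  bd <- bayes_decision(task, batch$inputs)
  ok <- !is.na(pred)
  expect_true(all(pred[ok] == bd[ok]))
})

test_that("online SGD decreases prequential cross-entropy", {
  # 100 seeded runs of 1000 steps at sigma = 0.3 in a convergent-rate
  # regime: mean loss over the last 100 steps is below the first 100
  d <- 20
  task <- make_task(d, canonical = TRUE)
  first_mean <- last_mean <- numeric(100)
  for (r in 1:100) {
    set.seed(1000 + r)
    net <- init_network(4, d, 0.05, seed = 2000 + r)
    losses <- numeric(1000)
    for (t in 1:1000) {
      y <- stats::rbinom(1, 1, 0.5)
      s <- sample(c(-1, 1), 1)
      x <- s * (if (y == 0) task$mu0 else task$mu1) + 0.3 * stats::rnorm(d)
      losses[t] <- curricsim:::bce_loss(net, x, y)
      net <- sgd_step(net, x, y, 0.1)
    }
    first_mean[r] <- mean(losses[1:100])
    last_mean[r] <- mean(losses[901:1000])
  }
  expect_lt(mean(last_mean), mean(first_mean))
})

test_that("network weights round-trip through the JSON checkpoint", {
  net <- init_network(4, 7, 0.05, seed = 13)
  path <- tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$W1, net$W1, tolerance = 1e-14)
  expect_equal(back$w2, net$w2, tolerance = 1e-14)
  x <- stats::rnorm(7)
  expect_equal(forward(back, x)$logit, forward(net, x)$logit)
})
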