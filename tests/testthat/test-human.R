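test_that("designs have the right trial structure per curriculum", {
  d <- design_experiment("ascending", 1, seed = 2)
  tr <- d$trials[d$trials$phase == "train", ]
  te <- d$trials[d$trials$phase == "test", ]
  expect_equal(nrow(tr), 100)
  expect_equal(nrow(te), 16)
  expect_equal(tr$motion_coherence[1], 1.00)
  expect_equal(tr$motion_coherence[100], 0.40)
  expect_lt(max(abs(diff(diff(tr$motion_coherence)))), 1e-12)  # linear

  h <- design_experiment("hard", 2, seed = 3)
  expect_true(all(h$trials$motion_coherence[h$trials$phase == "train"] == 0.40))

  r <- design_experiment("random", 3, seed = 4)
  rtr <- r$trials[r$trials$phase == "train", ]
  expect_equal(sort(rtr$motion_coherence), sort(tr$motion_coherence))
  expect_false(identical(rtr$motion_coherence, tr$motion_coherence))
})

test_that("the XOR response rule holds on every trial of every design", {
  for (cur in c("ascending", "hard", "random", "bad")) {
    for (pid in 1:4) {
      des <- design_experiment(cur, pid, seed = pid * 10)
      t <- des$trials
      prod_sign <- t$motion_sign * t$color_sign
      keys <- t$correct_response
      # same-product pairings share a key; opposite products differ
      expect_equal(length(unique(keys[prod_sign > 0])), 1)
      expect_equal(length(unique(keys[prod_sign < 0])), 1)
      expect_false(unique(keys[prod_sign > 0]) == unique(keys[prod_sign < 0]))
      expect_true(all(t$motion_coherence >= 0.40 & t$motion_coherence <= 1))
      expect_true(all(t$color_coherence >= 0.66 & t$color_coherence <= 1))
    }
  }
})

test_that("test trials are uniformly hard with counterbalanced pairings", {
  des <- design_experiment("ascending", 5, seed = 6)
  te <- des$trials[des$trials$phase == "test", ]
  expect_true(all(te$motion_coherence == 0.40))
  expect_equal(as.integer(table(te$pairing)), rep(4L, 4))
})

test_that("bad designs expose the first subset early and the second late", {
  frac_first <- function(des) {
    tr <- des$trials[des$trials$phase == "train", ]
    sub <- des$subset_first
    in_first <- switch(sub,
      yellow = tr$color_sign == -1, blue = tr$color_sign == 1,
      up = tr$motion_sign == 1, down = tr$motion_sign == -1)
    c(head = mean(in_first[1:20]), tail = mean(in_first[81:100]))
  }
  gaps <- vapply(1:12, function(i) {
    f <- frac_first(design_experiment("bad", i, seed = 100 + i))
    f["head"] - f["tail"]
  }, numeric(1))
  expect_gte(mean(gaps), 0.6)
  # subsets rotate over participants
  subs <- vapply(1:4, function(i)
    design_experiment("bad", i, seed = 1)$subset_first, character(1))
  expect_equal(sort(subs), c("blue", "down", "up", "yellow"))
})

test_that("a full-lapse responder guesses and an oracle responder is perfect", {
  des <- design_experiment("ascending", 1, seed = 7)
  guess <- default_learner(); guess$lapse <- 0.5
  accs <- vapply(1:30, function(s)
    mean(simulate_participant(des, guess, seed = s)), numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.03)

  # noiseless responder with an injected XOR solution answers every trial:
  # rows +-(1,1) with positive readout fire on product-positive pairings,
  # rows +-(1,-1) with negative readout on the rest
  oracle <- default_learner(); oracle$nu <- 0; oracle$lapse <- 0
  oracle$W1 <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  oracle$w2 <- c(1, 1, -1, -1)
  cr <- simulate_participant(des, oracle, seed = 1)
  te_idx <- attr(cr, "trials")$phase == "test"
  expect_equal(mean(cr[te_idx]), 1.0)
  expect_error(simulate_participant(des, within(default_learner(),
                                                lapse <- 0.7)), "lapse")
})

test_that("study generation is deterministic with the documented shape", {
  s1 <- generate_study(1, master_seed = 5)
  expect_equal(nrow(s1$data), 4 * 116)
  expect_equal(sort(unique(s1$data$curriculum)),
               c("ascending", "bad", "hard", "random"))
  s50 <- generate_study(3, master_seed = 5)
  expect_equal(length(unique(s50$data$participant)), 12)
  s1b <- generate_study(1, master_seed = 5)
  expect_identical(s1$data, s1b$data)
  s1c <- generate_study(1, master_seed = 6)
  expect_false(identical(s1$data, s1c$data))
  # bins label consecutive 20-trial groups of the training phase
  tr <- s1$data[s1$data$phase == "train" & s1$data$participant == 1, ]
  expect_equal(unique(tr$bin), 1:5)
  expect_true(all(is.na(s1$data$bin[s1$data$phase == "test"])))
})

test_that("ascending outperforms bad for the synthetic responder", {
  stu <- generate_study(50, master_seed = 77)
  te <- stu$data[stu$data$phase == "test", ]
  m <- tapply(te$correct, te$curriculum, mean)
  n <- sum(te$curriculum == "ascending")
  se <- sqrt(2 * 0.25 / n)
  expect_gt(m[["ascending"]] - m[["bad"]], 2 * se)
})

test_that("the analysis pipeline closes end-to-end on generated data", {
  stu <- generate_study(5, master_seed = 12)
  an <- analyze_human_study(stu)
  expect_equal(nrow(an$participant_summary), 20)
  expect_equal(nrow(an$contrasts), 6)
  expect_true(all(c("ascending", "bad", "hard", "random") %in%
                  names(an$achievers)))
  expect_true(all(an$binned$accuracy >= 0 & an$binned$accuracy <= 1))
  # round-trip through the external CSV schema
  dir <- tempfile(); dir.create(dir)
  write_study_csv(stu, dir)
  back <- read_participant_csv(file.path(dir, "human_study.csv"))
  an2 <- analyze_human_study(back)
  expect_equal(an2$contrasts$beta, an$contrasts$beta, tolerance = 1e-12)
})
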