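test_that("drug-centric seeds split eta / (1-eta) over the drug and its diseases", {
  net <- association_network(c("c1", "c2"), c("d1", "d2", "d3"),
                             rbind(c(1, 1, 0), c(0, 0, 0)))
  p0 <- initial_drug_centric(1, net, eta = 0.4)
  expect_equal(unname(p0), c(0.4, 0, 0.3, 0.3, 0))
  expect_equal(sum(p0), 1)
  # eta = 1: all mass on the drug regardless of associations
  expect_equal(unname(initial_drug_centric(1, net, eta = 1)),
               c(1, 0, 0, 0, 0))
  # a drug with no known disease still seeds a unit vector
  expect_equal(unname(initial_drug_centric(2, net, eta = 0.4)),
               c(0, 1, 0, 0, 0))
  expect_error(initial_drug_centric(3, net), "out of range")
})

test_that("disease-centric seeds mirror the drug-centric construction", {
  net <- association_network(c("c1", "c2", "c3", "c4"), c("d1", "d2"),
                             rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 0)))
  p0 <- initial_disease_centric(1, net, eta = 0.4)
  expect_equal(unname(p0), c(0.2, 0.2, 0.2, 0, 0.4, 0))
  expect_equal(unname(initial_disease_centric(1, net, eta = 0)),
               c(1/3, 1/3, 1/3, 0, 0, 0))
  expect_equal(unname(initial_disease_centric(2, net, eta = 0.4)),
               c(0, 0, 0, 0, 0, 1))
  # swap symmetry: on a mirror-image network the disease-centric seed is the
  # block-swapped drug-centric seed
  A <- rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0))
  mirror <- association_network(c("c1", "c2", "c3"), c("d1", "d2", "d3"), A)
  pd <- initial_disease_centric(1, mirror, eta = 0.4)
  pc <- initial_drug_centric(1, mirror, eta = 0.4)
  expect_equal(unname(pd), unname(c(pc[4:6], pc[1:3])))
})

test_that("alpha = 1 returns the restart distribution after one step", {
  rt <- random_transition(seed = 7)
  p0 <- initial_drug_centric(2, rt$fx$net, 0.4)
  r <- rwr(rt$T, p0, alpha = 1)
  expect_equal(r$n_iter, 1)
  expect_equal(r$p, p0)
})

test_that("the iteration matches the closed-form linear solve", {
  for (s in 1:10) {
    rt <- random_transition(seed = 500 + s)
    p0 <- initial_drug_centric(1 + (s %% 10), rt$fx$net, 0.4)
    r <- rwr(rt$T, p0, alpha = 0.3, epsilon = 1e-10)
    expect_lt(max(abs(r$p - rwr_closed_form(rt$T, p0, 0.3))), 1e-8)
    expect_true(all(r$p >= 0))
    expect_equal(sum(r$p), 1, tolerance = 1e-8)
  }
})

test_that("the fixed point is independent of where the iteration starts", {
  rt <- random_transition(seed = 13)
  p0 <- initial_disease_centric(3, rt$fx$net, 0.4)
  ref <- rwr(rt$T, p0, alpha = 0.3)$p
  # same restart vector, uniform starting state: same steady state
  tT <- t(as.matrix(rt$T$matrix))
  p <- rep(1 / length(p0), length(p0))
  for (i in 1:2000) {
    p_new <- as.numeric(0.7 * (tT %*% p)) + 0.3 * p0
    if (sum(abs(p_new - p)) < 1e-12) break
    p <- p_new
  }
  expect_lt(max(abs(p - ref)), 1e-8)
})

test_that("non-convergence inside max_iter is an error with the residual", {
  rt <- random_transition(seed = 21)
  p0 <- initial_drug_centric(1, rt$fx$net, 0.4)
  expect_error(rwr(rt$T, p0, alpha = 0.01, epsilon = 1e-10, max_iter = 3L),
               "did not converge")
  expect_error(rwr(rt$T, p0 * 2), "summing to 1")
})

test_that("score_pair refuses known associations and averages the two passes", {
  rt <- random_transition(seed = 31)
  net <- rt$fx$net
  cfg <- walk_config(seed = 31)
  edge <- which(net$adjacency == 1, arr.ind = TRUE)[1, ]
  expect_error(score_pair(edge[1], edge[2], rt$T, net, cfg), "not a candidate")
  cand <- which(net$adjacency == 0, arr.ind = TRUE)[3, ]
  s <- score_pair(cand[1], cand[2], rt$T, net, cfg)
  expect_equal(s$mean_prob,
               (s$drug_centric_prob + s$disease_centric_prob) / 2)
  expect_true(s$mean_prob >= min(s$drug_centric_prob, s$disease_centric_prob))
  expect_true(s$mean_prob <= max(s$drug_centric_prob, s$disease_centric_prob))
})

test_that("score_all reuses one walk per node and agrees with score_pair", {
  rt <- random_transition(seed = 37)
  net <- rt$fx$net
  cfg <- walk_config(seed = 37)
  tab <- score_all(net, rt$T, cfg)
  n <- length(net$drug_ids); m <- length(net$disease_ids)
  expect_equal(attr(tab, "n_walks"), n + m)
  expect_equal(nrow(tab), sum(net$adjacency == 0))
  expect_equal(sort(tab$rank), seq_len(nrow(tab)))
  expect_equal(tab$mean_prob,
               (tab$drug_centric_prob + tab$disease_centric_prob) / 2)
  # scores are cached steady states, identical to per-pair evaluation
  cand <- which(net$adjacency == 0, arr.ind = TRUE)
  for (k in c(1, 11, 29)) {
    s <- score_pair(cand[k, 1], cand[k, 2], rt$T, net, cfg)
    row <- tab[tab$drug_id == net$drug_ids[cand[k, 1]] &
               tab$disease_id == net$disease_ids[cand[k, 2]], ]
    expect_equal(row$mean_prob, s$mean_prob, tolerance = 1e-14)
    expect_equal(row$drug_centric_prob, s$drug_centric_prob, tolerance = 1e-14)
  }
  # restricting candidates changes rows, not values
  sub <- score_all(net, rt$T, cfg,
                   candidates = tab[5:8, c("drug_id", "disease_id")])
  expect_equal(sort(sub$mean_prob), sort(tab$mean_prob[5:8]), tolerance = 1e-14)
})

test_that("a mirror-symmetric network gives equal drug- and disease-centric scores", {
  # square symmetric adjacency and identical intra-layer similarities make
  # the two layers exact mirror images; for the pair (i, i) the two passes
  # coincide
  A <- rbind(c(0, 1, 1, 0), c(1, 0, 0, 1), c(1, 0, 0, 0), c(0, 1, 0, 0))
  net <- association_network(paste0("c", 1:4), paste0("d", 1:4), A)
  W <- withr::with_seed(8, matrix(stats::runif(16, 0.1, 1), 4, 4))
  W <- (W + t(W)) / 2
  sim <- similarity_matrix(paste0("c", 1:4), pmin(W, 1), TRUE)
  simd <- similarity_matrix(paste0("d", 1:4), pmin(W, 1), TRUE)
  T <- build_transition(sim, simd, net, 0.8)
  cfg <- walk_config()
  for (i in 1:4) {
    s <- score_pair(i, i, T, net, cfg)
    expect_equal(s$drug_centric_prob, s$disease_centric_prob,
                 tolerance = 1e-12)
  }
})

test_that("steady-state mass is conserved, and leaks only at zero rows", {
  rt <- random_transition(seed = 41)
  expect_equal(assert_stochastic(rt$T), character(0))
  p0 <- initial_drug_centric(4, rt$fx$net, 0.4)
  expect_equal(sum(rwr(rt$T, p0)$p), 1, tolerance = 1e-8)
  # an absorbing zero row can only lose mass
  net <- association_network(c("c1", "c2", "c3"), c("d1", "d2"),
                             rbind(c(1, 1), c(1, 0), c(0, 0)))
  wc <- similarity_matrix(net$drug_ids,
                          rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)), FALSE)
  wd <- similarity_matrix(net$disease_ids, rbind(c(0, 1), c(1, 0)), TRUE)
  T <- build_transition(wc, wd, net, 0.8)
  p <- rwr(T, initial_drug_centric(1, net, 0.4))$p
  expect_lte(sum(p), 1 + 1e-12)
})

test_that("dense and sparse transition storage walk to the same fixed point", {
  rt <- random_transition(seed = 55)
  sparse <- rt$T
  sparse$matrix <- methods::as(rt$T$matrix, "CsparseMatrix")
  p0 <- initial_drug_centric(2, rt$fx$net, 0.4)
  expect_lt(max(abs(rwr(rt$T, p0)$p - rwr(sparse, p0)$p)), 1e-12)
})

test_that("within-block candidates outrank between-block candidates", {
  deltas <- vapply(1:20, function(s) {
    fx <- simulate_fixture(14, 12, 2, 0.7, 0.05, 64, 0.05, seed = 700 + s)
    tab <- suppressWarnings(
      predict_indications(fx$net, fx$fingerprints, fx$concepts,
                          walk_config(seed = s)))
    blk_c <- fx$drug_blocks[match(tab$drug_id, fx$net$drug_ids)]
    blk_d <- fx$disease_blocks[match(tab$disease_id, fx$net$disease_ids)]
    mean(tab$rank[blk_c == blk_d]) - mean(tab$rank[blk_c != blk_d])
  }, numeric(1))
  expect_true(all(deltas < 0))   # smaller rank = better
})
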