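test_that("binarize applies the >= rule elementwise", {
  sc <- matrix(c(0.3, 0.5, 0.7, 0.2), 2, 2,
               dimnames = list(c("t1", "t2"), c("m1", "m2")))
  taus <- c(m1 = 0.5, m2 = 0.5)
  v <- binarize(sc, taus)
  # a score exactly at the threshold votes 1
  expect_equal(v["t2", "m1"], 1L)
  expect_equal(as.vector(v), c(0L, 1L, 1L, 0L))
  # all-zero scores with positive thresholds vote 0
  expect_true(all(binarize(matrix(0, 2, 2, dimnames = dimnames(sc)),
                           taus) == 0L))
  expect_error(binarize(sc, c(m1 = 0.5)), "m2")
  # random matrix against a scalar loop oracle
  set.seed(20)
  sc2 <- matrix(runif(300), 50, 6,
                dimnames = list(sprintf("t%02d", 1:50), sprintf("m%d", 1:6)))
  tv <- stats::setNames(runif(6), colnames(sc2))
  v2 <- binarize(sc2, tv)
  for (i in 1:50) for (j in 1:6)
    expect_equal(v2[i, j], as.integer(sc2[i, j] >= tv[j]))
})

test_that("majority vote follows the strict rule and breaks ties deterministically", {
  mk <- function(vote_sums, n, scores_mean, tau_mean = 0.5) {
    votes <- t(vapply(vote_sums, function(k) rep(c(1L, 0L), c(k, n - k)),
                      integer(n)))
    rownames(votes) <- sprintf("t%d", seq_along(vote_sums))
    colnames(votes) <- sprintf("m%d", 1:n)
    attr(votes, "taus") <- rep(tau_mean, n)
    scores <- matrix(scores_mean, nrow = length(vote_sums), ncol = n,
                     dimnames = dimnames(votes))
    list(votes = votes, scores = scores)
  }
  x <- mk(c(6, 0, 10), 10, 0.5)
  mv <- majority_vote(x$votes, x$scores)
  expect_equal(mv$predicted_label, c(1L, 0L, 1L))
  expect_false(any(mv$tie_flag))
  expect_equal(mv$self_agreement, c(6L, 10L, 10L))
  # tie at 5/10: mean score below mean tau -> 0; at/above -> 1
  lo <- mk(5, 10, 0.4); hi <- mk(5, 10, 0.5)
  mvlo <- majority_vote(lo$votes, lo$scores)
  mvhi <- majority_vote(hi$votes, hi$scores)
  expect_true(mvlo$tie_flag && mvhi$tie_flag)
  expect_equal(mvlo$predicted_label, 0L)
  expect_equal(mvhi$predicted_label, 1L)
  # model reordering leaves the decision unchanged
  set.seed(21)
  v <- matrix(rbinom(200, 1, 0.5), 20, 10,
              dimnames = list(sprintf("t%d", 1:20), sprintf("m%d", 1:10)))
  attr(v, "taus") <- runif(10)
  s <- matrix(runif(200), 20, 10, dimnames = dimnames(v))
  perm <- sample(10)
  vp <- v[, perm]; attr(vp, "taus") <- attr(v, "taus")[perm]
  expect_equal(majority_vote(v, s)$predicted_label,
               majority_vote(vp, s[, perm])$predicted_label)
})

test_that("agreement counts votes for the true class", {
  lab <- make_labels(3); lab$l <- c(1L, 0L, 0L)
  votes <- rbind(rep(1L, 10), rep(0L, 10), rep(c(1L, 0L), c(7, 3)))
  rownames(votes) <- lab$tile_id
  colnames(votes) <- sprintf("m%d", 1:10)
  a <- agreement(votes, lab)
  expect_equal(unname(a), c(10L, 10L, 3L))
  # bounds and the complement identity on random instances
  set.seed(22)
  for (rep in 1:30) {
    n <- sample(c(5, 10), 1)
    m <- 50
    lab2 <- make_labels(m, runif(1, 0.2, 0.8))
    v <- matrix(rbinom(m * n, 1, runif(1, 0.2, 0.8)), m, n,
                dimnames = list(lab2$tile_id, sprintf("m%d", 1:n)))
    a2 <- agreement(v, lab2)
    expect_true(all(a2 >= 0 & a2 <= n))
    # per-tile loop oracle
    for (i in seq_len(m)) {
      want <- if (lab2$l[i] == 1) sum(v[i, ]) else n - sum(v[i, ])
      expect_equal(unname(a2[i]), want)
    }
    wrong <- ifelse(lab2$l == 1, n - rowSums(v), rowSums(v))
    expect_true(all(a2 + wrong == n))
  }
  expect_error(agreement(votes, make_labels(2)), "missing")
})

test_that("closed-form ensemble success matches enumeration and hand values", {
  expect_equal(ensemble_success_probability(5, 1), 1)
  expect_equal(ensemble_success_probability(3, 0.8), 0.896)
  expect_equal(ensemble_success_probability(10, 0.8),
               oracle_majority_success(10, 0.8), tolerance = 1e-12)
})

test_that("ensemble success is monotone in p and in T for odd ensembles", {
  ps <- seq(0.55, 0.95, by = 0.05)
  for (T in c(3, 5, 7, 9)) {
    pe <- ensemble_success_probability(T, ps)
    expect_true(all(pe > ps))            # gain over a single voter
    expect_true(all(diff(pe) > 0))       # increasing in p
    pe_next <- ensemble_success_probability(T + 2, ps)
    expect_true(all(pe_next >= pe))      # larger odd ensembles do better
  }
  # p = 0.5 is the neutral point for odd T
  expect_equal(ensemble_success_probability(7, 0.5), 0.5)
})

test_that("verify_theory reconciles simulation with the closed form", {
  rep <- verify_theory(make_specs(10, p_correct = 0.8), tiles = 20000,
                       seed = 23)
  expect_true(rep$within_3se)
  expect_gt(rep$empirical_majority_success, rep$mean_single_accuracy)
  # p = 0.5: no ensemble gain
  rep2 <- verify_theory(make_specs(9, p_correct = 0.5), tiles = 20000,
                        seed = 24)
  expect_lt(abs(rep2$empirical_majority_success - 0.5),
            3 * sqrt(0.25 / 20000) + 0.01)
  # correlated voters fall below the independent prediction
  rep3 <- verify_theory(make_specs(10, p_correct = 0.7, rho = 0.9),
                        tiles = 20000, seed = 25)
  expect_lt(rep3$empirical_majority_success,
            rep3$predicted_success - 3 * rep3$mc_se)
})

test_that("majority-vote accuracy equals the agreement cutoff rule without ties", {
  set.seed(26)
  lab <- make_labels(500, 0.4)
  sc <- simulate_scores(lab, make_specs(9, p_correct = 0.75), seed = 27)
  tv <- stats::setNames(rep(0.5, 9), colnames(sc))
  votes <- binarize(sc, tv)
  res <- ensemble_result(votes, sc, lab)
  expect_false(any(res$tie_flag))   # odd n: ties impossible
  acc <- mean(res$predicted_label == lab$l)
  expect_equal(acc, mean(res$agreement >= 5))
})
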