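# helper: single-stratum plan with the given division layout
flat_plan <- function(wsi_ids, divisions) {
  data.frame(wsi_id = wsi_ids, split = "train", division = divisions,
             stringsAsFactors = FALSE)
}

# labels spread over `ndiv` single-WSI divisions
div_labels <- function(n, ndiv, positive_fraction = 0.5) {
  lab <- make_labels(n, positive_fraction)
  lab$wsi_id <- sprintf("w%02d", rep_len(seq_len(ndiv), n))
  lab
}

test_that("dice_score matches hand values and the confusion oracle", {
  expect_equal(dice_score(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(dice_score(c(1, 1, 1, 0, 1), c(1, 1, 1, 1, 0)), 0.75)
  expect_equal(dice_score(c(0, 0), c(0, 0)), 1)   # no positives anywhere
  expect_error(dice_score(c(1, 0), c(1)), "length")
  set.seed(10)
  for (rep in 1:50) {
    pred <- rbinom(200, 1, runif(1, 0.1, 0.9))
    truth <- rbinom(200, 1, runif(1, 0.1, 0.9))
    expect_equal(dice_score(pred, truth), oracle_dice(pred, truth))
  }
})

test_that("perfectly separating scores give the gap-midpoint threshold", {
  lab <- div_labels(40, 2)
  sc <- ifelse(lab$l == 1, 0.8, 0.2)
  names(sc) <- lab$tile_id
  res <- calibrate_threshold(sc, lab, flat_plan(c("w01", "w02"), 1:2),
                             own_division = 1)
  # only out-of-division tiles (w02) are pooled; gap midpoint = 0.5
  expect_equal(res$tau, 0.5)
  expect_equal(res$dice, 1)
  expect_equal(res$n_tiles, 20)
})

test_that("identical scores degenerate to the endpoint candidates", {
  lab <- div_labels(10, 2, positive_fraction = 0.6)
  sc <- rep(0.4, 10); names(sc) <- lab$tile_id
  res <- calibrate_threshold(sc, lab, flat_plan(c("w01", "w02"), 1:2), 1)
  # predicting everything positive beats predicting nothing when positives
  # exist; smallest optimal candidate is 0
  expect_equal(res$tau, 0)
  expect_equal(res$dice, dice_score(rep(1, res$n_tiles),
                                    lab$l[lab$wsi_id == "w02"]))
})

test_that("returned threshold maximises pooled Dice over all candidates", {
  set.seed(11)
  for (rep in 1:30) {
    lab <- div_labels(60, 3)
    sc <- runif(60); names(sc) <- lab$tile_id
    plan <- flat_plan(c("w01", "w02", "w03"), 1:3)
    res <- calibrate_threshold(sc, lab, plan, own_division = 1)
    pool <- lab$wsi_id != "w01"
    cand <- threshold_candidates(sc[lab$tile_id[pool]])
    dices <- vapply(cand, function(t)
      dice_score(as.integer(sc[lab$tile_id[pool]] >= t), lab$l[pool]),
      numeric(1))
    expect_true(res$tau %in% cand)
    expect_equal(res$dice, max(dices))
    # tie-break to the smallest optimal candidate
    expect_equal(res$tau, cand[which(dices == max(dices))[1]])
  }
})

test_that("midpoint search is equivalent to a dense threshold grid", {
  set.seed(12)
  grid <- seq(0, 1, by = 1e-3)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    lab <- div_labels(n, 2, positive_fraction = runif(1, 0.2, 0.8))
    sc <- round(runif(n), 2); names(sc) <- lab$tile_id
    plan <- flat_plan(c("w01", "w02"), 1:2)
    res <- calibrate_threshold(sc, lab, plan, own_division = 1)
    pool <- lab$wsi_id == "w02"
    best_dense <- max(vapply(grid, function(t)
      dice_score(as.integer(sc[lab$tile_id[pool]] >= t), lab$l[pool]),
      numeric(1)))
    expect_equal(res$dice, best_dense)
  }
})

test_that("calibration recovers a planted optimal threshold", {
  lab <- div_labels(10000, 10)
  plan <- flat_plan(sprintf("w%02d", 1:10), 1:10)
  for (tau_star in c(0.2, 0.3, 0.5, 0.7)) {
    sp <- sim_model_spec("m1", p_correct = 0.95, true_threshold = tau_star)
    sc <- simulate_scores(lab, list(sp), seed = round(tau_star * 100))[, 1]
    res <- calibrate_threshold(sc, lab, plan, own_division = 1)
    expect_lt(abs(res$tau - tau_star), 0.05)
  }
})

test_that("calibration never sees the model's own division or the test set", {
  lab <- div_labels(30, 3)
  plan <- flat_plan(c("w01", "w02", "w03"), c(1, 2, NA))
  plan$split[3] <- "test"
  sc <- runif(30); names(sc) <- lab$tile_id
  res <- calibrate_threshold(sc, lab, plan, own_division = 1)
  expect_equal(res$n_tiles, sum(lab$wsi_id == "w02"))
  # a single-division plan leaves nothing to calibrate on
  expect_error(
    calibrate_threshold(sc, lab, flat_plan(c("w01", "w02", "w03"),
                                           c(1, 1, 1)), 1),
    "no tiles")
})

test_that("threshold vectors round-trip through JSON", {
  lab <- div_labels(200, 4)
  plan <- flat_plan(sprintf("w%02d", 1:4), 1:4)
  sc <- simulate_scores(lab, make_specs(3, tau = 0.4), seed = 6)
  taus <- calibrate_thresholds(sc, lab, plan, model_divisions = c(1, 2, 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_thresholds(taus, f)
  got <- read_thresholds(f)
  expect_equal(got$tau, taus$tau)
  expect_equal(got$model_id, taus$model_id)
})
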