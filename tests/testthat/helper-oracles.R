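# Independent oracles, deliberately implemented apart from the package:
# scalar crossing-number point-in-polygon, loop-based confusion counting,
# and exhaustive vote enumeration.

# classic crossing-number test for ONE point and one ring (scalar loop);
# boundary points are resolved by an explicit on-segment check
oracle_point_in_ring <- function(x, y, ring) {
  rx <- ring[, 1]; ry <- ring[, 2]
  n <- nrow(ring)
  if (rx[n] == rx[1] && ry[n] == ry[1]) { rx <- rx[-n]; ry <- ry[-n]; n <- n - 1 }
  on_seg <- function(ax, ay, bx, by) {
    cr <- (x - ax) * (by - ay) - (y - ay) * (bx - ax)
    abs(cr) < 1e-9 && x >= min(ax, bx) - 1e-9 && x <= max(ax, bx) + 1e-9 &&
      y >= min(ay, by) - 1e-9 && y <= max(ay, by) + 1e-9
  }
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    if (on_seg(rx[j], ry[j], rx[i], ry[i])) return(TRUE)
    if ((ry[i] > y) != (ry[j] > y)) {
      xint <- rx[i] + (y - ry[i]) * (rx[j] - rx[i]) / (ry[j] - ry[i])
      if (x < xint) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# per-element confusion counting by explicit loop
oracle_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    else fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_dice <- function(pred, truth) {
  cc <- oracle_confusion(pred, truth)
  d <- 2 * cc[["tp"]] + cc[["fp"]] + cc[["fn"]]
  if (d == 0) 1 else 2 * cc[["tp"]] / d
}

# exhaustive enumeration of all 2^T vote outcomes: probability that a
# strict majority of independent Bernoulli(p) voters is correct
oracle_majority_success <- function(T, p) {
  total <- 0
  for (m in 0:(2^T - 1)) {
    bits <- as.integer(intToBits(m))[1:T]
    k <- sum(bits)
    if (k > T / 2) total <- total + p^k * (1 - p)^(T - k)
  }
  total
}

# a random simple star-shaped ring around a center (for property tests)
random_star_ring <- function(cx, cy, rmin, rmax, n_angles = 8) {
  r <- runif(n_angles, rmin, rmax)
  th <- sort(runif(n_angles, 0, 2 * pi))
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# tiny labeled tile table for simulator/ensemble tests
make_labels <- function(n, positive_fraction = 0.5) {
  data.frame(tile_id = sprintf("t%05d", seq_len(n)),
             wsi_id = "w1",
             l = as.integer(seq_len(n) <= round(n * positive_fraction)),
             stringsAsFactors = FALSE)
}

# model spec list with shared settings
make_specs <- function(n, p_correct = 0.8, tau = 0.5, conc = 2, rho = 0) {
  lapply(seq_len(n), function(i)
    sim_model_spec(sprintf("m%02d", i), p_correct, tau, conc, rho))
}
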