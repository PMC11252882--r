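# Stratified train/test splitting and division of training slides into
# N equal groups, preserving the joint distribution of clinical covariates
# (NHG grade and ER / HER2 / Ki67 status). One division per base model.

# joint stratum key; NA and "" collapse to "missing"
stratum_key <- function(clinical) {
  f <- function(v) {
    v <- as.character(v)
    v[is.na(v) | v == ""] <- "missing"
    v
  }
  paste(f(clinical$nhg), f(clinical$er), f(clinical$her2), f(clinical$ki67),
        sep = "|")
}

#' Split slides into training and held-out test sets
#'
#' Stratified sampling on the joint cross of (NHG, ER, HER2, Ki67), with
#' "missing" as its own level. The total test size is
#' `round(test_fraction * n)`; per-stratum test counts are apportioned by
#' largest remainder, and members are drawn with a seeded RNG so the split
#' is reproducible.
#'
#' @param clinical data.frame with columns `wsi_id, nhg, er, her2, ki67`
#'   (one row per slide).
#' @param test_fraction fraction held out, in (0, 1); default 0.2.
#' @param seed integer RNG seed (mandatory).
#' @return a partition plan: data.frame with columns `wsi_id`, `split`
#'   ("train"/"test") and `division` (NA until [make_divisions()] fills it),
#'   with attributes `seed` and `test_fraction`.
#' @export
split_train_test <- function(clinical, test_fraction = 0.2, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (anyDuplicated(clinical$wsi_id))
    stop("duplicate wsi_id in clinical table")
  n <- nrow(clinical)
  if (n < 2) stop("need at least 2 slides to split")
  key <- stratum_key(clinical)
  strata <- sort(unique(key))
  n_s <- vapply(strata, function(s) sum(key == s), integer(1))
  total_test <- round(test_fraction * n)
  quota <- test_fraction * n_s
  base <- floor(quota)
  rem <- total_test - sum(base)
  if (rem > 0) {
    frac <- quota - base
    # largest remainder; ties broken by stratum order (deterministic)
    extra <- order(-frac, seq_along(strata))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  base <- pmin(base, n_s)
  split <- rep("train", n)
  set.seed(seed)
  for (j in seq_along(strata)) {
    idx <- which(key == strata[j])
    if (base[j] > 0) {
      take <- idx[sample.int(length(idx), base[j])]
      split[take] <- "test"
    }
  }
  plan <- data.frame(wsi_id = as.character(clinical$wsi_id), split = split,
                     division = NA_integer_, stringsAsFactors = FALSE)
  attr(plan, "seed") <- seed
  attr(plan, "test_fraction") <- test_fraction
  plan
}

#' Divide training slides into N equal groups preserving covariate proportions
#'
#' Within each joint clinical stratum the training slides are shuffled with
#' a seeded RNG and dealt round-robin to the `N` divisions. The starting
#' division for each stratum continues from where the previous stratum
#' stopped, so global division sizes differ by at most 1, and within every
#' stratum the per-division counts also differ by at most 1.
#'
#' @param plan partition plan from [split_train_test()].
#' @param clinical clinical table (same slides).
#' @param N number of divisions (one per base model), `2 <= N <=` train size.
#' @param seed integer RNG seed.
#' @return the plan with `division` filled in (1..N) for training slides,
#'   and attributes `N` and `division_seed` added.
#' @export
make_divisions <- function(plan, clinical, N, seed) {
  stopifnot(N >= 2)
  train_ids <- plan$wsi_id[plan$split == "train"]
  if (N > length(train_ids))
    stop("N (", N, ") exceeds the number of training slides (",
         length(train_ids), ")")
  key_all <- stratum_key(clinical)
  names(key_all) <- as.character(clinical$wsi_id)
  key <- key_all[train_ids]
  strata <- sort(unique(key))
  division <- stats::setNames(integer(length(train_ids)), train_ids)
  set.seed(seed)
  offset <- 0L
  for (s in strata) {
    ids <- train_ids[key == s]
    ids <- ids[sample.int(length(ids))]
    division[ids] <- ((offset + seq_along(ids) - 1L) %% N) + 1L
    offset <- (offset + length(ids)) %% N
  }
  plan$division <- ifelse(plan$split == "train",
                          division[plan$wsi_id], NA_integer_)
  attr(plan, "N") <- N
  attr(plan, "division_seed") <- seed
  plan
}

#' Read / write clinical covariate tables
#'
#' CSV with columns `wsi_id, nhg, er, her2, ki67`.
#' @param x clinical table.
#' @param path CSV file path.
#' @export
write_clinical <- function(x, path) {
  utils::write.csv(x[, c("wsi_id", "nhg", "er", "her2", "ki67")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  utils::read.csv(path, colClasses = "character")
}

#' Read / write partition plans
#'
#' The plan itself is a CSV (`wsi_id, split, division`); the seeds, `N` and
#' `test_fraction` go to a JSON sidecar (`<path>.json`) so a plan can be
#' reproduced and audited.
#'
#' @param plan partition plan.
#' @param path CSV file path; the sidecar is written at `paste0(path, ".json")`.
#' @export
write_partition_plan <- function(plan, path) {
  utils::write.csv(plan, path, row.names = FALSE, quote = TRUE)
  meta <- list(seed = attr(plan, "seed"),
               test_fraction = attr(plan, "test_fraction"),
               N = attr(plan, "N"),
               division_seed = attr(plan, "division_seed"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition_plan
#' @export
read_partition_plan <- function(path) {
  plan <- utils::read.csv(path, colClasses = c(wsi_id = "character",
                                               split = "character"))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (nm in names(meta)) attr(plan, nm) <- meta[[nm]]
  }
  plan
}
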