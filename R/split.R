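#' Participant-level stratified train/test split
#'
#' Draws a single 80/20 (by default) split stratified by group at the
#' participant level; each participant lands in exactly one partition and
#' the identical partition is reused across all models of a benchmark run.
#' Per class, `round(n_class * test_fraction)` participants go to the test
#' set (77 participants at 0.2 give a 16-participant test set).
#'
#' @param table A scenario feature table (see [build_scenario_table()]).
#' @param test_fraction Fraction of each class held out (default 0.2).
#' @param split_seed Integer seed making the split deterministic.
#' @return List with `train` and `test` (row subsets of `table`),
#'   `test_ids` and `split_seed`.
#' @export
make_split <- function(table, test_fraction = 0.2, split_seed = 42L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- as_group_factor(table$group)
  if (any(table(y) < 2L)) stop("need at least 2 participants per class")
  set.seed(as.integer(split_seed))
  test_idx <- integer()
  for (g in levels(y)) {
    idx <- which(y == g)
    n_test <- round(length(idx) * test_fraction)
    if (n_test < 1L || n_test >= length(idx)) {
      stop(sprintf("class %s would be absent from one partition", g))
    }
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  list(
    train = table[-test_idx, , drop = FALSE],
    test = table[test_idx, , drop = FALSE],
    test_ids = table$participant_id[test_idx],
    split_seed = as.integer(split_seed)
  )
}

# stratified k-fold assignment (seeded)
stratified_folds <- function(y, k = 5L, seed = 42L) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (g in levels(y)) {
    idx <- sample(which(y == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
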