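#' Stratified repeated train/test splits
#'
#' Repeated random train/test partitioning that preserves the class
#' proportions of `labels` in every partition (the stratified shuffle-split
#' scheme).  The train size is `round(train_fraction * N)`; per-class train
#' counts deviate from exact proportionality by at most one sample (floors
#' plus largest-remainder allocation of the shortfall).  Each iteration draws
#' from its own seed `seed + iteration`, so any iteration is reproducible in
#' isolation.
#'
#' @param labels factor (or coercible) of class labels.
#' @param train_fraction fraction of samples in the train partition, in (0,1).
#' @param n_iterations number of independent splits (default 10).
#' @param seed integer base seed.
#' @return object of class `"split_plan"`: a list with `iterations` (each a
#'   list of integer `train` and `test` index vectors), plus the call
#'   parameters.
#' @examples
#' sp <- stratified_shuffle_split(rep(1:7, each = 40), 0.1, n_iterations = 2, seed = 1)
#' lengths(sp$iterations[[1]])
#' @export
stratified_shuffle_split <- function(labels, train_fraction, n_iterations = 10L, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (n == 0L) stop("labels must be non-empty")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  if (any(table(labels) < 2L)) stop("every class needs at least 2 samples")
  n_train <- round(train_fraction * n)
  cls <- levels(labels)
  n_c <- as.integer(table(labels))
  base <- floor(train_fraction * n_c)
  rem <- n_train - sum(base)
  if (rem > 0) {
    frac <- train_fraction * n_c - base
    extra <- order(-frac, seq_along(cls))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  } else if (rem < 0) {
    frac <- train_fraction * n_c - base
    fewer <- order(frac, seq_along(cls))[seq_len(-rem)]
    base[fewer] <- base[fewer] - 1L
  }
  if (any(base < 1L))
    stop("train_fraction ", train_fraction, " leaves a class without train samples")
  idx_by_class <- split(seq_len(n), labels)
  iterations <- lapply(seq_len(n_iterations), function(it) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(derive_seed(seed, it))
    train <- integer(0)
    for (k in seq_along(cls)) {
      take <- sample(idx_by_class[[k]], base[k])
      train <- c(train, take)
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
  structure(list(iterations = iterations, train_fraction = train_fraction,
                 n_iterations = as.integer(n_iterations), seed = as.integer(seed),
                 n = n),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  n_tr <- length(x$iterations[[1L]]$train)
  cat(sprintf("Stratified shuffle split: %d iterations, %d train / %d test (fraction %.2f)\n",
              x$n_iterations, n_tr, x$n - n_tr, x$train_fraction))
  invisible(x)
}
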