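#' Protein-level cross-validation fold assignment
#'
#' Assigns whole proteins (never individual windows) to k folds so that fold
#' window totals are approximately equal and every fold contains both
#' classes. Proteins are shuffled by `seed`, then each class is placed
#' greedily in descending window-count order onto the fold with the smallest
#' running window total; near the tail, folds still lacking the current class
#' are served first so no fold ends up single-class.
#'
#' @param ids protein identifiers.
#' @param labels parallel `{"disordered","ordered"}` labels.
#' @param n_windows parallel window counts per protein.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the shuffle.
#' @return Integer vector of fold indices (1..k), named by `ids`.
#' @export
assign_folds <- function(ids, labels, n_windows, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (length(ids) != length(labels) || length(ids) != length(n_windows))
    stop("ids, labels and n_windows must be parallel")
  if (anyDuplicated(ids)) stop("duplicate protein ids")
  for (cl in c("disordered", "ordered"))
    if (sum(labels == cl) < k)
      stop("need at least k = ", k, " proteins of class '", cl, "'")
  rng <- .local_rng(seed)
  ord <- rng$sample(seq_along(ids))
  ids <- ids[ord]; labels <- labels[ord]; n_windows <- n_windows[ord]

  fold_total <- numeric(k)
  fold_has <- matrix(FALSE, nrow = k, ncol = 2,
                     dimnames = list(NULL, c("disordered", "ordered")))
  assignment <- setNames(integer(length(ids)), ids)
  for (cl in c("disordered", "ordered")) {
    idx <- which(labels == cl)
    idx <- idx[order(n_windows[idx], decreasing = TRUE)]
    for (j in seq_along(idx)) {
      i <- idx[j]
      remaining <- length(idx) - j + 1L
      needy <- which(!fold_has[, cl])
      cand <- if (length(needy) >= remaining) needy else seq_len(k)
      f <- cand[which.min(fold_total[cand])]
      assignment[ids[i]] <- f
      fold_total[f] <- fold_total[f] + n_windows[i]
      fold_has[f, cl] <- TRUE
    }
  }
  attr(assignment, "fold_totals") <- fold_total
  assignment
}

# Deterministic local RNG that does not disturb the global .Random.seed.
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  state <- get(".Random.seed", envir = globalenv())
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
  with_state <- function(f) {
    assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      restore()
    })
    f()
  }
  restore()
  list(
    sample = function(x, ...) with_state(function() sample(x, ...)),
    runif = function(n, ...) with_state(function() runif(n, ...)),
    rgamma = function(n, ...) with_state(function() rgamma(n, ...)),
    rint = function(n, max = .Machine$integer.max)
      with_state(function() sample.int(max, n))
  )
}
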