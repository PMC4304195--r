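#' Pearson correlation between two amino-acid scales
#'
#' Product-moment correlation of two residue-aligned 20-vectors.
#'
#' @param x,y numeric vectors of length 20 (named by residue or in the
#'   canonical alphabet order), or `aa_scale` objects.
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  x <- .scale_values(x); y <- .scale_values(y)
  if (length(x) != 20L || length(y) != 20L)
    stop("scales must have 20 residue values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for a constant scale")
  stats::cor(x, y, method = "pearson")
}

.scale_values <- function(x) {
  if (inherits(x, "aa_scale")) x <- x$values
  if (!is.null(names(x))) {
    missing <- setdiff(AA, names(x))
    if (length(missing)) stop("missing residue(s): ",
                              paste(missing, collapse = ", "))
    x <- x[AA]
  }
  as.numeric(x)
}

#' Read an amino-acid index collection from TSV
#'
#' Simplified flat format: header
#' `id<TAB>cluster<TAB>A<TAB>C ... <TAB>Y` followed by one row per index.
#' Cluster labels follow the property-group convention: A (alpha/turn
#' propensity), B (beta propensity), C (composition), H (hydropathy),
#' P (physicochemical), O (other); anything else is kept verbatim.
#'
#' @param path TSV path.
#' @return data.frame with columns `id`, `cluster` and the 20 residues.
#' @export
read_index_collection <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("id", "cluster", AA)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("index collection missing column(s): ",
         paste(missing, collapse = ", "))
  df[, need]
}

#' Correlate one scale against an index collection
#'
#' One Pearson r per index, residue-aligned by one-letter code; constant
#' indices are skipped with a warning.
#'
#' @param scale an `aa_scale` (or named 20-vector).
#' @param collection data.frame as from [read_index_collection()].
#' @return data.frame with columns `id`, `cluster`, `r`, `abs_r`.
#' @export
correlate_scale_vs_collection <- function(scale, collection) {
  if (nrow(collection) == 0L) stop("empty index collection")
  sv <- .scale_values(scale)
  rows <- lapply(seq_len(nrow(collection)), function(i) {
    v <- as.numeric(collection[i, AA])
    if (stats::var(v) == 0) {
      warning("skipping constant index '", collection$id[i], "'")
      return(NULL)
    }
    data.frame(id = collection$id[i], cluster = collection$cluster[i],
               r = stats::cor(sv, v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable (non-constant) indices in collection")
  out$abs_r <- abs(out$r)
  out
}

#' Per-cluster summary of |r|
#'
#' Mean, median, sample standard deviation (n-1), max and min of `abs_r` per
#' cluster, sorted by descending mean. Singleton clusters report `NA` for the
#' standard deviation.
#'
#' @param rows data.frame from [correlate_scale_vs_collection()].
#' @return data.frame `cluster`, `n`, `mean`, `median`, `std`, `max`, `min`.
#' @export
cluster_summary <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) stop("no correlation rows")
  if (!all(c("cluster", "abs_r") %in% names(rows)))
    stop("rows must carry 'cluster' and 'abs_r'")
  sp <- split(rows$abs_r, rows$cluster)
  out <- do.call(rbind, lapply(names(sp), function(cl) {
    v <- sp[[cl]]
    data.frame(cluster = cl, n = length(v), mean = mean(v),
               median = stats::median(v),
               std = if (length(v) > 1) stats::sd(v) else NA_real_,
               max = max(v), min = min(v), stringsAsFactors = FALSE)
  }))
  out[order(out$mean, decreasing = TRUE), , drop = FALSE]
}
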