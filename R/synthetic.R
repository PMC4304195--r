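#' Generate a synthetic labelled protein corpus
#'
#' Emulates the compositional contrast the C-H model assumes: the two classes
#' differ along a planted hydropathy direction and in net charge. Per-class
#' residue log-weights are flat log(1/20) plus `s * beta * u`, where `u` is
#' the planted scale oriented hydrophobic-positive, mean-centered and scaled
#' to unit Euclidean norm, and `s` is +1 for ordered and -1 for disordered
#' proteins; the disordered class additionally receives `+gamma` on Glu and
#' `+gamma/2` on Lys (asymmetric, so the absolute net charge rises rather
#' than cancelling between acidic and basic enrichment). The
#' log-weights are mapped through softmax to a class composition, each
#' protein draws its own composition from a Dirichlet with concentration
#' `alpha` around it, and residues are sampled i.i.d. Lengths are uniform
#' integers over `length_range`. Everything is deterministic given `seed`,
#' and the global RNG state is left untouched.
#'
#' @param n_disordered,n_ordered class sizes.
#' @param length_range integer interval of protein lengths (default 82-410,
#'   so every protein yields at least two 41-residue windows).
#' @param planted_scale the `aa_scale` defining the hydropathy direction
#'   (default: the bundled `idp_hydropathy` scale).
#' @param beta class-shift strength along the planted direction (default 2).
#' @param gamma extra charge tilt for the disordered class. The default
#'   1.25 is calibrated so the disordered class's expected absolute net
#'   charge is about 0.10 at `beta = 2` (ordered stays near 0.0), the
#'   elevated-charge geometry the C-H model presupposes; at `gamma = 0` the
#'   two classes differ in charge only through the planted direction.
#' @param alpha Dirichlet concentration controlling per-protein composition
#'   dispersion (default 60; larger = less dispersion).
#' @param seed integer seed.
#' @return A list of class `ch_corpus` with `seqs` (named character vector),
#'   `labels`, and `truth` (the generator parameters, including the planted
#'   scale).
#' @export
generate_corpus <- function(n_disordered = 300L, n_ordered = 300L,
                            length_range = c(82L, 410L),
                            planted_scale = get_builtin_scale("idp_hydropathy"),
                            beta = 2, gamma = 1.25, alpha = 60, seed = 1L) {
  stopifnot(inherits(planted_scale, "aa_scale"))
  if (n_disordered < 1L || n_ordered < 1L) stop("class sizes must be >= 1")
  if (length(length_range) != 2L || length_range[1] < 42L ||
      length_range[2] > 10000L || length_range[1] > length_range[2])
    stop("length_range must lie within [42, 10000]")
  if (beta < 0 || gamma < 0 || alpha <= 0)
    stop("beta, gamma must be >= 0 and alpha > 0")

  sv <- orient_hydrophobic_positive(planted_scale)$values[AA]
  u <- sv - mean(sv)
  u <- u / sqrt(sum(u^2))

  class_logits <- function(s, disordered) {
    lw <- rep(log(1 / 20), 20) + s * beta * u
    if (disordered) {
      lw[AA == "E"] <- lw[AA == "E"] + gamma
      lw[AA == "K"] <- lw[AA == "K"] + gamma / 2
    }
    lw
  }
  softmax <- function(lw) { e <- exp(lw - max(lw)); e / sum(e) }
  p_dis <- softmax(class_logits(-1, TRUE))
  p_ord <- softmax(class_logits(+1, FALSE))

  rng <- .local_rng(seed)
  n <- n_disordered + n_ordered
  labels <- c(rep("disordered", n_disordered), rep("ordered", n_ordered))
  lens <- length_range[1] +
    floor(rng$runif(n) * (length_range[2] - length_range[1] + 1L))
  lens <- pmin(as.integer(lens), length_range[2])
  seqs <- character(n)
  for (i in seq_len(n)) {
    p <- if (labels[i] == "disordered") p_dis else p_ord
    g <- rng$rgamma(20, shape = alpha * p, rate = 1)
    if (sum(g) <= 0) g <- p   # numerically degenerate draw: fall back to mean
    comp <- g / sum(g)
    idx <- rng$sample(20L, size = lens[i], replace = TRUE, prob = comp)
    seqs[i] <- paste(AA[idx], collapse = "")
  }
  names(seqs) <- sprintf("%s_%04d", ifelse(labels == "disordered", "dis", "ord"),
                         seq_len(n))
  structure(list(
    seqs = seqs, labels = labels,
    truth = list(n_disordered = n_disordered, n_ordered = n_ordered,
                 length_range = as.integer(length_range),
                 planted_scale = planted_scale, beta = beta, gamma = gamma,
                 alpha = alpha, seed = seed,
                 class_composition = list(disordered = setNames(p_dis, AA),
                                          ordered = setNames(p_ord, AA)))
  ), class = "ch_corpus")
}

#' @export
print.ch_corpus <- function(x, ...) {
  t <- x$truth
  cat(sprintf(
    "Synthetic C-H corpus: %d disordered + %d ordered, lengths %d-%d\n",
    t$n_disordered, t$n_ordered, t$length_range[1], t$length_range[2]))
  cat(sprintf("  planted scale '%s', beta = %g, gamma = %g, alpha = %g, seed = %d\n",
              t$planted_scale$id, t$beta, t$gamma, t$alpha, t$seed))
  invisible(x)
}

#' Planted scale of a synthetic corpus
#' @param corpus a `ch_corpus`.
#' @return The exact `aa_scale` used for generation (the recovery target).
#' @export
planted_scale <- function(corpus) {
  stopifnot(inherits(corpus, "ch_corpus"))
  corpus$truth$planted_scale
}

#' Write a corpus to FASTA + manifest + truth JSON
#' @param corpus a `ch_corpus`.
#' @param dir output directory (created if needed).
#' @param prefix file name stem.
#' @return Invisibly, the paths written.
#' @export
write_corpus <- function(corpus, dir, prefix = "corpus") {
  stopifnot(inherits(corpus, "ch_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  mf <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  tj <- file.path(dir, paste0(prefix, "_truth.json"))
  write_fasta(corpus$seqs, fa)
  utils::write.table(
    data.frame(id = names(corpus$seqs), label = corpus$labels),
    mf, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- corpus$truth
  truth$planted_scale <- list(id = truth$planted_scale$id,
                              values = as.list(truth$planted_scale$values),
                              orientation = truth$planted_scale$orientation)
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, manifest = mf, truth = tj))
}

#' Read a labelled manifest TSV (columns id, label)
#' @param path TSV path.
#' @return data.frame with `id` and `label`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df)))
    stop("manifest must have columns 'id' and 'label'")
  bad <- setdiff(unique(df$label), c("disordered", "ordered"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  df
}
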