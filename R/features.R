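#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that canonicalizes to
#' uppercase, strips stop characters (`*`), and rejects duplicate record ids
#' (the id is the first whitespace-delimited token of the header).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# residue counts over the canonical alphabet; also reports non-canonical tally
.residue_counts <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars <- chars[chars != "*"]
  counts <- table(factor(chars, levels = AA))
  noncanon <- sum(!chars %in% AA)
  list(counts = as.numeric(counts), noncanon = noncanon, total = length(chars))
}

#' Amino-acid composition and net charge of a sequence
#'
#' Computes the 20 composition fractions over canonical residues plus the
#' signed normalized net charge (Arg + Lys - Glu - Asp)/length, the 21
#' features used throughout. Non-canonical letters (B, J, O, U, X, Z and `*`)
#' are either skipped (excluded from numerator and denominator, default) or
#' raise an error; under `"skip"`, more than 10% non-canonical content
#' triggers a warning (likely wrong input), and a sequence with no canonical
#' residues at all is always an error.
#'
#' @param sequence a protein sequence string.
#' @param noncanonical_policy `"skip"` (default) or `"error"`.
#' @return A list of class `composition_vector` with elements `comp` (named
#'   20-vector summing to 1), `net_charge_signed`, `effective_length`,
#'   `n_noncanonical`.
#' @export
#' @examples
#' composition("KE")$net_charge_signed  # 0
composition <- function(sequence, noncanonical_policy = c("skip", "error")) {
  noncanonical_policy <- match.arg(noncanonical_policy)
  rc <- .residue_counts(sequence)
  if (rc$noncanon > 0 && noncanonical_policy == "error")
    stop("sequence contains ", rc$noncanon, " non-canonical residue(s)")
  if (rc$total == 0 || sum(rc$counts) == 0)
    stop("sequence has no canonical residues")
  if (rc$noncanon / rc$total > 0.10)
    warning("more than 10% non-canonical residues (",
            rc$noncanon, "/", rc$total, ")")
  n <- sum(rc$counts)
  comp <- setNames(rc$counts / n, AA)
  structure(
    list(comp = comp,
         net_charge_signed = unname(comp["R"] + comp["K"] - comp["E"] - comp["D"]),
         effective_length = as.integer(n),
         n_noncanonical = as.integer(rc$noncanon)),
    class = "composition_vector"
  )
}

#' Signed normalized net charge
#'
#' (nArg + nLys - nGlu - nAsp) / effective length; histidine carries zero
#' charge. Value in \[-1, 1\].
#'
#' @inheritParams composition
#' @return A number in \[-1, 1\].
#' @export
net_charge_signed <- function(sequence, noncanonical_policy = c("skip", "error")) {
  composition(sequence, noncanonical_policy)$net_charge_signed
}

#' Absolute normalized net charge
#'
#' |(nArg + nLys) - (nGlu + nAsp)| / effective length — the charge coordinate
#' of the C-H plot.
#'
#' @inheritParams composition
#' @return A number in \[0, 1\].
#' @export
net_charge_abs <- function(sequence, noncanonical_policy = c("skip", "error")) {
  abs(net_charge_signed(sequence, noncanonical_policy))
}

#' Composition-weighted mean hydropathy
#'
#' Dot product of the composition fractions with a normalized,
#' hydrophobic-positive scale: the hydropathy coordinate of the C-H plot.
#' Order-independent by construction (whole-sequence composition, not a
#' sliding-window average).
#'
#' @inheritParams composition
#' @param scale an `aa_scale`, already oriented hydrophobic-positive and
#'   normalized to \[0, 1\] (see [prepare_scale()]).
#' @return A number in \[0, 1\].
#' @export
mean_hydropathy <- function(sequence, scale,
                            noncanonical_policy = c("skip", "error")) {
  stopifnot(inherits(scale, "aa_scale"))
  if (scale$orientation != "hydrophobic_positive" || !scale$normalized)
    stop("scale must be oriented hydrophobic-positive and normalized; ",
         "use prepare_scale()")
  comp <- composition(sequence, noncanonical_policy)$comp
  unname(sum(comp * scale$values[names(comp)]))
}

#' Chop a sequence into fixed-width windows
#'
#' Consecutive non-overlapping windows of `width` residues from position 1.
#' A trailing remainder of at least `width/2` residues is emitted as a final
#' full-width window anchored at the sequence end (overlapping its
#' predecessor); shorter remainders are discarded. Sequences shorter than
#' `width` come back whole as a single window.
#'
#' @param sequence a protein sequence string.
#' @param width window width in residues (default 41).
#' @param remainder_policy `"anchor"` (default, behaviour above) or
#'   `"discard"` (drop any partial remainder).
#' @return A data.frame with columns `start`, `end`, `window`.
#' @export
#' @examples
#' nrow(chop_windows(strrep("A", 82)))   # 2
#' nrow(chop_windows(strrep("A", 100)))  # 2 (remainder 18 < 20.5 discarded)
chop_windows <- function(sequence, width = 41L,
                         remainder_policy = c("anchor", "discard")) {
  remainder_policy <- match.arg(remainder_policy)
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("width must be >= 1")
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  if (n < width) {
    return(data.frame(start = 1L, end = n,
                      window = sequence, stringsAsFactors = FALSE))
  }
  k <- n %/% width
  starts <- (seq_len(k) - 1L) * width + 1L
  ends <- starts + width - 1L
  remainder <- n - k * width
  if (remainder_policy == "anchor" && remainder >= width / 2) {
    starts <- c(starts, n - width + 1L)
    ends <- c(ends, n)
  }
  data.frame(start = starts, end = ends,
             window = substring(sequence, starts, ends),
             stringsAsFactors = FALSE)
}
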