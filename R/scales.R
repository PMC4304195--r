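# canonical one-letter residue alphabet, fixed order used throughout
AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

NONCANONICAL <- c("B", "J", "O", "U", "X", "Z", "*")

#' Construct an amino-acid scale
#'
#' An amino-acid scale assigns one real value to each of the 20 canonical
#' residues. Orientation metadata records whether larger values mean more
#' hydrophobic (`"hydrophobic_positive"`, the Kyte-Doolittle convention) or
#' more hydrophilic (`"hydrophilic_positive"`, the Guy convention). The
#' orientation is explicit rather than inferred because legitimate scales mix
#' signs on both sides.
#'
#' @param id short identifier.
#' @param values named numeric vector over exactly the 20 canonical one-letter
#'   residue codes.
#' @param orientation `"hydrophobic_positive"` or `"hydrophilic_positive"`.
#' @param normalized logical; `TRUE` iff values span exactly \[0, 1\].
#' @param source free-text provenance.
#' @return An object of class `aa_scale`.
#' @export
#' @examples
#' s <- aa_scale("toy", setNames(seq(0, 1, length.out = 20), chplot:::AA))
aa_scale <- function(id, values, orientation = "hydrophobic_positive",
                     normalized = FALSE, source = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!orientation %in% c("hydrophobic_positive", "hydrophilic_positive"))
    stop("orientation must be 'hydrophobic_positive' or 'hydrophilic_positive'")
  if (is.null(names(values)))
    stop("'values' must be named by one-letter residue codes")
  extra <- setdiff(names(values), AA)
  if (length(extra))
    stop("unknown residue code(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(AA, names(values))
  if (length(missing))
    stop("missing residue(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(names(values)))
    stop("duplicate residue(s) in 'values'")
  values <- as.numeric(values[AA])
  names(values) <- AA
  if (!all(is.finite(values))) stop("all scale values must be finite")
  if (max(values) <= min(values)) stop("degenerate scale: max must exceed min")
  if (isTRUE(normalized) &&
      (abs(min(values)) > 1e-12 || abs(max(values) - 1) > 1e-12))
    stop("normalized scale must have min 0 and max 1")
  structure(
    list(id = id, values = values, orientation = orientation,
         normalized = isTRUE(normalized), source = as.character(source)),
    class = "aa_scale"
  )
}

#' @export
print.aa_scale <- function(x, ...) {
  cat(sprintf("Amino-acid scale '%s' (%s%s)\n", x$id, x$orientation,
              if (x$normalized) ", normalized [0,1]" else ""))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  print(round(x$values, 4))
  invisible(x)
}

# Bundled scale values and the Guy sign convention; built lazily so the
# returned objects are always fresh copies.
.builtin_scale_data <- function() {
  list(
    idp_hydropathy = list(
      values = c(W = 10.66, Y = 6.64, I = 6.19, F = 5.79, C = 5.62, L = 5.17,
                 V = 4.64, M = 2.49, N = 2.06, T = 1.22, A = 0.91, R = 0.07,
                 G = 0.02, D = -0.48, Q = -1.23, S = -1.84, H = 2.18,
                 E = -2.20, K = -2.43, P = -3.89),
      orientation = "hydrophobic_positive",
      source = "IDP-Hydropathy (SVM parameters scale)"
    ),
    guy = list(
      values = c(W = -0.51, Y = -0.21, I = -1.13, F = -2.12, C = -1.42,
                 L = -1.18, V = -1.27, M = -1.59, N = 0.48, T = 0.07,
                 A = 0.10, R = 1.91, G = 0.33, D = 0.78, Q = 0.83, S = 0.52,
                 H = -0.50, E = 0.95, K = 1.40, P = 0.73),
      orientation = "hydrophilic_positive",
      source = "Guy (1985) transfer free-energy scale"
    ),
    kyte_doolittle = list(
      values = c(W = -0.90, Y = -1.30, I = 4.50, F = 2.80, C = 2.50, L = 3.80,
                 V = 4.20, M = 1.90, N = -3.50, T = -0.70, A = 1.80,
                 R = -4.50, G = -0.40, D = -3.50, Q = -3.50, S = -0.80,
                 H = -3.20, E = -3.50, K = -3.90, P = -1.60),
      orientation = "hydrophobic_positive",
      source = "Kyte & Doolittle (1982) hydropathy scale"
    )
  )
}

#' Bundled hydropathy scales
#'
#' Three scales ship with the package: `idp_hydropathy` (the SVM-derived
#' disorder-optimised scale), `guy` (Guy 1985; hydrophilic-positive sign
#' convention) and `kyte_doolittle` (Kyte & Doolittle 1982).
#'
#' @param name one of `"idp_hydropathy"`, `"guy"`, `"kyte_doolittle"`.
#' @return An `aa_scale`.
#' @export
#' @examples
#' get_builtin_scale("kyte_doolittle")$values[["W"]]  # -0.9
get_builtin_scale <- function(name) {
  dat <- .builtin_scale_data()
  if (!is.character(name) || length(name) != 1L || !name %in% names(dat))
    stop("unknown builtin scale '", paste(name, collapse = ","),
         "'; available: ", paste(names(dat), collapse = ", "))
  d <- dat[[name]]
  aa_scale(name, d$values, orientation = d$orientation, source = d$source)
}

#' List bundled scale names
#' @return Character vector of builtin scale identifiers.
#' @export
builtin_scale_names <- function() names(.builtin_scale_data())

#' Orient a scale hydrophobic-positive
#'
#' Scales using the hydrophilic-positive convention (e.g. Guy) are multiplied
#' by -1 so that larger values always mean more hydrophobic. Idempotent.
#'
#' @param scale an `aa_scale`.
#' @return An `aa_scale` with `orientation = "hydrophobic_positive"`.
#' @export
orient_hydrophobic_positive <- function(scale) {
  stopifnot(inherits(scale, "aa_scale"))
  if (scale$orientation == "hydrophobic_positive") return(scale)
  aa_scale(scale$id, -scale$values, orientation = "hydrophobic_positive",
           source = scale$source)
}

#' Rescale a scale to the unit interval
#'
#' Maps values v to (v - min)/(max - min), so the most hydrophilic residue is
#' 0 and the most hydrophobic is 1. The scale must already be oriented
#' hydrophobic-positive; residue ranking is preserved.
#'
#' @param scale an `aa_scale` with orientation `"hydrophobic_positive"`.
#' @return A normalized `aa_scale`.
#' @export
normalize_unit <- function(scale) {
  stopifnot(inherits(scale, "aa_scale"))
  if (scale$orientation != "hydrophobic_positive")
    stop("orient the scale hydrophobic-positive before normalizing")
  v <- scale$values
  rng <- range(v)
  if (rng[2] <= rng[1]) stop("degenerate scale: max must exceed min")
  out <- (v - rng[1]) / (rng[2] - rng[1])
  # force exact endpoints against rounding
  out[which.min(v)] <- 0
  out[which.max(v)] <- 1
  aa_scale(scale$id, out, orientation = "hydrophobic_positive",
           normalized = TRUE, source = scale$source)
}

#' Orient and normalize in one step
#' @param scale an `aa_scale`.
#' @return A hydrophobic-positive `aa_scale` spanning \[0, 1\].
#' @export
prepare_scale <- function(scale) {
  if (scale$normalized && scale$orientation == "hydrophobic_positive")
    return(scale)
  normalize_unit(orient_hydrophobic_positive(scale))
}

#' Read / write a scale as TSV
#'
#' The on-disk format is UTF-8 text: optional `#`-prefixed metadata lines
#' (`# id:`, `# orientation:`, `# source:`), a `residue<TAB>value` header and
#' exactly 20 data rows. Values are written with 15 significant digits so a
#' write/read round trip is value-exact.
#'
#' @param path file path.
#' @return `read_scale_tsv` returns an `aa_scale`; `write_scale_tsv`
#'   invisibly returns `path`.
#' @export
read_scale_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(id = tools::file_path_sans_ext(basename(path)),
               orientation = "hydrophobic_positive", source = "")
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*(id|orientation|source):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("empty scale file: ", path)
  if (!grepl("^residue\\tvalue", body[1]))
    stop("expected header 'residue<TAB>value' in ", path)
  body <- body[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) stop("malformed row in ", path)
  res <- vapply(parts, `[[`, "", 1L)
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(val)) stop("non-numeric value for residue(s): ",
                       paste(res[is.na(val)], collapse = ", "))
  bad <- setdiff(res, AA)
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(res)) stop("duplicate residue(s): ",
                               paste(unique(res[duplicated(res)]), collapse = ", "))
  missing <- setdiff(AA, res)
  if (length(missing)) stop("missing residue(s): ",
                            paste(missing, collapse = ", "))
  aa_scale(meta$id, setNames(val, res), orientation = meta$orientation,
           source = meta$source)
}

#' @rdname read_scale_tsv
#' @param scale an `aa_scale` to serialize.
#' @export
write_scale_tsv <- function(scale, path) {
  stopifnot(inherits(scale, "aa_scale"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# id: %s", scale$id),
               sprintf("# orientation: %s", scale$orientation),
               sprintf("# source: %s", scale$source),
               "residue\tvalue"), con)
  writeLines(sprintf("%s\t%.17g", AA, scale$values[AA]), con)
  invisible(path)
}
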