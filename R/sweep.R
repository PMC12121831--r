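# Spaced-word indexing and random orthonormal projection: a biological-
# sequence-format string becomes a sparse high-dimensional count vector
# (one cell per possible spaced word) and is compressed to a fixed-length
# dense base vector through a seeded orthonormal basis.

#' Spaced-word mask
#'
#' A binary pattern over sequence windows: `1` marks a care position that
#' contributes a letter to the indexed word, `0` a don't-care position.
#' The pattern must start and end with `1`.
#'
#' @param pattern Binary string, e.g. `"11011"`.
#' @return An object of class `spaced_mask` with fields `pattern`, `care`
#'   (care-position offsets), `weight` (number of ones) and `span`.
#' @export
spaced_mask <- function(pattern = "11011") {
  if (!grepl("^[01]+$", pattern)) stop("mask pattern must be a binary string")
  bits <- as.integer(strsplit(pattern, "")[[1]])
  if (bits[1] != 1L || bits[length(bits)] != 1L) {
    stop("mask pattern must start and end with 1")
  }
  structure(list(pattern = pattern, care = which(bits == 1L),
                 weight = sum(bits), span = length(bits)),
            class = "spaced_mask")
}

#' @export
print.spaced_mask <- function(x, ...) {
  cat(sprintf("<spaced_mask '%s': weight %d, span %d>\n", x$pattern, x$weight, x$span))
  invisible(x)
}

#' Index the spaced words of a sequence
#'
#' Slides the mask across the sequence; at every window the letters at the
#' care positions form a word whose cell in the `alphabet^weight`-dimensional
#' count vector is incremented (`mode = "counts"`) or set to one
#' (`mode = "binary"`). Sequences shorter than the mask span yield the zero
#' vector. The result is stored sparsely.
#'
#' @param seq A single BSF sequence string.
#' @param mask A [spaced_mask] (or pattern string).
#' @param alphabet `"amino20"` or `"dna4"`.
#' @param mode `"counts"` or `"binary"`.
#' @return An object of class `hd_vector`: list with integer cell indices
#'   `i` (1-based, sorted), values `x`, and `dim = alphabet_size^weight`.
#' @examples
#' v <- index_spaced_words("ACGT", "101", alphabet = "dna4")
#' @export
index_spaced_words <- function(seq, mask, alphabet = c("amino20", "dna4"),
                               mode = c("counts", "binary")) {
  alphabet <- match.arg(alphabet)
  mode <- match.arg(mode)
  if (!inherits(mask, "spaced_mask")) mask <- spaced_mask(mask)
  letters_ <- bsf_alphabet(alphabet)
  a <- length(letters_)
  dim <- a^mask$weight
  s <- as.character(seq)
  n <- nchar(s)
  if (n < mask$span) {
    return(structure(list(i = integer(0), x = numeric(0), dim = dim,
                          weight = mask$weight, alphabet = alphabet),
                     class = "hd_vector"))
  }
  code <- match(strsplit(s, "", fixed = TRUE)[[1]], letters_) - 1
  if (anyNA(code)) {
    stop("symbol outside alphabet '", alphabet, "' at position ", which(is.na(code))[1])
  }
  nwin <- n - mask$span + 1L
  idx <- rep(1, nwin)
  for (j in seq_len(mask$weight)) {
    # first care position is the most significant digit
    idx <- idx + code[seq_len(nwin) + mask$care[j] - 1L] * a^(mask$weight - j)
  }
  tab <- sort(idx)
  r <- rle(tab)
  val <- if (mode == "counts") as.numeric(r$lengths) else rep(1, length(r$values))
  structure(list(i = as.integer(r$values), x = val, dim = dim,
                 weight = mask$weight, alphabet = alphabet),
            class = "hd_vector")
}

#' @export
print.hd_vector <- function(x, ...) {
  cat(sprintf("<hd_vector: %d nonzero cells of %g (%s^%d)>\n",
              length(x$i), x$dim, x$alphabet, x$weight))
  invisible(x)
}

#' Spaced word labels of the nonzero cells
#' @param v An `hd_vector`.
#' @return Character vector of spaced words, parallel to `v$i`.
#' @export
hd_words <- function(v) {
  letters_ <- bsf_alphabet(v$alphabet)
  a <- length(letters_)
  cell <- v$i - 1
  out <- matrix("", length(cell), v$weight)
  for (j in rev(seq_len(v$weight))) {
    out[, j] <- letters_[cell %% a + 1]
    cell <- cell %/% a
  }
  apply(out, 1, paste0, collapse = "")
}

#' Seeded random orthonormal projection basis
#'
#' Draws a `dimension x p` standard-normal matrix under `seed` and
#' orthonormalizes its columns by Householder QR. Identical
#' `(dimension, p, seed)` give bit-identical bases; the caller's RNG state
#' is untouched.
#'
#' @param dimension Row dimension (the spaced-word space size).
#' @param p Projection length, `1 <= p <= dimension` (default 1369, the
#'   length used for whole-corpus document vectors).
#' @param seed Integer seed.
#' @return Object of class `projection_basis` with fields `matrix`
#'   (orthonormal columns), `dimension`, `p`, `seed`.
#' @export
make_basis <- function(dimension, p = 1369, seed = 42) {
  if (p < 1 || p > dimension) {
    stop("projection length p must satisfy 1 <= p <= dimension (p = ", p,
         ", dimension = ", dimension, ")")
  }
  Q <- with_seed(seed, {
    A <- matrix(rnorm(as.double(dimension) * p), dimension, p)
    qrA <- qr(A, LAPACK = TRUE)
    rm(A)
    qr.Q(qrA)
  })
  structure(list(matrix = Q, dimension = as.integer(dimension),
                 p = as.integer(p), seed = as.integer(seed)),
            class = "projection_basis")
}

#' @export
print.projection_basis <- function(x, ...) {
  cat(sprintf("<projection_basis: %d x %d, seed %d>\n", x$dimension, x$p, x$seed))
  invisible(x)
}

#' Project a high-dimensional vector onto the basis
#'
#' Computes `t(B) %*% v` without densifying the sparse input.
#'
#' @param v An `hd_vector` (or a dense numeric vector of length
#'   `basis$dimension`).
#' @param basis A [make_basis()] result.
#' @return Dense numeric vector of length `basis$p`.
#' @export
project <- function(v, basis) {
  stopifnot(inherits(basis, "projection_basis"))
  if (inherits(v, "hd_vector")) {
    if (v$dim != basis$dimension) {
      stop("dimension mismatch: hd_vector ", v$dim, " vs basis ", basis$dimension)
    }
    if (!length(v$i)) return(numeric(basis$p))
    return(as.numeric(crossprod(basis$matrix[v$i, , drop = FALSE], v$x)))
  }
  if (length(v) != basis$dimension) {
    stop("dimension mismatch: vector ", length(v), " vs basis ", basis$dimension)
  }
  as.numeric(crossprod(basis$matrix, v))
}

#' Vectorizer configuration
#'
#' Bundles every knob of the document -> base-vector map: the spaced-word
#' mask, the codec (hence alphabet), the counting mode, the projection
#' length and the basis seed. The document map is fully deterministic given
#' this configuration.
#'
#' @param mask Mask pattern string or [spaced_mask] (default `"11011"`).
#' @param codec `"aminocode"` or `"dnabits"`.
#' @param mode `"counts"` (default; abstracts are short, multiplicity is
#'   informative) or `"binary"`.
#' @param p Projection length (default 1369).
#' @param seed Basis seed (default 42).
#' @param normalize L2-normalize base vectors (default FALSE).
#' @return Object of class `sweep_config`.
#' @export
sweep_config <- function(mask = "11011", codec = c("aminocode", "dnabits"),
                         mode = c("counts", "binary"), p = 1369, seed = 42,
                         normalize = FALSE) {
  codec <- match.arg(codec)
  mode <- match.arg(mode)
  if (!inherits(mask, "spaced_mask")) mask <- spaced_mask(mask)
  alphabet <- codec_alphabet(codec)
  dimension <- length(bsf_alphabet(alphabet))^mask$weight
  if (p > dimension) {
    stop("p = ", p, " exceeds spaced-word dimension ", dimension,
         " (alphabet ", alphabet, ", weight ", mask$weight, ")")
  }
  structure(list(mask = mask, codec = codec, alphabet = alphabet,
                 mode = mode, p = as.integer(p), seed = as.integer(seed),
                 dimension = dimension, normalize = isTRUE(normalize)),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf("<sweep_config: mask %s, %s/%s, dim %g -> p %d, seed %d%s>\n",
              x$mask$pattern, x$codec, x$mode, x$dimension, x$p, x$seed,
              if (x$normalize) ", L2-normalized" else ""))
  invisible(x)
}

#' Vectorize one document
#'
#' The base vector of a document is the projection of the spaced-word count
#' vector of its encoded normalized title-plus-abstract.
#'
#' @param title,abstract Raw text fields.
#' @param config A [sweep_config].
#' @param basis A [make_basis()] result matching the config; built on the
#'   fly when `NULL`.
#' @return Numeric vector of length `config$p`.
#' @export
vectorize_document <- function(title, abstract, config = sweep_config(),
                               basis = NULL) {
  if (is.null(basis)) basis <- make_basis(config$dimension, config$p, config$seed)
  seq <- bsf_encode(normalize_text(paste(title, abstract)), config$codec)
  v <- index_spaced_words(seq, config$mask, config$alphabet, config$mode)
  out <- project(v, basis)
  if (config$normalize) {
    nrm <- sqrt(sum(out^2))
    if (nrm > 0) out <- out / nrm
  }
  out
}

#' Vectorize a corpus into the base-vector matrix (Wbase)
#'
#' @param x A [corpus].
#' @inheritParams vectorize_document
#' @return An embedding matrix (rows = documents, rownames = doc ids,
#'   `p` columns) with attributes `space_tag = "Wbase"` and `config`.
#' @export
vectorize_corpus <- function(x, config = sweep_config(), basis = NULL) {
  if (is.null(basis)) basis <- make_basis(config$dimension, config$p, config$seed)
  out <- matrix(0, nrow(x), config$p, dimnames = list(x$doc_id, NULL))
  for (i in seq_len(nrow(x))) {
    out[i, ] <- vectorize_document(x$title[i], x$abstract[i], config, basis)
  }
  embedding_matrix(out, "Wbase", config = config)
}
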