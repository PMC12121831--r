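# Text normalization and the two text <-> biological-sequence codecs
# (AMINOcode and DNAbits). Both codecs operate on normalized text only and
# are exact inverses of each other's encode step by construction.

.diacritic_from <- paste0(
  "áàâãäåçéèêë",
  "íìîïñóòôõö",
  "úùûüýÿ",
  "ÁÀÂÃÄÅÇÉÈÊË",
  "ÍÌÎÏÑÓÒÔÕÖ",
  "ÚÙÛÜÝ"
)
.diacritic_to <- paste0(
  "aaaaaaceeee", "iiiinooooo", "uuuuyy",
  "AAAAAACEEEE", "IIIINOOOOO", "UUUUY"
)

# Character inventory of normalized text: A-Z, digits, space, and this
# fixed punctuation set (20 characters).
.inventory_punct <- c(
  ".", ",", ";", ":", "!", "?", "-", "'", "\"", "(",
  ")", "/", "&", "%", "+", "=", "*", "[", "]", "_"
)

#' Character inventory of normalized text
#'
#' @return Character vector of every character a [normalize_text()] result
#'   may contain: the 26 uppercase letters, the 10 digits, the space, and a
#'   fixed set of 20 punctuation marks.
#' @export
text_inventory <- function() {
  c(LETTERS, as.character(0:9), " ", .inventory_punct)
}

#' Normalize raw text to the declared character inventory
#'
#' Uppercases, strips Latin-1 diacritics to their base letters, replaces any
#' character outside the inventory (see [text_inventory()]) with a space,
#' collapses whitespace runs to a single space and trims the ends.
#'
#' @param x Character vector of raw text.
#' @return Character vector of normalized text.
#' @examples
#' normalize_text("café")            # "CAFE"
#' normalize_text("Yoga   &   health")    # "YOGA & HEALTH"
#' @export
normalize_text <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- chartr(.diacritic_from, .diacritic_to, x)
  x <- toupper(x)
  inv <- text_inventory()
  # escape the inventory for use inside a character class
  cls <- paste0("[^", gsub("([][\\^-])", "\\\\\\1", paste(inv, collapse = "")), "]")
  x <- gsub(cls, " ", x, perl = TRUE)
  x <- gsub("[ \t\r\n]+", " ", x)
  trimws(x)
}

#' Biological alphabets
#'
#' @return Character vector of alphabet letters: the 20 amino-acid one-letter
#'   codes for `"amino20"`, the 4 nucleotides for `"dna4"`.
#' @param alphabet `"amino20"` or `"dna4"`.
#' @export
bsf_alphabet <- function(alphabet = c("amino20", "dna4")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "amino20") {
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  } else {
    c("A", "C", "G", "T")
  }
}

# -- AMINOcode ---------------------------------------------------------------

# Prefix-free substitution table over the 20 amino-acid letters. Nineteen
# amino letters code for themselves; 'W' is the escape prefix (it encodes as
# "WW"); the remaining letters, digits, and the space take two-letter W+x
# codes, punctuation takes three-letter WV+x codes. Prefix-freeness makes
# decoding unambiguous (greedy left-to-right).
.build_aminocode_table <- function() {
  aa <- bsf_alphabet("amino20")
  self <- setdiff(aa, "W")
  tab <- c(setNames(self, self), W = "WW")
  non_aa <- c("B", "J", "O", "U", "X", "Z")
  tab[non_aa] <- paste0("W", c("A", "C", "D", "E", "F", "G"))
  tab[as.character(0:9)] <- paste0("W", c("H", "I", "K", "L", "M", "N", "P", "Q", "R", "S"))
  tab[" "] <- "WT"
  tab[.inventory_punct] <- paste0("WV", aa)
  tab[text_inventory()]
}

.aminocode_default <- .build_aminocode_table()

#' The default AMINOcode substitution table
#'
#' One entry per inventory character (see [text_inventory()]); values are
#' prefix-free codes over the 20 amino-acid letters, so decoding is a
#' deterministic greedy scan. The same table ships as a two-column TSV in
#' `inst/extdata/aminocode_default.tsv` and can be swapped for another
#' (e.g. a user-supplied canonical table) via [read_codec_table()].
#'
#' @return Named character vector mapping characters to amino-acid codes.
#' @export
aminocode_table <- function() .aminocode_default

#' Read or write a codec substitution table
#'
#' Tables are two-column tab-separated files (character, code) with a leading
#' `# name` comment line naming the table version.
#'
#' @param path File path.
#' @param table Named character vector (names are single characters).
#' @param name Version name written into the header comment.
#' @return `read_codec_table()` returns a named character vector.
#' @export
read_codec_table <- function(path) {
  if (!file.exists(path)) stop("codec table not found: ", path)
  ln <- readLines(path, encoding = "UTF-8")
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  chars <- vapply(parts, function(p) if (p[[1]] == "<SPACE>") " " else p[[1]], "")
  codes <- vapply(parts, `[[`, "", 2L)
  if (anyDuplicated(chars)) stop("duplicate characters in codec table")
  setNames(codes, chars)
}

#' @rdname read_codec_table
#' @export
write_codec_table <- function(table, path, name = "aminocode-v1") {
  chars <- names(table)
  chars[chars == " "] <- "<SPACE>"
  writeLines(c(paste0("# ", name), paste(chars, table, sep = "\t")), path, useBytes = TRUE)
  invisible(path)
}

# inverted, sorted longest-first for greedy decoding
.decode_map <- function(table) setNames(names(table), table)

#' Encode normalized text as an amino-acid sequence (AMINOcode)
#'
#' Character-wise substitution through a prefix-free table; injective, so
#' [aminocode_decode()] is an exact inverse.
#'
#' @param x Character vector of normalized text (see [normalize_text()]).
#' @param table Substitution table, default [aminocode_table()].
#' @return Character vector of sequences over the 20 amino-acid letters.
#' @export
aminocode_encode <- function(x, table = aminocode_table()) {
  vapply(as.character(x), function(s) {
    if (!nzchar(s)) return("")
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    codes <- table[ch]
    if (anyNA(codes)) {
      bad <- which(is.na(codes))[1]
      stop("aminocode: character not in table: '", ch[bad], "' at position ", bad)
    }
    paste0(codes, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Decode an AMINOcode sequence back to text
#'
#' @param x Character vector of amino-acid sequences produced by
#'   [aminocode_encode()] under the same table.
#' @inheritParams aminocode_encode
#' @return Character vector of normalized text.
#' @export
aminocode_decode <- function(x, table = aminocode_table()) {
  rev_map <- .decode_map(table)
  maxlen <- max(nchar(table))
  vapply(as.character(x), function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    out <- character(0)
    i <- 1L
    while (i <= n) {
      hit <- NA_character_
      for (w in seq_len(min(maxlen, n - i + 1L))) {
        # greedy: try longest code first so escape codes win over 'W' misreads
        cand <- substr(s, i, i + (min(maxlen, n - i + 1L) - w))
        if (!is.na(rev_map[cand])) { hit <- cand; break }
      }
      if (is.na(hit)) {
        stop("aminocode: undecodable sequence at offset ", i - 1L)
      }
      out <- c(out, rev_map[[hit]])
      i <- i + nchar(hit)
    }
    paste0(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# -- DNAbits -----------------------------------------------------------------

.dna_digits <- c("A", "C", "G", "T") # 00, 01, 10, 11

#' Encode normalized text as a DNA sequence (DNAbits)
#'
#' Each character's 8-bit code (Latin-1 range) is emitted as four
#' nucleotides via the 2-bit map 00->A, 01->C, 10->G, 11->T, most
#' significant pair first; the output is exactly 4x the input length.
#' `"A"` (code 65 = 01000001) encodes as `"CAAC"`.
#'
#' @param x Character vector of normalized text.
#' @return Character vector of DNA sequences.
#' @export
dnabits_encode <- function(x) {
  vapply(as.character(x), function(s) {
    if (!nzchar(s)) return("")
    code <- utf8ToInt(s)
    if (any(code > 255L)) {
      bad <- which(code > 255L)[1]
      stop("dnabits: character outside 8-bit range at position ", bad)
    }
    d <- rbind(code %/% 64L, (code %/% 16L) %% 4L, (code %/% 4L) %% 4L, code %% 4L)
    paste0(.dna_digits[as.vector(d) + 1L], collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Decode a DNAbits sequence back to text
#'
#' @param x Character vector of DNA sequences (length divisible by 4,
#'   alphabet ACGT).
#' @return Character vector of normalized text.
#' @export
dnabits_decode <- function(x) {
  vapply(as.character(x), function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    if (n %% 4L != 0L) stop("dnabits: sequence length ", n, " not divisible by 4")
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    d <- match(ch, .dna_digits) - 1L
    if (anyNA(d)) {
      stop("dnabits: invalid symbol '", ch[which(is.na(d))[1]],
           "' at offset ", which(is.na(d))[1] - 1L)
    }
    m <- matrix(d, nrow = 4L)
    intToUtf8(m[1, ] * 64L + m[2, ] * 16L + m[3, ] * 4L + m[4, ])
  }, "", USE.NAMES = FALSE)
}

#' Encode or decode with a codec chosen by name
#'
#' @param x Character vector.
#' @param codec `"aminocode"` or `"dnabits"`.
#' @param table AMINOcode substitution table (ignored for DNAbits).
#' @return Character vector of sequences (`bsf_encode`) or text
#'   (`bsf_decode`).
#' @export
bsf_encode <- function(x, codec = c("aminocode", "dnabits"), table = aminocode_table()) {
  codec <- match.arg(codec)
  if (codec == "aminocode") aminocode_encode(x, table) else dnabits_encode(x)
}

#' @rdname bsf_encode
#' @export
bsf_decode <- function(x, codec = c("aminocode", "dnabits"), table = aminocode_table()) {
  codec <- match.arg(codec)
  if (codec == "aminocode") aminocode_decode(x, table) else dnabits_decode(x)
}

#' Alphabet for a codec
#' @param codec `"aminocode"` or `"dnabits"`.
#' @return `"amino20"` or `"dna4"`.
#' @export
codec_alphabet <- function(codec = c("aminocode", "dnabits")) {
  if (match.arg(codec) == "aminocode") "amino20" else "dna4"
}

# -- FASTA interchange -------------------------------------------------------

#' Write/read encoded corpora as FASTA
#'
#' One record per document, header = document id, so external sequence tools
#' can consume an encoded corpus. Requires the Biostrings package.
#'
#' @param seqs Named character vector of BSF sequences (names are ids).
#' @param path Output file.
#' @param alphabet `"amino20"` or `"dna4"`.
#' @return `read_bsf_fasta()` returns a named character vector.
#' @export
write_bsf_fasta <- function(seqs, path, alphabet = c("amino20", "dna4")) {
  alphabet <- match.arg(alphabet)
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA I/O")
  }
  set <- if (alphabet == "amino20") Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @rdname write_bsf_fasta
#' @export
read_bsf_fasta <- function(path, alphabet = c("amino20", "dna4")) {
  alphabet <- match.arg(alphabet)
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA I/O")
  }
  set <- if (alphabet == "amino20") Biostrings::readAAStringSet(path) else Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}
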