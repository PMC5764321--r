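# Shared constants and small helpers.

# The 20 standard residues; X is the only ambiguity code kept after
# normalization (B/Z/U/J are folded into X at the I/O boundary).
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_ALPHABET <- c(AA_STANDARD, "X")
AA_AMBIGUOUS <- c("B", "Z", "U", "J")

LINEAGES <- c(
  "plant", "vertebrate", "invertebrate", "fungus",
  "kinetoplast", "ciliate", "other"
)

#' Normalize an amino-acid sequence
#'
#' Uppercases, strips a single terminal stop (`*`), maps the ambiguity codes
#' B/Z/U/J to `X` (with a warning), and errors on any character outside the
#' 20-letter alphabet plus `X`, reporting its position.
#'
#' @param seq Character scalar, an amino-acid sequence.
#' @param id Identifier used in error messages.
#' @return The normalized sequence (character scalar).
#' @export
#' @examples
#' normalize_seq("macd*")
normalize_seq <- function(seq, id = "<sequence>") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  s <- sub("\\*$", "", s)
  if (!nzchar(s)) {
    stop(sprintf("sequence '%s' is empty after normalization", id), call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  amb <- chars %in% AA_AMBIGUOUS
  if (any(amb)) {
    warning(sprintf(
      "sequence '%s': %d ambiguous residue(s) (%s) mapped to X",
      id, sum(amb), paste(unique(chars[amb]), collapse = ",")
    ), call. = FALSE)
    chars[amb] <- "X"
  }
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    pos <- which(bad)[1L]
    stop(sprintf(
      "sequence '%s': illegal character '%s' at position %d",
      id, chars[pos], pos
    ), call. = FALSE)
  }
  paste(chars, collapse = "")
}

# split a sequence into a character vector of residues
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# check a lineage tag, mapping unknown values to "other"
normalize_lineage <- function(x) {
  x <- tolower(as.character(x %||% "other"))
  ifelse(x %in% LINEAGES, x, "other")
}

assert_protein_tbl <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("id", "lineage", "seq") %in% names(records))) {
    stop("expected a protein tibble with columns id, lineage, seq", call. = FALSE)
  }
  invisible(records)
}
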