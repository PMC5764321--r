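# FASTA I/O for protein records.

#' Read a protein FASTA file
#'
#' Sequences are uppercased, a single terminal stop (`*`) is stripped,
#' B/Z/U/J are mapped to X with a warning, and any other non-alphabet
#' character is an error reporting its position.  A `lineage=<tag>` key in
#' the description sets the record's lineage; unknown or absent tags map to
#' `"other"`.  The record id is the first whitespace-delimited token of the
#' header.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id`, `lineage`, `seq`.
#' @export
read_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    stop(sprintf("FASTA file '%s' contains no records", path), call. = FALSE)
  }
  headers <- names(raw)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  lineage <- normalize_lineage(
    ifelse(grepl("lineage=", headers),
           sub(".*lineage=([^ \t]+).*", "\\1", headers),
           "other")
  )
  seqs <- vapply(seq_along(raw), function(i) {
    normalize_seq(as.character(raw[[i]]), id = ids[i])
  }, character(1L))
  tibble::tibble(id = ids, lineage = lineage, seq = unname(seqs))
}

#' Write protein records to FASTA
#'
#' The lineage tag is carried in the description as `lineage=<tag>` so that
#' [read_fasta()] round-trips the record set.
#'
#' @param records Protein tibble (`id`, `lineage`, `seq`).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  assert_protein_tbl(records)
  lines <- unlist(purrr::pmap(
    list(records$id, records$lineage, records$seq),
    function(id, lineage, seq) {
      body <- substring(seq, seq(1L, nchar(seq), by = width),
                        pmin(seq(width, nchar(seq) + width - 1L, by = width),
                             nchar(seq)))
      c(sprintf(">%s lineage=%s", id, lineage), body)
    }
  ))
  writeLines(lines, path)
  invisible(path)
}
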