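# TSV report writers and Newick serialization.

# collapse list-columns of integer vectors to comma-joined strings
flatten_list_cols <- function(tbl) {
  is_list <- vapply(tbl, is.list, logical(1L))
  for (nm in names(tbl)[is_list]) {
    tbl[[nm]] <- vapply(tbl[[nm]], function(x) paste(x, collapse = ","),
                        character(1L), USE.NAMES = FALSE)
  }
  tbl
}

#' Write a hits or calls table to TSV
#'
#' List-columns (ligand positions, spacings, inserts, evidence) are
#' comma-joined; an empty table produces a header-only file.
#'
#' @param hits Tibble (e.g. from [scan_ring_domains()], [scan_motif()],
#'   [classify_proteome()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  tbl <- flatten_list_cols(hits)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a TSV written by [write_hits_tsv()]
#'
#' @param path Path to a TSV file.
#' @return A tibble (list-columns stay comma-joined strings).
#' @export
read_hits_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(
    path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    colClasses = NA, check.names = FALSE
  ))
}

# serialize an ape phylo to Newick with fixed 6-decimal branch lengths and
# optional internal-node labels (bootstrap supports)
phylo_to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  lab <- function(node) {
    if (node <= n_tip) {
      return(tree$tip.label[node])
    }
    if (!is.null(tree$node.label)) {
      l <- tree$node.label[node - n_tip]
      if (!is.na(l) && nzchar(l)) return(l)
    }
    ""
  }
  build <- function(node) {
    rows <- children[[as.character(node)]]
    if (is.null(rows)) {
      return(lab(node))
    }
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2L]
      len <- if (is.null(tree$edge.length)) 1 else tree$edge.length[r]
      sprintf("%s:%.6f", build(child), len)
    }, character(1L))
    sprintf("(%s)%s", paste(parts, collapse = ","), lab(node))
  }
  paste0(build(root), ";")
}

#' Write a tree to Newick
#'
#' Branch lengths are written with six decimals; internal-node labels (e.g.
#' bootstrap supports from [bootstrap_support()]) are preserved.
#'
#' @param tree An `ape` `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(phylo_to_newick(tree), path)
  invisible(path)
}
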