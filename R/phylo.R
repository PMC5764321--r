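# Domain-anchored alignment, distances, Neighbor-Joining, bootstrap and
# anchor-based group assignment.
#
# Instead of a general-purpose aligner, RING domains are aligned by their
# grammar: the eight metal-ligand positions are fixed columns and each
# inter-ligand spacer block is right-padded with '-' to the longest spacer
# observed at that block.  This is deterministic and exact for domains
# recognised by the same ligand scheme.

#' Align RING domains on their metal-ligand anchors
#'
#' @param hits RING-hit tibble ([scan_ring_domains()]); needs >= 2 hits, all
#'   with the same number of ligand positions.
#' @param records Protein tibble supplying the sequences.
#' @param ids Optional row labels; defaults to `protein_id`, suffixed when a
#'   protein has several hits.
#' @return An `anchored_alignment`: list with `rows` (named character vector
#'   of equal-length aligned strings) and `block_width` (spacer widths).
#' @export
anchor_align <- function(hits, records, ids = NULL) {
  if (nrow(hits) < 2L) {
    stop("anchored alignment needs at least 2 domain hits", call. = FALSE)
  }
  n_lig <- unique(vapply(hits$ligand_pos, length, integer(1L)))
  if (length(n_lig) != 1L) {
    stop("hits use incompatible ligand schemes (differing ligand counts)",
         call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- hits$protein_id
    if (anyDuplicated(ids)) {
      ids <- make.unique(ids, sep = "#")
    }
  }
  seqs <- records$seq[match(hits$protein_id, records$id)]
  if (anyNA(seqs)) {
    stop("hit protein_id missing from records", call. = FALSE)
  }
  spacers <- purrr::map2(seqs, hits$ligand_pos, function(seq, pos) {
    vapply(seq_len(n_lig - 1L), function(k) {
      if (pos[k + 1L] - pos[k] == 1L) "" else
        substr(seq, pos[k] + 1L, pos[k + 1L] - 1L)
    }, character(1L))
  })
  widths <- apply(do.call(rbind, lapply(spacers, nchar)), 2L, max)
  rows <- purrr::pmap_chr(
    list(seqs, hits$ligand_pos, spacers),
    function(seq, pos, sp) {
      parts <- character(0)
      for (k in seq_len(n_lig)) {
        parts <- c(parts, substr(seq, pos[k], pos[k]))
        if (k < n_lig) {
          parts <- c(parts, sp[k], strrep("-", widths[k] - nchar(sp[k])))
        }
      }
      paste(parts, collapse = "")
    }
  )
  structure(
    list(rows = setNames(rows, ids), block_width = widths),
    class = "anchored_alignment"
  )
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat(sprintf("<anchored_alignment> %d rows x %d columns\n",
              length(x$rows), nchar(x$rows[[1L]])))
  invisible(x)
}

#' Pairwise distances on an anchored alignment
#'
#' Pairwise-deletion p-distance: columns where either row carries a gap are
#' skipped for that pair; `model = "poisson"` applies the correction
#' d = -ln(1 - p).
#'
#' @param aln An `anchored_alignment` (or named character vector of
#'   equal-length aligned strings).
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
aln_distances <- function(aln, model = c("p", "poisson")) {
  model <- match.arg(model)
  rows <- if (inherits(aln, "anchored_alignment")) aln$rows else aln
  stopifnot(length(rows) >= 2L, length(unique(nchar(rows))) == 1L)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     names(rows)[i], names(rows)[j]), call. = FALSE)
      }
      p <- mean(mat[i, ok] != mat[j, ok])
      d <- if (model == "poisson") {
        if (p >= 1) {
          stop(sprintf("Poisson distance undefined for p = 1 ('%s' vs '%s')",
                       names(rows)[i], names(rows)[j]), call. = FALSE)
        }
        -log(1 - p)
      } else {
        p
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

validate_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || is.null(rownames(D))) {
    stop("distance matrix must be square with row/col names", call. = FALSE)
  }
  if (any(D < 0)) {
    stop("distance matrix has negative entries", call. = FALSE)
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12)) ||
      any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  invisible(D)
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration.  Ties in Q are broken by the smallest
#' (row, column) index pair in the current matrix; negative branch lengths
#' are clamped to zero with a warning.  For n = 3 the closed-form three-taxon
#' solution is used; for n = 2 the two leaves are joined by a path of total
#' length d.  The returned tree is unrooted (basal multifurcation).
#'
#' @param D Symmetric distance matrix with zero diagonal and labels.
#' @return An `ape` `phylo` object.
#' @export
#' @examples
#' D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighbor_joining(D)
neighbor_joining <- function(D) {
  validate_distance_matrix(D)
  n <- nrow(D)
  if (n < 2L) {
    stop("need at least 2 taxa", call. = FALSE)
  }
  clamp <- function(v) {
    if (any(v < 0)) {
      warning("negative branch length(s) clamped to 0", call. = FALSE)
      v[v < 0] <- 0
    }
    v
  }
  fmt <- function(x) sprintf("%.15g", x)
  # each active node carries a newick fragment; join until 3 remain
  labels <- rownames(D)
  frag <- labels
  if (n == 2L) {
    v <- clamp(rep(D[1L, 2L] / 2, 2L))
    nwk <- sprintf("(%s:%s,%s:%s);", frag[1L], fmt(v[1L]), frag[2L], fmt(v[2L]))
    return(ape::read.tree(text = nwk))
  }
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # smallest (i, j), i < j, among minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]
    j <- best[1L, 2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    v <- clamp(c(vi, vj))
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(v[1L]),
                        frag[j], fmt(v[2L]))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    lbl <- c(rownames(D)[keep], sprintf("u%d", m))
    dimnames(D2) <- list(lbl, lbl)
    D <- D2
    frag <- c(frag[keep], new_frag)
  }
  v <- clamp(c(
    (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2,
    (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2,
    (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  ))
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1L], fmt(v[1L]), frag[2L], fmt(v[2L]),
                 frag[3L], fmt(v[3L]))
  ape::read.tree(text = nwk)
}

# non-trivial bipartitions of an unrooted tree, as canonical keys
tree_splits <- function(tree) {
  n_tip <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  root <- n_tip + 1L
  internal <- setdiff(unique(tree$edge[, 2L]), seq_len(n_tip))
  keys <- vapply(internal, function(node) {
    tips <- sort(tree$tip.label[clade_tips(tree, node)])
    if (length(tips) <= 1L || length(tips) >= n_tip - 1L) {
      return(NA_character_)
    }
    if (all_tips[1L] %in% tips) {
      tips <- setdiff(all_tips, tips)
    }
    paste(tips, collapse = "|")
  }, character(1L))
  stats::setNames(keys, internal)
}

# tip indices under an internal node
clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  out <- integer(0)
  for (k in kids) {
    out <- c(out, if (k <= n_tip) k else clade_tips(tree, k))
  }
  out
}

#' Neighbor-Joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and labels each internal node of the original tree with the
#' fraction of replicates containing the corresponding bipartition.
#'
#' @inheritParams aln_distances
#' @param n_reps Number of bootstrap replicates (the reference analysis used
#'   1000).
#' @param seed Integer seed; the whole procedure is reproducible.
#' @param model Distance model passed to [aln_distances()].
#' @return A `phylo` tree whose `node.label` holds supports in `[0, 1]`
#'   (empty for the root and trivial splits).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L,
                              model = c("p", "poisson")) {
  model <- match.arg(model)
  stopifnot(n_reps >= 1L)
  rows <- if (inherits(aln, "anchored_alignment")) aln$rows else aln
  tree <- neighbor_joining(aln_distances(rows, model))
  splits <- tree_splits(tree)
  counts <- stats::setNames(numeric(length(splits)), names(splits))
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- names(rows)
  n_col <- ncol(mat)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(n_col, n_col, replace = TRUE)
    rep_rows <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    rep_tree <- suppressWarnings(
      neighbor_joining(aln_distances(rep_rows, model))
    )
    rep_splits <- tree_splits(rep_tree)
    hit <- !is.na(splits) & splits %in% rep_splits
    counts[hit] <- counts[hit] + 1
  }
  support <- counts / n_reps
  n_tip <- length(tree$tip.label)
  node_lab <- rep("", tree$Nnode)
  for (k in seq_along(splits)) {
    if (!is.na(splits[k])) {
      node <- as.integer(names(splits)[k])
      node_lab[node - n_tip] <- sprintf("%.3f", support[k])
    }
  }
  tree$node.label <- node_lab
  tree
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(list = ".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Assign leaves to groups by nearest reference anchor
#'
#' Each non-anchor leaf takes the group of its nearest anchor by tree path
#' length.  Leaves whose nearest-group margin is ambiguous — the best anchor
#' of a different group is within `margin` (relative) of the nearest — go to
#' the catch-all group `"H"`, mirroring the treatment of plant CTLs that
#' lacked phylogenetic congruence.
#'
#' @param tree A `phylo` tree.
#' @param anchors Named character vector or list mapping group -> anchor leaf
#'   id(s).
#' @param margin Relative margin below which assignment is ambiguous
#'   (default 0.1).
#' @return Tibble with columns `id`, `group`.
#' @export
assign_groups <- function(tree, anchors, margin = 0.1) {
  if (length(anchors) == 0L) {
    stop("anchor set is empty", call. = FALSE)
  }
  anchor_ids <- unlist(anchors, use.names = FALSE)
  anchor_grp <- rep(names(anchors), lengths(anchors))
  missing <- setdiff(anchor_ids, tree$tip.label)
  if (length(missing) > 0L) {
    stop(sprintf("anchor id(s) not in tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  D <- ape::cophenetic.phylo(tree)
  out <- purrr::map_chr(tree$tip.label, function(leaf) {
    if (leaf %in% anchor_ids) {
      return(anchor_grp[match(leaf, anchor_ids)])
    }
    d <- D[leaf, anchor_ids]
    d1 <- min(d)
    g1 <- anchor_grp[which.min(d)]
    if (d1 == 0) {
      return(g1)
    }
    other <- anchor_grp != g1
    if (!any(other)) {
      return(g1)
    }
    d2 <- min(d[other])
    if ((d2 - d1) / d1 < margin) "H" else g1
  })
  tibble::tibble(id = tree$tip.label, group = out)
}
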