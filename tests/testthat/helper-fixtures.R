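# Shared fixtures and independent oracles.

AA_STANDARD_TEST <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Build a RING domain string from explicit gaps: ligand residues C,C,C,H,H
# (or lig5 override), C,C,C separated by `gaps` filler residues.
build_ring_seq <- function(gaps = c(2, 14, 2, 2, 2, 10, 2), lig5 = "H",
                           filler = "A", pre = "", post = "") {
  ligands <- c("C", "C", "C", "H", lig5, "C", "C", "C")
  out <- character(0)
  for (k in 1:8) {
    out <- c(out, ligands[k])
    if (k < 8) out <- c(out, strrep(filler, gaps[k]))
  }
  paste0(pre, paste(out, collapse = ""), post)
}

protein_rec <- function(seq, id = "p1", lineage = "other") {
  tibble::tibble(id = id, lineage = lineage, seq = seq)
}

# Reference gene layouts mirroring published plant CTL architectures:
# ath|CTL01 has 5'UTR introns of 235 and 472 nt and 4 CDS introns;
# ath|CTL17 has no 5'UTR intron and 8 CDS introns.
ath_ctl01_layout <- function(strand = "+") {
  list(gene_id = "ath_CTL01", strand = strand,
       utr5_exons = c(120, 90, 60), utr5_introns = c(235, 472),
       cds_exons = c(150, 120, 120, 120, 150),
       cds_introns = c(88, 95, 102, 110))
}

ath_ctl17_layout <- function(strand = "+") {
  list(gene_id = "ath_CTL17", strand = strand,
       utr5_exons = integer(0),
       cds_exons = rep(120, 9), cds_introns = seq(81, 88))
}

# ---- brute-force RING oracle: level-wise join over all index 8-tuples ----

oracle_ring_tuples <- function(chars, profile) {
  cls <- profile$ligand_classes
  smin <- profile$spacing[, "min"]
  smax <- profile$spacing[, "max"]
  tuples <- matrix(which(chars %in% cls[[1L]]), ncol = 1L)
  for (k in 2:8) {
    out <- list()
    for (r in seq_len(nrow(tuples))) {
      last <- tuples[r, k - 1L]
      rng <- (last + smin[k - 1L] + 1L):(last + smax[k - 1L] + 1L)
      rng <- rng[rng >= 1L & rng <= length(chars)]
      rng <- rng[chars[rng] %in% cls[[k]]]
      for (p in rng) out[[length(out) + 1L]] <- c(tuples[r, ], p)
    }
    if (length(out) == 0L) return(matrix(integer(0), ncol = 8L))
    tuples <- do.call(rbind, out)
  }
  tuples
}

# spec overlap rule, written plainly: leftmost start, then minimal total
# |insert|, then lexicographic; no shared ligand positions
oracle_ring_resolve <- function(tuples, canonical) {
  if (nrow(tuples) == 0L) return(tuples)
  ins <- apply(tuples, 1L, function(t) sum(abs((diff(t) - 1L) - canonical)))
  key <- do.call(order, c(list(tuples[, 1L], ins),
                          lapply(2:8, function(j) tuples[, j])))
  tuples <- tuples[key, , drop = FALSE]
  taken <- integer(0)
  keep <- c()
  for (i in seq_len(nrow(tuples))) {
    if (length(intersect(tuples[i, ], taken)) == 0L) {
      keep <- c(keep, i)
      taken <- c(taken, tuples[i, ])
    }
  }
  tuples[keep, , drop = FALSE]
}

oracle_ring_scan <- function(seq, profile) {
  chars <- strsplit(seq, "")[[1L]]
  oracle_ring_resolve(oracle_ring_tuples(chars, profile),
                      profile$canonical_spacing)
}

# ---- brute-force motif oracle: per-window position loop ----

oracle_motif_scan <- function(seq, pattern, budget) {
  chars <- strsplit(seq, "")[[1L]]
  m <- length(pattern$positions)
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  if (length(chars) < m) return(hits)
  for (s in 1:(length(chars) - m + 1L)) {
    mm <- 0L
    for (k in seq_len(m)) {
      allowed <- pattern$positions[[k]]
      if (is.null(allowed)) next
      if (!(chars[s + k - 1L] %in% allowed)) mm <- mm + 1L
    }
    if (mm <= budget) {
      hits <- rbind(hits, data.frame(start = s, mismatches = mm))
    }
  }
  hits
}

# ---- additive matrices and brute-force topology enumeration ----

random_additive_tree <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  tr
}

# tips (indices) below each edge's child, as a logical mask matrix
edge_masks <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, desc))
  }
  t(vapply(seq_len(nrow(tree$edge)), function(e) {
    mask <- rep(FALSE, n_tip)
    mask[desc(tree$edge[e, 2L])] <- TRUE
    mask
  }, logical(n_tip)))
}

# least-squares branch lengths of D on a fixed topology; returns
# list(lengths, rss)
ls_fit_topology <- function(topo, D) {
  labs <- rownames(D)
  ord <- match(topo$tip.label, labs)
  n <- length(labs)
  masks <- edge_masks(topo)
  pairs <- t(utils::combn(n, 2L))
  X <- vapply(seq_len(nrow(masks)), function(e) {
    mask <- masks[e, ]
    xor(mask[pairs[, 1L]], mask[pairs[, 2L]])
  }, logical(nrow(pairs)))
  y <- D[cbind(ord[pairs[, 1L]], ord[pairs[, 2L]])]
  fit <- stats::lm.fit(X * 1, y)
  list(lengths = fit$coefficients, rss = sum(fit$residuals^2))
}

# brute-force: the unique additive topology for D among all unrooted trees
brute_force_best_topology <- function(D) {
  labs <- rownames(D)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  rss <- vapply(topos, function(tp) ls_fit_topology(tp, D)$rss, numeric(1L))
  topos[[which.min(rss)]]
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# path-length matrix of a tree, in the order of labels
tree_metric <- function(tree, labs) {
  M <- ape::cophenetic.phylo(tree)
  M[labs, labs]
}
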