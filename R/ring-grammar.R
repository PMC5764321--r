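# RING-domain detection by a position grammar over the eight metal ligands.

# All positions of `chars` whose residue is in `class` (a character vector).
class_positions <- function(chars, class) which(chars %in% class)

# Enumerate every 8-tuple of strictly increasing positions whose residues
# satisfy the profile's ligand classes and whose 7 gaps (residues strictly
# between consecutive ligands) fall in the profile ranges.  Returns an
# integer matrix with one row per placement.  X never satisfies a class.
ring_enumerate <- function(chars, profile) {
  n <- length(chars)
  smin <- profile$spacing[, "min"]
  smax <- profile$spacing[, "max"]
  min_span <- 8L + sum(smin)
  if (n < min_span) {
    return(matrix(integer(0), ncol = 8L))
  }
  out <- list()
  n_out <- 0L
  tuple <- integer(8L)
  recurse <- function(k, pos) {
    tuple[k] <<- pos
    if (k == 8L) {
      n_out <<- n_out + 1L
      out[[n_out]] <<- tuple
      return(invisible(NULL))
    }
    lo <- pos + smin[k] + 1L
    hi <- min(pos + smax[k] + 1L, n)
    if (lo > hi) return(invisible(NULL))
    cand <- lo:hi
    cand <- cand[chars[cand] %in% profile$ligand_classes[[k + 1L]]]
    for (p in cand) recurse(k + 1L, p)
    invisible(NULL)
  }
  starts <- class_positions(chars, profile$ligand_classes[[1L]])
  starts <- starts[starts + min_span - 1L <= n]
  for (p in starts) recurse(1L, p)
  if (n_out == 0L) {
    return(matrix(integer(0), ncol = 8L))
  }
  do.call(rbind, out)
}

# Greedy overlap resolution: leftmost start first; among candidates with the
# same start, minimal total |insert|, then lexicographically smallest tuple;
# a candidate is dropped if it shares any ligand position with an accepted hit.
ring_resolve <- function(tuples, canonical_spacing) {
  if (nrow(tuples) == 0L) {
    return(tuples)
  }
  gaps <- tuples[, -1L, drop = FALSE] - tuples[, -8L, drop = FALSE] - 1L
  total_insert <- rowSums(abs(sweep(gaps, 2L, canonical_spacing)))
  ord <- do.call(order, c(
    list(tuples[, 1L], total_insert),
    lapply(2:8, function(j) tuples[, j])
  ))
  tuples <- tuples[ord, , drop = FALSE]
  used <- integer(0)
  keep <- logical(nrow(tuples))
  for (i in seq_len(nrow(tuples))) {
    if (!any(tuples[i, ] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, tuples[i, ])
    }
  }
  tuples[keep, , drop = FALSE]
}

#' Type the RING variant at a placement
#'
#' The fifth metal ligand distinguishes the two major RING variants:
#' histidine gives RING-H2, cysteine the canonical RING-HC.
#'
#' @param seq Normalized amino-acid sequence.
#' @param ligand_pos Integer vector of 8 ligand positions (1-based).
#' @return `"RING-H2"` or `"RING-HC"`.
#' @export
classify_variant <- function(seq, ligand_pos) {
  r5 <- substr(seq, ligand_pos[5L], ligand_pos[5L])
  if (r5 == "H") {
    "RING-H2"
  } else if (r5 == "C") {
    "RING-HC"
  } else {
    stop(sprintf(
      "residue '%s' at ligand position 5 violates the RING grammar", r5
    ), call. = FALSE)
  }
}

#' Evaluate family-diagnostic residues around a RING placement
#'
#' The ATL family is marked by three residues — Leu one position downstream of
#' the second metal ligand, Arg four positions upstream of the third, and Asp
#' one position downstream of the sixth; BTL by a Pro two positions downstream
#' of the sixth ligand.  A conserved Pro adjacent to the third ligand
#' (upstream side) is reported as `adjacent` / `separated_by_one` / `absent`.
#'
#' @inheritParams classify_variant
#' @return A one-row tibble of diagnostic flags.
#' @export
match_diagnostics <- function(seq, ligand_pos) {
  chars <- seq_chars(seq)
  n <- length(chars)
  at <- function(pos, res) {
    if (pos < 1L || pos > n) {
      warning(sprintf(
        "diagnostic offset %d outside sequence (length %d); flag set FALSE",
        pos, n
      ), call. = FALSE)
      return(FALSE)
    }
    chars[pos] == res
  }
  pro <- if (ligand_pos[3L] - 1L >= 1L && chars[ligand_pos[3L] - 1L] == "P") {
    "adjacent"
  } else if (ligand_pos[3L] - 2L >= 1L && chars[ligand_pos[3L] - 2L] == "P") {
    "separated_by_one"
  } else {
    "absent"
  }
  tibble::tibble(
    atl_L_at_lig2p1 = at(ligand_pos[2L] + 1L, "L"),
    atl_R_at_lig3m4 = at(ligand_pos[3L] - 4L, "R"),
    atl_D_at_lig6p1 = at(ligand_pos[6L] + 1L, "D"),
    btl_P_at_lig6p2 = at(ligand_pos[6L] + 2L, "P"),
    pro_adjacent_lig3 = pro
  )
}

#' Scan proteins for RING domains under a lineage spacing profile
#'
#' Finds every placement of eight metal-ligand residues whose seven
#' inter-ligand gaps fall within the profile's ranges, resolves overlaps
#' (leftmost start first, then minimal total insert; reported hits never share
#' a ligand position), types the RING-H2/RING-HC variant, and evaluates the
#' ATL/BTL diagnostic residues.
#'
#' @param records Protein tibble with columns `id`, `lineage`, `seq`
#'   (as returned by [read_fasta()] or [generate_proteome()]).
#' @param profile A single [lineage_profile] to use for every record, or
#'   `NULL` to pick per record from `profiles` by its lineage tag.
#' @param profiles Named profile list used when `profile` is `NULL`;
#'   see [ctl_profiles()].
#' @return A tibble with one row per hit: `protein_id`, `profile`, `start`,
#'   `end` (1-based inclusive span of the domain), `variant`, list-columns
#'   `ligand_pos`, `spacing`, `inserts`, and the diagnostic flag columns of
#'   [match_diagnostics()].
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   id = "p1", lineage = "plant",
#'   seq = paste0(
#'     "C", "AA", "C", strrep("A", 14), "C", "AA", "H", "AA", "H",
#'     "AA", "C", strrep("A", 10), "C", "AA", "C"
#'   )
#' )
#' scan_ring_domains(rec)
scan_ring_domains <- function(records, profile = NULL,
                              profiles = ctl_profiles()) {
  assert_protein_tbl(records)
  rows <- purrr::pmap(
    list(records$id, records$lineage, records$seq),
    function(id, lineage, seq) {
      prof <- profile %||% profile_for_lineage(lineage, profiles)
      scan_ring_one(id, seq, prof)
    }
  )
  dplyr::bind_rows(c(list(ring_hit_prototype()), rows))
}

ring_hit_prototype <- function() {
  tibble::tibble(
    protein_id = character(0), profile = character(0),
    start = integer(0), end = integer(0), variant = character(0),
    ligand_pos = list(), spacing = list(), inserts = list(),
    atl_L_at_lig2p1 = logical(0), atl_R_at_lig3m4 = logical(0),
    atl_D_at_lig6p1 = logical(0), btl_P_at_lig6p2 = logical(0),
    pro_adjacent_lig3 = character(0)
  )
}

scan_ring_one <- function(id, seq, profile) {
  chars <- seq_chars(seq)
  tuples <- ring_resolve(ring_enumerate(chars, profile),
                         profile$canonical_spacing)
  if (nrow(tuples) == 0L) {
    return(ring_hit_prototype())
  }
  prof_name <- profile$name
  canon <- profile$canonical_spacing
  purrr::map_dfr(seq_len(nrow(tuples)), function(i) {
    pos <- tuples[i, ]
    gaps <- diff(pos) - 1L
    dplyr::bind_cols(
      tibble::tibble(
        protein_id = id, profile = prof_name,
        start = pos[1L], end = pos[8L],
        variant = classify_variant(seq, pos),
        ligand_pos = list(pos),
        spacing = list(gaps),
        inserts = list(gaps - canon)
      ),
      match_diagnostics(seq, pos)
    )
  })
}
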