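# ATL / BTL / CTL family calling from RING hits, diagnostics and motif hits.
#
# Decision order (first rule that fires wins):
#   1. no RING-H2 hit                                  -> none
#   2. YEELL within budget strictly upstream of ligand 1,
#      gap <= upstream window                          -> CTL
#   3. >= atl_min_flags of the 3 ATL diagnostics       -> ATL
#   4. BTL Pro diagnostic                              -> BTL
#   5. YEELL upstream at the degraded budget
#      (budget + degraded_extra)                       -> CTL-like
#   6. otherwise                                       -> RING-H2-unclassified
# YEELL co-occurrence takes precedence over the residue diagnostics because
# it is the family-defining criterion for CTLs.

FAMILY_LABELS <- c("ATL", "BTL", "CTL", "CTL-like", "RING-H2-unclassified",
                   "none")

#' Classification parameters
#'
#' @param max_mismatch YEELL mismatch budget for a CTL call (default 3).
#' @param upstream_window Maximum residues between motif end and the first
#'   metal ligand (default 150).
#' @param atl_min_flags ATL diagnostics required (default 2 of 3).
#' @param degraded_extra Extra mismatches tolerated for a CTL-like call
#'   (default 2).
#' @return Named list of parameters.
#' @export
classify_params <- function(max_mismatch = 3L, upstream_window = 150L,
                            atl_min_flags = 2L, degraded_extra = 2L) {
  list(
    max_mismatch = as.integer(max_mismatch),
    upstream_window = as.integer(upstream_window),
    atl_min_flags = as.integer(atl_min_flags),
    degraded_extra = as.integer(degraded_extra)
  )
}

# best upstream motif hit for a given ligand-1 position: within the gap
# window and mismatch budget; fewest mismatches, then largest end (nearest)
best_upstream_motif <- function(motif_hits, lig1, budget, window) {
  if (nrow(motif_hits) == 0L) {
    return(NULL)
  }
  cand <- dplyr::filter(
    motif_hits,
    .data$end < lig1,
    lig1 - .data$end - 1L <= window,
    .data$mismatches <= budget
  )
  if (nrow(cand) == 0L) {
    return(NULL)
  }
  cand <- dplyr::arrange(cand, .data$mismatches, dplyr::desc(.data$end))
  cand[1L, ]
}

classify_one <- function(id, ring_hits, motif_hits, params) {
  call_row <- function(label, ring = NULL, motif = NULL, evidence = character(0)) {
    lig1 <- if (!is.null(ring)) ring$ligand_pos[[1L]][1L] else NA_integer_
    tibble::tibble(
      protein_id = id,
      label = label,
      ring_start = if (is.null(ring)) NA_integer_ else ring$start,
      ring_end = if (is.null(ring)) NA_integer_ else ring$end,
      variant = if (is.null(ring)) NA_character_ else ring$variant,
      motif_start = if (is.null(motif)) NA_integer_ else motif$start,
      motif_end = if (is.null(motif)) NA_integer_ else motif$end,
      motif_mismatches = if (is.null(motif)) NA_integer_ else motif$mismatches,
      gap_to_ring = if (is.null(motif) || is.null(ring)) {
        NA_integer_
      } else {
        lig1 - motif$end - 1L
      },
      evidence = list(evidence)
    )
  }
  ring_hits <- dplyr::filter(ring_hits, .data$variant == "RING-H2")
  if (nrow(ring_hits) == 0L) {
    return(call_row("none", evidence = "no RING-H2 domain"))
  }
  if (nrow(ring_hits) > 1L) {
    # classify against the hit maximizing evidence: prefer one with a
    # qualifying upstream motif, then more diagnostic flags, then leftmost
    score <- vapply(seq_len(nrow(ring_hits)), function(i) {
      h <- ring_hits[i, ]
      lig1 <- h$ligand_pos[[1L]][1L]
      has_motif <- !is.null(best_upstream_motif(
        motif_hits, lig1, params$max_mismatch + params$degraded_extra,
        params$upstream_window
      ))
      flags <- sum(h$atl_L_at_lig2p1, h$atl_R_at_lig3m4, h$atl_D_at_lig6p1,
                   h$btl_P_at_lig6p2)
      10L * has_motif + flags
    }, numeric(1L))
    keep <- which(score == max(score))[1L]
    message(sprintf(
      "protein '%s': %d RING-H2 hits; classifying against hit %d",
      id, nrow(ring_hits), keep
    ))
    ring_hits <- ring_hits[keep, , drop = FALSE]
  }
  ring <- ring_hits[1L, ]
  lig1 <- ring$ligand_pos[[1L]][1L]
  evidence <- sprintf("RING-H2 at %d-%d (profile %s)", ring$start, ring$end,
                      ring$profile)

  motif <- best_upstream_motif(motif_hits, lig1, params$max_mismatch,
                               params$upstream_window)
  if (!is.null(motif)) {
    evidence <- c(evidence, sprintf(
      "YEELL at %d-%d (%d mismatch(es)) %d residues upstream of ligand 1",
      motif$start, motif$end, motif$mismatches, lig1 - motif$end - 1L
    ))
    return(call_row("CTL", ring, motif, evidence))
  }

  n_atl <- sum(ring$atl_L_at_lig2p1, ring$atl_R_at_lig3m4, ring$atl_D_at_lig6p1)
  if (n_atl >= params$atl_min_flags) {
    fired <- c("L@lig2+1", "R@lig3-4", "D@lig6+1")[
      c(ring$atl_L_at_lig2p1, ring$atl_R_at_lig3m4, ring$atl_D_at_lig6p1)
    ]
    evidence <- c(evidence, sprintf("ATL diagnostics: %s",
                                    paste(fired, collapse = ", ")))
    return(call_row("ATL", ring, evidence = evidence))
  }

  if (isTRUE(ring$btl_P_at_lig6p2)) {
    evidence <- c(evidence, "BTL diagnostic: P@lig6+2")
    return(call_row("BTL", ring, evidence = evidence))
  }

  degraded <- best_upstream_motif(
    motif_hits, lig1, params$max_mismatch + params$degraded_extra,
    params$upstream_window
  )
  if (!is.null(degraded)) {
    evidence <- c(evidence, sprintf(
      "degraded YEELL at %d-%d (%d mismatches)",
      degraded$start, degraded$end, degraded$mismatches
    ))
    return(call_row("CTL-like", ring, degraded, evidence))
  }

  call_row("RING-H2-unclassified", ring,
           evidence = c(evidence, "no qualifying motif or diagnostics"))
}

#' Classify one protein from precomputed hits
#'
#' @param record One-row protein tibble.
#' @param ring_hits RING hits for this protein ([scan_ring_domains()]).
#' @param motif_hits YEELL motif hits for this protein ([scan_motif()]).
#' @param params See [classify_params()].
#' @return One-row call tibble (`protein_id`, `label`, ring/motif
#'   coordinates, `gap_to_ring`, `evidence` list-column).
#' @export
classify_protein <- function(record, ring_hits, motif_hits,
                             params = classify_params()) {
  stopifnot(nrow(record) == 1L)
  classify_one(record$id,
               dplyr::filter(ring_hits, .data$protein_id == record$id),
               dplyr::filter(motif_hits, .data$protein_id == record$id),
               params)
}

#' Classify a whole proteome
#'
#' Runs the RING scanner (per-lineage profiles), the YEELL motif scanner at
#' the degraded budget, and the family decision rules over every record.
#'
#' @param records Protein tibble (`id`, `lineage`, `seq`).
#' @param profiles Named list of lineage profiles ([ctl_profiles()]).
#' @param patterns Named list of motif patterns ([ctl_patterns()]); the
#'   `yeell` entry is used for family calling.
#' @param params See [classify_params()].
#' @return A `ctl_calls` tibble: one call row per record (see
#'   [classify_protein()]).  Use [glance()] for per-label summary counts and
#'   [summarize_calls()] for label-by-lineage counts.
#' @export
#' @examples
#' prot <- generate_proteome(synthetic_spec(n_per_label = c(CTL = 2), seed = 1))
#' classify_proteome(prot)
classify_proteome <- function(records, profiles = ctl_profiles(),
                              patterns = ctl_patterns(),
                              params = classify_params()) {
  assert_protein_tbl(records)
  ring_hits <- scan_ring_domains(records, profiles = profiles)
  motif_hits <- scan_motif(records, patterns$yeell,
                           params$max_mismatch + params$degraded_extra)
  calls <- purrr::map_dfr(records$id, function(id) {
    classify_one(id,
                 dplyr::filter(ring_hits, .data$protein_id == id),
                 dplyr::filter(motif_hits, .data$protein_id == id),
                 params)
  })
  if (nrow(calls) == 0L) {
    calls <- classify_one("x", ring_hits[0, ], motif_hits[0, ], params)[0, ]
  }
  calls$lineage <- records$lineage[match(calls$protein_id, records$id)]
  class(calls) <- c("ctl_calls", class(calls))
  calls
}

#' Summarise family calls by label and lineage
#'
#' @param calls A `ctl_calls` tibble.
#' @return Tibble of counts per (lineage, label), all labels present.
#' @export
summarize_calls <- function(calls) {
  calls |>
    dplyr::mutate(label = factor(.data$label, levels = FAMILY_LABELS)) |>
    dplyr::count(.data$lineage, .data$label, .drop = FALSE, name = "n") |>
    tibble::as_tibble()
}

#' @describeIn classify_proteome Per-label call counts (one row).
#' @param x A `ctl_calls` tibble.
#' @param ... Unused.
#' @export
glance.ctl_calls <- function(x, ...) {
  counts <- table(factor(x$label, levels = FAMILY_LABELS))
  out <- tibble::as_tibble(as.list(counts))
  names(out) <- c("atl", "btl", "ctl", "ctl_like", "unclassified", "none")
  out$n <- nrow(x)
  out
}

#' @describeIn classify_proteome Calls with evidence collapsed to one string
#'   per protein.
#' @export
tidy.ctl_calls <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$evidence <- vapply(out$evidence, paste, "", collapse = "; ")
  out
}
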