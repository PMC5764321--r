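# Chou-Fasman alpha-helix prediction.
#
# Classic nucleation/extension scheme with the original published propensity
# tables.  Used to check that a motif occurrence sits in helix-compatible
# context, as CTL YEELL motifs do.

# Chou & Fasman helix (P_alpha) and strand (P_beta) conformational
# propensities for the 20 standard residues.  X is given propensity 0 so it
# can never support a helix.
CF_P_ALPHA <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57, H = 1.00,
  I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67, P = 0.57, Q = 1.11,
  R = 0.98, S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69, X = 0
)
CF_P_BETA <- c(
  A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75, H = 0.87,
  I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89, P = 0.55, Q = 1.10,
  R = 0.93, S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47, X = 0
)

#' Predict alpha-helix segments by the Chou-Fasman method
#'
#' Nucleates a helix at any 6-residue window with at least `min_formers`
#' residues of helix propensity above `nucleation`, extends in both
#' directions while the mean propensity of the advancing `ext_window`-residue
#' edge stays at or above `cutoff`, merges overlapping segments, and keeps
#' segments whose mean helix propensity exceeds their mean strand propensity.
#'
#' @param seq Amino-acid sequence (length >= 6 for any prediction).
#' @param nucleation Propensity threshold a residue must exceed to count as a
#'   helix former (default 1.03).
#' @param min_formers Formers required in a 6-residue nucleation window
#'   (default 4).
#' @param ext_window Width of the extension edge (default 4).
#' @param cutoff Mean edge propensity required to keep extending (default 1.00).
#' @return Tibble with columns `start`, `end` (1-based inclusive helix
#'   segments); zero rows if none.
#' @export
#' @examples
#' chou_fasman_helix("AEAEAEAEAEAEAEAE")
chou_fasman_helix <- function(seq, nucleation = 1.03, min_formers = 4L,
                              ext_window = 4L, cutoff = 1.00) {
  empty <- tibble::tibble(start = integer(0), end = integer(0))
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 6L) {
    return(empty)
  }
  pa <- unname(CF_P_ALPHA[chars])
  pb <- unname(CF_P_BETA[chars])
  former <- pa > nucleation
  # nucleation: 6-residue windows with >= min_formers formers
  win_formers <- vapply(seq_len(n - 5L), function(i) sum(former[i:(i + 5L)]),
                        integer(1L))
  nuclei <- which(win_formers >= min_formers)
  if (length(nuclei) == 0L) {
    return(empty)
  }
  segs <- lapply(nuclei, function(i) {
    lo <- i
    hi <- i + 5L
    while (hi < n && mean(pa[(hi - ext_window + 2L):(hi + 1L)]) >= cutoff) {
      hi <- hi + 1L
    }
    while (lo > 1L && mean(pa[(lo - 1L):(lo + ext_window - 2L)]) >= cutoff) {
      lo <- lo - 1L
    }
    c(lo, hi)
  })
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs[, 1L], segs[, 2L]), , drop = FALSE]
  # merge overlapping/adjacent segments
  merged <- list(segs[1L, ])
  for (i in seq_len(nrow(segs))[-1L]) {
    last <- merged[[length(merged)]]
    if (segs[i, 1L] <= last[2L] + 1L) {
      merged[[length(merged)]] <- c(last[1L], max(last[2L], segs[i, 2L]))
    } else {
      merged[[length(merged) + 1L]] <- segs[i, ]
    }
  }
  out <- do.call(rbind, merged)
  keep <- vapply(seq_len(nrow(out)), function(i) {
    idx <- out[i, 1L]:out[i, 2L]
    mean(pa[idx]) > mean(pb[idx])
  }, logical(1L))
  out <- out[keep, , drop = FALSE]
  tibble::tibble(start = as.integer(out[, 1L]), end = as.integer(out[, 2L]))
}

#' Does a motif hit fall in predicted helix context?
#'
#' @param record One-row protein tibble (or any row with `seq`).
#' @param hit One-row motif-hit tibble with `start`, `end`.
#' @param min_overlap Minimum fraction of the motif length that a helix
#'   segment must cover (default 0.5).
#' @param ... Passed to [chou_fasman_helix()].
#' @return Logical scalar.
#' @export
motif_helix_check <- function(record, hit, min_overlap = 0.5, ...) {
  stopifnot(nrow(record) == 1L, nrow(hit) == 1L)
  segs <- chou_fasman_helix(record$seq, ...)
  if (nrow(segs) == 0L) {
    return(FALSE)
  }
  motif_len <- hit$end - hit$start + 1L
  overlap <- pmin(segs$end, hit$end) - pmax(segs$start, hit$start) + 1L
  any(overlap >= min_overlap * motif_len)
}
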