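# CDS / 5'UTR intron architecture of gene models.

# gap sizes (nt) between consecutive segments in transcript orientation
seg_gaps <- function(segs, strand) {
  n <- nrow(segs)
  if (n < 2L) {
    return(integer(0))
  }
  if (strand == "+") {
    as.integer(segs$start[-1L] - segs$end[-n] - 1L)
  } else {
    as.integer(segs$start[-n] - segs$end[-1L] - 1L)
  }
}

#' Count CDS and 5'UTR introns per gene model
#'
#' CDS introns are the gaps between consecutive CDS segments in transcript
#' orientation; 5'UTR introns are the gaps between exon parts lying entirely
#' 5' of the first coding base.  Sizes are genomic nucleotides and
#' strand-aware (a minus-strand mirror reports identically).
#'
#' @param models Gene-model tibble ([read_gff3()], [generate_gene_models()]).
#' @return Tibble with `gene_id`, `cds_intron_count`, `utr5_intron_count`,
#'   and list-column `utr5_introns` (sizes in nt, 5'->3').
#' @export
count_introns <- function(models) {
  purrr::map_dfr(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    utr_gaps <- seg_gaps(m$utr5[[1L]], m$strand)
    tibble::tibble(
      gene_id = m$gene_id,
      cds_intron_count = max(nrow(m$cds[[1L]]) - 1L, 0L),
      utr5_intron_count = length(utr_gaps),
      utr5_introns = list(utr_gaps)
    )
  })
}

#' Does a splice junction fall inside a motif's coding span?
#'
#' Protein residue i occupies CDS nucleotides 3(i-1)+1 .. 3i; the test is
#' true iff any CDS intron junction lies strictly inside the motif's
#' nucleotide span.
#'
#' @param model One-row gene-model tibble.
#' @param motif_span Integer pair: first and last motif residue (1-based) in
#'   the protein encoded by the model's CDS.
#' @return Logical scalar.
#' @export
splice_in_motif <- function(model, motif_span) {
  stopifnot(nrow(model) == 1L, length(motif_span) == 2L,
            motif_span[1L] >= 1L, motif_span[1L] <= motif_span[2L])
  cds <- model$cds[[1L]]
  lens <- cds$end - cds$start + 1L
  total <- sum(lens)
  nt_a <- 3L * (motif_span[1L] - 1L) + 1L
  nt_b <- 3L * motif_span[2L]
  if (nt_b > total) {
    stop(sprintf("motif span %d-%d extends beyond the CDS (%d nt)",
                 motif_span[1L], motif_span[2L], total), call. = FALSE)
  }
  if (nrow(cds) < 2L) {
    return(FALSE)
  }
  junctions <- cumsum(lens)[-nrow(cds)]
  any(junctions >= nt_a & junctions < nt_b)
}

#' Summarise intron architecture per group
#'
#' @param reports Tibble from [count_introns()].
#' @param group_map Tibble with `gene_id`, `group` (or named character
#'   vector id -> group); unmapped genes go to `"ungrouped"`.
#' @return Tibble per group: `n_genes`, `n_utr5_intron` /
#'   `n_no_utr5_intron`, and the CDS intron count range.
#' @export
summarize_architecture <- function(reports, group_map = NULL) {
  if (nrow(reports) == 0L) {
    return(tibble::tibble(
      group = character(0), n_genes = integer(0),
      n_utr5_intron = integer(0), n_no_utr5_intron = integer(0),
      cds_intron_min = integer(0), cds_intron_max = integer(0)
    ))
  }
  grp <- if (is.null(group_map)) {
    rep("ungrouped", nrow(reports))
  } else {
    if (is.data.frame(group_map)) {
      group_map <- setNames(group_map$group, group_map$gene_id)
    }
    g <- unname(group_map[reports$gene_id])
    ifelse(is.na(g), "ungrouped", g)
  }
  reports |>
    dplyr::mutate(group = grp) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_utr5_intron = sum(.data$utr5_intron_count > 0L),
      n_no_utr5_intron = sum(.data$utr5_intron_count == 0L),
      cds_intron_min = min(.data$cds_intron_count),
      cds_intron_max = max(.data$cds_intron_count),
      .groups = "drop"
    )
}
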