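# ggplot2 views of scan and classification results.

#' Plot protein maps of motif and RING-domain hits
#'
#' One horizontal track per protein showing its length, YEELL motif hits and
#' RING-domain hits.
#'
#' @param records Protein tibble.
#' @param ring_hits Tibble from [scan_ring_domains()] (optional).
#' @param motif_hits Tibble from [scan_motif()] (optional).
#' @return A ggplot object.
#' @export
plot_protein_map <- function(records, ring_hits = NULL, motif_hits = NULL) {
  assert_protein_tbl(records)
  backbone <- tibble::tibble(
    protein_id = records$id,
    start = 1L,
    end = nchar(records$seq),
    feature = "protein"
  )
  feats <- backbone
  if (!is.null(ring_hits) && nrow(ring_hits) > 0L) {
    feats <- dplyr::bind_rows(feats, dplyr::transmute(
      ring_hits, protein_id = .data$protein_id, start = .data$start,
      end = .data$end, feature = .data$variant
    ))
  }
  if (!is.null(motif_hits) && nrow(motif_hits) > 0L) {
    feats <- dplyr::bind_rows(feats, dplyr::transmute(
      motif_hits, protein_id = .data$protein_id, start = .data$start,
      end = .data$end, feature = .data$pattern
    ))
  }
  ggplot2::ggplot(feats, ggplot2::aes(y = .data$protein_id)) +
    ggplot2::geom_segment(
      data = dplyr::filter(feats, .data$feature == "protein"),
      ggplot2::aes(x = .data$start, xend = .data$end,
                   yend = .data$protein_id),
      linewidth = 0.4, colour = "grey60"
    ) +
    ggplot2::geom_segment(
      data = dplyr::filter(feats, .data$feature != "protein"),
      ggplot2::aes(x = .data$start, xend = .data$end,
                   yend = .data$protein_id, colour = .data$feature),
      linewidth = 3
    ) +
    ggplot2::labs(x = "residue", y = NULL, colour = "feature") +
    ggplot2::theme_minimal()
}

#' @describeIn classify_proteome Bar chart of family-call counts.
#' @param object A `ctl_calls` tibble.
#' @export
autoplot.ctl_calls <- function(object, ...) {
  counts <- dplyr::count(
    tibble::as_tibble(object),
    label = factor(.data$label, levels = FAMILY_LABELS),
    .drop = FALSE
  )
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "family call", y = "proteins") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
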