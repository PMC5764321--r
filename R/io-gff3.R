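# GFF3 gene-model I/O.
#
# A gene-model tibble has one row per mRNA: `gene_id` (the mRNA id),
# `seqid`, `strand`, and list-columns `exons`, `cds`, `utr5`, each a tibble
# of genomic 1-based inclusive intervals ordered 5'->3' in transcript
# orientation.  The 5'UTR is always derived from exons and CDS (the exon
# parts strictly 5' of the first coding base), so models from annotations
# with or without explicit five_prime_UTR features are comparable.

# order interval tibble into transcript orientation
orient_segments <- function(segs, strand) {
  if (nrow(segs) == 0L) {
    return(segs)
  }
  ord <- order(segs$start, decreasing = (strand == "-"))
  segs[ord, , drop = FALSE]
}

# exon parts strictly 5' of the first coding base, transcript orientation
derive_utr5 <- function(exons, cds, strand) {
  empty <- tibble::tibble(start = integer(0), end = integer(0))
  if (nrow(cds) == 0L || nrow(exons) == 0L) {
    return(empty)
  }
  if (strand == "+") {
    first_cds <- min(cds$start)
    parts <- dplyr::filter(exons, .data$start < first_cds)
    parts$end <- pmin(parts$end, first_cds - 1L)
  } else {
    first_cds <- max(cds$end)
    parts <- dplyr::filter(exons, .data$end > first_cds)
    parts$start <- pmax(parts$start, first_cds + 1L)
  }
  orient_segments(parts[, c("start", "end")], strand)
}

new_gene_model <- function(gene_id, seqid, strand, exons, cds) {
  exons <- orient_segments(exons, strand)
  cds <- orient_segments(cds, strand)
  # every CDS segment must lie inside an exon
  contained <- vapply(seq_len(nrow(cds)), function(i) {
    any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
  }, logical(1L))
  if (!all(contained)) {
    stop(sprintf("model '%s': CDS segment outside exons", gene_id),
         call. = FALSE)
  }
  utr5 <- derive_utr5(exons, cds, strand)
  tibble::tibble(
    gene_id = gene_id, seqid = seqid, strand = strand,
    exons = list(exons), cds = list(cds), utr5 = list(utr5)
  )
}

#' Read gene models from GFF3
#'
#' Builds one model per mRNA from `gene`/`mRNA`/`exon`/`CDS` features linked
#' by `Parent` attributes.  Coordinates stay 1-based inclusive (the GFF3 and
#' Bioconductor convention); minus-strand segment lists are ordered into
#' transcript orientation.
#'
#' @param path Path to a GFF3 file.
#' @return Gene-model tibble (see file-level description).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  df <- tibble::tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    id = as.character(gr$ID %||% rep(NA_character_, length(gr))),
    parent = vapply(as.list(gr$Parent), function(p) {
      if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
    }, character(1L))
  )
  mrnas <- dplyr::filter(df, .data$type %in% c("mRNA", "transcript"))
  if (nrow(mrnas) == 0L) {
    stop(sprintf("no mRNA features in '%s'", path), call. = FALSE)
  }
  kids <- dplyr::filter(df, .data$type %in% c("exon", "CDS"))
  if (nrow(kids) > 0L && anyNA(kids$parent)) {
    stop("exon/CDS feature without Parent attribute", call. = FALSE)
  }
  orphans <- setdiff(kids$parent, mrnas$id)
  if (length(orphans) > 0L) {
    stop(sprintf("Parent id(s) with no mRNA feature: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  models <- purrr::map_dfr(seq_len(nrow(mrnas)), function(i) {
    m <- mrnas[i, ]
    mine <- dplyr::filter(kids, .data$parent == m$id)
    seg <- function(tp) {
      s <- dplyr::filter(mine, .data$type == tp)
      tibble::tibble(start = as.integer(s$start), end = as.integer(s$end))
    }
    new_gene_model(m$id, m$seqid, m$strand, seg("exon"), seg("CDS"))
  })
  models
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA`, `exon`, `CDS` and `five_prime_UTR` features with
#' `Parent` linkage, round-trippable through [read_gff3()].
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  feat <- function(seqid, type, start, end, strand, attrs) {
    sprintf("%s\tctlscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, start, end, strand, attrs)
  }
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    exons <- m$exons[[1L]]
    cds <- m$cds[[1L]]
    utr5 <- m$utr5[[1L]]
    span <- range(c(exons$start, exons$end))
    gid <- paste0(m$gene_id, ".gene")
    lines <- c(
      lines,
      feat(m$seqid, "gene", span[1L], span[2L], m$strand,
           sprintf("ID=%s", gid)),
      feat(m$seqid, "mRNA", span[1L], span[2L], m$strand,
           sprintf("ID=%s;Parent=%s", m$gene_id, gid)),
      feat(m$seqid, "exon", exons$start, exons$end, m$strand,
           sprintf("ID=%s.exon%d;Parent=%s", m$gene_id,
                   seq_len(nrow(exons)), m$gene_id)),
      feat(m$seqid, "CDS", cds$start, cds$end, m$strand,
           sprintf("ID=%s.cds%d;Parent=%s", m$gene_id,
                   seq_len(nrow(cds)), m$gene_id))
    )
    if (nrow(utr5) > 0L) {
      lines <- c(lines, feat(
        m$seqid, "five_prime_UTR", utr5$start, utr5$end, m$strand,
        sprintf("ID=%s.utr5.%d;Parent=%s", m$gene_id,
                seq_len(nrow(utr5)), m$gene_id)
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
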