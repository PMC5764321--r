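# Seeded synthetic proteomes and gene models with known labels.
#
# A synthetic CTL protein is: N-terminal flank + YEELL instance (each
# constrained position drawn uniformly from its allowed set, wildcards from
# the background) + linker + RING-H2 domain drawn from a lineage profile.
# ATL/BTL proteins carry the corresponding diagnostic residues instead of
# the motif; background proteins are plain random sequence.  Flanks and
# spacers are rejection-sampled at the whole-protein level so that the
# scanners recover exactly the planted structure — truth labels are exact.

SYN_LABELS <- c("CTL", "ATL", "BTL", "background")

#' Specification for a synthetic proteome
#'
#' @param n_per_label Named counts for any of `CTL`, `ATL`, `BTL`,
#'   `background`.
#' @param lineage Named lineage tag per label (default `plant` for the three
#'   families, `other` for background); selects the spacing profile used to
#'   draw domains.
#' @param flank_range,linker_range Length ranges (residues) for the random
#'   N-terminal flank and the motif-to-domain linker.
#' @param motif_mutations Constrained YEELL positions mutated (to a residue
#'   outside the allowed set) per CTL motif.
#' @param ligand_mutations Metal-ligand positions mutated (to a non-ligand
#'   residue) per planted domain.
#' @param background_comp Residue sampling weights (named, standard 20);
#'   default uniform.
#' @param seed Integer seed fixing all randomness.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_label = c(CTL = 10L, ATL = 10L, BTL = 10L,
                                           background = 10L),
                           lineage = NULL,
                           flank_range = c(60L, 100L),
                           linker_range = c(20L, 40L),
                           motif_mutations = 0L,
                           ligand_mutations = 0L,
                           background_comp = NULL,
                           seed = 1L) {
  stopifnot(all(names(n_per_label) %in% SYN_LABELS), all(n_per_label >= 0L))
  lineage_default <- c(CTL = "plant", ATL = "plant", BTL = "plant",
                       background = "other")
  if (!is.null(lineage)) {
    lineage_default[names(lineage)] <- lineage
  }
  comp <- background_comp %||% setNames(rep(1, 20L), AA_STANDARD)
  stopifnot(all(AA_STANDARD %in% names(comp)), all(comp >= 0))
  structure(
    list(
      n_per_label = n_per_label,
      lineage = lineage_default,
      flank_range = as.integer(flank_range),
      linker_range = as.integer(linker_range),
      motif_mutations = as.integer(motif_mutations),
      ligand_mutations = as.integer(ligand_mutations),
      background_comp = comp[AA_STANDARD],
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

sample_residues <- function(n, comp) {
  if (n <= 0L) {
    return(character(0))
  }
  sample(AA_STANDARD, n, replace = TRUE, prob = comp)
}

# draw one motif instance from a pattern (constrained positions from their
# sets, wildcards from background)
sample_motif_instance <- function(pattern, comp) {
  vapply(pattern$positions, function(allowed) {
    if (is.null(allowed)) {
      sample_residues(1L, comp)
    } else {
      allowed[sample.int(length(allowed), 1L)]
    }
  }, character(1L))
}

# assemble one protein for a label; returns list(chars, truth fields)
build_protein <- function(label, spec, profile, pattern) {
  comp <- spec$background_comp
  flank_len <- sample(spec$flank_range[1L]:spec$flank_range[2L], 1L)
  chars <- sample_residues(flank_len, comp)
  motif_start <- NA_integer_
  motif_end <- NA_integer_
  if (label == "CTL") {
    inst <- sample_motif_instance(pattern, comp)
    motif_start <- length(chars) + 1L
    chars <- c(chars, inst)
    motif_end <- length(chars)
  }
  ring_pos <- rep(NA_integer_, 8L)
  if (label != "background") {
    linker_len <- sample(spec$linker_range[1L]:spec$linker_range[2L], 1L)
    chars <- c(chars, sample_residues(linker_len, comp))
    gaps <- profile$canonical_spacing
    domain <- character(0)
    lig_local <- integer(8L)
    for (k in 1:8) {
      cls <- profile$ligand_classes[[k]]
      res <- if (k == 5L) "H" else cls[sample.int(length(cls), 1L)]
      domain <- c(domain, res)
      lig_local[k] <- length(domain)
      if (k < 8L) {
        domain <- c(domain, sample_residues(gaps[k], comp))
      }
    }
    offset <- length(chars)
    ring_pos <- offset + lig_local
    chars <- c(chars, domain)
    chars <- c(chars, sample_residues(5L, comp))
    # pin diagnostic sites so family evidence is exactly as planted
    set_site <- function(pos, res) chars[pos] <<- res
    clear_site <- function(pos, res) {
      if (chars[pos] == res) {
        chars[pos] <<- sample(setdiff(AA_STANDARD, c(res, "C", "H")), 1L)
      }
    }
    atl_sites <- list(c(ring_pos[2L] + 1L, "L"), c(ring_pos[3L] - 4L, "R"),
                      c(ring_pos[6L] + 1L, "D"))
    btl_site <- c(ring_pos[6L] + 2L, "P")
    if (label == "ATL") {
      for (s in atl_sites) set_site(as.integer(s[1L]), s[2L])
      clear_site(as.integer(btl_site[1L]), btl_site[2L])
    } else if (label == "BTL") {
      set_site(as.integer(btl_site[1L]), btl_site[2L])
      for (s in atl_sites) clear_site(as.integer(s[1L]), s[2L])
    } else {
      for (s in atl_sites) clear_site(as.integer(s[1L]), s[2L])
      clear_site(as.integer(btl_site[1L]), btl_site[2L])
    }
  }
  list(chars = chars, motif_start = motif_start, motif_end = motif_end,
       ring_pos = ring_pos)
}

# does the assembled protein scan back to exactly the planted structure?
planted_ok <- function(built, label, spec, profile, pattern) {
  rec <- tibble::tibble(id = "tmp", lineage = "other",
                        seq = paste(built$chars, collapse = ""))
  hits <- scan_ring_one("tmp", rec$seq, profile)
  if (label == "background") {
    return(nrow(hits) == 0L)
  }
  if (nrow(hits) != 1L ||
      !identical(as.integer(hits$ligand_pos[[1L]]),
                 as.integer(built$ring_pos))) {
    return(FALSE)
  }
  if (label == "CTL") {
    mh <- scan_motif(rec, pattern)
    up <- dplyr::filter(mh, .data$end < built$ring_pos[1L])
    if (nrow(up) != 1L || up$start != built$motif_start ||
        up$mismatches != 0L) {
      return(FALSE)
    }
  } else {
    # no accidental in-budget YEELL upstream of the planted domain
    mh <- scan_motif(rec, pattern)
    if (any(mh$end < built$ring_pos[1L])) {
      return(FALSE)
    }
  }
  TRUE
}

apply_mutations <- function(built, label, spec, pattern) {
  chars <- built$chars
  if (label == "CTL" && spec$motif_mutations > 0L) {
    constrained <- which(!vapply(pattern$positions, is.null, logical(1L)))
    picks <- sample(constrained, min(spec$motif_mutations, length(constrained)))
    for (p in picks) {
      pos <- built$motif_start + p - 1L
      chars[pos] <- sample(setdiff(AA_STANDARD, pattern$positions[[p]]), 1L)
    }
  }
  if (label != "background" && spec$ligand_mutations > 0L) {
    picks <- sample(1:8, min(spec$ligand_mutations, 8L))
    for (k in picks) {
      chars[built$ring_pos[k]] <- sample(setdiff(AA_STANDARD, c("C", "H")), 1L)
    }
  }
  built$chars <- chars
  built
}

#' Generate one labelled synthetic protein
#'
#' @param label One of `CTL`, `ATL`, `BTL`, `background`.
#' @param spec A [synthetic_spec()].
#' @param id Record identifier.
#' @param profiles,patterns Profile and pattern sets.
#' @return One-row tibble: `id`, `lineage`, `seq` plus truth columns `label`,
#'   `motif_start`, `motif_end`, `ring_start`, `ring_end`.
#' @export
generate_protein <- function(label, spec, id = label,
                             profiles = ctl_profiles(),
                             patterns = ctl_patterns()) {
  stopifnot(label %in% SYN_LABELS)
  lineage <- spec$lineage[[label]]
  profile <- profile_for_lineage(lineage, profiles)
  pattern <- patterns$yeell
  for (try in 1:200) {
    built <- build_protein(label, spec, profile, pattern)
    if (planted_ok(built, label, spec, profile, pattern)) {
      built <- apply_mutations(built, label, spec, pattern)
      return(tibble::tibble(
        id = id, lineage = lineage,
        seq = paste(built$chars, collapse = ""),
        label = label,
        motif_start = built$motif_start, motif_end = built$motif_end,
        ring_start = built$ring_pos[1L], ring_end = built$ring_pos[8L]
      ))
    }
  }
  stop(sprintf("could not generate a clean '%s' protein in 200 tries", label),
       call. = FALSE)
}

#' Generate a labelled synthetic proteome
#'
#' @param spec A [synthetic_spec()]; its `seed` fixes all randomness.
#' @param profiles,patterns Profile and pattern sets.
#' @return Tibble with one row per protein: `id`, `lineage`, `seq` and the
#'   truth columns of [generate_protein()].  Write sequences with
#'   [write_fasta()] and truth labels with [write_hits_tsv()].
#' @export
#' @examples
#' prot <- generate_proteome(synthetic_spec(n_per_label = c(CTL = 3), seed = 7))
#' prot$label
generate_proteome <- function(spec, profiles = ctl_profiles(),
                              patterns = ctl_patterns()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  labels <- intersect(SYN_LABELS, names(spec$n_per_label))
  rows <- purrr::map(labels, function(lb) {
    n <- spec$n_per_label[[lb]]
    if (n == 0L) {
      return(NULL)
    }
    purrr::map_dfr(seq_len(n), function(i) {
      generate_protein(lb, spec, id = sprintf("%s_%03d", lb, i),
                       profiles, patterns)
    })
  })
  proto <- tibble::tibble(
    id = character(0), lineage = character(0), seq = character(0),
    label = character(0), motif_start = integer(0), motif_end = integer(0),
    ring_start = integer(0), ring_end = integer(0)
  )
  dplyr::bind_rows(c(list(proto), rows))
}

#' Generate gene models from explicit intron layouts
#'
#' Each layout gives exon-part and intron lengths for the 5'UTR and the CDS;
#' the last UTR part and the first CDS part are contiguous (one exon), so a
#' gene's exon structure is fully determined by its intron positions.
#'
#' @param layouts A list of layouts, each a list with `gene_id`, `strand`,
#'   `utr5_exons` (lengths, nt; may be empty), `utr5_introns` (sizes, one
#'   fewer than `utr5_exons`), `cds_exons` (lengths, >= 1), `cds_introns`
#'   (sizes, one fewer than `cds_exons`).
#' @param seqid Chromosome name for the emitted models.
#' @param gap Intergenic spacing.
#' @return Gene-model tibble; [count_introns()] on it reproduces each layout.
#' @export
#' @examples
#' lay <- list(list(gene_id = "g1", strand = "+",
#'                  utr5_exons = c(100, 80), utr5_introns = 235,
#'                  cds_exons = c(120, 120), cds_introns = 90))
#' count_introns(generate_gene_models(lay))
generate_gene_models <- function(layouts, seqid = "chr1", gap = 1000L) {
  offset <- 1L
  models <- purrr::map_dfr(layouts, function(lay) {
    u_ex <- as.integer(lay$utr5_exons %||% integer(0))
    u_in <- as.integer(lay$utr5_introns %||% integer(0))
    c_ex <- as.integer(lay$cds_exons)
    c_in <- as.integer(lay$cds_introns %||% integer(0))
    strand <- lay$strand %||% "+"
    introns <- c(u_in, c_in)
    if (length(c_ex) < 1L || any(c(u_ex, c_ex) <= 0L) ||
        (length(introns) > 0L && any(introns <= 0L))) {
      stop(sprintf("layout '%s': exon/intron lengths must be positive",
                   lay$gene_id), call. = FALSE)
    }
    if ((length(u_ex) > 0L && length(u_in) != length(u_ex) - 1L) ||
        length(c_in) != length(c_ex) - 1L) {
      stop(sprintf("layout '%s': need one fewer intron than exon parts",
                   lay$gene_id), call. = FALSE)
    }
    # walk the transcript, tagging each block
    blocks <- list()
    push <- function(kind, len) {
      blocks[[length(blocks) + 1L]] <<- list(kind = kind, len = len)
    }
    if (length(u_ex) > 0L) {
      for (k in seq_along(u_ex)) {
        push("utr5", u_ex[k])
        if (k <= length(u_in)) push("intron", u_in[k])
      }
    }
    for (k in seq_along(c_ex)) {
      push("cds", c_ex[k])
      if (k <= length(c_in)) push("intron", c_in[k])
    }
    total <- sum(vapply(blocks, `[[`, 0L, "len"))
    # relative 1-based intervals in plus orientation
    pos <- 1L
    rel <- purrr::map_dfr(blocks, function(b) {
      out <- tibble::tibble(kind = b$kind, start = pos, end = pos + b$len - 1L)
      pos <<- pos + b$len
      out
    })
    if (strand == "-") {
      new_start <- total - rel$end + 1L
      rel$end <- total - rel$start + 1L
      rel$start <- new_start
    }
    rel$start <- rel$start + offset - 1L
    rel$end <- rel$end + offset - 1L
    offset <<- offset + total + gap
    exonic <- dplyr::filter(rel, .data$kind != "intron") |>
      dplyr::arrange(.data$start)
    # fuse contiguous exonic blocks into exons
    exons <- exonic[1L, c("start", "end")]
    for (i in seq_len(nrow(exonic))[-1L]) {
      if (exonic$start[i] == exons$end[nrow(exons)] + 1L) {
        exons$end[nrow(exons)] <- exonic$end[i]
      } else {
        exons <- dplyr::bind_rows(exons,
                                  exonic[i, c("start", "end")])
      }
    }
    cds <- dplyr::filter(rel, .data$kind == "cds")[, c("start", "end")]
    new_gene_model(lay$gene_id, seqid, strand, exons, cds)
  })
  models
}
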