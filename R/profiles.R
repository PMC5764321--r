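# Lineage spacing profiles for the RING-domain grammar.
#
# A RING domain is recognised as eight metal-ligand residues (numbered 1-8
# from the N-terminus) whose seven inter-ligand gaps fall inside
# profile-specific ranges.  The canonical RING-H2 ligand scheme is C3H2C3
# (C,C,C,H,H,C,C,C); position 5 also admits C so that the RING-HC variant is
# matched by the same grammar and typed afterwards.

PROFILE_FIELDS <- c("name", "ligand_classes", "spacing", "canonical_spacing")

# canonical inter-ligand gaps g1..g7: only g2 = 14 is lineage-diagnostic;
# g1 and g7 are the universal C-x2-C bookends, the rest the generic RING
# envelope.  All values are configurable per profile.
CANONICAL_SPACING <- c(2L, 14L, 2L, 2L, 2L, 10L, 2L)

RING_H2_CLASSES <- list("C", "C", "C", "H", c("H", "C"), "C", "C", "C")

#' Construct a lineage spacing profile
#'
#' @param name Profile name.
#' @param spacing_min,spacing_max Integer vectors of length 7: bounds on the
#'   number of residues strictly between consecutive metal ligands
#'   (gaps g1..g7).
#' @param canonical_spacing Integer vector of length 7 used to compute insert
#'   counts (`observed gap - canonical gap`); must lie within the ranges.
#' @param ligand_classes List of 8 character vectors of allowed residues at
#'   each metal-ligand position.
#' @return An object of class `lineage_profile`.
#' @export
#' @examples
#' lineage_profile("tight", rep(2, 7), rep(2, 7), canonical_spacing = rep(2, 7))
lineage_profile <- function(name, spacing_min, spacing_max,
                            canonical_spacing = CANONICAL_SPACING,
                            ligand_classes = RING_H2_CLASSES) {
  spacing_min <- as.integer(spacing_min)
  spacing_max <- as.integer(spacing_max)
  canonical_spacing <- as.integer(canonical_spacing)
  if (length(ligand_classes) != 8L) {
    stop("profile must define 8 ligand classes", call. = FALSE)
  }
  if (length(spacing_min) != 7L || length(spacing_max) != 7L ||
      length(canonical_spacing) != 7L) {
    stop("profile must define 7 spacing ranges and 7 canonical gaps", call. = FALSE)
  }
  if (any(spacing_min < 0L) || any(spacing_min > spacing_max)) {
    stop(sprintf(
      "profile '%s': spacing ranges must satisfy 0 <= min <= max", name
    ), call. = FALSE)
  }
  if (any(canonical_spacing < spacing_min | canonical_spacing > spacing_max)) {
    stop(sprintf(
      "profile '%s': canonical_spacing must lie within the spacing ranges", name
    ), call. = FALSE)
  }
  bad <- !vapply(ligand_classes, function(x) {
    is.character(x) && length(x) >= 1L && all(x %in% AA_STANDARD)
  }, logical(1L))
  if (any(bad)) {
    stop(sprintf(
      "profile '%s': ligand class %d is not a set of standard residues",
      name, which(bad)[1L]
    ), call. = FALSE)
  }
  structure(
    list(
      name = as.character(name),
      ligand_classes = ligand_classes,
      spacing = cbind(min = spacing_min, max = spacing_max),
      canonical_spacing = canonical_spacing
    ),
    class = "lineage_profile"
  )
}

#' @export
print.lineage_profile <- function(x, ...) {
  cat(sprintf("<lineage_profile> %s\n", x$name))
  cat("  ligands:", vapply(x$ligand_classes, paste, "", collapse = "/"), "\n")
  cat("  gaps   :", paste(sprintf("[%d,%d]", x$spacing[, "min"],
                                  x$spacing[, "max"]), collapse = " "), "\n")
  invisible(x)
}

#' Built-in lineage profiles
#'
#' Four profiles transcribing the lineage-specific RING-H2 spacing patterns
#' of the CTL family:
#' * `canonical` — plants, vertebrates, invertebrates: fixed gaps
#'   (2, 14, 2, 2, 2, 10, 2), fourteen residues between ligands 2 and 3.
#' * `fungal` — exactly one extra residue between ligands 2-3 and between
#'   ligands 6-7 (gaps 15 and 11).
#' * `kinetoplast` — up to twenty-six extra residues between ligands 2 and 3
#'   (gap 14-40).
#' * `ciliate` — as `kinetoplast`.
#'
#' @return Named list of [lineage_profile] objects.
#' @export
#' @examples
#' ctl_profiles()$canonical
ctl_profiles <- function() {
  can <- CANONICAL_SPACING
  canonical <- lineage_profile("canonical", can, can)
  fung <- can
  fung[c(2L, 6L)] <- fung[c(2L, 6L)] + 1L
  fungal <- lineage_profile("fungal", fung, fung, canonical_spacing = fung)
  kin_min <- can
  kin_max <- can
  kin_max[2L] <- kin_max[2L] + 26L
  kinetoplast <- lineage_profile("kinetoplast", kin_min, kin_max)
  ciliate <- lineage_profile("ciliate", kin_min, kin_max)
  list(
    canonical = canonical, fungal = fungal,
    kinetoplast = kinetoplast, ciliate = ciliate
  )
}

# profile chosen per lineage tag; anything unknown falls back to canonical
profile_for_lineage <- function(lineage, profiles = ctl_profiles()) {
  key <- switch(normalize_lineage(lineage),
    fungus = "fungal",
    kinetoplast = "kinetoplast",
    ciliate = "ciliate",
    "canonical"
  )
  profiles[[key]] %||% profiles[["canonical"]]
}

#' Load lineage profiles from a YAML file
#'
#' The file holds a list of profile entries with keys `name`, `spacing_min`,
#' `spacing_max`, and optionally `canonical_spacing` and `ligand_classes`
#' (8 strings such as `"C"` or `"H/C"`).
#'
#' @param path Path to a YAML file.
#' @return Named list of [lineage_profile] objects.
#' @export
load_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || length(raw) == 0L) {
    stop("profile config is empty", call. = FALSE)
  }
  valid <- c("name", "spacing_min", "spacing_max", "canonical_spacing",
             "ligand_classes")
  profs <- lapply(raw, function(entry) {
    unknown <- setdiff(names(entry), valid)
    if (length(unknown) > 0L) {
      stop(sprintf(
        "unknown profile key(s) %s; valid keys are: %s",
        paste(sQuote(unknown), collapse = ", "),
        paste(valid, collapse = ", ")
      ), call. = FALSE)
    }
    classes <- if (is.null(entry$ligand_classes)) {
      RING_H2_CLASSES
    } else {
      lapply(entry$ligand_classes, function(x) {
        toupper(strsplit(as.character(x), "/", fixed = TRUE)[[1L]])
      })
    }
    lineage_profile(
      name = entry$name,
      spacing_min = entry$spacing_min,
      spacing_max = entry$spacing_max,
      canonical_spacing = entry$canonical_spacing %||% CANONICAL_SPACING,
      ligand_classes = classes
    )
  })
  setNames(profs, vapply(profs, `[[`, "", "name"))
}
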