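# Degenerate position-specific motif scanning with a mismatch budget.
#
# Patterns are PROSITE-like: each position is either a set of allowed
# residues or a wildcard.  Wildcards never match or mismatch; X in the
# sequence always counts as a mismatch at a constrained position.

# The 21-residue YEELL consensus: the family signature of CTL E3 ligases,
# immediately N-terminal to the RING-H2 domain.  Its 5-residue core is the
# Y-E-E-L-L block (pattern positions 5-9).
YEELL_CONSENSUS <-
  "(D/E/V)XX(S/T/N)(Y/F)E(E/Q/A)(L/M)(L/T/I)XLX(E/D/N)X(L/I/M)GX(V/A/E)XX(G/A/R)"

#' Parse a degenerate consensus string into a motif pattern
#'
#' The consensus grammar uses `(A/B/...)` for an allowed-residue set, a bare
#' letter for a single-residue position, and `X`/`x` for a wildcard.
#'
#' @param text Consensus string.
#' @param name Pattern name.
#' @param core Optional integer pair: 1-based start/end of the motif core
#'   within the pattern (e.g. `c(5, 9)` for the YEELL block).
#' @param max_mismatch Default mismatch budget carried by the pattern.
#' @return An object of class `motif_pattern`: a list with `name`,
#'   `positions` (list; `NULL` marks a wildcard), `core`, `max_mismatch`,
#'   and `n_constrained`.
#' @export
#' @examples
#' parse_consensus("YE(E/Q)LL", name = "core")
parse_consensus <- function(text, name = "motif", core = NULL,
                            max_mismatch = 3L) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- seq_chars(text)
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= length(chars)) {
        if (chars[j] == ")") {
          close <- j
          break
        }
        if (chars[j] == "(") break
        j <- j + 1L
      }
      if (is.na(close)) {
        stop(sprintf("unbalanced parenthesis at column %d", i), call. = FALSE)
      }
      inner <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      residues <- toupper(strsplit(inner, "/", fixed = TRUE)[[1L]])
      if (length(residues) == 0L || any(nchar(residues) != 1L) ||
          !all(residues %in% AA_STANDARD)) {
        stop(sprintf("illegal residue group '(%s)' at column %d", inner, i),
             call. = FALSE)
      }
      positions[[length(positions) + 1L]] <- residues
      i <- close + 1L
    } else if (toupper(ch) == "X") {
      positions[length(positions) + 1L] <- list(NULL)
      i <- i + 1L
    } else if (toupper(ch) %in% AA_STANDARD) {
      positions[[length(positions) + 1L]] <- toupper(ch)
      i <- i + 1L
    } else {
      stop(sprintf("illegal residue letter '%s' at column %d", ch, i),
           call. = FALSE)
    }
  }
  if (!is.null(core)) {
    core <- as.integer(core)
    if (length(core) != 2L || core[1L] < 1L || core[2L] > length(positions) ||
        core[1L] > core[2L]) {
      stop("core range must lie within the pattern", call. = FALSE)
    }
  }
  structure(
    list(
      name = name,
      positions = positions,
      core = core,
      max_mismatch = as.integer(max_mismatch),
      n_constrained = sum(!vapply(positions, is.null, logical(1L)))
    ),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf(
    "<motif_pattern> %s: %d positions (%d constrained), max_mismatch %d\n",
    x$name, length(x$positions), x$n_constrained, x$max_mismatch
  ))
  if (!is.null(x$core)) cat(sprintf("  core: %d-%d\n", x$core[1L], x$core[2L]))
  invisible(x)
}

#' Built-in motif patterns
#'
#' `yeell` is the 21-residue consensus with the 5-residue Y-E-E-L-L core at
#' pattern positions 5-9 and a default mismatch budget of 3 of the 13
#' constrained positions (about 75% matched).  `gld` and `gld_like` are
#' placeholder single-core patterns for the ATL/BTL upstream motifs: their
#' full residue composition is published only as sequence LOGOs, so users
#' supply real patterns via [load_patterns()] if that evidence is wanted.
#'
#' @return Named list of `motif_pattern` objects.
#' @export
ctl_patterns <- function() {
  list(
    yeell = parse_consensus(YEELL_CONSENSUS, name = "yeell", core = c(5L, 9L),
                            max_mismatch = 3L),
    gld = parse_consensus("GLD", name = "gld", max_mismatch = 0L),
    gld_like = parse_consensus("GDL", name = "gld_like", max_mismatch = 0L)
  )
}

#' Load motif patterns from a YAML file
#'
#' Entries carry keys `name`, `consensus`, optional `core` (two integers) and
#' `max_mismatch`.
#'
#' @param path Path to a YAML file.
#' @return Named list of `motif_pattern` objects.
#' @export
load_patterns <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || length(raw) == 0L) {
    stop("pattern config is empty", call. = FALSE)
  }
  valid <- c("name", "consensus", "core", "max_mismatch")
  pats <- lapply(raw, function(entry) {
    unknown <- setdiff(names(entry), valid)
    if (length(unknown) > 0L) {
      stop(sprintf(
        "unknown pattern key(s) %s; valid keys are: %s",
        paste(sQuote(unknown), collapse = ", "),
        paste(valid, collapse = ", ")
      ), call. = FALSE)
    }
    parse_consensus(
      entry$consensus, name = entry$name,
      core = if (!is.null(entry$core)) unlist(entry$core),
      max_mismatch = entry$max_mismatch %||% 3L
    )
  })
  setNames(pats, vapply(pats, `[[`, "", "name"))
}

# mismatch counts for every window of `chars` against the pattern
motif_window_mismatches <- function(chars, pattern) {
  m <- length(pattern$positions)
  n <- length(chars)
  if (n < m) {
    return(integer(0))
  }
  n_win <- n - m + 1L
  mism <- integer(n_win)
  for (k in seq_len(m)) {
    allowed <- pattern$positions[[k]]
    if (is.null(allowed)) next
    ok <- chars[k:(k + n_win - 1L)] %in% allowed
    mism <- mism + !ok
  }
  mism
}

#' Scan proteins for a degenerate motif
#'
#' Every window whose mismatch count at constrained positions is within the
#' budget is reported; overlapping hits are all kept (downstream callers
#' decide which to use).
#'
#' @inheritParams scan_ring_domains
#' @param pattern A `motif_pattern` (see [parse_consensus()], [ctl_patterns()]).
#' @param max_mismatch Mismatch budget; defaults to the pattern's own.
#' @return Tibble with one row per hit: `protein_id`, `pattern`, `start`,
#'   `end` (1-based inclusive), `mismatches`, `score` (matched constrained
#'   positions / constrained positions).
#' @export
#' @examples
#' rec <- tibble::tibble(id = "p", lineage = "other",
#'                       seq = "MDAASYEELLALAEALGAVAAGM")
#' scan_motif(rec, ctl_patterns()$yeell)
scan_motif <- function(records, pattern, max_mismatch = NULL) {
  assert_protein_tbl(records)
  stopifnot(inherits(pattern, "motif_pattern"))
  budget <- as.integer(max_mismatch %||% pattern$max_mismatch)
  stopifnot(budget >= 0L)
  m <- length(pattern$positions)
  pat_name <- pattern$name
  n_con <- pattern$n_constrained
  rows <- purrr::map2(records$id, records$seq, function(id, seq) {
    chars <- seq_chars(seq)
    mism <- motif_window_mismatches(chars, pattern)
    hit <- which(mism <= budget)
    tibble::tibble(
      protein_id = rep(id, length(hit)),
      pattern = rep(pat_name, length(hit)),
      start = hit,
      end = hit + m - 1L,
      mismatches = mism[hit],
      score = (n_con - mism[hit]) / n_con
    )
  })
  proto <- tibble::tibble(
    protein_id = character(0), pattern = character(0),
    start = integer(0), end = integer(0),
    mismatches = integer(0), score = numeric(0)
  )
  dplyr::bind_rows(c(list(proto), rows))
}
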