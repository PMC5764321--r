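profiles <- ctl_profiles()

test_that("canonical construction yields one RING-H2 hit with zero inserts", {
  rec <- protein_rec(build_ring_seq())
  hits <- scan_ring_domains(rec, profile = profiles$canonical)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$variant, "RING-H2")
  expect_equal(hits$spacing[[1]], c(2L, 14L, 2L, 2L, 2L, 10L, 2L))
  expect_equal(hits$inserts[[1]], rep(0L, 7))
  expect_equal(hits$ligand_pos[[1]], c(1L, 4L, 19L, 22L, 25L, 28L, 39L, 42L))
})

test_that("fungal profile reports the single-residue inserts at gaps 2 and 6", {
  gaps <- c(2, 15, 2, 2, 2, 11, 2)
  rec <- protein_rec(build_ring_seq(gaps))
  hits <- scan_ring_domains(rec, profile = profiles$fungal)
  expect_equal(nrow(hits), 1L)
  # fungal canonical spacing is the shifted vector, so inserts are zero
  expect_equal(hits$spacing[[1]], as.integer(gaps))
  expect_equal(hits$inserts[[1]], rep(0L, 7))
  # relative to the canonical plant/animal spacing the inserts are (0,1,...)
  expect_equal(hits$spacing[[1]] - profiles$canonical$canonical_spacing,
               c(0L, 1L, 0L, 0L, 0L, 1L, 0L))
  # and the canonical-gap domain is not matched by the fungal profile
  expect_equal(nrow(scan_ring_domains(protein_rec(build_ring_seq()),
                                      profile = profiles$fungal)), 0L)
})

test_that("kinetoplast profile accepts gap-2 inserts up to 26 and rejects 27", {
  accept <- protein_rec(build_ring_seq(c(2, 14 + 26, 2, 2, 2, 10, 2)))
  reject <- protein_rec(build_ring_seq(c(2, 14 + 27, 2, 2, 2, 10, 2)))
  h <- scan_ring_domains(accept, profile = profiles$kinetoplast)
  expect_equal(nrow(h), 1L)
  expect_equal(h$inserts[[1]][2], 26L)
  expect_equal(nrow(scan_ring_domains(reject,
                                      profile = profiles$kinetoplast)), 0L)
})

test_that("sequences without the grammar or too short give empty results", {
  expect_equal(nrow(scan_ring_domains(protein_rec(strrep("A", 100)))), 0L)
  expect_equal(nrow(scan_ring_domains(protein_rec("CACH"))), 0L)
})

test_that("variant typing follows the fifth metal ligand", {
  h2 <- protein_rec(build_ring_seq())
  hc <- protein_rec(build_ring_seq(lig5 = "C"))
  expect_equal(scan_ring_domains(h2)$variant, "RING-H2")
  expect_equal(scan_ring_domains(hc)$variant, "RING-HC")
  expect_error(classify_variant(build_ring_seq(lig5 = "A"),
                                c(1L, 4L, 19L, 22L, 25L, 28L, 39L, 42L)),
               "violates the RING grammar")
})

test_that("diagnostic residues are read at their ligand-relative offsets", {
  base <- build_ring_seq()
  chars <- strsplit(base, "")[[1]]
  lig <- c(1, 4, 19, 22, 25, 28, 39, 42)
  atl <- chars
  atl[lig[2] + 1] <- "L"
  atl[lig[3] - 4] <- "R"
  atl[lig[6] + 1] <- "D"
  d <- match_diagnostics(paste(atl, collapse = ""), lig)
  expect_true(all(d$atl_L_at_lig2p1, d$atl_R_at_lig3m4, d$atl_D_at_lig6p1))
  expect_false(d$btl_P_at_lig6p2)

  btl <- chars
  btl[lig[6] + 2] <- "P"
  d <- match_diagnostics(paste(btl, collapse = ""), lig)
  expect_true(d$btl_P_at_lig6p2)
  expect_false(any(d$atl_L_at_lig2p1, d$atl_R_at_lig3m4, d$atl_D_at_lig6p1))

  pro <- chars
  pro[lig[3] - 1] <- "P"
  expect_equal(match_diagnostics(paste(pro, collapse = ""), lig)$pro_adjacent_lig3,
               "adjacent")
  pro <- chars
  pro[lig[3] - 2] <- "P"
  expect_equal(match_diagnostics(paste(pro, collapse = ""), lig)$pro_adjacent_lig3,
               "separated_by_one")
  expect_equal(match_diagnostics(base, lig)$pro_adjacent_lig3, "absent")
})

test_that("X never satisfies a ligand class", {
  seq <- build_ring_seq()
  seq <- sub("^C", "X", seq)
  expect_equal(nrow(scan_ring_domains(protein_rec(seq))), 0L)
})

test_that("scanner agrees with brute-force enumeration on random sequences", {
  set.seed(101)
  kin <- profiles$kinetoplast
  n_hits_seen <- 0L
  for (i in 1:60) {
    n <- sample(30:150, 1)
    # C/H enriched so the grammar can fire by chance
    seq <- paste(sample(c(AA_STANDARD_TEST(), "C", "C", "H", "H"), n,
                        replace = TRUE), collapse = "")
    prof <- if (i %% 2 == 0) profiles$canonical else kin
    if (i %% 3 == 0) {
      # plant a valid domain so non-empty cases are well covered
      g2 <- if (identical(prof$name, "kinetoplast")) sample(14:40, 1) else 14
      seq <- paste0(substr(seq, 1, 25),
                    build_ring_seq(c(2, g2, 2, 2, 2, 10, 2)),
                    substr(seq, 26, n))
    }
    got <- scan_ring_domains(protein_rec(seq), profile = prof)
    want <- oracle_ring_scan(seq, prof)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      n_hits_seen <- n_hits_seen + nrow(got)
      expect_equal(do.call(rbind, got$ligand_pos), unname(want))
    }
  }
  expect_gt(n_hits_seen, 15)
})

test_that("widening a spacing range never removes a hit", {
  set.seed(7)
  base <- ctl_profiles()$kinetoplast
  wide <- lineage_profile(
    "wide",
    spacing_min = pmax(base$spacing[, "min"] - 1L, 0L),
    spacing_max = base$spacing[, "max"] + 2L,
    canonical_spacing = base$canonical_spacing
  )
  for (i in 1:20) {
    g2 <- sample(14:40, 1)
    seq <- build_ring_seq(
      c(2, g2, 2, 2, 2, 10, 2),
      pre = paste(sample(c(AA_STANDARD_TEST(), "C", "H"), 40, replace = TRUE),
                  collapse = ""),
      post = paste(sample(c(AA_STANDARD_TEST(), "C", "H"), 40, replace = TRUE),
                   collapse = "")
    )
    narrow_hits <- oracle_ring_tuples(strsplit(seq, "")[[1]], base)
    wide_hits <- oracle_ring_tuples(strsplit(seq, "")[[1]], wide)
    expect_gt(nrow(narrow_hits), 0)
    narrow_keys <- apply(narrow_hits, 1, paste, collapse = ",")
    wide_keys <- apply(wide_hits, 1, paste, collapse = ",")
    expect_true(all(narrow_keys %in% wide_keys))
  }
})

test_that("scanning is deterministic", {
  rec <- protein_rec(build_ring_seq(pre = strrep("M", 30)))
  expect_identical(scan_ring_domains(rec), scan_ring_domains(rec))
})
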