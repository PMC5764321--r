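yeell <- ctl_patterns()$yeell

test_that("the YEELL consensus parses to 21 positions with a 5-residue core", {
  expect_length(yeell$positions, 21L)
  expect_equal(yeell$core, c(5L, 9L))
  expect_equal(yeell$core[2] - yeell$core[1] + 1L, 5L)
  # the core block reads Y-E-E-L-L through its primary residues
  core_primary <- vapply(yeell$positions[5:9], `[[`, "", 1L)
  expect_equal(core_primary, c("Y", "E", "E", "L", "L"))
  wild <- vapply(yeell$positions, is.null, logical(1))
  expect_equal(sum(!wild), yeell$n_constrained)
})

test_that("consensus parsing handles groups, singles, wildcards and errors", {
  p <- parse_consensus("YE(E/Q)LL")
  expect_length(p$positions, 5L)
  expect_equal(p$n_constrained, 5L)
  expect_error(parse_consensus("Y(E/"), "unbalanced|illegal")
  expect_error(parse_consensus("Y(E/9)L"), "illegal residue")
  expect_error(parse_consensus("1YE"), "illegal residue letter '1' at column 1")
})

test_that("scan_motif finds exact and budgeted matches at the right window", {
  window <- "DAASYEELLALAEALGAVAAG"
  rec <- protein_rec(paste0("MM", window, "KK"))
  hit <- scan_motif(rec, yeell, max_mismatch = 0)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 3L)
  expect_equal(hit$end, 23L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$score, 1)

  # break the Y at pattern position 5
  broken <- sub("SYEE", "SAEE", window)
  rec2 <- protein_rec(paste0("MM", broken, "KK"))
  expect_equal(nrow(scan_motif(rec2, yeell, max_mismatch = 0)), 0L)
  h1 <- scan_motif(rec2, yeell, max_mismatch = 1)
  expect_equal(h1$mismatches, 1L)
  expect_equal(h1$score, (yeell$n_constrained - 1) / yeell$n_constrained)

  expect_equal(nrow(scan_motif(protein_rec(strrep("A", 50)), yeell)), 0L)
  expect_equal(nrow(scan_motif(protein_rec("ACD"), yeell)), 0L)
})

test_that("X in the sequence always mismatches at constrained positions", {
  window <- "DAASYEELLALAEALGAVAAG"
  xed <- sub("^D", "X", window)  # constrained position 1
  h <- scan_motif(protein_rec(xed), yeell, max_mismatch = 1)
  expect_equal(h$mismatches, 1L)
  # X at a wildcard position costs nothing
  xwild <- paste0("D", "X", substr(window, 3, 21))
  h <- scan_motif(protein_rec(xwild), yeell, max_mismatch = 0)
  expect_equal(nrow(h), 1L)
})

test_that("scan_motif agrees with the brute-force window check", {
  set.seed(202)
  pat_small <- parse_consensus("(A/C)X(D/E)L", name = "small")
  for (i in 1:100) {
    n <- sample(10:200, 1)
    seq <- paste(sample(AA_STANDARD_TEST(), n, replace = TRUE), collapse = "")
    pat <- if (i %% 2 == 0) yeell else pat_small
    budget <- sample(0:3, 1)
    got <- scan_motif(protein_rec(seq), pat, max_mismatch = budget)
    want <- oracle_motif_scan(seq, pat, budget)
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("prepending residues shifts hit coordinates exactly", {
  set.seed(9)
  window <- "DAASYEELLALAEALGAVAAG"
  base <- paste0(window, paste(sample(AA_STANDARD_TEST(), 30, replace = TRUE),
                               collapse = ""))
  h0 <- scan_motif(protein_rec(base), yeell)
  for (k in c(1, 7, 25)) {
    shifted <- paste0(strrep("G", k), base)
    hk <- scan_motif(protein_rec(shifted), yeell)
    expect_equal(hk$start, h0$start + k)
    expect_equal(hk$end, h0$end + k)
    expect_equal(hk$mismatches, h0$mismatches)
  }
})

test_that("the default budget admits instances with up to 3 constrained mutations", {
  set.seed(33)
  constrained <- which(!vapply(yeell$positions, is.null, logical(1)))
  for (i in 1:25) {
    inst <- vapply(yeell$positions, function(allowed) {
      if (is.null(allowed)) sample(AA_STANDARD_TEST(), 1)
      else sample(allowed, 1)
    }, "")
    k <- sample(0:3, 1)
    for (p in sample(constrained, k)) {
      inst[p] <- sample(setdiff(AA_STANDARD_TEST(), yeell$positions[[p]]), 1)
    }
    h <- scan_motif(protein_rec(paste(inst, collapse = "")), yeell)
    expect_equal(nrow(h), 1L)
    expect_equal(h$mismatches, k)
  }
})

test_that("pattern YAML configs load and validate", {
  pats <- load_patterns(system.file("extdata", "patterns.yaml",
                                    package = "ctlscan"))
  expect_named(pats, c("yeell", "gld", "gld_like"))
  expect_length(pats$yeell$positions, 21L)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- name: bad", "  consensus: YEL", "  cor: [1, 2]"), f)
  expect_error(load_patterns(f), "valid keys are")
})
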