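test_that("anchored alignment pads spacer blocks to the widest member", {
  spec <- synthetic_spec(n_per_label = c(CTL = 2), seed = 5)
  prot <- generate_proteome(spec)
  hits <- scan_ring_domains(prot)
  aln <- anchor_align(hits, prot)
  expect_length(aln$rows, 2L)
  expect_equal(length(unique(nchar(aln$rows))), 1L)
  # identical spacing profile: no gaps needed, degapping recovers domains
  for (i in 1:2) {
    domain <- substr(prot$seq[i], hits$start[i], hits$end[i])
    expect_equal(gsub("-", "", aln$rows[[i]]), domain)
  }

  # mixed spacings: the shorter spacer block gets exactly the difference
  k1 <- protein_rec(build_ring_seq(), id = "k1")
  k2 <- protein_rec(build_ring_seq(c(2, 15, 2, 2, 2, 10, 2)), id = "k2")
  recs <- rbind(k1, k2)
  kin <- ctl_profiles()$kinetoplast
  h <- scan_ring_domains(recs, profile = kin)
  a2 <- anchor_align(h, recs)
  expect_equal(sum(strsplit(a2$rows[["k1"]], "")[[1]] == "-"), 1L)
  expect_equal(sum(strsplit(a2$rows[["k2"]], "")[[1]] == "-"), 0L)

  expect_error(anchor_align(h[1, ], recs), "at least 2")
})

test_that("p and Poisson distances follow their closed forms", {
  rows <- c(A = "ACDE", B = "ACDF")
  D <- aln_distances(rows, model = "p")
  expect_equal(D["A", "B"], 0.25)
  expect_equal(diag(D), c(A = 0, B = 0))
  Dp <- aln_distances(rows, model = "poisson")
  expect_equal(Dp["A", "B"], -log(0.75), tolerance = 1e-12)
  expect_equal(Dp["A", "B"], 0.287682, tolerance = 1e-6)

  expect_equal(aln_distances(c(A = "ACDE", B = "ACDE"))["A", "B"], 0)

  # gapped columns are skipped pairwise
  rows <- c(A = "AC-E", B = "ACD-", C = "ACDE")
  D <- aln_distances(rows)
  expect_equal(D["A", "B"], 0)   # only columns 1-2 comparable
  expect_equal(D["A", "C"], 0)
  expect_error(aln_distances(c(A = "--", B = "--")), "no comparable")
})

test_that("NJ solves the three-taxon case in closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(D)
  lens <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                   tree$tip.label)
  expect_equal(lens, c(A = 1, B = 1, C = 3))
})

test_that("NJ recovers the four-taxon additive split with exact lengths", {
  # tree ((A:1,B:1):1,(C:1,D:1)): dAB = dCD = 2, all cross distances 4
  labs <- c("A", "B", "C", "D")
  D <- matrix(4, 4, 4, dimnames = list(labs, labs))
  diag(D) <- 0
  D["A", "B"] <- D["B", "A"] <- 2
  D["C", "D"] <- D["D", "C"] <- 2
  tree <- neighbor_joining(D)
  expect_equal(tree_metric(tree, labs), D, tolerance = 1e-12)
  best <- brute_force_best_topology(D)
  expect_true(same_topology(tree, best))
})

test_that("NJ handles n = 2 and rejects invalid matrices", {
  D <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- neighbor_joining(D)
  expect_equal(sum(tree$edge.length), 3)
  bad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(neg), "negative")
})

test_that("NJ recovers random additive trees and matches ape's NJ", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    gen <- random_additive_tree(n)
    labs <- gen$tip.label
    D <- tree_metric(gen, labs)
    tree <- neighbor_joining(D)
    expect_true(same_topology(tree, gen))
    expect_equal(tree_metric(tree, labs), D, tolerance = 1e-9)
    expect_true(same_topology(tree, ape::nj(D)))
  }
})

test_that("bootstrap supports are reproducible and bounded", {
  spec <- synthetic_spec(n_per_label = c(CTL = 5), seed = 13)
  prot <- generate_proteome(spec)
  hits <- scan_ring_domains(prot)
  aln <- anchor_align(hits, prot)
  t1 <- bootstrap_support(aln, n_reps = 25, seed = 99)
  t2 <- bootstrap_support(aln, n_reps = 25, seed = 99)
  expect_identical(ctlscan:::phylo_to_newick(t1),
                   ctlscan:::phylo_to_newick(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 1))
})

test_that("clearly separated clades get bootstrap support 1", {
  # two clades of identical rows, heavily different between clades
  rows <- c(A1 = strrep("A", 30), A2 = strrep("A", 30),
            B1 = strrep("W", 30), B2 = strrep("W", 30))
  tree <- bootstrap_support(rows, n_reps = 40, seed = 3)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup == 1))
})

test_that("group assignment follows nearest anchors with an H margin", {
  # anchors a1 (group A) and b1 (group B); q1 near a1, q2 equidistant
  nwk <- "((a1:0.1,q1:0.1):1.0,(b1:0.1,x:0.1):1.0,q2:1.1);"
  tree <- ape::read.tree(text = nwk)
  groups <- assign_groups(tree, list(A = "a1", B = "b1"))
  g <- setNames(groups$group, groups$id)
  expect_equal(g[["a1"]], "A")
  expect_equal(g[["b1"]], "B")
  expect_equal(g[["q1"]], "A")
  expect_equal(g[["x"]], "B")
  expect_equal(g[["q2"]], "H")
  expect_error(assign_groups(tree, list()), "empty")
  expect_error(assign_groups(tree, list(A = "nope")), "not in tree")
})
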