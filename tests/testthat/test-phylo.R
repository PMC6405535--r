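test_that("concatenation of identical-length genes has no gap columns", {
  panel <- fx_panel()
  aln <- concatenate_pcgs(panel[c("armigera_1", "armigera_2", "zea_1")])
  widths <- nchar(aln$seqs)
  expect_length(unique(widths), 1L)
  expect_false(any(grepl("-", aln$seqs)))
  ## total length equals the sum of the 13 PCG lengths in the layout
  ann <- fx_template()$annotations
  pcg_len <- sum((ann$end - ann$start)[!ann$gene %in% c("rrnL", "rrnS")])
  expect_equal(unique(widths), pcg_len)
  expect_equal(nrow(aln$partition), 13L)
  expect_equal(aln$partition$end[13], pcg_len)
})

test_that("a planted 3 bp insertion creates exactly 3 gap columns inside ND5", {
  panel <- fx_panel()
  e <- panel$zea_2
  ann <- e$annotations
  nd5 <- ann[ann$gene == "ND5", ]
  s <- e$record$residues
  ## ND5 is minus-strand; inserting mid-gene in genome space is still mid-gene
  at <- nd5$start + 800L
  s2 <- paste0(substr(s, 1, at), "ACT", substr(s, at + 1, nchar(s)))
  ann2 <- ann
  ann2$end[ann2$gene == "ND5"] <- ann2$end[ann2$gene == "ND5"] + 3L
  shift <- ann2$start >= nd5$end
  ann2$start[shift] <- ann2$start[shift] + 3L
  ann2$end[shift] <- ann2$end[shift] + 3L
  e2 <- list(record = seq_record("ins3", s2, topology = "circular"),
             annotations = ann2, species = "zea")
  aln <- concatenate_pcgs(list(panel$zea_1, panel$armigera_1, e2))
  gap_cols <- which(apply(do.call(rbind, strsplit(unlist(aln$seqs), "")) == "-", 2, any))
  expect_length(gap_cols, 3L)
  nd5_part <- aln$partition[aln$partition$gene == "ND5", ]
  expect_true(all(gap_cols >= nd5_part$start & gap_cols <= nd5_part$end))
})

test_that("taxa missing a gene are dropped with a warning", {
  panel <- fx_panel()
  e <- panel$gelotopoeon_2
  e$annotations <- e$annotations[e$annotations$gene != "ATP8", ]
  expect_warning(aln <- concatenate_pcgs(list(panel$zea_1, panel$armigera_1, e)),
                 "gelotopoeon_2")
  expect_setequal(aln$taxa, c("zea_1", "armigera_1"))
})

test_that("K2P matches the closed form and its small-divergence limit", {
  ## identical sequences
  expect_equal(unclass(k2p_distance(c(a = "ACGTACGT", b = "ACGTACGT")))["a", "b"], 0)
  ## 10% transitions, no transversions over 1000 sites: -log(0.8)/2
  s1 <- strrep("A", 1000)
  s2 <- paste0(strrep("G", 100), strrep("A", 900))
  d <- k2p_distance(c(a = s1, b = s2))
  expect_equal(unclass(d)["a", "b"], -0.5 * log(0.8), tolerance = 1e-12)
  ## K2P ~ p for small p
  set.seed(87)
  a <- random_seq(5000)
  bv <- strsplit(a, "")[[1]]
  idx <- sample(5000, 100)
  bv[idx] <- vapply(bv[idx], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  d2 <- unclass(k2p_distance(c(a = a, b = paste(bv, collapse = ""))))["a", "b"]
  expect_lt(abs(d2 / 0.02 - 1), 0.05)  # within 5% relative of the p-distance
})

test_that("K2P agrees with the reference implementation in ape", {
  set.seed(98)
  seqs <- setNames(lapply(1:5, function(i) random_seq(800)), paste0("t", 1:5))
  base <- strsplit(seqs$t1, "")[[1]]
  for (i in 2:5) {
    v <- base
    idx <- sample(800, 15 * i)
    v[idx] <- vapply(v[idx], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    seqs[[i]] <- paste(v, collapse = "")
  }
  mine <- unclass(k2p_distance(unlist(seqs)))
  bin <- ape::as.DNAbin(lapply(seqs, function(s) strsplit(tolower(s), "")[[1]]))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("gap and N columns are excluded pairwise; saturation is flagged", {
  d <- k2p_distance(c(a = "ACGTACGTNN", b = "ACGTACGT--"))
  expect_equal(unclass(d)["a", "b"], 0)
  dd <- k2p_distance(c(a = strrep("A", 50), b = strrep("C", 50)), ceiling = 7)
  expect_equal(unclass(dd)["a", "b"], 7)
  expect_length(attr(dd, "saturated"), 1L)
})

test_that("three taxa resolve to the unique unrooted star", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 1L)
  ## branch lengths from the three-point formulas
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["x"]), 0.5)
  expect_equal(unname(bl["y"]), 1.5)
  expect_equal(unname(bl["z"]), 2.5)
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    true <- ape::rtree(n)
    d <- stats::cophenetic(true)
    mine <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(true), ape::unroot(mine)), 0)
    ## branch lengths are recovered too (sum of all edges is tree length)
    expect_equal(sum(mine$edge.length), sum(ape::unroot(true)$edge.length),
                 tolerance = 1e-6)
  }
})

test_that("NJ is deterministic and invariant to taxon input order", {
  set.seed(29)
  true <- ape::rtree(8)
  d <- stats::cophenetic(true)
  t1 <- neighbor_joining(d)
  perm <- sample(rownames(d))
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0)
  ## and agrees with the reference implementation topologically
  t3 <- ape::nj(stats::as.dist(d))
  expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t3)), 0)
})

test_that("species form clades when intra << inter divergence", {
  panel <- fx_panel()
  tree <- neighbor_joining(k2p_distance(concatenate_pcgs(panel)))
  rooted <- ape::root(tree, "outgroup_1", resolve.root = TRUE)
  for (sp in c("armigera", "zea", "assulta", "punctigera", "gelotopoeon")) {
    tips <- grep(paste0("^", sp, "_"), tree$tip.label, value = TRUE)
    expect_true(ape::is.monophyletic(rooted, tips), label = paste(sp, "monophyly"))
  }
})

test_that("bootstrap labelling is seeded and reproducible", {
  panel <- fx_panel()
  aln <- concatenate_pcgs(panel[c("armigera_1", "armigera_2", "zea_1", "zea_2",
                                  "assulta_1", "outgroup_1")])
  b1 <- nj_bootstrap(aln, reps = 20, seed = 3)
  b2 <- nj_bootstrap(aln, reps = 20, seed = 3)
  expect_identical(b1$node.label, b2$node.label)
  expect_equal(phangorn::RF.dist(b1, b2), 0)
  ## conspecific pairs at these divergences are essentially always recovered
  expect_true(any(as.integer(b1$node.label) >= 95))
})
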