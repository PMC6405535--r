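test_that("identity basics: identical, single substitution, rounding", {
  set.seed(12)
  s <- random_seq(1000)
  expect_equal(pairwise_identity(s, s), 100)
  ## 20-mer with exactly one substitution, no gaps: 19/20
  a <- "ACGTACGTACGTACGTACGT"
  b <- "ACGTACGTACTTACGTACGT"
  expect_equal(pairwise_identity(a, b), 95)
})

test_that("N columns are excluded; gap-versus-base counts as mismatch", {
  a <- "ACGTACGTAC"
  b <- "ACGTNCGTAC"   # N column dropped from numerator and denominator
  expect_equal(pairwise_identity(a, b), 100)
  ## a deletion of one base: 9 matches over 10 columns (gap column mismatches)
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGTCGTAC"), 90)
})

test_that("banded aligner agrees with full dynamic programming at small sizes", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(300:1500, 1)
    a <- random_seq(n)
    b <- strsplit(a, "")[[1]]
    k <- sample(5:40, 1)
    idx <- sample(n, k)
    b[idx] <- vapply(b[idx], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    ## occasional short indel
    if (i %% 3 == 0) b <- b[-sample(n, 2)]
    b <- paste(b, collapse = "")
    ## alignment scores agree exactly; identity may differ marginally when
    ## co-optimal alignments place a gap differently
    full_al <- mitokey:::align_global_full(a, b)
    band_al <- align_banded(a, b)
    expect_equal(band_al$score, full_al$score, tolerance = 1e-9)
    full <- pairwise_identity(a, b, method = "full")
    banded <- pairwise_identity(a, b, method = "banded")
    expect_equal(banded, full, tolerance = 0.001)
  }
})

test_that("identity is symmetric and degrades monotonically", {
  set.seed(34)
  a <- random_seq(1200)
  b <- strsplit(a, "")[[1]]
  prev <- 100
  positions <- sample(1200, 50)
  for (k in c(5, 10, 20, 35, 50)) {
    bb <- b
    idx <- positions[seq_len(k)]
    bb[idx] <- vapply(b[idx], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    bb <- paste(bb, collapse = "")
    id_ab <- pairwise_identity(a, bb)
    id_ba <- pairwise_identity(bb, a)
    expect_equal(id_ab, id_ba)
    expect_lte(id_ab, prev)
    prev <- id_ab
  }
})

test_that("wildly different lengths fall back to local-core identity with a warning", {
  set.seed(45)
  core <- random_seq(300)
  long <- paste0(random_seq(400), core, random_seq(400))
  expect_warning(v <- pairwise_identity(core, long), "local-core")
  expect_gte(v, 99)
})

test_that("per-gene matrices localize differences to the right gene", {
  panel <- fx_panel()
  e1 <- panel$armigera_1
  ## copy differing only inside ND3
  ann <- e1$annotations
  nd3 <- ann[ann$gene == "ND3", ]
  s <- strsplit(e1$record$residues, "")[[1]]
  idx <- (nd3$start + 10L):(nd3$start + 14L)
  s[idx] <- vapply(s[idx], function(x) setdiff(c("A", "C", "G", "T"), x)[1], "")
  e2 <- list(record = seq_record("twin", paste(s, collapse = ""), topology = "circular"),
             annotations = ann, species = "armigera")
  gm <- gene_identity_matrix(list(e1, e2))
  for (g in names(gm)) {
    v <- gm[[g]]["armigera_1", "twin"]
    if (g == "ND3") expect_lt(v, 100) else expect_equal(v, 100)
  }
})

test_that("missing genes yield NA cells, not zero", {
  panel <- fx_panel()
  e1 <- panel$zea_1
  e2 <- panel$zea_2
  e2$annotations <- e2$annotations[e2$annotations$gene != "COB", ]
  gm <- gene_identity_matrix(list(e1, e2), gene_names = c("COB", "ND2"))
  expect_true(is.na(gm$COB["zea_1", "zea_2"]))
  expect_false(is.na(gm$ND2["zea_1", "zea_2"]))
})

test_that("panel identities match the generator's planted counts", {
  panel <- fx_panel()
  mism <- attr(panel, "expected_mismatches")
  ncomp <- attr(panel, "n_comparable")
  ids <- c("armigera_1", "zea_1", "assulta_1", "punctigera_1")
  for (pair in combn(ids, 2, simplify = FALSE)) {
    measured <- pairwise_identity(panel[[pair[1]]]$record, panel[[pair[2]]]$record,
                                  method = "banded")
    planted <- 100 * (ncomp - mism[pair[1], pair[2]]) / ncomp
    expect_equal(measured, planted, tolerance = 0.1)
  }
})

test_that("intraspecific identities exceed interspecific ones on the panel", {
  panel <- fx_panel()
  wm <- whole_identity_matrix(panel[c("armigera_1", "armigera_2", "zea_1", "zea_2",
                                      "assulta_1", "assulta_2")])
  sp <- sub("_[0-9]+$", "", rownames(wm))
  same <- outer(sp, sp, "==") & upper.tri(wm)
  diff <- outer(sp, sp, "!=") & upper.tri(wm)
  expect_gt(min(wm[same]), max(wm[diff]))
  ## and on the observed scale: conspecifics ~99.5%, armigera-zea ~97.2%
  expect_gt(min(wm[same]), 98.8)
  expect_lt(max(wm[diff]), 97.5)
})

test_that("misid_screen: a reference queried against its own panel is consistent", {
  panel <- fx_panel()
  refs <- panel[c("armigera_1", "assulta_1", "zea_1", "punctigera_1", "gelotopoeon_1")]
  rep0 <- misid_screen(panel$assulta_1, refs, gene_names = c("COI", "COB", "ND2"))
  expect_identical(rep0$verdict, "consistent")
  expect_equal(rep0$identity_to_label, 100)
})

test_that("misid_screen flags a relabelled genome and a chimera differently", {
  panel <- fx_panel()
  refs <- panel[c("armigera_1", "assulta_1", "zea_1", "punctigera_1", "gelotopoeon_1")]
  ## an armigera genome wearing an assulta label (the deposited-misidentified case)
  q <- panel$armigera_3
  q$species <- "assulta"
  q$record$id <- "mislabelled"
  rep1 <- misid_screen(q, refs)
  expect_identical(rep1$verdict, "misidentified")
  expect_identical(rep1$best_species, "armigera")
  expect_gte(rep1$identity_to_best - rep1$identity_to_label, 2)
  ## an assulta backbone carrying an armigera block (the chimeric-assembly case)
  rep2 <- misid_screen(fx_chimera(), refs)
  expect_identical(rep2$verdict, "chimeric_suspect")
  foreign <- rep2$gene_best$gene[rep2$gene_best$best_species == "armigera"]
  expect_setequal(foreign, c("COB", "ND1", "rrnL", "rrnS"))
  expect_error(misid_screen(q, list()), "empty")
})
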