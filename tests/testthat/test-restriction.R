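test_that("enzyme table notations parse to the documented cut offsets", {
  enz <- fx_enzymes()
  ## caret notation: cut position inside the site, bottom cut symmetric
  expect_identical(enz$Eco130I$recognition, "CCWWGG")
  expect_equal(enz$Eco130I$cut_top, 1L)
  expect_equal(enz$Eco130I$cut_bottom, 5L)
  expect_true(enz$Eco130I$palindromic)
  ## blunt degenerate cutter
  expect_equal(enz$BseJI$cut_top, 5L)
  expect_true(enz$BseJI$palindromic)
  ## offset notation counts past the site 3' end: GAGGAG(10/8) -> 6+10
  expect_equal(enz$BseRI$cut_top, 16L)
  expect_equal(enz$BseRI$cut_bottom, 14L)
  expect_false(enz$BseRI$palindromic)
  expect_equal(enz$BsaI$cut_top, 7L)
  ## the packaged panel carries all eight names of the consolidated key
  expect_setequal(names(enz), c("BseJI", "BsaI", "BsaBI", "BpuEI",
                                "Bco5I", "AquVI", "BseRI", "Eco130I"))
})

test_that("malformed enzyme definitions fail with the line number", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Good\tC^CWWGG", "Bad\tGGTCTC[1/5]"), p)
  expect_error(load_enzyme_table(p), "line 2")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Dup\tC^CWWGG", "Dup\tG^GATCC"), p2)
  expect_error(load_enzyme_table(p2), "duplicate")
})

test_that("degenerate sites match their IUPAC expansion", {
  enz <- fx_enzymes()
  s <- paste0(strrep("A", 20), "GATCCAAATC", strrep("A", 20))
  hits <- scan_sites(s, enz$BseJI)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 25L)  # site starts at 0-based 20, blunt cut at +5
  expect_equal(hits$site_start, 21L)
  ## N in the subject never satisfies a site, even at degenerate positions
  s_n <- paste0(strrep("A", 20), "GATCCNAATC", strrep("A", 20))
  expect_equal(nrow(scan_sites(s_n, enz$BseJI)), 0L)
  expect_equal(nrow(scan_sites(s_n, enz$BseJI, strict = FALSE)), 1L)
})

test_that("downstream cuts beyond the sequence end are dropped", {
  enz <- fx_enzymes()
  ## BpuEI cuts 22 bases from the site start; site 10 bp from the 3' end
  s <- paste0(strrep("A", 30), "CTTGAG", strrep("A", 4))
  expect_equal(nrow(scan_sites(s, enz$BpuEI)), 0L)
  ## with enough room the cut appears
  s2 <- paste0(strrep("A", 30), "CTTGAG", strrep("A", 30))
  hits <- scan_sites(s2, enz$BpuEI)
  expect_true(any(hits$strand == "+" & hits$position == 52L))
})

test_that("scanner agrees with a naive position-by-position matcher", {
  enz <- fx_enzymes()
  set.seed(33)
  for (i in 1:60) {
    s <- random_seq(300, c("A", "C", "G", "T", "N"), prob = c(.24, .24, .24, .24, .04))
    for (e in enz[c("BseJI", "BpuEI", "Eco130I", "BsaI")]) {
      expect_identical(sort(unique(scan_sites(s, e)$position)), naive_scan(s, e))
    }
  }
})

test_that("fragment lengths always sum to the amplicon length", {
  enz <- fx_enzymes()
  set.seed(44)
  for (i in 1:200) {
    s <- random_seq(sample(200:1500, 1))
    for (e in enz) {
      pat <- digest(s, e)
      expect_equal(sum(pat$fragments), pat$amplicon_length)
      expect_true(all(pat$fragments >= 1L))
      expect_equal(length(pat$fragments), length(pat$cut_positions) + 1L)
    }
  }
})

test_that("digesting the reverse complement reverses the fragment list", {
  ## Under top-strand cut arithmetic (the gel convention used throughout),
  ## reversal is exact for blunt cutters; sticky-end cutters shift every cut
  ## by the constant overhang cut_top - cut_bottom, so internal fragments are
  ## preserved and only the two terminal fragments move by that amount.
  enz <- fx_enzymes()
  set.seed(55)
  for (i in 1:50) {
    s <- random_seq(800)
    for (e in enz[c("BseJI", "Bco5I", "AquVI")]) {
      fw <- digest(s, e)$fragments
      rv <- digest(revcomp(s), e)$fragments
      expect_identical(rv, rev(fw))
    }
    for (e in enz[c("BseRI", "Eco130I")]) {
      fw <- rev(digest(s, e)$fragments)
      rv <- digest(revcomp(s), e)$fragments
      if (length(fw) < 2L || length(rv) != length(fw)) next  # end-shift merged a cut
      delta <- abs(e$cut_top - e$cut_bottom)
      n <- length(fw)
      if (n > 2L) expect_identical(rv[2:(n - 1)], fw[2:(n - 1)])
      expect_lte(abs(rv[1] - fw[1]), delta)
      expect_lte(abs(rv[n] - fw[n]), delta)
    }
  }
})

test_that("palindromic sites are not double counted", {
  enz <- fx_enzymes()
  s <- paste0(strrep("A", 10), "CCAAGG", strrep("A", 10))  # one Eco130I site
  hits <- scan_sites(s, enz$Eco130I)
  expect_equal(nrow(hits), 1L)
  expect_identical(digest(s, enz$Eco130I)$fragments, c(11L, 15L))
})

test_that("adding a recognition site never decreases fragment count", {
  enz <- fx_enzymes()
  set.seed(66)
  for (i in 1:30) {
    s <- random_seq(600)
    base_n <- length(digest(s, enz$Eco130I)$fragments)
    pos <- sample(100:450, 1)
    s2 <- paste0(substr(s, 1, pos), "CCAAGG", substr(s, pos + 7, 600))
    expect_gte(length(digest(s2, enz$Eco130I)$fragments), base_n)
  }
})

test_that("two arbitrary cuts produce the expected arithmetic", {
  enz <- fx_enzymes()
  set.seed(77)
  for (i in 1:25) {
    repeat {
      ab <- sort(sample(30:670, 2))
      if (diff(ab) > 20) break
    }
    a <- ab[1]; b <- ab[2]
    s <- strsplit(random_seq(698, prob = c(.45, .05, .05, .45)), "")[[1]]
    ## plant Bco5I (CCT^AAG, cut_top 3) at cuts a and b
    s[(a - 2):(a + 3)] <- strsplit("CCTAAG", "")[[1]]
    s[(b - 2):(b + 3)] <- strsplit("CCTAAG", "")[[1]]
    s <- paste(s, collapse = "")
    if (!identical(sort(unique(scan_sites(s, enz$Bco5I)$position)), c(a, b))) next
    expect_identical(digest(s, enz$Bco5I)$fragments, c(a, b - a, 698L - b))
  }
})

test_that("circular digestion joins the origin-spanning fragment", {
  enz <- fx_enzymes()
  ## one site near each end of the linearization
  s <- paste0("TTT", "CCAAGG", strrep("A", 50), "CCAAGG", "TTTT")
  lin <- digest(s, enz$Eco130I, circular = FALSE)$fragments
  circ <- digest(s, enz$Eco130I, circular = TRUE)$fragments
  expect_equal(sum(circ), nchar(s))
  expect_equal(length(circ), length(lin) - 1L)
  ## uncut circular molecule is one full-length fragment
  expect_identical(digest(strrep("AT", 40), enz$Eco130I, circular = TRUE)$fragments, 80L)
})

test_that("fragment spans print in gel-report notation", {
  expect_identical(format_fragments(c(461L, 237L)), "1.0.461 (461 bp) 462.0.698 (237 bp)")
  expect_identical(format_fragments(c(511L)), "1.0.511 (511 bp)")
})
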