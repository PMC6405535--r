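## Shared fixtures, built once per test run and cached. Everything is
## generated in code from pinned seeds; no binary data.

.fixtures <- new.env(parent = emptyenv())

fx_enzymes <- function() {
  if (is.null(.fixtures$enzymes)) .fixtures$enzymes <- load_enzyme_table()
  .fixtures$enzymes
}

fx_key <- function() {
  if (is.null(.fixtures$key)) .fixtures$key <- load_key()
  .fixtures$key
}

## mitogenome panel with enough individuals per species for consensus donor
## sets and clade checks; outgroup included for rooting
fx_panel <- function() {
  if (is.null(.fixtures$panel)) {
    .fixtures$panel <- make_genome_panel(fixture_spec(
      seed = 5,
      n_per_species = c(punctigera = 2L, armigera = 3L, assulta = 3L,
                        zea = 2L, gelotopoeon = 2L),
      include_outgroup = TRUE))
  }
  .fixtures$panel
}

fx_template <- function() {
  if (is.null(.fixtures$template)) .fixtures$template <- genome_template()
  .fixtures$template
}

## chimera emulating the published case: assulta backbone with an armigera
## block spanning COB..rrnS
fx_chimera <- function() {
  if (is.null(.fixtures$chimera)) {
    ann <- fx_template()$annotations
    .fixtures$chimera <- make_chimera(
      fx_panel()$assulta_3, fx_panel()$armigera_1,
      ann$start[ann$gene == "COB"] + 1L, ann$end[ann$gene == "rrnS"],
      id = "suspect_chimera")
  }
  .fixtures$chimera
}

## naive position-by-position degenerate matcher: the slow reference
## implementation for site scanning (strict-N semantics)
naive_scan <- function(sequence, enz) {
  expand <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                 Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                 K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                 D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
  n <- nchar(sequence)
  cuts <- integer(0)
  pats <- list(list(p = enz$recognition, cut = function(s, L) s + enz$cut_top))
  if (!enz$palindromic) {
    pats <- c(pats, list(list(p = revcomp(enz$recognition),
                              cut = function(s, L) s + L - enz$cut_bottom)))
  }
  for (pp in pats) {
    pat <- strsplit(pp$p, "")[[1]]
    L <- length(pat)
    for (s in 0:(n - L)) {
      win <- strsplit(substr(sequence, s + 1, s + L), "")[[1]]
      ok <- TRUE
      for (k in seq_len(L)) {
        if (!(win[k] %in% c("A", "C", "G", "T")) || !(win[k] %in% expand[[pat[k]]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) cuts <- c(cuts, pp$cut(s, L))
    }
  }
  sort(unique(cuts[cuts > 0 & cuts < n]))
}

## fast independent oracle via Biostrings pattern matching plus strict-N
## window filter
biostrings_scan <- function(sequence, enz) {
  cuts <- integer(0)
  pats <- unique(c(enz$recognition, revcomp(enz$recognition)))
  for (pat in pats) {
    hits <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(pat), Biostrings::DNAString(sequence),
      fixed = c(pattern = FALSE, subject = TRUE))) - 1L
    keep <- vapply(hits, function(h) {
      !grepl("[^ACGT]", substr(sequence, h + 1L, h + nchar(pat)))
    }, TRUE)
    hits <- hits[keep]
    cut <- if (pat == enz$recognition) hits + enz$cut_top else hits + nchar(pat) - enz$cut_bottom
    cuts <- c(cuts, cut)
  }
  sort(unique(cuts[cuts > 0 & cuts < nchar(sequence)]))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}
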