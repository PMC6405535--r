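## synthetic_fixtures: seeded generators for amplicons carrying the key's
## cut-site layout, mitogenome panels at target nucleotide identities, and
## chimeras spliced at known coordinates. Every fixture carries its ground
## truth so downstream modules can be tested without any downloads.
##
## All randomness flows through with_seed(); the same seed gives the same
## fixture on any platform (R's default Mersenne-Twister RNG).

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

## AT-rich random background resembling lepidopteran mtDNA (A+T ~ 80%)
random_dna <- function(n, at = 0.80) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)), collapse = "")
}

## concrete instance of a degenerate recognition site
concretize_site <- function(recognition) {
  paste(vapply(strsplit(recognition, "")[[1]], function(ch) {
    opts <- IUPAC_EXPANSION[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

#' Generate a synthetic diagnostic amplicon for one species
#'
#' Draws a seeded AT-rich background of the region length, rejection-sampling
#' until no panel enzyme has a spurious site, then plants each recognition
#' site the key expects for the species so that the cut coordinates equal the
#' key's. Degenerate bases in recognition sequences are resolved by seeded
#' random choice; sites may be planted in either orientation when the
#' top-strand placement collides with an already-planted site. The result is
#' re-verified: digesting it with every panel enzyme reproduces the key's
#' fragment lengths exactly.
#'
#' @param species species name from the key.
#' @param region region name from the key.
#' @param key a `diagnostic_key` (defaults to the packaged key).
#' @param enzymes named list of [enzyme()] objects (defaults to the packaged
#'   panel).
#' @param seed integer seed; same seed, same amplicon.
#' @param at background A+T fraction.
#' @param max_attempts rejection-sampling cap.
#' @return A [seq_record] (linear) with attribute `truth` giving the planted
#'   cut coordinates per enzyme.
#' @export
make_amplicon <- function(species, region, key = load_key(),
                          enzymes = load_enzyme_table(), seed = 1L,
                          at = 0.80, max_attempts = 10000L) {
  panel <- key_enzymes(key, region)
  missing_e <- setdiff(panel, names(enzymes))
  if (length(missing_e)) stop("enzyme definitions missing: ", paste(missing_e, collapse = ", "))
  len <- unname(key$region_lengths[region])
  expected <- lapply(setNames(panel, panel), function(e) key_pattern(key, species, region, e))
  cuts_needed <- lapply(expected, function(f) if (length(f) > 1L) cumsum(f)[-length(f)] else integer(0))

  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      bg <- random_dna(len, at = at)
      if (any(vapply(panel, function(e) nrow(scan_sites(bg, enzymes[[e]])) > 0L, TRUE))) next
      seqv <- strsplit(bg, "")[[1]]
      occupied <- integer(0)
      ok <- TRUE
      for (e in panel) {
        enz <- enzymes[[e]]
        L <- nchar(enz$recognition)
        for (cut in cuts_needed[[e]]) {
          cur <- paste(seqv, collapse = "")
          if (cut %in% scan_sites(cur, enz)$position) next  # isoschizomer already planted
          placed <- FALSE
          for (orient in c("+", "-")) {
            s <- if (orient == "+") cut - enz$cut_top else cut - L + enz$cut_bottom
            if (s < 0L || s + L > len) next
            span <- (s + 1L):(s + L)
            if (any(span %in% occupied)) next
            motif <- concretize_site(enz$recognition)
            if (orient == "-") motif <- revcomp(motif)
            seqv[span] <- strsplit(motif, "")[[1]]
            occupied <- c(occupied, span)
            placed <- TRUE
            break
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) next
      out <- paste(seqv, collapse = "")
      verified <- all(vapply(panel, function(e) {
        identical(digest(out, enzymes[[e]])$fragments, as.integer(expected[[e]]))
      }, TRUE))
      if (verified) {
        rec <- seq_record(paste(species, region, sep = "_"), out,
                          description = sprintf("synthetic %s amplicon (%s)", region, species))
        attr(rec, "truth") <- list(species = species, region = region,
                                   cuts = cuts_needed[lengths(cuts_needed) > 0L], seed = seed)
        return(rec)
      }
    }
    stop("failed to build a clean ", species, "/", region, " amplicon in ",
         max_attempts, " attempts; consider a longer region or different seed")
  })
}

## ---- genome panel --------------------------------------------------------

#' Mitogenome layout used by the generator
#'
#' Gene order, lengths and strands follow the shared synteny of these moth
#' mitogenomes (13 protein-coding genes and both rRNAs; the minority strand
#' carries ND5/ND4/ND4L/ND1 and both rRNAs), with 100 bp intergenic spacers
#' and a control region containing the 5N origin spacer low-complexity
#' marker. Total length ~15.3 kb.
#'
#' @param spacer intergenic spacer length (bp).
#' @param control_region control-region length (bp), 5N spacer included.
#' @return list with `length`, `annotations` (0-based half-open) and
#'   `n_positions` (coordinates of the Ns).
#' @export
genome_template <- function(spacer = 100L, control_region = 440L) {
  genes <- data.frame(
    gene = c("ND2", "COI", "COII", "ATP8", "ATP6", "COIII", "ND3",
             "ND5", "ND4", "ND4L", "ND6", "COB", "ND1", "rrnL", "rrnS"),
    length = c(1023L, 1531L, 688L, 162L, 678L, 789L, 354L,
               1741L, 1341L, 290L, 531L, 1149L, 937L, 1400L, 779L),
    strand = c("+", "+", "+", "+", "+", "+", "+",
               "-", "-", "-", "+", "+", "-", "-", "-"),
    stringsAsFactors = FALSE)
  start <- integer(nrow(genes))
  pos <- spacer
  for (i in seq_len(nrow(genes))) {
    start[i] <- pos
    pos <- pos + genes$length[i] + spacer
  }
  ann <- data.frame(gene = genes$gene, start = start, end = start + genes$length,
                    strand = genes$strand, unmapped = FALSE, stringsAsFactors = FALSE)
  total <- pos + control_region
  n_pos <- (pos + 200L):(pos + 204L)  # 5N origin spacer inside the control region
  list(length = total, annotations = ann, n_positions = n_pos)
}

## default species tree: branch lengths in expected substitutions per site,
## chosen so the realized pairwise identities land on the observed structure
## (armigera-zea ~97.24%, assulta vs armigera/zea ~94.8%, punctigera most
## divergent, intraspecific ~99.5%)
default_species_tree <- function(include_outgroup = FALSE) {
  n1 <- list(label = "n1", branch = 0.0122,
             children = list(list(label = "armigera", branch = 0.0113),
                             list(label = "zea", branch = 0.0113)))
  n2 <- list(label = "n2", branch = 0.004,
             children = list(n1, list(label = "assulta", branch = 0.0235)))
  n4 <- list(label = "n4", branch = 0.003,
             children = list(n2, list(label = "gelotopoeon", branch = 0.020)))
  kids <- list(n4, list(label = "punctigera", branch = 0.030))
  if (include_outgroup) kids <- c(kids, list(list(label = "outgroup", branch = 0.09)))
  list(label = "root", branch = 0, children = kids)
}

#' Fixture specification for a synthetic mitogenome panel
#'
#' @param seed integer seed.
#' @param n_per_species named integer vector: individuals per species.
#' @param intra_divergence expected substitutions/site between two
#'   conspecific individuals (default 0.005, i.e. ~99.5% identity).
#' @param include_outgroup add a deeply diverged outgroup taxon (for rooting
#'   topology checks).
#' @param tree species tree (nested list with `label`, `branch`, `children`);
#'   defaults to the packaged Helicoverpa tree.
#' @param template genome layout from [genome_template()].
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_per_species = c(punctigera = 2L, armigera = 2L, assulta = 2L,
                                           zea = 2L, gelotopoeon = 2L),
                         intra_divergence = 0.005,
                         include_outgroup = FALSE,
                         tree = default_species_tree(include_outgroup),
                         template = genome_template()) {
  if (intra_divergence < 0 || intra_divergence >= 1) stop("intra_divergence outside (0, 1)")
  structure(list(seed = seed, n_per_species = n_per_species,
                 intra_divergence = intra_divergence,
                 include_outgroup = include_outgroup, tree = tree,
                 template = template),
            class = "fixture_spec")
}

## expand species leaves into individual leaves
expand_individuals <- function(node, n_per_species, intra) {
  if (is.null(node$children)) {
    n <- if (node$label %in% names(n_per_species)) n_per_species[[node$label]] else 1L
    ids <- if (n == 1L) paste0(node$label, "_1") else paste0(node$label, "_", seq_len(n))
    node$children <- lapply(ids, function(id) list(label = id, branch = intra / 2, species = node$label))
    node$species <- node$label
  } else {
    node$children <- lapply(node$children, expand_individuals, n_per_species = n_per_species,
                            intra = intra)
  }
  node
}

#' Generate a synthetic annotated mitogenome panel
#'
#' Builds a seeded base mitogenome on the shared gene layout, then mutates it
#' along the species tree: each branch receives `round(branch_length *
#' n_mutable)` substitutions at globally disjoint positions (never inside the
#' 5N spacer), so realized pairwise divergences equal the tree's path lengths
#' up to rounding and the planted substitution counts are exact ground truth.
#'
#' @param spec a [fixture_spec()].
#' @return A list of annotated records (each with `record`, `annotations`,
#'   `species`), with attributes `expected_mismatches` (pairwise planted
#'   mismatch counts), `n_comparable` (identity denominator: genome length
#'   minus the N spacer) and `spec`.
#' @export
make_genome_panel <- function(spec = fixture_spec()) {
  tpl <- spec$template
  tree <- expand_individuals(spec$tree, spec$n_per_species, spec$intra_divergence)
  with_seed(spec$seed, {
    base <- strsplit(random_dna(tpl$length), "")[[1]]
    base[tpl$n_positions] <- "N"
    mutable <- setdiff(seq_len(tpl$length), tpl$n_positions)
    n_mut <- length(mutable)
    pool <- sample(mutable)
    cursor <- 0L
    take <- function(k) {
      if (cursor + k > length(pool)) stop("infeasible target set: mutation pool exhausted")
      out <- pool[(cursor + 1L):(cursor + k)]
      cursor <<- cursor + k
      out
    }
    leaves <- list()
    mut_sets <- list()
    walk <- function(node, seqv, muts) {
      k <- round(node$branch * n_mut)
      if (k > 0L) {
        at <- take(k)
        for (p in at) seqv[p] <- sample(setdiff(c("A", "C", "G", "T"), seqv[p]), 1L)
        muts <- c(muts, at)
      }
      if (is.null(node$children)) {
        leaves[[node$label]] <<- list(seq = seqv, species = node$species)
        mut_sets[[node$label]] <<- muts
      } else {
        for (ch in node$children) walk(ch, seqv, muts)
      }
    }
    walk(tree, base, integer(0))

    ids <- names(leaves)
    mism <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
    for (pair in combn(seq_along(ids), 2L, simplify = FALSE)) {
      i <- pair[1]; j <- pair[2]
      ## disjoint branch positions: pairwise mismatches = symmetric difference
      shared <- intersect(mut_sets[[ids[i]]], mut_sets[[ids[j]]])
      mism[i, j] <- mism[j, i] <- length(mut_sets[[ids[i]]]) + length(mut_sets[[ids[j]]]) -
        2L * length(shared)
    }
    panel <- lapply(ids, function(id) {
      list(record = seq_record(id, paste(leaves[[id]]$seq, collapse = ""),
                               description = sprintf("synthetic %s mitogenome", leaves[[id]]$species),
                               topology = "circular"),
           annotations = tpl$annotations,
           species = leaves[[id]]$species)
    })
    names(panel) <- ids
    attr(panel, "expected_mismatches") <- mism
    attr(panel, "n_comparable") <- n_mut
    attr(panel, "spec") <- spec
    panel
  })
}

#' Splice a donor segment into a backbone genome
#'
#' Replaces the backbone bases between `start` and `end` (1-based inclusive)
#' with the donor's homologous segment, emulating a chimeric assembly from
#' PCR contamination. Backbone and donor must come from the same panel
#' (equal-length, collinear), so the homologous segment shares coordinates.
#'
#' @param backbone,donor annotated records from [make_genome_panel()].
#' @param start,end splice interval, 1-based inclusive; `end < start` gives a
#'   zero-length splice (backbone unchanged).
#' @param id id for the chimera record.
#' @return An annotated record labelled with the *backbone* species, with
#'   attribute `truth` recording the splice coordinates and donor species.
#' @export
make_chimera <- function(backbone, donor, start, end,
                         id = paste0(backbone$record$id, "_chimera")) {
  n <- length(backbone$record)
  if (length(donor$record) != n) stop("backbone and donor must be from the same panel (equal length)")
  if (start < 1L || end > n) stop("splice interval outside [1, ", n, "]")
  s <- backbone$record$residues
  if (end >= start) {
    s <- paste0(substr(s, 1L, start - 1L), substr(donor$record$residues, start, end),
                substr(s, end + 1L, n))
  }
  rec <- seq_record(id, s, description = sprintf("synthetic chimera: %s backbone, %s segment %d-%d",
                                                 backbone$species, donor$species, start, end),
                    topology = "circular")
  out <- list(record = rec, annotations = backbone$annotations, species = backbone$species)
  attr(out, "truth") <- list(backbone = backbone$record$id, donor = donor$record$id,
                             donor_species = donor$species, start = as.integer(start),
                             end = as.integer(end))
  out
}

#' Write a panel to FASTA + GenBank + ground-truth TSV
#'
#' @param panel output of [make_genome_panel()] (or a list of annotated
#'   records).
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(lapply(panel, function(e) e$record), file.path(dir, "panel.fasta"))
  for (e in panel) {
    write_genbank(e$record, e$annotations, file.path(dir, paste0(e$record$id, ".gb")))
  }
  truth <- data.frame(id = vapply(panel, function(e) e$record$id, ""),
                      species = vapply(panel, function(e) e$species, ""),
                      length = vapply(panel, function(e) length(e$record), 0L),
                      stringsAsFactors = FALSE)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
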