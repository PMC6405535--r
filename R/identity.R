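## identity_qc: pairwise nucleotide identities (whole molecule and per gene)
## and the misidentification screen for assembled mitogenomes.
##
## Identity convention: matched columns / aligned columns, excluding columns
## where both sequences have a gap and columns where either sequence has an
## undetermined base (N and other ambiguity codes); gap-versus-base columns
## count as mismatches. The exclusion of N keeps low-complexity assembly
## spacers (the 5N origin-of-replication spacer in these mitogenomes) from
## depressing identity.

identity_from_alignment <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  both_gap <- ca == "-" & cb == "-"
  amb <- (!(ca %in% c("A", "C", "G", "T", "-"))) | (!(cb %in% c("A", "C", "G", "T", "-")))
  use <- !both_gap & !amb
  denom <- sum(use)
  if (denom == 0L) return(NA_real_)
  round(100 * sum(ca[use] == cb[use] & ca[use] != "-") / denom, 2)
}

## global affine alignment of two short sequences via Biostrings
align_global_full <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a), Biostrings::DNAString(b),
                                      type = "global", substitutionMatrix = mat,
                                      gapOpening = 2, gapExtension = 0.5)
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

#' Banded global alignment of two long sequences
#'
#' Affine-gap global alignment restricted to a diagonal band (automatically
#' widened by the length difference), scoring match +1, mismatch -1, gap open
#' -2, gap extend -0.5. Adequate for near-collinear molecules such as two
#' mitogenomes of the same genus; full dynamic programming (see
#' `Biostrings::pairwiseAlignment`) is the reference at small sizes.
#'
#' @param a,b DNA strings or [seq_record]s.
#' @param band band half-width in bp.
#' @return list with aligned strings `a`, `b` and the alignment `score`.
#' @export
align_banded <- function(a, b, band = 200L) {
  if (inherits(a, "seq_record")) a <- a$residues
  if (inherits(b, "seq_record")) b <- b$residues
  .banded_align_cpp(toupper(a), toupper(b), match = 1, mismatch = -1,
                    gap_open = 2, gap_ext = 0.5, band = as.integer(band))
}

#' Percent nucleotide identity of two sequences
#'
#' Aligns the two sequences globally (full dynamic programming up to
#' `full_dp_limit` bases, banded alignment beyond) and reports percent
#' identity to two decimals under the package's identity convention (see
#' above). Sequences whose lengths differ by more than a factor of two are
#' compared over their best local core instead, with a warning.
#'
#' @param a,b DNA strings or [seq_record]s.
#' @param method `"auto"` (default), `"full"`, or `"banded"`.
#' @param band band half-width for the banded aligner.
#' @param full_dp_limit maximum length for full dynamic programming under
#'   `method = "auto"`.
#' @return Percent identity in `[0, 100]`, rounded to 2 decimals.
#' @export
pairwise_identity <- function(a, b, method = c("auto", "full", "banded"),
                              band = 200L, full_dp_limit = 3000L) {
  method <- match.arg(method)
  if (inherits(a, "seq_record")) a <- a$residues
  if (inherits(b, "seq_record")) b <- b$residues
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  ratio <- max(nchar(a), nchar(b)) / min(nchar(a), nchar(b))
  if (ratio > 2) {
    warning("sequence lengths differ by more than 2x; using local-core identity")
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
    al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a), Biostrings::DNAString(b),
                                        type = "local", substitutionMatrix = mat,
                                        gapOpening = 2, gapExtension = 0.5)
    return(identity_from_alignment(as.character(Biostrings::alignedPattern(al)),
                                   as.character(Biostrings::alignedSubject(al))))
  }
  if (method == "auto") {
    method <- if (max(nchar(a), nchar(b)) <= full_dp_limit) "full" else "banded"
  }
  al <- if (method == "full") align_global_full(a, b) else align_banded(a, b, band = band)
  identity_from_alignment(al$a, al$b)
}

## extract one gene from an annotated record, in coding orientation
gene_sequence <- function(entry, gene) {
  ann <- entry$annotations
  i <- which(ann$gene == gene)
  if (length(i) == 0L) return(NULL)
  i <- i[1]
  s <- substr(entry$record$residues, ann$start[i] + 1L, ann$end[i])
  if (ann$strand[i] == "-") s <- revcomp(s)
  s
}

#' Per-gene pairwise identity matrices
#'
#' Extracts each requested gene from every annotated record (strand-aware,
#' coding orientation), aligns all pairs and reports one symmetric percent
#' identity matrix per gene. Records missing a gene get `NA` cells for it.
#'
#' @param entries list of annotated records: each element a list with
#'   `record` (a [seq_record]) and `annotations` (data.frame as produced by
#'   [read_genbank()] or the fixture generator).
#' @param gene_names genes to compare; defaults to the 13 protein-coding
#'   genes plus the two rRNAs.
#' @return Named list of matrices (class `identity_matrix`, `scope`
#'   attribute `gene:<name>`), labels taken from record ids.
#' @export
gene_identity_matrix <- function(entries, gene_names = GENE_VOCAB) {
  ids <- vapply(entries, function(e) e$record$id, "")
  if (anyDuplicated(ids)) stop("duplicate record ids in panel")
  out <- list()
  for (g in gene_names) {
    seqs <- lapply(entries, gene_sequence, gene = g)
    m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- ifelse(vapply(seqs, is.null, TRUE), NA_real_, 100)
    if (length(ids) >= 2L) {
      for (pair in combn(seq_along(ids), 2L, simplify = FALSE)) {
        i <- pair[1]; j <- pair[2]
        if (is.null(seqs[[i]]) || is.null(seqs[[j]])) next
        v <- pairwise_identity(seqs[[i]], seqs[[j]])
        m[i, j] <- m[j, i] <- v
      }
    }
    attr(m, "scope") <- paste0("gene:", g)
    class(m) <- c("identity_matrix", class(m))
    out[[g]] <- m
  }
  out
}

#' Whole-molecule identity matrix for a panel of records
#'
#' @param entries list of annotated records (or bare [seq_record]s wrapped in
#'   lists); whole-molecule identities are computed with the banded aligner.
#' @return A symmetric percent-identity matrix (class `identity_matrix`,
#'   scope `whole`).
#' @export
whole_identity_matrix <- function(entries) {
  ids <- vapply(entries, function(e) e$record$id, "")
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  if (length(ids) >= 2L) {
    for (pair in combn(seq_along(ids), 2L, simplify = FALSE)) {
      i <- pair[1]; j <- pair[2]
      v <- pairwise_identity(entries[[i]]$record, entries[[j]]$record, method = "banded")
      m[i, j] <- m[j, i] <- v
    }
  }
  attr(m, "scope") <- "whole"
  class(m) <- c("identity_matrix", class(m))
  m
}

#' Screen a mitogenome for species misidentification
#'
#' Compares a labelled query mitogenome against a reference panel with at
#' least one mitogenome per candidate species. The verdict logic follows the
#' identity structure of these moths: conspecific mitogenomes are >= ~99%
#' identical while even the closest species pair sits near 97%, so a query
#' whose best interspecific identity beats its own label by a clear margin is
#' called misidentified. A query whose genes split between species (some
#' genes best-matching the label, a contiguous block best-matching another
#' species) is flagged as a chimera suspect and handed to the chimera
#' scanner.
#'
#' @param query annotated record: list with `record`, `annotations`, and
#'   `species` (the label under scrutiny).
#' @param references list of annotated records, each with a `species` label;
#'   at least one per candidate species.
#' @param thresholds list with `conspecific_floor` (minimum identity to call
#'   a conspecific, default 98.0), `margin` (percentage points by which the
#'   best species must beat the label, default 2.0) and `min_genes` (genes
#'   per species needed to call a chimera suspect, default 2).
#' @param gene_names genes used for the per-gene screen.
#' @return An object of class `misid_report`.
#' @export
misid_screen <- function(query, references,
                         thresholds = list(conspecific_floor = 98.0, margin = 2.0, min_genes = 2L),
                         gene_names = GENE_VOCAB) {
  if (length(references) == 0L) stop("empty reference panel")
  ref_species <- vapply(references, function(r) r$species, "")
  label <- query$species
  if (!label %in% ref_species) {
    stop("no reference for labelled species '", label, "'")
  }
  floor_ <- thresholds$conspecific_floor %||% 98.0
  margin <- thresholds$margin %||% 2.0
  min_genes <- thresholds$min_genes %||% 2L

  whole <- vapply(references, function(r) {
    pairwise_identity(query$record, r$record, method = "banded")
  }, 0)
  names(whole) <- vapply(references, function(r) r$record$id, "")
  by_species <- tapply(whole, ref_species, max)
  best_species <- names(by_species)[which.max(by_species)]
  identity_to_best <- unname(max(by_species))
  identity_to_label <- unname(by_species[[label]])

  ## per-gene best species (bimodality = chimera suspect)
  gene_best <- data.frame(gene = character(), best_species = character(),
                          identity = numeric(), stringsAsFactors = FALSE)
  for (g in gene_names) {
    qs <- gene_sequence(query, g)
    if (is.null(qs)) next
    per_sp <- rep(NA_real_, length(unique(ref_species)))
    names(per_sp) <- unique(ref_species)
    for (sp in unique(ref_species)) {
      vals <- vapply(references[ref_species == sp], function(r) {
        rs <- gene_sequence(r, g)
        if (is.null(rs)) NA_real_ else pairwise_identity(qs, rs)
      }, 0)
      per_sp[sp] <- suppressWarnings(max(vals, na.rm = TRUE))
    }
    per_sp <- per_sp[is.finite(per_sp)]
    if (!length(per_sp)) next
    gene_best <- rbind(gene_best, data.frame(
      gene = g, best_species = names(per_sp)[which.max(per_sp)],
      identity = unname(max(per_sp)), stringsAsFactors = FALSE))
  }
  tab <- table(gene_best$best_species)
  bimodal <- sum(tab >= min_genes) >= 2L

  verdict <- if (bimodal) {
    "chimeric_suspect"
  } else if (best_species != label &&
             identity_to_best - identity_to_label >= margin &&
             identity_to_best >= floor_) {
    "misidentified"
  } else if (best_species == label) {
    "consistent"
  } else {
    "inconclusive"
  }
  structure(list(query_id = query$record$id, labeled_species = label,
                 best_species = best_species,
                 identity_to_label = identity_to_label,
                 identity_to_best = identity_to_best,
                 verdict = verdict, whole_identities = whole,
                 gene_best = gene_best, thresholds = thresholds),
            class = "misid_report")
}

#' @export
print.misid_report <- function(x, ...) {
  cat(sprintf("<misid_report> %s (labelled %s): %s\n", x$query_id, x$labeled_species, x$verdict))
  cat(sprintf("  identity to label %.2f%%, to best (%s) %.2f%%\n",
              x$identity_to_label, x$best_species, x$identity_to_best))
  if (nrow(x$gene_best)) {
    splits <- split(x$gene_best$gene, x$gene_best$best_species)
    for (sp in names(splits)) {
      cat(sprintf("  genes best-matching %s: %s\n", sp, paste(splits[[sp]], collapse = ", ")))
    }
  }
  invisible(x)
}
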