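## core_io: sequence records, FASTA/GenBank input/output, coordinate
## conventions and IUPAC logic shared by every other module.
##
## Internal coordinates are 0-based half-open throughout; everything printed
## for the user (reports, fragment spans, breakpoints) is 1-based inclusive.

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N", "-" = "-")

#' Create a sequence record
#'
#' The basic container used throughout the package: an identifier, optional
#' description, an uppercase IUPAC DNA string and a topology flag. Amplicons
#' are linear; assembled mitogenomes are circular (but all fragment and
#' identity arithmetic operates on the linearized representation as
#' deposited).
#'
#' @param id record identifier (unique within a collection).
#' @param residues DNA string over the IUPAC alphabet; coerced to upper case.
#' @param description free-text description.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, description = "", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("record '", id, "': residues must be non-empty")
  bad <- gregexpr(sprintf("[^%s-]", paste(names(IUPAC_BITS), collapse = "")), residues)[[1]]
  if (bad[1] != -1L) {
    stop("record '", id, "': non-IUPAC character '",
         substr(residues, bad[1], bad[1]), "' at position ", bad[1])
  }
  structure(list(id = as.character(id), description = as.character(description),
                 residues = residues, topology = topology),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%s, %d bp)\n", x$id, x$topology, nchar(x$residues)))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$residues)

#' Reverse complement of an IUPAC DNA string
#'
#' Handles all ambiguity codes and gaps; an involution by construction.
#'
#' @param x a DNA character scalar.
#' @return The reverse complement character scalar.
#' @export
revcomp <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Convert 1-based inclusive coordinates to 0-based half-open (and back)
#'
#' All internal arithmetic uses 0-based half-open intervals; user-facing
#' tables use 1-based inclusive positions. These two helpers are mutual
#' inverses.
#'
#' @param start,end interval bounds in the source convention.
#' @return A list with `start` and `end` in the target convention.
#' @export
to_zero_based <- function(start, end) list(start = start - 1L, end = end)

#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) list(start = start + 1L, end = end)

#' Read sequences from a FASTA file
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @param topology topology recorded on each record.
#' @return A list of [seq_record] objects, names set to record ids.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  desc <- sub("^\\S+\\s*", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate record id in ", path, ": ", ids[duplicated(ids)][1])
  recs <- lapply(seq_along(set), function(i) {
    seq_record(ids[i], as.character(set[[i]]), description = desc[i], topology = topology)
  })
  setNames(recs, ids)
}

#' Write sequence records to a FASTA file
#'
#' @param records a list of [seq_record] objects.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", header), con)
    s <- r$residues
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## ---- gene-name normalization -------------------------------------------

GENE_ALIASES <- c(
  "COX1" = "COI",  "CO1" = "COI",  "COI" = "COI",
  "COX2" = "COII", "CO2" = "COII", "COII" = "COII",
  "COX3" = "COIII", "CO3" = "COIII", "COIII" = "COIII",
  "CYTB" = "COB", "COB" = "COB", "CYB" = "COB",
  "NAD1" = "ND1", "ND1" = "ND1", "NAD2" = "ND2", "ND2" = "ND2",
  "NAD3" = "ND3", "ND3" = "ND3", "NAD4" = "ND4", "ND4" = "ND4",
  "NAD4L" = "ND4L", "ND4L" = "ND4L", "NAD5" = "ND5", "ND5" = "ND5",
  "NAD6" = "ND6", "ND6" = "ND6",
  "ATP6" = "ATP6", "ATP8" = "ATP8",
  "16S" = "rrnL", "RRNL" = "rrnL", "L-RRNA" = "rrnL", "LRRNA" = "rrnL",
  "12S" = "rrnS", "RRNS" = "rrnS", "S-RRNA" = "rrnS", "SRRNA" = "rrnS"
)

#' Normalize a mitochondrial gene name to the controlled vocabulary
#'
#' Maps common aliases (Cytb/cob to COB, 16S to rrnL, 12S to rrnS, COX1 to
#' COI, nad2 to ND2, ...). tRNA names are passed through with a `tRNA-`
#' prefix. Unmappable names are returned verbatim with attribute
#' `unmapped = TRUE`.
#'
#' @param name a gene name as found in an annotation.
#' @return The normalized name (character scalar).
#' @export
normalize_gene_name <- function(name) {
  key <- toupper(trimws(name))
  if (grepl("^TRN", key) || grepl("^TRNA", key)) {
    return(paste0("tRNA-", sub("^TRNA?-?", "", name)))
  }
  if (key %in% names(GENE_ALIASES)) return(unname(GENE_ALIASES[key]))
  structure(name, unmapped = TRUE)
}

## ---- GenBank flat files --------------------------------------------------
## Minimal reader/writer for LOCUS/FEATURES/ORIGIN flat files carrying CDS,
## rRNA and tRNA features with /gene qualifiers and complement() locations.
## Only the subset needed to carry gene coordinates; no installed package
## parses local GenBank flat files.

parse_gb_location <- function(loc) {
  strand <- if (grepl("^complement", loc)) "-" else "+"
  nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) < 2L) stop("cannot parse feature location: ", loc)
  ## GenBank is 1-based inclusive -> 0-based half-open
  list(start = nums[1] - 1L, end = nums[length(nums)], strand = strand)
}

#' Read a GenBank flat file
#'
#' Parses the sequence plus CDS/rRNA/tRNA features into a gene-annotation
#' table. Gene names are normalized to the controlled vocabulary
#' (Cytb = COB, 16S = rrnL, 12S = rrnS); unmappable names are retained
#' verbatim and flagged. Coordinates are converted from GenBank 1-based
#' inclusive to internal 0-based half-open.
#'
#' @param path path to a GenBank flat file.
#' @return A list with `record` (a [seq_record], topology circular if the
#'   LOCUS line says so) and `annotations` (data.frame with columns `gene`,
#'   `start`, `end`, `strand`, `unmapped`).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1] else basename(path)
  topology <- if (length(locus) && grepl("circular", locus[1], ignore.case = TRUE)) "circular" else "linear"

  ## sequence: between ORIGIN and //
  o <- grep("^ORIGIN", lines)
  if (!length(o)) stop(path, ": no ORIGIN section")
  endl <- grep("^//", lines)
  endl <- endl[endl > o[1]][1]
  seqlines <- lines[(o[1] + 1L):(endl - 1L)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))

  ## features
  f <- grep("^FEATURES", lines)
  ann <- data.frame(gene = character(), start = integer(), end = integer(),
                    strand = character(), unmapped = logical(),
                    stringsAsFactors = FALSE)
  if (length(f)) {
    block <- lines[(f[1] + 1L):(o[1] - 1L)]
    keyidx <- grep("^ {5}\\S", block)
    for (k in seq_along(keyidx)) {
      i0 <- keyidx[k]
      i1 <- if (k < length(keyidx)) keyidx[k + 1] - 1L else length(block)
      key <- trimws(substr(block[i0], 1, 21))
      if (!key %in% c("CDS", "rRNA", "tRNA", "gene")) next
      if (key == "gene") next  # gene features duplicate CDS/rRNA/tRNA here
      loc <- trimws(substr(block[i0], 22, nchar(block[i0])))
      quals <- block[(i0 + 1L):i1]
      gq <- grep('/(gene|product)=', quals, value = TRUE)
      gname <- if (length(gq)) gsub('.*="?([^"]*)"?.*', "\\1", gq[1]) else key
      locp <- parse_gb_location(loc)
      norm <- normalize_gene_name(gname)
      ann <- rbind(ann, data.frame(gene = as.character(norm),
                                   start = locp$start, end = locp$end,
                                   strand = locp$strand,
                                   unmapped = isTRUE(attr(norm, "unmapped")),
                                   stringsAsFactors = FALSE))
    }
  }
  if (nrow(ann) == 0L) warning(path, ": no CDS/rRNA/tRNA features found")
  rec <- seq_record(id, residues, topology = topology)
  n <- length(rec)
  if (nrow(ann) && any(ann$start < 0L | ann$end > n | ann$start >= ann$end)) {
    stop(path, ": feature coordinates outside [1, ", n, "]")
  }
  list(record = rec, annotations = ann)
}

#' Write a GenBank flat file
#'
#' Counterpart of [read_genbank()]; used by the synthetic-fixture generator
#' so annotated genomes round-trip through the standard flat-file format.
#'
#' @param record a [seq_record].
#' @param annotations data.frame with `gene`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @param path output path.
#' @export
write_genbank <- function(record, annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(record)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNK",
                     record$id, n, record$topology), con)
  writeLines(sprintf("DEFINITION  %s", if (nzchar(record$description)) record$description else record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  if (nrow(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      a <- annotations[i, ]
      key <- if (a$gene %in% RRNA_NAMES) "rRNA" else if (grepl("^tRNA", a$gene)) "tRNA" else "CDS"
      span <- sprintf("%d..%d", a$start + 1L, a$end)
      if (a$strand == "-") span <- sprintf("complement(%s)", span)
      writeLines(sprintf("     %-15s %s", key, span), con)
      writeLines(sprintf('                     /gene="%s"', a$gene), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$residues)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

## ---- regions -------------------------------------------------------------

#' Define a diagnostic amplicon region
#'
#' A region is the unit the PCR-RFLP key operates on: a name, an expected
#' amplicon length (698 bp for the 5' COI region, 511 bp for the 3' COI
#' region) and one reference amplicon per species used to locate the region
#' in longer sequences by local alignment.
#'
#' @param name region name, `"coi5p_698"` or `"coi3p_511"` for the packaged key.
#' @param reference_amplicons named character vector of per-species reference
#'   amplicon sequences (each of the expected length).
#' @param expected_length expected amplicon length in bp.
#' @return An object of class `region_def`.
#' @export
region_def <- function(name, reference_amplicons, expected_length) {
  if (any(nchar(reference_amplicons) != expected_length)) {
    stop("region '", name, "': reference amplicon length != expected_length")
  }
  structure(list(name = name, reference_amplicons = toupper(reference_amplicons),
                 expected_length = as.integer(expected_length)),
            class = "region_def")
}

#' Load the packaged diagnostic regions
#'
#' Reads the packaged regions config (name, expected length, reference FASTA)
#' and returns the two COI regions of the consolidated key with synthetic
#' per-species reference amplicons.
#'
#' @param config path to a regions config file (key=value text); defaults to
#'   the packaged one.
#' @return A named list of [region_def] objects.
#' @export
load_regions <- function(config = system.file("extdata", "regions.conf", package = "mitokey")) {
  lines <- grep("^\\s*(#|$)", readLines(config), invert = TRUE, value = TRUE)
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "\t")[[1]]
    if (length(kv) != 3L) stop("malformed regions config line: ", ln)
    name <- kv[1]; len <- as.integer(kv[2]); fa <- kv[3]
    if (!file.exists(fa)) fa <- file.path(dirname(config), fa)
    refs <- read_fasta(fa)
    refs <- refs[grep(paste0("_", name, "$"), names(refs))]
    amps <- setNames(vapply(refs, function(r) r$residues, ""),
                     sub(paste0("_", name, "$"), "", names(refs)))
    out[[name]] <- region_def(name, amps, len)
  }
  out
}

#' Extract a diagnostic region from a longer sequence
#'
#' Locates the best local alignment of any of the region's reference
#' amplicons in the record and returns the matching subsequence. Intended for
#' pulling the 698 bp / 511 bp COI fragments out of assembled mitogenomes.
#'
#' @param record a [seq_record].
#' @param region a [region_def].
#' @param min_identity minimum local-alignment identity (fraction) below
#'   which the region is declared not found.
#' @return The extracted DNA string, with attributes `start`/`end` (1-based
#'   inclusive coordinates on the record) and `matched_reference`.
#' @export
extract_region <- function(record, region, min_identity = 0.80) {
  stopifnot(inherits(record, "seq_record"), inherits(region, "region_def"))
  subject <- Biostrings::DNAString(gsub("[^ACGT]", "N", record$residues))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
  best <- NULL
  best_score <- -Inf
  best_ref <- NA_character_
  for (sp in names(region$reference_amplicons)) {
    pat <- Biostrings::DNAString(region$reference_amplicons[[sp]])
    al <- Biostrings::pairwiseAlignment(pat, subject, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 4, gapExtension = 1)
    if (Biostrings::score(al) > best_score) {
      best_score <- Biostrings::score(al)
      best <- al
      best_ref <- sp
    }
  }
  pid <- Biostrings::pid(best) / 100
  coverage <- Biostrings::width(best@pattern@range) / region$expected_length
  if (pid < min_identity || coverage < 0.8) {
    stop("region '", region$name, "' not found in record '", record$id,
         "' (best local hit: ", sprintf("%.1f%% identity over %.0f%% of the reference",
                                        100 * pid, 100 * coverage), ")")
  }
  sub_range <- best@subject@range
  out <- substr(record$residues, Biostrings::start(sub_range), Biostrings::end(sub_range))
  if (abs(nchar(out) - region$expected_length) > 5L) {
    stop("region '", region$name, "': extracted segment length ", nchar(out),
         " deviates from expected ", region$expected_length, " by more than 5 bp")
  }
  structure(out, start = Biostrings::start(sub_range), end = Biostrings::end(sub_range),
            matched_reference = best_ref)
}
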