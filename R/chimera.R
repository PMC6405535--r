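## chimera_scan: localize chimeric segments in a query mitogenome by
## assigning diagnostic SNPs to donor species and segmenting the resulting
## donor track. This is the computational form of reading a SNP alignment
## table by eye: find the sites where the two candidate donors differ, ask
## which donor the query matches at each, and call maximal runs.

#' Build a SNP matrix from aligned sequences
#'
#' Retains only the columns where at least one individual differs from the
#' reference (the first individual unless `reference_id` is given), the
#' construction behind published SNP alignment tables.
#'
#' @param aligned named character vector (or named list) of equal-length
#'   aligned sequences; gaps as `-`.
#' @param reference_id id of the reference individual; defaults to the first.
#' @param region_name label for the region the alignment covers.
#' @return An object of class `snp_matrix`: `positions` (1-based alignment
#'   columns), `individuals`, `alleles` (individuals x positions character
#'   matrix, fully expanded), `reference`.
#' @export
build_snp_matrix <- function(aligned, reference_id = NULL, region_name = "region") {
  aligned <- vapply(aligned, function(x) {
    toupper(if (inherits(x, "seq_record")) x$residues else as.character(x))
  }, "")
  if (is.null(names(aligned)) || any(!nzchar(names(aligned)))) {
    stop("aligned sequences must be named by individual id")
  }
  if (length(unique(nchar(aligned))) != 1L) stop("aligned sequences must have equal length")
  reference_id <- reference_id %||% names(aligned)[1]
  if (!reference_id %in% names(aligned)) stop("reference '", reference_id, "' not in alignment")
  aligned <- c(aligned[reference_id], aligned[setdiff(names(aligned), reference_id)])
  chars <- do.call(rbind, strsplit(aligned, ""))
  rownames(chars) <- names(aligned)
  variable <- which(colSums(chars != chars[rep(1L, nrow(chars)), , drop = FALSE]) > 0L)
  new_snp_matrix(region_name, variable, names(aligned),
                 chars[, variable, drop = FALSE])
}

new_snp_matrix <- function(region_name, positions, individuals, alleles) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE)) stop("positions must be strictly increasing")
  alleles <- matrix(as.character(alleles), nrow = length(individuals),
                    dimnames = list(individuals, positions))
  ok <- alleles %in% c("A", "C", "G", "T", "-")
  if (!all(ok)) stop("invalid allele value(s): ", paste(unique(alleles[!ok]), collapse = ", "))
  structure(list(region_name = region_name, positions = positions,
                 individuals = individuals, alleles = alleles,
                 reference = individuals[1]),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %s: %d sites x %d individuals (reference %s)\n",
              x$region_name, length(x$positions), length(x$individuals), x$reference))
  invisible(x)
}

#' Read a SNP matrix from a delimited file
#'
#' Expects a TSV with a `position` column followed by one column per
#' individual; `.` means "same as the reference" (the first individual
#' column) and `-` is an alignment gap. This is the file form of a published
#' SNP alignment table.
#'
#' @param path path to the TSV.
#' @param region_name label; defaults to the file name.
#' @return An object of class `snp_matrix` (alleles fully expanded).
#' @export
read_snp_matrix <- function(path, region_name = NULL) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "position") stop("first column must be 'position'")
  positions <- as.integer(df$position)
  individuals <- names(df)[-1]
  alleles <- t(as.matrix(df[, -1, drop = FALSE]))
  alleles <- toupper(alleles)
  ## expand the '.' convention against the reference row
  ref <- alleles[1, ]
  if (any(ref == ".")) stop("reference row (first individual) may not contain '.'")
  for (i in seq_len(nrow(alleles))) {
    dots <- alleles[i, ] == "."
    alleles[i, dots] <- ref[dots]
  }
  new_snp_matrix(region_name %||% sub("\\.[^.]*$", "", basename(path)),
                 positions, individuals, alleles)
}

#' Write a SNP matrix using the `.` convention
#'
#' @param m a `snp_matrix`.
#' @param path output path.
#' @export
write_snp_matrix <- function(m, path) {
  enc <- m$alleles
  ref <- enc[1, ]
  for (i in seq_len(nrow(enc))[-1]) {
    same <- enc[i, ] == ref
    enc[i, same] <- "."
  }
  df <- data.frame(position = m$positions, t(enc), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign each diagnostic SNP of a query to a donor species
#'
#' A site is diagnostic when the donor-A consensus differs from the donor-B
#' consensus; consensus requires unanimity within a donor set (sites with
#' intra-donor variation are demoted to uninformative). At each diagnostic
#' site the query is called `A_donor` or `B_donor` when it matches the
#' respective consensus, and `neither` when it carries a private allele.
#'
#' @param m a `snp_matrix`.
#' @param donor_a_ids,donor_b_ids individual ids of the two donor sets.
#' @param query_id id of the query individual.
#' @return An object of class `donor_track`: `positions` and `calls` (one of
#'   `A_donor`, `B_donor`, `neither`, `uninformative` per position).
#' @export
assign_donors <- function(m, donor_a_ids, donor_b_ids, query_id) {
  ids <- c(donor_a_ids, donor_b_ids, query_id)
  missing_ids <- setdiff(ids, m$individuals)
  if (length(missing_ids)) stop("not in matrix: ", paste(missing_ids, collapse = ", "))
  consensus <- function(rows) {
    apply(m$alleles[rows, , drop = FALSE], 2, function(col) {
      u <- unique(col)
      if (length(u) == 1L) u else NA_character_
    })
  }
  cons_a <- consensus(donor_a_ids)
  cons_b <- consensus(donor_b_ids)
  q <- m$alleles[query_id, ]
  diagnostic <- !is.na(cons_a) & !is.na(cons_b) & cons_a != cons_b
  calls <- rep("uninformative", length(m$positions))
  calls[diagnostic & q == cons_a] <- "A_donor"
  calls[diagnostic & q == cons_b] <- "B_donor"
  calls[diagnostic & q != cons_a & q != cons_b] <- "neither"
  if (!any(diagnostic)) warning("no diagnostic sites between the donor sets")
  structure(list(positions = m$positions, calls = calls, query_id = query_id,
                 region_name = m$region_name),
            class = "donor_track")
}

#' @export
print.donor_track <- function(x, ...) {
  cat(sprintf("<donor_track> %s, query %s: %d sites (%d A, %d B, %d neither, %d uninformative)\n",
              x$region_name, x$query_id, length(x$calls),
              sum(x$calls == "A_donor"), sum(x$calls == "B_donor"),
              sum(x$calls == "neither"), sum(x$calls == "uninformative")))
  invisible(x)
}

#' Segment a donor track into chimeric segments
#'
#' Reports maximal runs of at least `min_run` consecutive same-donor calls.
#' `neither` (private-allele) and `uninformative` sites are skipped without
#' breaking a run; a call for the opposite donor breaks it. The breakpoint
#' interval before each segment spans from the last site of the previous
#' reported segment to the first site of this one -- the resolution limit the
#' diagnostic-site spacing imposes on the true splice point.
#'
#' @param track a `donor_track`.
#' @param min_run minimum number of supporting sites per segment (default 3:
#'   one or two matching sites are within reach of homoplasy or private
#'   variation, three consecutive sites are not, at these divergences).
#' @return data.frame (class `chimera_segments`) with columns `donor`,
#'   `first_site`, `last_site`, `n_support_sites`, `bp_before_left`,
#'   `bp_before_right`.
#' @export
segment_track <- function(track, min_run = 3L) {
  keep <- track$calls %in% c("A_donor", "B_donor")
  pos <- track$positions[keep]
  calls <- substr(track$calls[keep], 1, 1)
  empty <- data.frame(donor = character(), first_site = integer(), last_site = integer(),
                      n_support_sites = integer(), bp_before_left = integer(),
                      bp_before_right = integer(), stringsAsFactors = FALSE)
  if (length(pos) == 0L) {
    return(structure(empty, class = c("chimera_segments", "data.frame")))
  }
  r <- rle(calls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_run <- r$lengths >= min_run
  seg <- data.frame(donor = r$values[keep_run],
                    first_site = pos[starts[keep_run]],
                    last_site = pos[ends[keep_run]],
                    n_support_sites = r$lengths[keep_run],
                    stringsAsFactors = FALSE)
  seg$bp_before_left <- c(NA_integer_, head(seg$last_site, -1L))
  seg$bp_before_right <- ifelse(is.na(seg$bp_before_left), NA_integer_, seg$first_site)
  structure(seg, class = c("chimera_segments", "data.frame"))
}

## project aligned donor bases onto query coordinates: returns a string of
## length nchar(query) giving, per query base, the aligned donor character
project_onto_query <- function(query_aln, donor_aln) {
  qa <- strsplit(query_aln, "")[[1]]
  da <- strsplit(donor_aln, "")[[1]]
  paste(da[qa != "-"], collapse = "")
}

#' Scan a genome for chimeric segments against two donor panels
#'
#' Full pipeline: align each donor to the query (banded global alignment),
#' build the SNP matrix in query coordinates, assign donors at diagnostic
#' sites and segment the track. Coordinates in the output are 1-based
#' positions on the query; a per-gene donor summary reports which annotated
#' genes fall inside which donor segment.
#'
#' @param query annotated record (list with `record`, `annotations`).
#' @param donors_a,donors_b lists of annotated records for the two candidate
#'   donor species (A = the labelled species, B = the suspected contaminant).
#' @param min_run see [segment_track()].
#' @param band band half-width for the aligner.
#' @return A `chimera_segments` data.frame with a `genes` list-column and
#'   attributes `track` (the donor track) and `gene_summary`.
#' @export
scan_genome <- function(query, donors_a, donors_b, min_run = 3L, band = 200L) {
  a_ids <- vapply(donors_a, function(d) d$record$id, "")
  b_ids <- vapply(donors_b, function(d) d$record$id, "")
  seqs <- c(setNames(list(query$record$residues), query$record$id))
  for (d in c(donors_a, donors_b)) {
    al <- align_banded(query$record, d$record, band = band)
    if (!nzchar(al$a)) stop("alignment failure against ", d$record$id)
    seqs[[d$record$id]] <- project_onto_query(al$a, al$b)
  }
  m <- build_snp_matrix(unlist(seqs), reference_id = query$record$id,
                        region_name = query$record$id)
  track <- assign_donors(m, a_ids, b_ids, query$record$id)
  seg <- segment_track(track, min_run = min_run)
  ann <- query$annotations
  seg$genes <- lapply(seq_len(nrow(seg)), function(i) {
    ann$gene[ann$start + 1L <= seg$last_site[i] & ann$end >= seg$first_site[i]]
  })
  gene_summary <- if (nrow(seg)) {
    do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      if (!length(seg$genes[[i]])) return(NULL)
      data.frame(gene = seg$genes[[i]], donor = seg$donor[i], stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene = character(), donor = character(), stringsAsFactors = FALSE)
  }
  attr(seg, "track") <- track
  attr(seg, "gene_summary") <- gene_summary
  seg
}
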