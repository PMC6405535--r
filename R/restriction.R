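## restriction_digest: restriction-enzyme models, degenerate site scanning on
## both strands, and in-silico digestion of linear (or circular) DNA.
##
## Cut coordinates are top-strand only: a cut at coordinate c means c bases
## lie 5' of the cut, so fragment lengths are consecutive differences of the
## sorted cut coordinates augmented with {0, length}. This single-number
## arithmetic is what gel-predicted RFLP patterns tabulate (sticky-end
## overhangs are not modelled).

#' Construct a restriction enzyme
#'
#' @param name enzyme name (unique within a panel).
#' @param recognition IUPAC recognition sequence (length >= 4; ambiguity
#'   codes allowed).
#' @param cut_top top-strand cut coordinate relative to the first base of the
#'   recognition site (number of bases of the site/downstream region 5' of
#'   the cut; may exceed the site length for downstream cutters).
#' @param cut_bottom bottom-strand cut coordinate in the same frame; defaults
#'   to `length(recognition) - cut_top` (symmetric cutter).
#' @return An object of class `rfl_enzyme`.
#' @export
enzyme <- function(name, recognition, cut_top, cut_bottom = NULL) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) stop("enzyme ", name, ": recognition site shorter than 4 bp")
  if (!grepl(sprintf("^[%s]+$", paste(names(IUPAC_BITS), collapse = "")), recognition)) {
    stop("enzyme ", name, ": recognition contains non-IUPAC characters")
  }
  if (is.null(cut_bottom)) cut_bottom <- nchar(recognition) - cut_top
  structure(list(name = name, recognition = recognition,
                 cut_top = as.integer(cut_top), cut_bottom = as.integer(cut_bottom),
                 palindromic = identical(recognition, revcomp(recognition))),
            class = "rfl_enzyme")
}

#' @export
print.rfl_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s  %s  cut %d/%d%s\n", x$name, x$recognition,
              x$cut_top, x$cut_bottom, if (x$palindromic) " (palindromic)" else ""))
  invisible(x)
}

## Vectorized degenerate motif matcher over IUPAC bitmasks.
## Strict semantics: ambiguity codes in the *pattern* expand; any non-ACGT
## character in the subject (N and friends) never satisfies a site, so
## low-complexity N-spacers cannot produce phantom cuts.
## Returns 0-based match start positions.
match_iupac <- function(sequence, pattern, strict = TRUE) {
  n <- nchar(sequence)
  L <- nchar(pattern)
  if (n < L) return(integer(0))
  sub_chars <- strsplit(sequence, "")[[1]]
  sub_bits <- unname(IUPAC_BITS[sub_chars])
  if (strict) {
    sub_bits[!(sub_bits %in% c(1L, 2L, 4L, 8L)) | is.na(sub_bits)] <- 16L
  } else {
    sub_bits[is.na(sub_bits)] <- 16L
  }
  pat_bits <- unname(IUPAC_BITS[strsplit(pattern, "")[[1]]])
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    b <- sub_bits[j:(j + n - L)]
    ok <- ok & (bitwAnd(pat_bits[j], b) == b)
  }
  which(ok) - 1L
}

#' Scan a sequence for restriction sites on both strands
#'
#' Finds every top-strand match of the recognition pattern and, for
#' non-palindromic enzymes, every bottom-strand match (cut coordinate
#' transformed into top-strand space). Ambiguity codes in the recognition
#' sequence match their IUPAC expansion; ambiguity codes in the subject never
#' match (strict mode, default). Cuts falling at or beyond the sequence ends
#' are dropped.
#'
#' @param sequence a DNA string or [seq_record].
#' @param enz an [enzyme()].
#' @param strict if `TRUE` (default), non-ACGT subject characters never match.
#' @return data.frame with columns `position` (top-strand cut coordinate:
#'   bases 5' of the cut), `enzyme`, `strand`, `site_start`, `site_end`
#'   (1-based inclusive site location).
#' @export
scan_sites <- function(sequence, enz, strict = TRUE) {
  if (inherits(sequence, "seq_record")) sequence <- sequence$residues
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  L <- nchar(enz$recognition)
  out <- data.frame(position = integer(), enzyme = character(), strand = character(),
                    site_start = integer(), site_end = integer(), stringsAsFactors = FALSE)
  s_top <- match_iupac(sequence, enz$recognition, strict = strict)
  if (length(s_top)) {
    out <- rbind(out, data.frame(position = s_top + enz$cut_top, enzyme = enz$name,
                                 strand = "+", site_start = s_top + 1L,
                                 site_end = s_top + L, stringsAsFactors = FALSE))
  }
  if (!enz$palindromic) {
    s_bot <- match_iupac(sequence, revcomp(enz$recognition), strict = strict)
    if (length(s_bot)) {
      out <- rbind(out, data.frame(position = s_bot + L - enz$cut_bottom, enzyme = enz$name,
                                   strand = "-", site_start = s_bot + 1L,
                                   site_end = s_bot + L, stringsAsFactors = FALSE))
    }
  }
  out <- out[out$position > 0L & out$position < n, , drop = FALSE]
  out[order(out$position), , drop = FALSE]
}

#' Digest a sequence with one enzyme
#'
#' Fragment lengths are consecutive differences of the sorted unique
#' top-strand cut coordinates augmented with the sequence ends; an uncut
#' sequence yields a single full-length fragment. For circular molecules
#' fragments run between consecutive cuts around the circle (sites spanning
#' the origin are found by scanning the doubled sequence).
#'
#' @param sequence DNA string or [seq_record]; a circular [seq_record] is
#'   digested circularly unless `circular` is given.
#' @param enz an [enzyme()].
#' @param circular override topology.
#' @param strict see [scan_sites()].
#' @return An object of class `digest_pattern`: enzyme name, amplicon length,
#'   ordered 5'->3' fragment lengths and cut coordinates.
#' @export
digest <- function(sequence, enz, circular = NULL, strict = TRUE) {
  if (inherits(sequence, "seq_record")) {
    if (is.null(circular)) circular <- sequence$topology == "circular"
    sequence <- sequence$residues
  }
  circular <- isTRUE(circular)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (!circular) {
    cuts <- sort(unique(scan_sites(sequence, enz, strict = strict)$position))
    fragments <- diff(c(0L, cuts, n))
  } else {
    doubled <- paste0(sequence, sequence)
    sites <- scan_sites(doubled, enz, strict = strict)
    sites <- sites[sites$site_start <= n, , drop = FALSE]
    cuts <- sort(unique(((sites$position - 1L) %% n) + 1L))
    cuts <- cuts[cuts > 0L & cuts <= n]
    fragments <- if (length(cuts) == 0L) n else if (length(cuts) == 1L) n else {
      c(diff(cuts), n - cuts[length(cuts)] + cuts[1])
    }
  }
  structure(list(enzyme_name = enz$name, amplicon_length = n,
                 fragments = as.integer(fragments), cut_positions = as.integer(cuts),
                 circular = circular),
            class = "digest_pattern")
}

#' @export
print.digest_pattern <- function(x, ...) {
  cat(sprintf("<digest> %s on %d bp (%s): %s\n", x$enzyme_name, x$amplicon_length,
              if (x$circular) "circular" else "linear",
              if (length(x$fragments) == 1L) "uncut" else format_fragments(x)))
  invisible(x)
}

#' Format a digest pattern in gel-report span notation
#'
#' Prints each fragment as `start.0.end (len bp)` with 1-based inclusive
#' spans, the notation used in published RFLP keys.
#'
#' @param pattern a `digest_pattern` (or integer fragment vector).
#' @return A character scalar.
#' @export
format_fragments <- function(pattern) {
  frags <- if (inherits(pattern, "digest_pattern")) pattern$fragments else as.integer(pattern)
  ends <- cumsum(frags)
  starts <- c(1L, head(ends, -1L) + 1L)
  paste(sprintf("%d.0.%d (%d bp)", starts, ends, frags), collapse = " ")
}

#' Load a restriction-enzyme definition table
#'
#' Parses a REBASE-style tab-delimited text file of `name <TAB> site` rows.
#' Two site notations are understood: caret notation (`G^GTCTC`,
#' `GATNN^NNATC`) for within-site cutters, with the bottom-strand cut taken
#' symmetric, and offset notation (`GGTCTC(1/5)`) for downstream cutters,
#' where the offsets count bases past the 3' end of the recognition site.
#'
#' @param path path to the enzyme table; defaults to the packaged 8-enzyme
#'   panel of the consolidated key.
#' @return A named list of [enzyme()] objects.
#' @export
load_enzyme_table <- function(path = system.file("extdata", "enzymes.tsv", package = "mitokey")) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- list()
  for (i in which(keep)) {
    fields <- strsplit(sub("\\s*#.*$", "", lines[i]), "\t")[[1]]
    fields <- fields[nzchar(trimws(fields))]
    if (length(fields) < 2L) stop("line ", i, ": expected 'name<TAB>site'")
    name <- trimws(fields[1]); site <- trimws(fields[2])
    if (grepl("^[A-Z]+\\(-?[0-9]+/-?[0-9]+\\)$", site)) {
      rec <- sub("\\(.*$", "", site)
      offs <- as.integer(regmatches(site, gregexpr("-?[0-9]+", site))[[1]])
      e <- enzyme(name, rec, cut_top = nchar(rec) + offs[1], cut_bottom = nchar(rec) + offs[2])
    } else if (grepl("\\^", site)) {
      if (lengths(gregexpr("\\^", site)) != 1L) stop("line ", i, ": multiple '^' in site ", site)
      cut_top <- as.integer(regexpr("\\^", site)) - 1L
      rec <- gsub("\\^", "", site)
      e <- enzyme(name, rec, cut_top = cut_top)
    } else {
      stop("line ", i, ": malformed site notation '", site, "' (need '^' or '(a/b)')")
    }
    if (e$name %in% names(out)) stop("line ", i, ": duplicate enzyme name ", e$name)
    out[[e$name]] <- e
  }
  out
}
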