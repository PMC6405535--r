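## species_key: the consolidated five-species diagnostic key, pattern-based
## classification of unknowns, and exhaustive search for minimal
## discriminating enzyme panels.

#' Load a diagnostic key file
#'
#' Reads a tab-delimited key (`species`, `region`, `region_length`, `enzyme`,
#' `fragments` with comma-joined lengths; uncut encoded as the single
#' full-length fragment) and validates it: every fragment list must sum to
#' its region length, and every species must have an entry for every enzyme
#' used in its region.
#'
#' @param path path to a key file; defaults to the packaged consolidated
#'   five-species COI key (698 bp 5' region and 511 bp 3' region).
#' @return An object of class `diagnostic_key`.
#' @export
load_key <- function(path = system.file("extdata", "key_coi_rflp.tsv", package = "mitokey")) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "region", "region_length", "enzyme", "fragments")
  if (!all(need %in% names(df))) stop("key file must have columns: ", paste(need, collapse = ", "))
  df$fragments <- as.character(df$fragments)
  frag_list <- lapply(strsplit(df$fragments, ","), function(x) as.integer(trimws(x)))
  sums <- vapply(frag_list, sum, 0L)
  bad <- which(sums != df$region_length)
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf("key cell (%s, %s, %s): fragments [%s] sum to %d, not region length %d",
                 df$species[b], df$region[b], df$enzyme[b], df$fragments[b],
                 sums[b], df$region_length[b]))
  }
  if (any(vapply(frag_list, function(f) any(f < 1L), TRUE))) stop("key contains fragments < 1 bp")
  ## coverage: within each region, every species x enzyme combination present
  for (rg in unique(df$region)) {
    sub <- df[df$region == rg, ]
    tab <- table(sub$species, sub$enzyme)
    if (any(tab != 1L)) {
      stop("region ", rg, ": key must contain exactly one entry per species x enzyme")
    }
  }
  key <- list(entries = df[, need], fragment_list = frag_list,
              region_lengths = vapply(split(df$region_length, df$region), function(x) x[1], 0L))
  class(key) <- "diagnostic_key"
  key
}

#' @export
print.diagnostic_key <- function(x, ...) {
  cat(sprintf("<diagnostic_key> %d species, regions: %s\n",
              length(unique(x$entries$species)),
              paste(sprintf("%s (%d bp)", names(x$region_lengths), x$region_lengths),
                    collapse = ", ")))
  invisible(x)
}

#' Species, regions and enzymes covered by a key
#' @param key a `diagnostic_key`.
#' @param region region name (for `key_enzymes`).
#' @return Character vector.
#' @export
key_species <- function(key) sort(unique(key$entries$species))

#' @rdname key_species
#' @export
key_regions <- function(key) names(key$region_lengths)

#' @rdname key_species
#' @export
key_enzymes <- function(key, region) sort(unique(key$entries$enzyme[key$entries$region == region]))

#' Expected fragment pattern for one key cell
#'
#' @param key a `diagnostic_key`.
#' @param species,region,enzyme_name cell coordinates.
#' @return Integer vector of expected fragment lengths.
#' @export
key_pattern <- function(key, species, region, enzyme_name) {
  i <- which(key$entries$species == species & key$entries$region == region &
               key$entries$enzyme == enzyme_name)
  if (length(i) != 1L) {
    stop("no key entry for (", species, ", ", region, ", ", enzyme_name, ")")
  }
  key$fragment_list[[i]]
}

## fragment multiset comparison with per-fragment gel tolerance; one-to-one
## assignment is optimal for sorted 1-D values
fragments_match <- function(observed, expected, tolerance_bp = 0L) {
  if (length(observed) != length(expected)) return(FALSE)
  all(abs(sort(as.integer(observed)) - sort(as.integer(expected))) <= tolerance_bp)
}

#' Classify an unknown from observed digest patterns
#'
#' Compares observed fragment multisets (one per enzyme) against every
#' species' expected patterns for the region and ranks species by the number
#' of mismatching enzymes. In-silico patterns should use `tolerance_bp = 0`;
#' for empirical gel estimates a tolerance around 20 bp is a reasonable
#' starting point.
#'
#' @param observed named list mapping enzyme name to an integer vector of
#'   fragment lengths (or `digest_pattern` objects).
#' @param key a `diagnostic_key`.
#' @param region region name the observations come from.
#' @param tolerance_bp per-fragment length tolerance in bp.
#' @return An object of class `species_call`: `candidates` (data.frame of
#'   species and mismatch score, best first) and `status` (`"unique"`,
#'   `"ambiguous"` or `"no_match"`).
#' @export
classify <- function(observed, key, region, tolerance_bp = 0L) {
  if (!region %in% key_regions(key)) {
    stop("unknown region '", region, "'; key regions: ", paste(key_regions(key), collapse = ", "))
  }
  observed <- lapply(observed, function(o) {
    if (inherits(o, "digest_pattern")) o$fragments else as.integer(o)
  })
  enzymes_known <- key_enzymes(key, region)
  unknown <- setdiff(names(observed), enzymes_known)
  if (length(unknown)) {
    stop("enzyme(s) not in key for region ", region, ": ",
         paste(unknown, collapse = ", "), "; known: ", paste(enzymes_known, collapse = ", "))
  }
  if (length(observed) == 0L) stop("no observed patterns supplied")
  species <- key_species(key)
  score <- vapply(species, function(sp) {
    sum(!vapply(names(observed), function(e) {
      fragments_match(observed[[e]], key_pattern(key, sp, region, e), tolerance_bp)
    }, TRUE))
  }, 0L)
  ord <- order(score, species)
  candidates <- data.frame(species = species[ord], mismatch_score = score[ord],
                           row.names = NULL, stringsAsFactors = FALSE)
  nzero <- sum(candidates$mismatch_score == 0L)
  status <- if (nzero == 1L) "unique" else if (nzero > 1L) "ambiguous" else "no_match"
  structure(list(candidates = candidates, status = status, region = region),
            class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  top <- x$candidates[x$candidates$mismatch_score == min(x$candidates$mismatch_score), ]
  cat(sprintf("<species_call> %s: %s\n", x$status, paste(top$species, collapse = ", ")))
  invisible(x)
}

## profile of one species over a set of enzymes under a scoring mode
key_profile <- function(key, species, region, enzymes, scoring_mode) {
  parts <- vapply(enzymes, function(e) {
    frags <- key_pattern(key, species, region, e)
    if (scoring_mode == "presence_absence") {
      if (length(frags) > 1L) "cut" else "uncut"
    } else {
      paste(sort(frags), collapse = "+")
    }
  }, "")
  paste(parts, collapse = "|")
}

#' Search for minimal discriminating enzyme panels
#'
#' Exhaustively enumerates enzyme subsets of a region in increasing
#' cardinality and reports every smallest subset whose expected patterns
#' separate all species in the key. Under `presence_absence` scoring only the
#' cut/uncut state of each enzyme is compared (what a quick gel read-out
#' gives); under `size_aware` scoring the full fragment-length multisets are
#' compared, which can separate species that a cut/uncut reading cannot.
#'
#' @param key a `diagnostic_key`.
#' @param region region name.
#' @param scoring_mode `"presence_absence"` or `"size_aware"`.
#' @return An object of class `panel_solution`: `region`, `scoring_mode`,
#'   `separable` flag, `minimal_panels` (list of enzyme-name vectors, empty
#'   panel for a single-species key) and, when no subset separates all
#'   species, `best_partition` (the maximal achievable partition, as a list
#'   of species groups left indistinguishable by the full panel).
#' @export
minimal_panel <- function(key, region, scoring_mode = c("presence_absence", "size_aware")) {
  scoring_mode <- match.arg(scoring_mode)
  species <- key_species(key)
  enzymes <- key_enzymes(key, region)
  base <- list(region = region, scoring_mode = scoring_mode)
  if (length(species) <= 1L) {
    return(structure(c(base, list(separable = TRUE, minimal_panels = list(character(0)))),
                     class = "panel_solution"))
  }
  for (k in seq_along(enzymes)) {
    subsets <- combn(enzymes, k, simplify = FALSE)
    winners <- Filter(function(panel) {
      profiles <- vapply(species, key_profile, "", key = key, region = region,
                         enzymes = panel, scoring_mode = scoring_mode)
      !anyDuplicated(profiles)
    }, subsets)
    if (length(winners)) {
      return(structure(c(base, list(separable = TRUE, minimal_panels = winners)),
                       class = "panel_solution"))
    }
  }
  profiles <- vapply(species, key_profile, "", key = key, region = region,
                     enzymes = enzymes, scoring_mode = scoring_mode)
  partition <- unname(split(species, profiles))
  structure(c(base, list(separable = FALSE, minimal_panels = list(),
                         best_partition = partition)),
            class = "panel_solution")
}

#' @export
print.panel_solution <- function(x, ...) {
  if (x$separable) {
    sizes <- lengths(x$minimal_panels)
    cat(sprintf("<panel_solution> %s (%s): minimal cardinality %d; %d panel(s)\n",
                x$region, x$scoring_mode, if (length(sizes)) sizes[1] else 0L,
                length(x$minimal_panels)))
    for (p in x$minimal_panels) cat("  {", paste(p, collapse = ", "), "}\n")
  } else {
    cat(sprintf("<panel_solution> %s (%s): NOT separable; maximal partition:\n",
                x$region, x$scoring_mode))
    for (g in x$best_partition) cat("  {", paste(g, collapse = ", "), "}\n")
  }
  invisible(x)
}
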