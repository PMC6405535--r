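## phylo_nj: concatenate the 13 protein-coding genes, compute Kimura
## two-parameter distances, and build a neighbor-joining tree as a
## distance-based sanity check of species clustering (maximum-likelihood
## inference is deliberately out of scope; the acceptance surface is
## topology, never support values or branch lengths).

## ---- per-gene multiple alignment (center-star) ---------------------------
## Progressive alignment around a center taxon: every other sequence is
## aligned pairwise to the center, insertions relative to the center are
## merged by taking, per center position, the maximum insertion length over
## taxa. Exact for the generator's substitution-only panels and adequate for
## the rare short indel.

decompose_vs_center <- function(other_aln, center_aln) {
  oc <- strsplit(other_aln, "")[[1]]
  cc <- strsplit(center_aln, "")[[1]]
  L <- sum(cc != "-")
  bases <- character(L)
  ins <- vector("list", L + 1L)  # insertions after center position 0..L
  for (k in seq_len(L + 1L)) ins[[k]] <- character(0)
  cpos <- 0L
  for (i in seq_along(cc)) {
    if (cc[i] == "-") {
      ins[[cpos + 1L]] <- c(ins[[cpos + 1L]], oc[i])
    } else {
      cpos <- cpos + 1L
      bases[cpos] <- oc[i]
    }
  }
  list(bases = bases, ins = vapply(ins, paste, "", collapse = ""))
}

align_gene_set <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1L) return(seqs)  # already flush; no gaps needed
  tab <- table(lens)
  modal_len <- as.integer(names(tab)[which.max(tab)])
  center <- names(seqs)[which(lens == modal_len)[1]]
  others <- setdiff(names(seqs), center)
  L <- nchar(seqs[[center]])
  dec <- list()
  for (id in others) {
    al <- align_global_full(seqs[[id]], seqs[[center]])
    dec[[id]] <- decompose_vs_center(al$a, al$b)
  }
  ins_len <- rep(0L, L + 1L)
  for (id in others) ins_len <- pmax(ins_len, nchar(dec[[id]]$ins))
  pad <- function(x, n) paste0(x, strrep("-", n - nchar(x)))
  build <- function(bases, ins) {
    parts <- character(2L * L + 1L)
    parts[1L] <- pad(ins[1L], ins_len[1L])
    for (p in seq_len(L)) {
      parts[2L * p] <- bases[p]
      parts[2L * p + 1L] <- pad(ins[p + 1L], ins_len[p + 1L])
    }
    paste(parts, collapse = "")
  }
  out <- setNames(character(length(seqs)), names(seqs))
  ccb <- strsplit(seqs[[center]], "")[[1]]
  out[center] <- build(ccb, rep("", L + 1L))
  for (id in others) out[id] <- build(dec[[id]]$bases, dec[[id]]$ins)
  out
}

#' Concatenate aligned protein-coding genes across a panel
#'
#' Extracts each gene in coding orientation from every annotated record,
#' aligns the per-gene sets (center-star progressive alignment; flush if all
#' copies have equal length), and concatenates them in the shared gene order.
#' Taxa missing any requested gene are dropped with a warning.
#'
#' @param entries list of annotated records (`record` + `annotations`).
#' @param genes genes to concatenate; defaults to the 13 protein-coding genes.
#' @return An object of class `concat_alignment`: `taxa`, `seqs` (named
#'   aligned strings of equal length) and `partition` (data.frame `gene`,
#'   `start`, `end`, 1-based inclusive columns).
#' @export
concatenate_pcgs <- function(entries, genes = PCG_NAMES) {
  ids <- vapply(entries, function(e) e$record$id, "")
  names(entries) <- ids
  have <- vapply(entries, function(e) all(genes %in% e$annotations$gene), TRUE)
  if (!all(have)) {
    warning("dropping taxa missing genes: ", paste(ids[!have], collapse = ", "))
    entries <- entries[have]
    ids <- ids[have]
  }
  if (length(entries) < 2L) stop("need at least two taxa with all genes annotated")
  blocks <- list()
  partition <- data.frame(gene = character(), start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
  offset <- 0L
  for (g in genes) {
    seqs <- vapply(entries, function(e) gene_sequence(e, g), "")
    aligned <- align_gene_set(seqs)
    w <- nchar(aligned[[1]])
    blocks[[g]] <- aligned
    partition <- rbind(partition, data.frame(gene = g, start = offset + 1L,
                                             end = offset + w, stringsAsFactors = FALSE))
    offset <- offset + w
  }
  seqs <- setNames(vapply(ids, function(id) {
    paste(vapply(blocks, function(b) b[[id]], ""), collapse = "")
  }, ""), ids)
  structure(list(taxa = ids, seqs = seqs, partition = partition),
            class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concat_alignment> %d taxa x %d columns (%d partitions)\n",
              length(x$taxa), nchar(x$seqs[[1]]), nrow(x$partition)))
  invisible(x)
}

#' Write a concatenated alignment and its partition file
#'
#' @param aln a `concat_alignment`.
#' @param fasta_path,partition_path output paths (FASTA; TSV of gene, start,
#'   end in 1-based inclusive columns).
#' @export
write_alignment <- function(aln, fasta_path, partition_path = NULL) {
  con <- file(fasta_path, "w"); on.exit(close(con))
  for (id in aln$taxa) {
    writeLines(paste0(">", id), con)
    writeLines(aln$seqs[[id]], con)
  }
  if (!is.null(partition_path)) {
    write.table(aln$partition, partition_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Kimura two-parameter distance matrix
#'
#' For each pair, over columns where both taxa have a determined base
#' (A/C/G/T; gaps and Ns excluded pairwise), computes transition and
#' transversion proportions p and q and the K2P distance
#' `d = -log((1-2p-q) * sqrt(1-2q)) / 2`. Saturated pairs (non-positive log
#' argument) are set to `ceiling` and flagged.
#'
#' @param aln a `concat_alignment` or named character vector of equal-length
#'   aligned sequences.
#' @param ceiling distance assigned to saturated pairs.
#' @return A symmetric matrix (class `k2p_dist`) in substitutions/site, with
#'   attribute `saturated` listing flagged pairs.
#' @export
k2p_distance <- function(aln, ceiling = 5) {
  seqs <- if (inherits(aln, "concat_alignment")) aln$seqs else aln
  if (length(seqs) < 2L) stop("need at least two taxa")
  chars <- do.call(rbind, strsplit(toupper(unlist(seqs)), ""))
  rownames(chars) <- names(seqs)
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(rownames(chars), rownames(chars)))
  purine <- chars == "A" | chars == "G"
  determined <- chars == "A" | chars == "C" | chars == "G" | chars == "T"
  saturated <- character(0)
  for (pair in combn(n, 2L, simplify = FALSE)) {
    i <- pair[1]; j <- pair[2]
    use <- determined[i, ] & determined[j, ]
    L <- sum(use)
    if (L == 0L) stop("no comparable columns between ", rownames(chars)[i],
                      " and ", rownames(chars)[j])
    diffs <- use & (chars[i, ] != chars[j, ])
    ts <- sum(diffs & (purine[i, ] == purine[j, ]))   # transitions keep purine class
    tv <- sum(diffs) - ts
    p <- ts / L; q <- tv / L
    arg1 <- 1 - 2 * p - q
    arg2 <- 1 - 2 * q
    if (arg1 <= 0 || arg2 <= 0) {
      d[i, j] <- d[j, i] <- ceiling
      saturated <- c(saturated, paste(rownames(chars)[i], rownames(chars)[j], sep = ":"))
    } else {
      d[i, j] <- d[j, i] <- -0.5 * log(arg1 * sqrt(arg2))
    }
  }
  attr(d, "saturated") <- saturated
  class(d) <- c("k2p_dist", class(d))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration with deterministic tie-breaking:
#' among pairs minimizing the Q criterion, the pair whose (lexicographically
#' smallest, then largest) descendant tip labels sort first is joined.
#' Negative branch lengths are clamped to zero and flagged. Exact on additive
#' distance matrices.
#'
#' @param d a symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An `ape` `phylo` tree (unrooted). Attribute `clamped` lists any
#'   branch-length clamps.
#' @export
neighbor_joining <- function(d) {
  d <- unclass(d)
  taxa <- rownames(d)
  if (is.null(taxa)) stop("distance matrix must have taxon dimnames")
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  clamped <- character(0)
  bl <- function(x, lab) {
    if (x < 0) { clamped <<- c(clamped, lab); 0 } else x
  }
  ## working state: newick fragment and canonical label (smallest tip) per node
  nwk <- setNames(as.list(taxa), taxa)
  canon <- setNames(taxa, taxa)
  D <- d
  while (nrow(D) > 3L) {
    N <- nrow(D)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lab1 <- pmin(canon[rownames(D)[cand[, 1]]], canon[rownames(D)[cand[, 2]]])
    lab2 <- pmax(canon[rownames(D)[cand[, 1]]], canon[rownames(D)[cand[, 2]]])
    pick <- order(lab1, lab2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    ni <- rownames(D)[i]; nj <- rownames(D)[j]
    li <- bl(0.5 * D[i, j] + (r[i] - r[j]) / (2 * (N - 2)), paste0(ni, "|", nj))
    lj <- bl(D[i, j] - li, paste0(nj, "|", ni))
    u <- paste0("u", N)
    nwk[[u]] <- sprintf("(%s:%.10g,%s:%.10g)", nwk[[ni]], li, nwk[[nj]], lj)
    canon[u] <- min(canon[ni], canon[nj])
    others <- setdiff(rownames(D), c(ni, nj))
    newrow <- vapply(others, function(k) 0.5 * (D[ni, k] + D[nj, k] - D[ni, nj]), 0)
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, `colnames<-`(matrix(newrow, ncol = 1), u)),
               `rownames<-`(matrix(c(newrow, 0), nrow = 1), u))
    rownames(D)[nrow(D)] <- u
    colnames(D)[ncol(D)] <- u
  }
  ## resolve the final three nodes around the central vertex
  a <- rownames(D)[1]; b <- rownames(D)[2]; c3 <- rownames(D)[3]
  la <- bl(0.5 * (D[a, b] + D[a, c3] - D[b, c3]), a)
  lb <- bl(0.5 * (D[a, b] + D[b, c3] - D[a, c3]), b)
  lc <- bl(0.5 * (D[a, c3] + D[b, c3] - D[a, b]), c3)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    nwk[[a]], la, nwk[[b]], lb, nwk[[c3]], lc)
  tree <- ape::read.tree(text = newick)
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap clade support for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' per replicate and writes clade frequencies (percent) as internal node
#' labels on the reference tree. Support values are a reporting aid only.
#'
#' @param aln a `concat_alignment`.
#' @param reps number of bootstrap replicates.
#' @param seed RNG seed for resampling.
#' @return The NJ tree (`phylo`) with `node.label` set to percent support.
#' @export
nj_bootstrap <- function(aln, reps = 100L, seed = 1L) {
  ref <- neighbor_joining(k2p_distance(aln))
  chars <- do.call(rbind, strsplit(unlist(aln$seqs), ""))
  rownames(chars) <- names(aln$seqs)
  trees <- with_seed(seed, {
    lapply(seq_len(reps), function(i) {
      cols <- sample.int(ncol(chars), ncol(chars), replace = TRUE)
      boot <- setNames(apply(chars[, cols, drop = FALSE], 1, paste, collapse = ""),
                       rownames(chars))
      neighbor_joining(k2p_distance(boot))
    })
  })
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.character(round(100 * counts / reps))
  ref
}
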