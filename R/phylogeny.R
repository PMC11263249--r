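#' Progressive multiple alignment
#'
#' A deterministic progressive aligner: sequences are ordered by a k-mer
#' distance guide clustering, the first two are aligned globally (affine
#' gaps), and each further sequence is aligned against the running majority
#' consensus, with new gaps propagated into all rows. In codon mode the
#' translations are aligned and gaps expanded threefold, so nucleotide gaps
#' always come in multiples of 3.
#'
#' @param seqs Named character vector of sequences.
#' @param alphabet `"dna"` or `"protein"`.
#' @param codon Align in-frame CDSs via their translations.
#' @param code A [genetic_code()] (codon mode).
#' @param scoring match, mismatch, gap open, gap extend.
#' @return Object of class `msa`: list with `rows` (named aligned strings),
#'   `length`, `alphabet`.
#' @export
align_progressive <- function(seqs, alphabet = c("dna", "protein"),
                              codon = FALSE, code = genetic_code(4),
                              scoring = c(1, -1, -2, -1)) {
  alphabet <- match.arg(alphabet)
  seqs <- toupper(unlist(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (any(!nzchar(seqs))) stop("empty sequence")
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (codon) {
    prots <- vapply(seqs, function(s)
      suppressWarnings(translate_dna(s, code, "keep")), "")
    pal <- align_progressive(prots, alphabet = "protein",
                             scoring = c(2, -1, -8, -1))
    rows <- vapply(names(seqs), function(nm) {
      expand_codon_gaps(pal$rows[[nm]], seqs[[nm]])
    }, "")
    return(structure(list(rows = rows, length = nchar(rows[[1]]),
                          alphabet = "dna"), class = "msa"))
  }
  ord <- guide_order(seqs)
  aln <- seqs[ord[1]]
  for (i in ord[-1]) {
    cons <- msa_consensus(aln)
    al <- nw_align_cpp(cons, seqs[[i]], scoring[1], scoring[2], scoring[3],
                       scoring[4])
    aln <- propagate_gaps(aln, al$a)
    aln[[names(seqs)[i]]] <- al$b
  }
  aln <- aln[names(seqs)]
  structure(list(rows = aln, length = nchar(aln[[1]]), alphabet = alphabet),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns (%s)\n", length(x$rows),
              x$length, x$alphabet))
  invisible(x)
}

# deterministic addition order from average-linkage clustering of k-mer
# distances (most central pair first)
guide_order <- function(seqs, k = 4L) {
  n <- length(seqs)
  if (n == 2L) return(1:2)
  km <- lapply(seqs, function(s) unique(kmer_index(s, min(k, nchar(s)))))
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    inter <- length(intersect(km[[i]], km[[j]]))
    uni <- length(union(km[[i]], km[[j]]))
    d[i, j] <- d[j, i] <- 1 - inter / max(uni, 1L)
  }
  order(rowMeans(d)) # most central sequence first
}

msa_consensus <- function(rows) {
  m <- do.call(rbind, strsplit(unlist(rows), ""))
  paste(apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("N")
    names(sort(table(col), decreasing = TRUE))[1]
  }), collapse = "")
}

# insert the gaps newly present in aligned_cons into every existing row
propagate_gaps <- function(rows, aligned_cons) {
  gaps <- which(strsplit(aligned_cons, "")[[1]] == "-")
  if (!length(gaps)) return(rows)
  lapply(rows, function(r) {
    chars <- strsplit(r, "")[[1]]
    out <- character(nchar(aligned_cons))
    out[gaps] <- "-"
    out[-gaps] <- chars
    paste(out, collapse = "")
  })
}

# expand a gapped protein row back to its nucleotide sequence (x3 gaps)
expand_codon_gaps <- function(prot_row, nt_seq) {
  chars <- strsplit(prot_row, "")[[1]]
  out <- character(length(chars))
  pos <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "-") out[i] <- "---"
    else { out[i] <- substr(nt_seq, pos * 3L + 1L, pos * 3L + 3L); pos <- pos + 1L }
  }
  # carry any trailing bases (e.g. terminal stop codon) on the last column
  tail_nt <- substr(nt_seq, pos * 3L + 1L, nchar(nt_seq))
  paste0(paste(out, collapse = ""), tail_nt)
}

#' Remove gap-rich alignment columns
#'
#' @param msa An `msa` object.
#' @param max_gap_fraction Columns with a higher gap fraction are removed.
#' @param codon Remove whole codon triplets (alignment length must be a
#'   multiple of 3); a triplet goes when any of its three columns exceeds
#'   the threshold.
#' @return Trimmed `msa`.
#' @export
trim_columns <- function(msa, max_gap_fraction = 0.5, codon = FALSE) {
  m <- do.call(rbind, strsplit(unlist(msa$rows), ""))
  gapfrac <- colMeans(m == "-")
  drop <- gapfrac > max_gap_fraction
  if (codon) {
    stopifnot(ncol(m) %% 3L == 0L)
    bad <- apply(matrix(drop, nrow = 3L), 2, any)
    drop <- rep(bad, each = 3L)
  }
  if (all(drop)) stop("all columns removed by trimming")
  keep <- which(!drop)
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  names(rows) <- names(msa$rows)
  structure(list(rows = rows, length = length(keep), alphabet = msa$alphabet),
            class = "msa")
}

## ---- supermatrices ---------------------------------------------------------

DATASET_KINDS <- c("PCG", "PCG12", "PCGR", "PCG12R", "AA")

#' Build a concatenated analysis dataset
#'
#' Dataset kinds follow the usual mitophylogenomics conventions:
#' PCG = the 14 conserved protein-coding genes concatenated; PCG12 = the
#' same with third codon positions removed; PCGR / PCG12R append the rnl and
#' rns alignments; AA = the codon-wise translation of the PCG concatenate.
#' Species missing a marker are padded with gaps and flagged.
#'
#' @param per_gene_msas Named list of `msa` objects (names = markers; codon
#'   alignments for the PCGs, nucleotide alignments for rnl/rns).
#' @param dataset_kind One of PCG, PCG12, PCGR, PCG12R, AA.
#' @param pcg_genes Which markers count as the conserved PCGs.
#' @param code A [genetic_code()] (for AA).
#' @return Object of class `supermatrix`: `kind`, `rows` (named aligned
#'   strings), `length`, `partitions` (data.frame marker/start/end, 1-based).
#' @export
build_supermatrix <- function(per_gene_msas,
                              dataset_kind = c("PCG", "PCG12", "PCGR",
                                               "PCG12R", "AA"),
                              pcg_genes = CONSERVED_PCGS,
                              code = genetic_code(4)) {
  dataset_kind <- match.arg(dataset_kind)
  species <- sort(unique(unlist(lapply(per_gene_msas,
                                       function(m) names(m$rows)))))
  markers <- intersect(names(per_gene_msas), pcg_genes)
  if (!length(markers)) stop("no conserved PCG alignments supplied")
  use_rrna <- dataset_kind %in% c("PCGR", "PCG12R")
  rrna <- intersect(names(per_gene_msas), RRNA_GENES)
  padded <- character(0)
  get_rows <- function(marker, transform = identity) {
    m <- per_gene_msas[[marker]]
    out <- setNames(rep(strrep("-", m$length), length(species)), species)
    out[names(m$rows)] <- unlist(m$rows)
    if (length(setdiff(species, names(m$rows))))
      padded <<- c(padded, marker)
    vapply(out, transform, "")
  }
  drop3 <- function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(chars[seq_along(chars) %% 3L != 0L], collapse = "")
  }
  to_aa <- function(s) {
    n <- nchar(s) - nchar(s) %% 3L
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- ifelse(codons == "---", "-",
                 ifelse(codons %in% names(code$codons),
                        unname(code$codons[codons]), "X"))
    paste(aa, collapse = "")
  }
  tf <- switch(dataset_kind, PCG = , PCGR = identity,
               PCG12 = , PCG12R = drop3, AA = to_aa)
  blocks <- lapply(markers, get_rows, transform = tf)
  names(blocks) <- markers
  if (use_rrna) {
    for (rg in rrna) blocks[[rg]] <- get_rows(rg)
  }
  lens <- vapply(blocks, function(b) nchar(b[[1]]), 1L)
  ends <- cumsum(lens)
  partitions <- data.frame(marker = names(blocks),
                           start = c(1L, head(ends, -1L) + 1L), end = ends,
                           stringsAsFactors = FALSE)
  rows <- setNames(do.call(paste0, blocks), species)
  structure(list(kind = dataset_kind, rows = rows, length = sum(lens),
                 partitions = partitions, padded = unique(padded),
                 alphabet = if (dataset_kind == "AA") "protein" else "dna"),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %s: %d species x %d columns, %d partitions\n",
              x$kind, length(x$rows), x$length, nrow(x$partitions)))
  invisible(x)
}

## ---- trees -----------------------------------------------------------------

#' Distance matrix of a supermatrix or alignment
#'
#' K2P with pairwise deletion for nucleotides; p-distance (optionally
#' Poisson-corrected) for amino acids.
#'
#' @param x `supermatrix`, `msa`, or named character vector.
#' @param correction `"poisson"` or `"p"` for protein data.
#' @return Symmetric distance matrix.
#' @export
supermatrix_distances <- function(x, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  rows <- if (is.list(x) && !is.null(x$rows)) x$rows else x
  alphabet <- if (is.list(x) && !is.null(x$alphabet)) x$alphabet else "dna"
  if (alphabet == "dna") return(k2p_matrix(rows))
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(rows[[i]], "")[[1]]; b <- strsplit(rows[[j]], "")[[1]]
    ok <- a != "-" & b != "-" & a != "X" & b != "X"
    p <- mean(a[ok] != b[ok])
    d[i, j] <- d[j, i] <- if (correction == "poisson") -log(1 - p) else p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining; negative branch lengths are clamped to zero
#' (flagged in attribute `"clamped"`). Saturated (NA) entries are not
#' accepted.
#'
#' @param distances Symmetric matrix with zero diagonal.
#' @return An [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(distances) {
  if (!isSymmetric(unname(as.matrix(distances))))
    stop("distance matrix must be symmetric")
  if (any(is.na(distances))) stop("distance matrix contains missing values")
  tr <- ape::nj(as.matrix(distances))
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Bootstrap support for an alignment's NJ tree
#'
#' Columns are resampled with replacement; each replicate's NJ tree is built
#' on the same distance (K2P for nucleotide, Poisson for protein) and the
#' support of every internal edge of the original tree is the percentage of
#' replicates containing that bipartition.
#'
#' @param x `supermatrix` or `msa`.
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Random seed (reproducible).
#' @return The original NJ tree with node labels set to support percentages.
#' @export
bootstrap_support <- function(x, n_replicates = 100L, seed = 1L) {
  rows <- x$rows
  m <- do.call(rbind, strsplit(unlist(rows), ""))
  rownames(m) <- names(rows)
  dna <- is.null(x$alphabet) || x$alphabet == "dna"
  codes <- if (dna)
    setNames(lapply(seq_len(nrow(m)),
                    function(i) match(m[i, ], c("A", "C", "G", "T"))),
             rownames(m))
  build <- function(cols) {
    if (dna) {
      sub <- lapply(codes, `[`, cols)
      return(nj_tree(k2p_matrix_codes(sub)))
    }
    rs <- setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                   rownames(m))
    nj_tree(supermatrix_distances(list(rows = rs, alphabet = x$alphabet)))
  }
  main <- build(seq_len(ncol(m)))
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    reps[[r]] <- build(sample.int(ncol(m), ncol(m), replace = TRUE))
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / n_replicates)
  main
}

#' Fitch small-parsimony score of a tree on an alignment
#'
#' Unordered Fitch parsimony summed over columns; gaps and ambiguity codes
#' are treated as missing (full state set).
#'
#' @param tree An [ape::phylo].
#' @param msa `msa`/`supermatrix` or named character vector of aligned
#'   sequences covering the tree's tips.
#' @return Integer parsimony score.
#' @export
parsimony_score <- function(tree, msa) {
  rows <- if (is.list(msa) && !is.null(msa$rows)) msa$rows else msa
  if (!setequal(tree$tip.label, names(rows)))
    stop("leaf set of tree and alignment differ")
  m <- do.call(rbind, strsplit(unlist(rows[tree$tip.label]), ""))
  states <- sort(unique(as.vector(m)))
  states <- setdiff(states, c("-", "N", "X", "?"))
  nstate <- length(states)
  code <- function(ch) {
    v <- matrix(FALSE, length(ch), nstate)
    for (k in seq_len(nstate)) v[, k] <- ch == states[k]
    miss <- rowSums(v) == 0L
    v[miss, ] <- TRUE
    v
  }
  tr <- if (ape::is.rooted(tree)) tree else
    ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  tr <- ape::reorder.phylo(tr, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  total <- 0L
  ncols <- ncol(m)
  # node state sets as logical matrices: nnode x nstate, per column batch
  sets <- array(FALSE, c(nnode, nstate, ncols))
  for (i in seq_len(ntip)) sets[i, , ] <- t(code(m[i, ]))
  score <- integer(ncols)
  children <- split(tr$edge[, 2], tr$edge[, 1])
  ord <- unique(tr$edge[, 1]) # postorder: children precede parents
  for (nd in ord) {
    kids <- children[[as.character(nd)]]
    acc <- sets[kids[1], , , drop = FALSE][1, , ]
    if (nstate == 1L) acc <- matrix(acc, nrow = 1L)
    for (kid in kids[-1]) {
      kset <- sets[kid, , ]
      if (nstate == 1L) kset <- matrix(kset, nrow = 1L)
      inter <- acc & kset
      empty <- colSums(inter) == 0L
      score[empty] <- score[empty] + 1L
      uni <- acc | kset
      acc[, empty] <- uni[, empty]
      acc[, !empty] <- inter[, !empty]
    }
    sets[nd, , ] <- acc
  }
  sum(score)
}

#' Test monophyly of a taxon set on an unrooted tree
#'
#' TRUE iff some edge bipartition isolates exactly the given taxa (either
#' side of the split).
#'
#' @param tree An [ape::phylo].
#' @param taxa Character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, taxa) {
  if (!length(taxa)) stop("empty taxa set")
  if (!all(taxa %in% tree$tip.label)) stop("taxa not all in the tree")
  tips <- tree$tip.label
  if (setequal(taxa, tips) || length(taxa) == 1L) return(TRUE)
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  for (p in parts) {
    side <- labels[p]
    if (setequal(side, taxa) || setequal(setdiff(tips, side), taxa))
      return(TRUE)
  }
  FALSE
}
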