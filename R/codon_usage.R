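#' Count codons over a set of coding sequences
#'
#' Frame-0 codons of each sequence are tallied; codons containing N (or any
#' non-ACGT character) are skipped. The first and last codon of each gene are
#' recorded as its start/stop usage.
#'
#' @param cds_set Named list/vector of in-frame DNA strings (names = genes).
#' @param code A [genetic_code()].
#' @return List of class `codon_usage`: `counts` (named 64-vector),
#'   `aa_totals`, `start_codon`, `stop_codon` (per gene), `n_codons`.
#' @export
count_codons <- function(cds_set, code = genetic_code(4)) {
  cds_set <- as.list(cds_set)
  all_codons <- names(code$codons)
  counts <- setNames(integer(64L), all_codons)
  starts <- stops <- character(length(cds_set))
  for (i in seq_along(cds_set)) {
    s <- toupper(cds_set[[i]])
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3L) stop("coding sequence shorter than one codon")
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    ok <- codons %in% all_codons
    tab <- table(codons[ok])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    starts[i] <- codons[1L]
    stops[i] <- codons[length(codons)]
  }
  names(starts) <- names(stops) <- names(cds_set)
  structure(list(counts = counts, aa_totals = aa_usage(counts, code),
                 start_codon = starts, stop_codon = stops,
                 n_codons = sum(counts), code = code),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %d codons over %d genes\n", x$n_codons,
              length(x$start_codon)))
  invisible(x)
}

synonymous_families <- function(code, include_stops = TRUE) {
  fam <- split(names(code$codons), unname(code$codons))
  if (!include_stops) fam[["*"]] <- NULL
  fam
}

#' Relative synonymous codon usage
#'
#' For codon j of amino acid i with synonymous family size k_i,
#' RSCU_ij = x_ij / ((1/k_i) * sum_j x_ij). A family with zero total count
#' yields NA for all its codons. Under translation table 4 the stop family is
#' {TAA, TAG} (TGA encodes tryptophan).
#'
#' @param counts Named codon-count vector (as from [count_codons()]`$counts`).
#' @param code A [genetic_code()].
#' @param include_stops Include the stop-codon family.
#' @return Named numeric vector of RSCU values (one per codon considered).
#' @export
rscu <- function(counts, code = genetic_code(4), include_stops = TRUE) {
  fams <- synonymous_families(code, include_stops)
  out <- numeric(0)
  for (fam in fams) {
    x <- counts[fam]
    x[is.na(x)] <- 0
    tot <- sum(x)
    val <- if (tot > 0) x / (tot / length(fam)) else rep(NA_real_, length(fam))
    out <- c(out, setNames(as.numeric(val), fam))
  }
  out[order(names(out))]
}

#' Amino-acid usage totals
#'
#' @param counts Named codon-count vector.
#' @param code A [genetic_code()].
#' @return Named integer vector of amino-acid totals (stops under `"*"`).
#' @export
aa_usage <- function(counts, code = genetic_code(4)) {
  aa <- unname(code$codons[names(counts)])
  tot <- tapply(as.integer(counts), aa, sum)
  out <- setNames(as.integer(tot), names(tot))
  out[order(names(out))]
}

#' PCA of RSCU vectors
#'
#' Rows (species x scope concatenates) are centered per codon and decomposed
#' on the covariance; NA values (zero-count families) are imputed to the
#' family-neutral value 1 before centering. The sign of each component is
#' fixed so that its largest-magnitude loading is positive.
#'
#' @param mat Numeric matrix, rows = RSCU vectors, columns = codons.
#' @param n_components Number of components to keep.
#' @return List of class `rscu_pca`: `scores`, `loadings`,
#'   `explained_variance` (fractions).
#' @export
rscu_pca <- function(mat, n_components = 2L) {
  if (nrow(mat) < 3L) stop("PCA needs at least 3 rows")
  mat[is.na(mat)] <- 1
  keep <- apply(mat, 2, function(x) sd(x) > 0)
  if (!any(keep)) stop("constant RSCU matrix: explained variance undefined")
  p <- prcomp(mat[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  scores <- p$x[, seq_len(k), drop = FALSE]
  load <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = load,
                 explained_variance = ev[seq_len(k)]),
            class = "rscu_pca")
}

#' @export
print.rscu_pca <- function(x, ...) {
  cat(sprintf("<rscu_pca> %d rows; PC variance fractions: %s\n",
              nrow(x$scores),
              paste(sprintf("%.3f", x$explained_variance), collapse = ", ")))
  invisible(x)
}

#' Build per-species RSCU matrix for a cohort
#'
#' Concatenates the requested genes of each genome and computes one RSCU
#' vector per genome; used as PCA input for comparing core-gene and uORF
#' codon bias.
#'
#' @param genomes List of [mitogenome()].
#' @param kind Feature kind to concatenate ("CDS" for core genes, "uORF").
#' @param genes Optional gene-label filter.
#' @param code A [genetic_code()].
#' @param include_stops Passed to [rscu()].
#' @return Matrix, one row per genome (rownames `<species>|<kind>`).
#' @export
cohort_rscu_matrix <- function(genomes, kind = "CDS", genes = NULL,
                               code = genetic_code(4), include_stops = FALSE) {
  rows <- list()
  for (g in genomes) {
    kinds <- vapply(g$features, `[[`, "", "kind")
    sel <- kinds == kind
    if (!is.null(genes))
      sel <- sel & vapply(g$features, `[[`, "", "gene") %in% genes
    if (!any(sel)) next
    seqs <- lapply(g$features[sel], function(f) extract_gene_sequence(g, f))
    cu <- count_codons(seqs, code)
    rows[[paste(g$species, kind, sep = "|")]] <-
      rscu(cu$counts, code, include_stops)
  }
  do.call(rbind, rows)
}
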