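PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_transition <- function(x, y) {
  (x %in% PURINES & y %in% PURINES) | (x %in% PYRIMIDINES & y %in% PYRIMIDINES)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Columns containing a gap or N in either sequence are excluded (pairwise
#' deletion). With transition proportion P and transversion proportion Q,
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q). When a logarithm argument is
#' non-positive the distance is NA and flagged saturated.
#'
#' @param a,b Aligned DNA strings of equal length (gaps `-`).
#' @return List of class `k2p_distance`: `P`, `Q`, `d`, `sites_compared`,
#'   `saturated`.
#' @export
k2p_distance <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  if (length(x) != length(y)) stop("sequences must be aligned (equal length)")
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0L) stop("no comparable sites")
  diff <- x != y
  P <- sum(diff & is_transition(x, y)) / n
  Q <- sum(diff & !is_transition(x, y)) / n
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  saturated <- a1 <= 0 || a2 <= 0
  d <- if (saturated) NA_real_ else -0.5 * log(a1) - 0.25 * log(a2)
  structure(list(P = P, Q = Q, d = d, sites_compared = n,
                 saturated = saturated),
            class = "k2p_distance")
}

#' @export
print.k2p_distance <- function(x, ...) {
  cat(sprintf("<k2p> d = %s (P = %.4f, Q = %.4f, n = %d%s)\n",
              if (is.na(x$d)) "NA" else sprintf("%.5f", x$d), x$P, x$Q,
              x$sites_compared, if (x$saturated) ", saturated" else ""))
  invisible(x)
}

## integer-coded (A=1 C=2 G=3 T=4, NA = gap/ambiguity) K2P between two rows
k2p_from_codes <- function(xi, xj) {
  ok <- !is.na(xi) & !is.na(xj)
  nn <- sum(ok)
  if (nn == 0L) return(NA_real_)
  df <- ok & xi != xj
  ts <- sum(df & ((xi == 1L | xi == 3L) == (xj == 1L | xj == 3L)), na.rm = TRUE)
  P <- ts / nn
  Q <- (sum(df, na.rm = TRUE) - ts) / nn
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) - 0.25 * log(a2)
}

seq_to_codes <- function(s) match(strsplit(toupper(s), "")[[1]],
                                  c("A", "C", "G", "T"))

k2p_matrix_codes <- function(codes) {
  n <- length(codes)
  d <- matrix(0, n, n, dimnames = list(names(codes), names(codes)))
  if (n < 2) return(d)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- k2p_from_codes(codes[[i]], codes[[j]])
  d
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param aln Named character vector of aligned sequences.
#' @return Symmetric matrix of K2P distances (saturated pairs NA).
#' @export
k2p_matrix <- function(aln) {
  k2p_matrix_codes(lapply(aln, seq_to_codes))
}

## ---- Nei-Gojobori (1986) ---------------------------------------------------

# Fraction of the three possible changes at each codon position that are
# synonymous; changes creating a stop codon count as nonsynonymous.
ng86_syn_sites <- function(codon, code) {
  aa <- code$codons[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (b in setdiff(bases, orig)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code$codons[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous differences between two codons over all
# shortest substitution pathways; pathways passing through a stop codon are
# excluded unless every pathway does.
ng86_diffs <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(pos) else {
    if (nd == 2L) list(pos, rev(pos)) else {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    }
  }
  eval_path <- function(order) {
    cur <- c1; sd <- 0; ndd <- 0; through_stop <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- code$codons[[cur]]; a2 <- code$codons[[nxt]]
      if (a2 == "*" && nxt != c2) through_stop <- TRUE
      if (a1 == a2) sd <- sd + 1 else ndd <- ndd + 1
      cur <- nxt
    }
    c(sd, ndd, through_stop)
  }
  res <- t(vapply(perms, eval_path, numeric(3)))
  keep <- res[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(res))
  c(sd = mean(res[keep, 1]), nd = mean(res[keep, 2]))
}

#' Nei-Gojobori (1986) Ka/Ks between two aligned coding sequences
#'
#' Synonymous and nonsynonymous sites are counted per codon under the active
#' code and averaged over the two sequences; differences at multi-substitution
#' codons are averaged over all shortest pathways (stop-passing pathways
#' excluded when avoidable). Proportions are Jukes-Cantor corrected:
#' K = -3/4 ln(1 - 4/3 p). Codons containing a gap or N are dropped.
#'
#' @param a,b Codon-aligned in-frame DNA strings (equal length, multiple of 3).
#' @param code A [genetic_code()].
#' @return List of class `kaks`: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`,
#'   `Ka`, `ratio`, `codons_compared`, `saturated`.
#' @export
ng86_kaks <- function(a, b, code = genetic_code(4)) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  if (nchar(a) %% 3L != 0L) stop("aligned length must be a multiple of 3")
  n <- nchar(a)
  ca <- substring(a, seq(1L, n, 3L), seq(3L, n, 3L))
  cb <- substring(b, seq(1L, n, 3L), seq(3L, n, 3L))
  valid <- names(code$codons)
  ok <- ca %in% valid & cb %in% valid
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codons")
  # drop codon pairs where either is a stop (terminal stops are not sites)
  nonstop <- code$codons[ca] != "*" & code$codons[cb] != "*"
  ca <- ca[nonstop]; cb <- cb[nonstop]
  nc <- length(ca)
  uc <- unique(c(ca, cb))
  ss <- vapply(uc, ng86_syn_sites, 1, code = code)
  S <- (sum(ss[ca]) + sum(ss[cb])) / 2
  N <- 3 * nc - S
  Sd <- 0; Nd <- 0
  for (i in which(ca != cb)) {
    d <- ng86_diffs(ca[i], cb[i], code)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS); Ka <- jc(pN)
  saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio, codons_compared = nc,
                 saturated = saturated),
            class = "kaks")
}

#' @export
print.kaks <- function(x, ...) {
  cat(sprintf("<kaks> Ka = %s, Ks = %s, Ka/Ks = %s (%d codons)\n",
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              format(x$ratio, digits = 4), x$codons_compared))
  invisible(x)
}

#' Per-gene summary of pairwise distance and Ka/Ks records
#'
#' Arithmetic means over all defined pairwise values per gene (NA excluded),
#' with the count of missing values reported.
#'
#' @param records data.frame with columns `gene` and any of `d`, `Ka`, `Ks`,
#'   `ratio`.
#' @return data.frame, one row per gene: means of the available statistics
#'   plus `n_pairs` and `n_missing`.
#' @export
per_gene_summary <- function(records) {
  stats <- intersect(c("d", "Ka", "Ks", "ratio"), names(records))
  genes <- unique(records$gene)
  rows <- lapply(genes, function(g) {
    sub <- records[records$gene == g, , drop = FALSE]
    out <- data.frame(gene = g, n_pairs = nrow(sub),
                      n_missing = sum(!stats::complete.cases(sub[stats])),
                      stringsAsFactors = FALSE)
    for (s in stats)
      out[[paste0("mean_", s)]] <- mean(sub[[s]], na.rm = TRUE)
    out
  })
  do.call(rbind, rows)
}

#' Pairwise K2P and Ka/Ks records for the core genes of a cohort
#'
#' Extracts each core gene from every genome and evaluates all unordered
#' species pairs. Sequences are compared directly when equal-length (the
#' usual case for conserved mitochondrial genes) and codon-aligned with
#' [align_progressive()] otherwise.
#'
#' @param genomes List of [mitogenome()].
#' @param genes Gene labels (default 15 core PCGs).
#' @param code A [genetic_code()].
#' @return data.frame: gene, species1, species2, d, P, Q, Ka, Ks, ratio.
#' @export
cohort_rate_records <- function(genomes, genes = CORE_PCGS,
                                code = genetic_code(4)) {
  rows <- list()
  for (gene in genes) {
    seqs <- list()
    for (g in genomes) {
      kinds <- vapply(g$features, `[[`, "", "kind")
      labels <- vapply(g$features, `[[`, "", "gene")
      hit <- which(labels == gene & kinds == "CDS")
      if (length(hit)) seqs[[g$species]] <-
          extract_gene_sequence(g, g$features[[hit[1]]])
    }
    if (length(seqs) < 2L) next
    if (length(unique(nchar(unlist(seqs)))) > 1L) {
      aln <- align_progressive(unlist(seqs), alphabet = "dna", codon = TRUE,
                               code = code)
      seqs <- as.list(aln$rows)
    }
    sp <- names(seqs)
    for (i in 1:(length(sp) - 1)) for (j in (i + 1):length(sp)) {
      k2 <- k2p_distance(seqs[[i]], seqs[[j]])
      kk <- ng86_kaks(seqs[[i]], seqs[[j]], code)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, species1 = sp[i], species2 = sp[j],
        d = k2$d, P = k2$P, Q = k2$Q,
        Ka = kk$Ka, Ks = kk$Ks, ratio = kk$ratio, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
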