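## k-mer seed -> diagonal chain -> verify machinery shared by dispersed-repeat
## detection (genome self-comparison) and pairwise synteny search.

# positions (1-based) of each k-mer of s; k-mers occurring more than
# max_occ times (low-complexity) are masked out
kmer_index <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# seed matches between two sequences (or self if b missing); returns
# data.frame(qpos, spos, strand) of 1-based k-mer start pairs. k-mers
# occurring more than max_occ times on either side are masked out
# (low-complexity filter).
seed_matches <- function(a, b = NULL, k = 16L, max_occ = 12L) {
  self <- is.null(b)
  nb <- nchar(if (self) a else b)
  tab <- function(vec) {
    dt <- data.table::data.table(kmer = vec, pos = seq_along(vec))
    dt <- dt[!grepl("N", dt$kmer, fixed = TRUE)]
    dt[, n := .N, by = "kmer"]
    dt[dt$n <= max_occ, c("kmer", "pos")]
  }
  da <- tab(kmer_index(a, k))
  out <- list()
  for (strand in c("+", "-")) {
    db <- if (strand == "+") {
      if (self) da else tab(kmer_index(b, k))
    } else tab(kmer_index(reverse_complement(if (self) a else b), k))
    if (self && strand == "+") {
      # only duplicated k-mers can seed a self-repeat
      dup <- da[duplicated(da$kmer) | duplicated(da$kmer, fromLast = TRUE)]
      if (!nrow(dup)) next
      mm <- merge(dup, dup, by = "kmer", allow.cartesian = TRUE)
    } else {
      mm <- merge(da, db, by = "kmer", allow.cartesian = TRUE)
    }
    if (!nrow(mm)) next
    spos <- mm$pos.y
    if (strand == "-") spos <- nb - (spos + k - 1L) + 1L # map to + coords
    out[[strand]] <- data.frame(qpos = mm$pos.x, spos = spos,
                                strand = strand, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(qpos = integer(), spos = integer(),
                                      strand = character()))
  do.call(rbind, out)
}

# chain seeds on common diagonals into candidate paired loci
chain_seeds <- function(hits, k, max_gap = 100L) {
  if (!nrow(hits)) return(NULL)
  hits$diag <- ifelse(hits$strand == "+", hits$spos - hits$qpos,
                      hits$spos + hits$qpos)
  keys <- paste(hits$strand, hits$diag)
  out <- list()
  for (key in unique(keys)) {
    h <- hits[keys == key, , drop = FALSE]
    h <- h[order(h$qpos), , drop = FALSE]
    brk <- c(0L, which(diff(h$qpos) > max_gap), nrow(h))
    for (i in seq_len(length(brk) - 1L)) {
      seg <- h[(brk[i] + 1L):brk[i + 1L], , drop = FALSE]
      q1 <- min(seg$qpos); q2 <- max(seg$qpos) + k - 1L
      # spos is always the k-mer's left end in + coordinates (seed_matches
      # maps minus-strand hits), so both strands use the same arithmetic
      s1 <- min(seg$spos); s2 <- max(seg$spos) + k - 1L
      out[[length(out) + 1L]] <- data.frame(
        qstart = q1, qend = q2, sstart = s1, send = s2,
        strand = seg$strand[1], n_seeds = nrow(seg), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# percent identity of two candidate regions: ungapped when equal-length,
# global alignment otherwise (gap-inclusive identity)
region_identity <- function(sa, sb, scoring = c(1, -2, -5, -2)) {
  if (nchar(sa) == nchar(sb))
    return(as.numeric(ungapped_identity_cpp(sa, sb)))
  if ((nchar(sa) + 1) * (nchar(sb) + 1) > 2.5e7) {
    m <- min(nchar(sa), nchar(sb))
    return(as.numeric(ungapped_identity_cpp(substr(sa, 1, m), substr(sb, 1, m))))
  }
  al <- nw_align_cpp(sa, sb, scoring[1], scoring[2], scoring[3], scoring[4])
  x <- strsplit(al$a, "")[[1]]; y <- strsplit(al$b, "")[[1]]
  100 * sum(x == y & x != "-") / length(x)
}

#' Detect dispersed repeats by genome self-comparison
#'
#' k-mer seeded self-comparison on both strands; seeds sharing a diagonal are
#' chained, the paired loci realigned, and pairs passing the length and
#' identity thresholds reported. The trivial self-match is excluded and
#' mirror-image duplicate pairs are collapsed.
#'
#' @param genome A [mitogenome()] (or plain DNA string).
#' @param min_len Minimum repeat length (nt).
#' @param min_identity Minimum percent identity.
#' @param seed_k Seed k-mer length.
#' @param exclude_overlapping Drop pairs whose two loci overlap (tandem-type
#'   self-matches, reported by [find_tandem_repeats()] instead).
#' @return data.frame: start1, end1, start2, end2 (1-based inclusive),
#'   strand (`+` direct, `-` inverted), length, identity — ordered by locus.
#' @export
find_dispersed_repeats <- function(genome, min_len = 30L, min_identity = 70,
                                   seed_k = 16L, exclude_overlapping = TRUE) {
  s <- if (inherits(genome, "mitogenome")) genome$sequence else toupper(genome)
  if (nchar(s) < min_len) stop("genome shorter than min_len")
  hits <- seed_matches(s, NULL, k = seed_k)
  # drop trivial self-diagonal and keep one orientation of each pair
  hits <- hits[!(hits$strand == "+" & hits$spos == hits$qpos), , drop = FALSE]
  hits <- hits[hits$strand == "-" | hits$spos > hits$qpos, , drop = FALSE]
  if (hits_empty(hits)) return(empty_repeat_df())
  ch <- chain_seeds(hits, seed_k)
  ch <- ch[pmin(ch$qend - ch$qstart, ch$send - ch$sstart) + 1L >= min_len, ,
           drop = FALSE]
  if (is.null(ch) || !nrow(ch)) return(empty_repeat_df())
  # inverted-strand self pairs appear twice (A~B and B~A): canonical order
  if (nrow(ch)) {
    flip <- ch$qstart > ch$sstart
    tmp <- ch[flip, c("sstart", "send", "qstart", "qend")]
    ch[flip, c("qstart", "qend", "sstart", "send")] <- tmp
    ch <- ch[!duplicated(ch[c("qstart", "qend", "sstart", "send", "strand")]), ,
             drop = FALSE]
    # self-overlapping inverted chains (palindromes) excluded
    ch <- ch[!(ch$qstart == ch$sstart & ch$qend == ch$send), , drop = FALSE]
    if (exclude_overlapping)
      ch <- ch[ch$sstart > ch$qend | ch$qstart > ch$send, , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(ch))) {
    r <- ch[i, ]
    sa <- substr(s, r$qstart, r$qend)
    sb <- substr(s, r$sstart, r$send)
    if (r$strand == "-") sb <- reverse_complement(sb)
    ident <- region_identity(sa, sb)
    if (!is.na(ident) && ident >= min_identity)
      out[[length(out) + 1L]] <- data.frame(
        start1 = r$qstart, end1 = r$qend, start2 = r$sstart, end2 = r$send,
        strand = r$strand, length = max(nchar(sa), nchar(sb)),
        identity = ident, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_repeat_df())
  res <- do.call(rbind, out)
  res[order(res$start1, res$start2), , drop = FALSE]
}

hits_empty <- function(h) is.null(h) || nrow(h) == 0L

empty_repeat_df <- function() data.frame(
  start1 = integer(), end1 = integer(), start2 = integer(), end2 = integer(),
  strand = character(), length = integer(), identity = numeric(),
  stringsAsFactors = FALSE)

#' Detect tandem repeats
#'
#' Candidate periods are found by scanning self-matches at lag p; each
#' candidate locus is verified against its tiled majority consensus. When
#' several periods explain overlapping loci, the smallest period is kept.
#'
#' @param genome A [mitogenome()] or DNA string.
#' @param max_period Maximum repeat-unit length.
#' @param min_copies Minimum copy number.
#' @param min_unit_matches Minimum percent match of the locus to its tiled
#'   consensus.
#' @param min_len Minimum array length (nt) reported; plays the role of a
#'   minimum alignment score, suppressing 2-copy micro-arrays that saturate
#'   AT-rich sequence.
#' @return data.frame: start, end (1-based inclusive), period, copies
#'   (fractional), consensus, matches (percent).
#' @export
find_tandem_repeats <- function(genome, max_period = 200L, min_copies = 2,
                                min_unit_matches = 80, min_len = 24L) {
  s <- if (inherits(genome, "mitogenome")) genome$sequence else toupper(genome)
  cand <- tandem_scan_cpp(s, as.integer(max_period), as.integer(min_copies),
                          min_unit_matches / 100)
  cand <- data.frame(start = cand$start, end = cand$end, period = cand$period,
                     copies = (cand$end - cand$start + 1) / cand$period,
                     consensus = cand$consensus, matches = cand$matches,
                     stringsAsFactors = FALSE)
  cand <- cand[cand$matches >= min_unit_matches & cand$copies >= min_copies &
                 cand$end - cand$start + 1 >= min_len, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  # smallest period wins among candidates covering the same locus: harmonics
  # of a true period-p array (2p, 3p, ...) report near-identical loci
  cand <- cand[order(cand$period, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  ks <- integer(0); ke <- integer(0)
  for (i in seq_len(nrow(cand))) {
    len_i <- cand$end[i] - cand$start[i] + 1L
    ov <- if (length(ks))
      max(pmin(ke, cand$end[i]) - pmax(ks, cand$start[i]) + 1L) else 0L
    if (ov >= 0.5 * len_i) next
    keep[i] <- TRUE
    ks <- c(ks, cand$start[i]); ke <- c(ke, cand$end[i])
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize repeat content of a genome
#'
#' @param genome A [mitogenome()] or DNA string.
#' @param dispersed Output of [find_dispersed_repeats()].
#' @param tandem Output of [find_tandem_repeats()].
#' @return One-row data.frame: counts, longest lengths, and percent of the
#'   genome covered by the union of repeat loci.
#' @export
repeat_summary <- function(genome, dispersed, tandem) {
  L <- if (inherits(genome, "mitogenome")) genome$length else nchar(genome)
  ivs <- rbind(
    if (nrow(dispersed)) cbind(dispersed$start1, dispersed$end1),
    if (nrow(dispersed)) cbind(dispersed$start2, dispersed$end2),
    if (nrow(tandem)) cbind(tandem$start, tandem$end))
  union_len <- interval_union_length(ivs)
  data.frame(
    n_dispersed = nrow(dispersed),
    longest_dispersed = if (nrow(dispersed)) max(dispersed$length) else 0L,
    n_tandem = nrow(tandem),
    longest_tandem = if (nrow(tandem)) max(tandem$end - tandem$start + 1L) else 0L,
    repeat_percent = 100 * union_len / L)
}

# total length of the union of 1-based inclusive intervals
interval_union_length <- function(ivs) {
  if (is.null(ivs) || !nrow(ivs)) return(0L)
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  tot <- 0L; cur_s <- ivs[1, 1]; cur_e <- ivs[1, 2]
  for (i in seq_len(nrow(ivs))[-1]) {
    if (ivs[i, 1] <= cur_e + 1L) cur_e <- max(cur_e, ivs[i, 2])
    else { tot <- tot + cur_e - cur_s + 1L; cur_s <- ivs[i, 1]; cur_e <- ivs[i, 2] }
  }
  tot + cur_e - cur_s + 1L
}
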