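#' Extract the circular gene order of a genome
#'
#' The canonical markers (by default the 15 core protein-coding genes plus
#' rnl and rns) are sorted by start coordinate on the circle, the order is
#' rotated so that cox1 comes first, and if cox1 lies on the minus strand the
#' whole order is reflected and sign-flipped so that cox1 reads forward.
#'
#' @param genome A [mitogenome()].
#' @param markers Canonical marker set.
#' @return Object of class `gene_order`: character vector of signed labels
#'   (`"cox1"`, `"-nad4"`, ...), with attributes `species` and `missing`.
#' @export
extract_gene_order <- function(genome, markers = CORE_MARKERS) {
  kinds <- vapply(genome$features, `[[`, "", "kind")
  labels <- vapply(genome$features, `[[`, "", "gene")
  sel <- which(labels %in% markers & kinds %in% c("CDS", "rRNA"))
  labs <- labels[sel]
  if (anyDuplicated(labs))
    stop("duplicate canonical markers: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  starts <- vapply(genome$features[sel], feature_start, 1L)
  strands <- vapply(genome$features[sel], `[[`, "", "strand")
  o <- order(starts)
  labs <- labs[o]; strands <- strands[o]
  if ("cox1" %in% labs) {
    i <- which(labs == "cox1")
    idx <- c(i:length(labs), seq_len(i - 1L))
    labs <- labs[idx]; strands <- strands[idx]
    if (strands[1] == "-") {
      # reflect around cox1 and flip all strands
      labs <- c(labs[1], rev(labs[-1]))
      strands <- c("+", rev(ifelse(strands[-1] == "+", "-", "+")))
    }
  }
  out <- ifelse(strands == "-", paste0("-", labs), labs)
  structure(out, class = "gene_order", species = genome$species,
            missing = setdiff(markers, labs))
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s: %s\n", attr(x, "species"),
              paste(unclass(x), collapse = " ")))
  if (length(attr(x, "missing")))
    cat("  missing:", paste(attr(x, "missing"), collapse = ", "), "\n")
  invisible(x)
}

signed_name <- function(x) sub("^-", "", x)
signed_sign <- function(x) ifelse(grepl("^-", x), -1L, 1L)
negate_marker <- function(x) ifelse(grepl("^-", x), sub("^-", "", x),
                                    paste0("-", x))

# canonical signed circular adjacency set of an order
circular_adjacencies <- function(ord) {
  ord <- unclass(ord)
  n <- length(ord)
  nxt <- ord[c(2:n, 1)]
  adj <- paste(ord, nxt, sep = "|")
  # adjacency (a,b) is equivalent to (-b,-a); keep the lexicographically
  # smaller form
  alt <- paste(negate_marker(nxt), negate_marker(ord), sep = "|")
  pmin(adj, alt)
}

#' Signed circular breakpoint distance between two gene orders
#'
#' Number of signed adjacencies (on the shared marker set) present in `a`
#' but not in `b`. Zero iff the circular signed orders are identical up to
#' rotation and global strand flip.
#'
#' @param a,b [extract_gene_order()] results (or signed label vectors).
#' @return Integer distance.
#' @export
breakpoint_distance <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  shared <- intersect(signed_name(a), signed_name(b))
  if (length(shared) < 2L) stop("orders share fewer than 2 markers")
  a <- a[signed_name(a) %in% shared]
  b <- b[signed_name(b) %in% shared]
  aa <- circular_adjacencies(a)
  bb <- circular_adjacencies(b)
  sum(!aa %in% bb)
}

#' Group species by identical gene arrangement
#'
#' Equivalence classes under breakpoint distance zero.
#'
#' @param orders List of [extract_gene_order()] results.
#' @return List of character vectors of species names, largest group first.
#' @export
order_groups <- function(orders) {
  n <- length(orders)
  sp <- vapply(orders, function(o) attr(o, "species") %||% NA_character_, "")
  sp[is.na(sp)] <- paste0("order", which(is.na(sp)))
  grp <- integer(n)
  ng <- 0L
  for (i in seq_len(n)) {
    if (grp[i] > 0L) next
    ng <- ng + 1L
    grp[i] <- ng
    if (i < n) for (j in (i + 1L):n) {
      if (grp[j] == 0L && breakpoint_distance(orders[[i]], orders[[j]]) == 0L)
        grp[j] <- ng
    }
  }
  out <- split(sp, grp)
  out[order(-lengths(out))]
}

#' Find pairwise synteny blocks between two genomes
#'
#' Seed-chain-extend comparison on both strands; chained regions are
#' realigned and only blocks meeting the identity and length thresholds are
#' returned (gap-inclusive identity).
#'
#' @param a,b [mitogenome()] objects (or DNA strings).
#' @param min_identity Minimum percent identity.
#' @param min_len Minimum block length (nt).
#' @param seed_k Seed k-mer length.
#' @param max_gap Maximum seed gap when chaining.
#' @return data.frame: astart, aend, bstart, bend (1-based inclusive),
#'   strand, length, identity.
#' @export
find_synteny_blocks <- function(a, b, min_identity = 70, min_len = 500L,
                                seed_k = 16L, max_gap = 300L) {
  sa <- if (inherits(a, "mitogenome")) a$sequence else toupper(a)
  sb <- if (inherits(b, "mitogenome")) b$sequence else toupper(b)
  hits <- seed_matches(sa, sb, k = seed_k)
  empty <- data.frame(astart = integer(), aend = integer(),
                      bstart = integer(), bend = integer(),
                      strand = character(), length = integer(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (hits_empty(hits)) return(empty)
  ch <- chain_seeds(hits, seed_k, max_gap = max_gap)
  if (is.null(ch) || !nrow(ch)) return(empty)
  ch <- ch[pmin(ch$qend - ch$qstart, ch$send - ch$sstart) + 1L >= min_len, ,
           drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ch))) {
    r <- ch[i, ]
    ra <- substr(sa, r$qstart, r$qend)
    rb <- substr(sb, r$sstart, r$send)
    if (r$strand == "-") rb <- reverse_complement(rb)
    ident <- region_identity(ra, rb)
    if (!is.na(ident) && ident >= min_identity)
      out[[length(out) + 1L]] <- data.frame(
        astart = r$qstart, aend = r$qend, bstart = r$sstart, bend = r$send,
        strand = r$strand, length = max(nchar(ra), nchar(rb)),
        identity = ident, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$astart, res$bstart), , drop = FALSE]
}
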