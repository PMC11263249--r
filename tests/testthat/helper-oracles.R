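# independent adjacency-count oracle for signed circular gene orders
breakpoint_oracle <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  adj <- function(x) {
    n <- length(x)
    pairs <- cbind(x, x[c(2:n, 1)])
    apply(pairs, 1, function(p) {
      alt <- c(ifelse(grepl("^-", p[2]), sub("^-", "", p[2]),
                      paste0("-", p[2])),
               ifelse(grepl("^-", p[1]), sub("^-", "", p[1]),
                      paste0("-", p[1])))
      min(paste(p, collapse = "|"), paste(alt, collapse = "|"))
    })
  }
  sum(!adj(a) %in% adj(b))
}

# independent equivalence check: some rotation of b, or of its
# reversed-and-negated form, equals a
circular_equivalent <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) return(FALSE)
  rot <- function(x, i) x[c(i:length(x), seq_len(i - 1))[seq_along(x)]]
  flip <- function(x) rev(ifelse(grepl("^-", x), sub("^-", "", x),
                                 paste0("-", x)))
  for (i in seq_along(b)) {
    if (identical(a, rot(b, i))) return(TRUE)
    if (identical(a, rot(flip(b), i))) return(TRUE)
  }
  FALSE
}
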