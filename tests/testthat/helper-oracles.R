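# Independent oracles, deliberately naive and separate from the package's
# alignment/coloring code paths.

# Exhaustive affine-gap local alignment: O(n * m * (n + m)) dynamic program
# enumerating every gap length at every cell. A gap of length k costs
# open + k * ext.
naive_swg <- function(a, b, mat = default_matrix(), open = 11, ext = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0L || m == 0L) return(0)
  H <- matrix(0, n + 1L, m + 1L)
  for (i in 1:n) for (j in 1:m) {
    best <- max(0, H[i, j] + mat[av[i], bv[j]])
    if (i > 1L || TRUE)
      best <- max(best, max(H[1:i, j + 1L] - open - ext * (i:1)))
    best <- max(best, max(H[i + 1L, 1:j] - open - ext * (j:1)))
    H[i + 1L, j + 1L] <- best
  }
  max(H)
}

# Brute-force connected components by breadth-first search over the
# thresholded score matrix; returns a membership vector.
bf_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Two membership vectors describe the same partition?
same_partition <- function(x, y) {
  length(x) == length(y) &&
    all(outer(x, x, "==") == outer(y, y, "=="))
}

random_peptide <- function(len) {
  paste(sample(setdiff(aa_alphabet(), "X"), len, replace = TRUE),
        collapse = "")
}
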