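# Independent brute-force oracles used to validate the fast implementations.

rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# quadratic maximal exact repeat finder over all (anti)diagonals; linear
# sequences only; N never matches
bf_repeats <- function(seq, min_len = 30, direct = TRUE, inverted = TRUE) {
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  ok <- s %in% c("A", "C", "G", "T")
  hits <- list()
  add <- function(p1, p2, len, ori)
    hits[[length(hits) + 1]] <<- data.frame(
      pos1 = min(p1, p2), pos2 = max(p1, p2), length = len, orientation = ori,
      stringsAsFactors = FALSE)
  if (direct) {
    for (d in seq_len(L - 1)) {
      n <- L - d
      if (n < min_len) break
      m <- (s[seq_len(n)] == s[d + seq_len(n)]) & ok[seq_len(n)] & ok[d + seq_len(n)]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (i in which(r$values & r$lengths >= min_len))
        add(starts[i], starts[i] + d, r$lengths[i], "direct")
    }
  }
  if (inverted) {
    rbar <- strsplit(rc_chr(seq), "")[[1]]
    okr <- rev(ok)
    for (o in (-(L - 1)):(L - 1)) {
      ia <- max(1, 1 + o); ib <- min(L, L + o)
      n <- ib - ia + 1
      if (n < min_len) next
      si <- ia:ib; ri <- si - o
      m <- (s[si] == rbar[ri]) & ok[si] & okr[ri]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (i in which(r$values & r$lengths >= min_len)) {
        l <- r$lengths[i]
        p <- si[starts[i]]
        q <- L - (p - o) - l + 2
        add(p, q, l, "inverted")
      }
    }
  }
  if (!length(hits))
    return(data.frame(pos1 = integer(), pos2 = integer(), length = integer(),
                      orientation = character(), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$pos1, out$pos2, out$length, out$orientation), ]
  rownames(out) <- NULL
  out
}

# brute-force longest pair of disjoint inverted segments (linear coordinates)
bf_longest_inverted <- function(seq, min_len) {
  h <- bf_repeats(seq, min_len, direct = FALSE, inverted = TRUE)
  if (nrow(h) == 0) return(NULL)
  disj <- h$pos2 > h$pos1 + h$length - 1
  h <- h[disj, , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  h[order(-h$length, h$pos1), ][1, ]
}

# enumerate all signed permutations of 1..n
all_signed_perms <- function(n) {
  permute <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (r in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], r)
    out
  }
  ps <- permute(seq_len(n))
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  res <- matrix(0L, nrow = length(ps) * nrow(signs), ncol = n)
  k <- 1
  for (p in ps) for (si in seq_len(nrow(signs))) {
    res[k, ] <- as.integer(p * signs[si, ])
    k <- k + 1
  }
  res
}

random_signed_perm <- function(n)
  as.integer(sample(n) * sample(c(-1L, 1L), n, replace = TRUE))
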