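# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()]
#' that tolerates `N`.
#'
#' @param x Character vector of DNA strings (A, C, G, T, N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence at a given A+T fraction
#'
#' @param n Length in bp.
#' @param at_fraction Target A+T proportion (A and T equiprobable).
#' @return A single DNA string.
#' @export
random_dna <- function(n, at_fraction = 0.702) {
  stopifnot(n >= 0, at_fraction >= 0, at_fraction <= 1)
  if (n == 0) return("")
  p <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
         G = (1 - at_fraction) / 2, T = at_fraction / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# derive independent substream seeds from one top-level seed; kept < 2^31
seed_stream <- function(seed, stream) {
  (as.numeric(seed) * 1009 + stream * 9973) %% 2147483629
}

# circular position arithmetic (1-based)
mod1 <- function(x, L) ((x - 1) %% L) + 1

# is position x inside the circular interval starting at s with length len?
circ_inside <- function(x, s, len, L) ((x - s) %% L) < len

# circular arc length from just after a to just before b (exclusive ends)
circ_gap <- function(a, b, L) (b - a - 1) %% L

# sorted "k=v;k=v" serialization of a named list (deterministic round trips)
attrs_build <- function(x) {
  if (is.null(x) || length(x) == 0) return("")
  x <- x[order(names(x))]
  paste(paste0(names(x), "=", vapply(x, as.character, "")), collapse = ";")
}

attrs_parse <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) if (length(p) > 1) paste(p[-1], collapse = "=") else "")
  names(out) <- vapply(kv, `[`, "", 1)
  out
}

# uppercase, RNA->DNA, collapse everything outside {A,C,G,T} to N
normalize_dna <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGTN]", "N", x)
}
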