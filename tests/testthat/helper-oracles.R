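# Independent oracles and small generators used across the test files.

# Plain recursive Levenshtein: explores every edit script. Exponential,
# only for short words; deliberately independent of the package's
# dynamic-programming implementation.
lev_recursive <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- if (substr(a, 1, 1) == substr(b, 1, 1)) 0L else 1L
  min(lev_recursive(substr(a, 2, nchar(a)), b) + 1L,
      lev_recursive(a, substr(b, 2, nchar(b))) + 1L,
      lev_recursive(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost)
}

# Memoized variant of the same recursion, for slightly longer words.
lev_recursive_memo <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > length(av)) return(length(bv) - j + 1L)
    if (j > length(bv)) return(length(av) - i + 1L)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (av[i] == bv[j]) 0L else 1L
    val <- min(rec(i + 1L, j) + 1L, rec(i, j + 1L) + 1L,
               rec(i + 1L, j + 1L) + cost)
    memo[[key]] <- val
    val
  }
  rec(1L, 1L)
}

# Hamming distance for equal-length words (upper bound on Levenshtein).
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_tags <- function(k, n) {
  vapply(seq_len(k), function(i)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
}

# all words of the given length over an alphabet
all_words <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return("")
  g <- do.call(expand.grid, rep(list(alphabet), n))
  do.call(paste0, g)
}
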