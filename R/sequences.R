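# Internal tag representation helpers.
#
# Tags are plain uppercase character strings over {A,C,G,T} at the API
# surface; hot paths use an integer matrix (one row per tag, A=0, C=1,
# G=2, T=3) and a base-4 numeric encoding for O(1) membership tests.

#' Canonicalize and check tag sequences
#'
#' Upcases sequences and verifies that every residue is one of A, C, G, T.
#' IUPAC ambiguity codes (including N) are rejected: a tag is a concrete
#' synthesizable oligonucleotide, not a degenerate pattern.
#'
#' @param tags character vector of sequences (5' to 3').
#' @param require_equal_length if `TRUE`, all tags must share one length.
#' @return the canonicalized (uppercase) character vector, invisibly checked.
#' @examples
#' check_tags(c("acgt", "TTGA"))
#' @export
check_tags <- function(tags, require_equal_length = FALSE) {
  if (!is.character(tags) || length(tags) == 0L)
    stop("'tags' must be a non-empty character vector", call. = FALSE)
  tags <- toupper(tags)
  bad <- grepl("[^ACGT]", tags)
  if (any(bad))
    stop("invalid alphabet: sequences may only contain A, C, G, T (got ",
         paste(sQuote(head(tags[bad], 3L)), collapse = ", "), ")",
         call. = FALSE)
  if (any(nchar(tags) == 0L))
    stop("zero-length sequence", call. = FALSE)
  if (require_equal_length && length(unique(nchar(tags))) > 1L)
    stop("length mismatch: all tags in a set must share one length",
         call. = FALSE)
  tags
}

# character tags -> integer matrix (rows = tags), A=0 C=1 G=2 T=3
tags_to_mat <- function(tags) {
  n <- nchar(tags[1L])
  codes <- match(unlist(strsplit(tags, "", fixed = TRUE)), DNA_BASES) - 1L
  matrix(codes, nrow = length(tags), ncol = n, byrow = TRUE)
}

mat_to_tags <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  letters <- DNA_BASES[mat + 1L]
  dim(letters) <- dim(mat)
  do.call(paste0, lapply(seq_len(ncol(mat)), function(j) letters[, j]))
}

# base-4 numeric key per row (exact for n <= 26 in double precision)
encode_rows <- function(mat) {
  n <- ncol(mat)
  as.numeric(mat %*% 4^((n - 1L):0L))
}

# reverse complement on the integer matrix: complement (3 - x), reversed
revcomp_mat <- function(mat) {
  n <- ncol(mat)
  (3L - mat)[, n:1L, drop = FALSE]
}
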