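# Tag set input/output and the seeded fixture generator.

#' Read a tag set from file
#'
#' Reads FASTA (via Biostrings; record names preserved as tag names) or
#' plain one-sequence-per-line text. Sequences are upcased; any character
#' outside A/C/G/T — including N and other IUPAC ambiguity codes — is an
#' error, since a tag must be a concrete synthesizable sequence.
#'
#' @param path file to read.
#' @param format `"auto"` (FASTA when the file starts with `>`),
#'   `"fasta"`, or `"lines"`.
#' @param profile optional [constraint_profile()] to attach to the set.
#' @return a [tag_set()].
#' @export
read_tagset <- function(path, format = c("auto", "fasta", "lines"),
                        profile = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (length(first) && startsWith(first, ">")) "fasta" else "lines"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path)  # BString: keep raw characters
    tags <- as.character(seqs)
    nms <- names(seqs)
  } else {
    tags <- readLines(path)
    tags <- tags[nzchar(trimws(tags))]
    tags <- trimws(tags)
    nms <- NULL
  }
  if (length(tags) == 0L) stop("empty file: ", path, call. = FALSE)
  tags <- check_tags(tags, require_equal_length = TRUE)
  s <- tag_set(tags, profile)
  if (!is.null(nms)) names(s$tags) <- nms
  s
}

#' Write a tag set to file
#'
#' FASTA records are named `tag_0001`, `tag_0002`, ... unless the set
#' carries names. The TSV format adds per-tag GC percentage, longest
#' homopolymer run and nearest-neighbor Tm. Output is byte-deterministic
#' for a fixed set (no timestamps), and `read_tagset()` round-trips the
#' FASTA and lines formats exactly.
#'
#' @param S a [tag_set()] or character vector.
#' @param path output file.
#' @param format `"fasta"`, `"lines"`, or `"tsv"`.
#' @param model a [thermo_model()] (used for the TSV Tm column).
#' @return `path`, invisibly.
#' @export
write_tagset <- function(S, path, format = c("fasta", "lines", "tsv"),
                         model = thermo_model()) {
  format <- match.arg(format)
  S <- as_tag_set(S)
  tags <- S$tags
  nms <- names(tags)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- sprintf("tag_%04d", seq_along(tags))
  if (format == "fasta") {
    writeLines(paste0(">", nms, "\n", unname(tags)), path)
  } else if (format == "lines") {
    writeLines(unname(tags), path)
  } else {
    df <- data.frame(name = nms, sequence = unname(tags),
                     gc_percent = gc_content(unname(tags)),
                     longest_run = longest_run(unname(tags)),
                     tm_celsius = round(melting_temperature(unname(tags),
                                                            model), 4))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Generate a random tag set fixture
#'
#' Rejection-samples `m` distinct random tags satisfying the single-tag
#' rules of the profile (GC, homopolymer cap, self-complementarity). The
#' pairwise distance rule is only enforced when `enforce_distance = TRUE`
#' (greedy filtering, which may need many attempts for tight profiles).
#' A planted violation can be injected to exercise validators: the
#' reverse complement of an existing member (`"cross_complement"`) or a
#' duplicated member (`"duplicate"`).
#'
#' @param n tag length.
#' @param m number of tags.
#' @param profile a [constraint_profile()] supplying the single-tag rules.
#' @param seed integer seed; the fixture is reproducible.
#' @param enforce_distance also enforce pairwise edit distance >= d.
#' @param plant `"none"`, `"cross_complement"` or `"duplicate"`.
#' @param max_tries attempts before giving up with an error.
#' @return a [tag_set()] (the planted variants are returned as plain
#'   character vectors since they violate tag-set invariants).
#' @export
generate_fixture_set <- function(n, m, profile = constraint_profile(1),
                                 seed = 1, enforce_distance = FALSE,
                                 plant = c("none", "cross_complement",
                                           "duplicate"),
                                 max_tries = 10000 * m) {
  plant <- match.arg(plant)
  set.seed(seed)
  n <- as.integer(n)
  kept <- character(0)
  tries <- 0L
  while (length(kept) < m && tries < max_tries) {
    tries <- tries + 1L
    cand <- paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
    mat <- tags_to_mat(cand)
    if (!single_tag_ok_mat(mat, profile)) next
    if (cand %in% kept) next
    if (enforce_distance && length(kept) > 0L &&
        tte(cand, kept) < profile$d) next
    if (profile$complementarity == "cross" &&
        reverse_complement(cand) %in% kept) next
    kept <- c(kept, cand)
  }
  if (length(kept) < m)
    stop("could not assemble ", m, " tags after ", max_tries,
         " attempts; the requested rules may be infeasible", call. = FALSE)
  if (plant == "cross_complement") {
    rc <- reverse_complement(kept[1L])
    return(c(kept, rc))
  }
  if (plant == "duplicate") return(c(kept, kept[1L]))
  tag_set(kept, profile)
}
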