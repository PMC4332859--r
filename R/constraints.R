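# Constraint mathematics for DNA tag sets: edit distance, tag-tag edit
# distance (TTE), GC content, homopolymer continuity, and the two
# reverse-complement exclusion rules.

#' Constraint profile for a tag set
#'
#' Bundles the criteria a tag set must satisfy: the minimum pairwise edit
#' distance `d`, a GC rule, a homopolymer cap, and a complementarity rule.
#'
#' Two GC modes are supported. `"range"` keeps the GC percentage of every
#' tag inside `[gc_min, gc_max]` (inclusive), the loose window used by most
#' barcode designers. `"fixed"` pins the number of G/C bases of every tag to
#' exactly `gc_fixed_count` (default `floor(n/2)`, resolved when the tag
#' length is known), which holds melting temperatures in a much narrower
#' band. `"off"` disables the GC rule.
#'
#' Complementarity `"self"` forbids tags equal to their own reverse
#' complement (self-hybridizing palindromes). `"cross"` additionally forbids
#' any tag equal to the reverse complement of any other tag in the set;
#' the self rule is the diagonal case of the cross rule, so `"cross"`
#' implies `"self"`.
#'
#' @param d minimum pairwise edit distance (positive integer).
#' @param gc_mode one of `"range"`, `"fixed"`, `"off"`.
#' @param gc_min,gc_max GC percentage bounds for `gc_mode = "range"`.
#' @param gc_fixed_count exact number of G/C bases for `gc_mode = "fixed"`;
#'   `NULL` means `floor(n/2)` for tag length n.
#' @param continuity_max maximum allowed homopolymer run length.
#' @param complementarity one of `"none"`, `"self"`, `"cross"`.
#' @return an object of class `"constraint_profile"`.
#' @examples
#' constraint_profile(d = 3)
#' constraint_profile(d = 4, gc_mode = "fixed", complementarity = "cross")
#' @export
constraint_profile <- function(d,
                               gc_mode = c("range", "fixed", "off"),
                               gc_min = 40, gc_max = 60,
                               gc_fixed_count = NULL,
                               continuity_max = 2,
                               complementarity = c("self", "none", "cross")) {
  gc_mode <- match.arg(gc_mode)
  complementarity <- match.arg(complementarity)
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("'d' must be a positive integer", call. = FALSE)
  if (!(gc_min >= 0 && gc_min <= gc_max && gc_max <= 100))
    stop("need 0 <= gc_min <= gc_max <= 100", call. = FALSE)
  if (!is.null(gc_fixed_count)) {
    gc_fixed_count <- as.integer(gc_fixed_count)
    if (is.na(gc_fixed_count) || gc_fixed_count < 0L)
      stop("'gc_fixed_count' must be a non-negative integer", call. = FALSE)
  }
  continuity_max <- as.integer(continuity_max)
  if (is.na(continuity_max) || continuity_max < 1L)
    stop("'continuity_max' must be >= 1", call. = FALSE)
  structure(
    list(d = d, gc_mode = gc_mode, gc_min = gc_min, gc_max = gc_max,
         gc_fixed_count = gc_fixed_count, continuity_max = continuity_max,
         complementarity = complementarity),
    class = "constraint_profile")
}

#' @export
print.constraint_profile <- function(x, ...) {
  gc <- switch(x$gc_mode,
    range = sprintf("%g%% <= GC <= %g%%", x$gc_min, x$gc_max),
    fixed = sprintf("exactly %s G/C bases",
                    if (is.null(x$gc_fixed_count)) "floor(n/2)"
                    else x$gc_fixed_count),
    off   = "off")
  cat("Constraint profile\n",
      "  min edit distance d : ", x$d, "\n",
      "  GC rule             : ", gc, "\n",
      "  max homopolymer run : ", x$continuity_max, "\n",
      "  complementarity     : ", x$complementarity, "\n", sep = "")
  invisible(x)
}

# resolve the fixed G/C count for tag length n
resolve_gc_count <- function(profile, n) {
  if (!is.null(profile$gc_fixed_count)) profile$gc_fixed_count
  else n %/% 2L
}

#' Published-table constraint profiles
#'
#' Convenience constructors for the three constraint bundles used in the
#' design experiments: `"range_gc"` (GC window 40-60%, homopolymer cap 2,
#' self-complementary tags excluded), `"fixed_gc"` (exactly `floor(n/2)`
#' G/C bases, otherwise as `"range_gc"`) and `"cross_comp"` (fixed GC plus
#' the cross-tag reverse-complement exclusion).
#'
#' @param which profile template name.
#' @param d minimum pairwise edit distance.
#' @return a [constraint_profile()].
#' @export
design_profile <- function(which = c("range_gc", "fixed_gc", "cross_comp"), d) {
  which <- match.arg(which)
  switch(which,
    range_gc   = constraint_profile(d, gc_mode = "range",
                                    complementarity = "self"),
    fixed_gc   = constraint_profile(d, gc_mode = "fixed",
                                    complementarity = "self"),
    cross_comp = constraint_profile(d, gc_mode = "fixed",
                                    complementarity = "cross"))
}

#' Construct a tag set
#'
#' A tag set is an ordered collection of distinct, equal-length DNA tags
#' together with the constraint profile it is meant to satisfy. The
#' constructor checks alphabet, length agreement and duplicates only;
#' [validate_set()] checks the constraints themselves.
#'
#' @param tags character vector of tag sequences.
#' @param profile a [constraint_profile()], or `NULL`.
#' @return an object of class `"tag_set"`.
#' @examples
#' tag_set(c("ACTG", "CAGT", "GAGT"), constraint_profile(d = 1))
#' @export
tag_set <- function(tags, profile = NULL) {
  tags <- check_tags(tags, require_equal_length = TRUE)
  if (anyDuplicated(tags))
    stop("duplicate tags in set", call. = FALSE)
  if (!is.null(profile) && !inherits(profile, "constraint_profile"))
    stop("'profile' must be a constraint_profile", call. = FALSE)
  structure(list(tags = tags, n = nchar(tags[1L]), profile = profile),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat("Tag set: ", length(x$tags), " tags of length ", x$n, "\n", sep = "")
  shown <- head(x$tags, 6L)
  cat("  ", paste(shown, collapse = " "),
      if (length(x$tags) > 6L) " ..." else "", "\n", sep = "")
  if (!is.null(x$profile)) print(x$profile)
  invisible(x)
}

#' @export
length.tag_set <- function(x) length(x$tags)

as_tag_set <- function(x, profile = NULL) {
  if (inherits(x, "tag_set")) {
    if (!is.null(profile)) x$profile <- profile
    return(x)
  }
  tag_set(x, profile)
}

#' Levenshtein edit distance between two sequences
#'
#' Minimum number of single-character insertions, deletions or
#' substitutions transforming `u` into `v`, computed by unit-cost dynamic
#' programming. The metric does not require equal lengths.
#'
#' @param u,v DNA sequences (character scalars over A/C/G/T).
#' @return a non-negative integer.
#' @examples
#' edit_distance("ACTG", "CAGT")  # 3
#' edit_distance("CAGT", "GAGT")  # 1
#' @export
edit_distance <- function(u, v) {
  u <- check_tags(u); v <- check_tags(v)
  edit_dist_pair_cpp(tags_to_mat(u)[1L, ], tags_to_mat(v)[1L, ])
}

#' Pairwise edit distance matrix
#'
#' @param x,y character vectors of sequences; `y` defaults to `x`.
#' @return integer matrix of distances, `length(x)` by `length(y)`.
#' @export
edit_distance_matrix <- function(x, y = x) {
  x <- check_tags(x); y <- check_tags(y)
  m <- edit_dist_cross_cpp(tags_to_mat(x), tags_to_mat(y))
  dimnames(m) <- list(x, y)
  m
}

#' Tag-tag edit distance (TTE)
#'
#' The minimum edit distance from `u` to any member of the set distinct
#' from `u`. When the set is empty, or contains `u` and nothing else, the
#' minimum is vacuous and `Inf` is returned: such a tag is unconstrained
#' and acceptable at any distance threshold.
#'
#' @param u a DNA sequence.
#' @param S a [tag_set()] or character vector of tags (may be empty).
#' @return a non-negative number, possibly `Inf`.
#' @examples
#' tte("ACTG", c("ACTG", "CAGT", "GAGT"))  # 3
#' tte("CAGT", c("ACTG", "CAGT", "GAGT"))  # 1
#' @export
tte <- function(u, S) {
  u <- check_tags(u)
  tags <- if (inherits(S, "tag_set")) S$tags else
    if (length(S) == 0L) character(0) else check_tags(S)
  if (length(tags) == 0L) return(Inf)
  v <- tte_cpp(tags_to_mat(u), tags_to_mat(tags))[1L]
  if (is.na(v)) Inf else as.numeric(v)
}

#' GC content of a sequence
#'
#' @param u DNA sequence(s); vectorized.
#' @return percentage of G or C bases, in `[0, 100]`.
#' @examples
#' gc_content("ACTG")  # 50
#' @export
gc_content <- function(u) {
  u <- check_tags(u)
  m <- tags_to_mat(u)
  if (length(unique(nchar(u))) > 1L)
    return(vapply(u, function(s) gc_content(s), numeric(1), USE.NAMES = FALSE))
  100 * rowSums(m == 1L | m == 2L) / ncol(m)
}

#' Does a tag satisfy the profile's GC rule?
#'
#' @param u DNA sequence(s); vectorized.
#' @param profile a [constraint_profile()].
#' @return logical vector.
#' @export
gc_satisfied <- function(u, profile) {
  u <- check_tags(u)
  m <- tags_to_mat(u)
  gc_rule_mat(m, profile)
}

# vectorized GC rule on the integer matrix
gc_rule_mat <- function(mat, profile) {
  switch(profile$gc_mode,
    off = rep(TRUE, nrow(mat)),
    range = {
      pct <- 100 * rowSums(mat == 1L | mat == 2L) / ncol(mat)
      pct >= profile$gc_min - 1e-9 & pct <= profile$gc_max + 1e-9
    },
    fixed = {
      k <- resolve_gc_count(profile, ncol(mat))
      rowSums(mat == 1L | mat == 2L) == k
    })
}

#' Longest homopolymer run in a sequence
#'
#' @param u DNA sequence(s); vectorized over equal-length input.
#' @return length of the longest maximal run of one repeated base.
#' @examples
#' longest_run("AATGC")   # 2
#' longest_run("AAATTG")  # 3
#' @export
longest_run <- function(u) {
  u <- check_tags(u)
  if (length(unique(nchar(u))) > 1L)
    return(vapply(u, function(s) longest_run(s), integer(1), USE.NAMES = FALSE))
  longest_run_cpp(tags_to_mat(u))
}

#' Continuity of a tag set
#'
#' The maximum homopolymer run length over all members. Long runs of one
#' base destabilize the DNA structure and inflate sequencing error, so
#' designed sets cap this value (typically at 2).
#'
#' @param S a [tag_set()] or character vector; must be non-empty.
#' @return a positive integer.
#' @examples
#' continuity(c("AATGC", "AAATTG", "TCGTCA"))  # 3
#' @export
continuity <- function(S) {
  tags <- if (inherits(S, "tag_set")) S$tags else S
  if (length(tags) == 0L) stop("empty set has no continuity", call. = FALSE)
  max(longest_run(check_tags(tags)))
}

#' Reverse complement
#'
#' Watson-Crick complement of the sequence, written 5' to 3' (complement
#' each base, then reverse). Involutive. Backed by Biostrings.
#'
#' @param u DNA sequence(s); vectorized.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("GTCAA")  # "TTGAC"
#' reverse_complement("AATT")   # "AATT"
#' @export
reverse_complement <- function(u) {
  u <- check_tags(u)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(u)))
}

#' Is a tag its own reverse complement?
#'
#' Palindromic (self-complementary) tags can fold back or dimerize with
#' themselves and are excluded under the `"self"` and `"cross"`
#' complementarity modes. Only even-length words can be self-complementary.
#'
#' @param u DNA sequence(s); vectorized.
#' @return logical vector.
#' @examples
#' is_self_complementary("AATT")   # TRUE
#' is_self_complementary("GTCAA")  # FALSE
#' @export
is_self_complementary <- function(u) {
  u <- check_tags(u)
  u == reverse_complement(u)
}

#' Cross-complement violations within a set
#'
#' Finds every ordered pair (u, v) of set members, including u = v, with
#' u equal to the reverse complement of v. Any such pair can hybridize in
#' a pooled reaction, so a set satisfying the cross-complementarity
#' constraint yields an empty result.
#'
#' @param S a [tag_set()] or character vector.
#' @return a data.frame with columns `tag` and `complement_of` (zero rows
#'   when the constraint holds).
#' @examples
#' cross_complement_violations(c("GTCAA", "TTGAC"))
#' @export
cross_complement_violations <- function(S) {
  tags <- if (inherits(S, "tag_set")) S$tags else check_tags(S)
  if (length(tags) == 0L)
    return(data.frame(tag = character(0), complement_of = character(0)))
  rc <- reverse_complement(tags)
  hit <- outer(tags, rc, "==")
  idx <- which(hit, arr.ind = TRUE)
  data.frame(tag = tags[idx[, 1L]], complement_of = tags[idx[, 2L]],
             stringsAsFactors = FALSE)
}

# single-tag rules of a profile on the integer matrix; returns logical vector
single_tag_ok_mat <- function(mat, profile) {
  ok <- gc_rule_mat(mat, profile)
  ok <- ok & (longest_run_cpp(mat) <= profile$continuity_max)
  if (profile$complementarity %in% c("self", "cross")) {
    rc <- revcomp_mat(mat)
    ok <- ok & (rowSums(rc != mat) > 0L)
  }
  ok
}

#' Validate a candidate tag against a set
#'
#' Checks every rule of the profile for admitting `u` into the set `S`:
#' tag-tag edit distance at least `d`, the GC rule, the homopolymer cap,
#' the complementarity rules, and non-duplication.
#'
#' @param u a DNA sequence.
#' @param S a [tag_set()] or character vector (the current, valid set).
#' @param profile a [constraint_profile()].
#' @return a list with `ok` (logical) and `reasons` (character vector of
#'   codes among `"distance"`, `"gc"`, `"continuity"`, `"self_complement"`,
#'   `"cross_complement"`, `"duplicate"`; empty when `ok`).
#' @export
validate_tag <- function(u, S, profile) {
  u <- check_tags(u)
  tags <- if (inherits(S, "tag_set")) S$tags else
    if (length(S) == 0L) character(0) else check_tags(S)
  if (length(tags) > 0L && nchar(u) != nchar(tags[1L]))
    stop("length mismatch: candidate length ", nchar(u),
         " vs set length ", nchar(tags[1L]), call. = FALSE)
  reasons <- character(0)
  if (u %in% tags) reasons <- c(reasons, "duplicate")
  if (is.finite(profile$d) && tte(u, tags) < profile$d)
    reasons <- c(reasons, "distance")
  if (!gc_satisfied(u, profile)) reasons <- c(reasons, "gc")
  if (longest_run(u) > profile$continuity_max)
    reasons <- c(reasons, "continuity")
  if (profile$complementarity %in% c("self", "cross") &&
      is_self_complementary(u))
    reasons <- c(reasons, "self_complement")
  if (profile$complementarity == "cross" && length(tags) > 0L &&
      reverse_complement(u) %in% tags)
    reasons <- c(reasons, "cross_complement")
  list(ok = length(reasons) == 0L, reasons = reasons)
}

#' Validate a whole tag set against a profile
#'
#' Independent closure check: recomputes the minimum pairwise edit
#' distance, per-tag GC compliance, the set continuity and all
#' complementarity violations, and reports overall pass/fail. Every set
#' emitted by the designers in this package passes its own profile.
#'
#' @param S a [tag_set()] or character vector of tags.
#' @param profile a [constraint_profile()]; defaults to the profile stored
#'   in `S`.
#' @return an object of class `"tag_set_report"`: a list with fields
#'   `pass`, `min_pairwise_distance`, `gc_ok`, `continuity`,
#'   `self_complementary`, `cross_violations`, `duplicated`.
#' @export
validate_set <- function(S, profile = NULL) {
  S <- as_tag_set(S, profile)
  profile <- S$profile
  if (is.null(profile)) stop("no constraint profile supplied", call. = FALSE)
  tags <- S$tags
  m <- length(tags)
  mat <- tags_to_mat(tags)
  min_d <- if (m < 2L) Inf else {
    dm <- edit_dist_cross_cpp(mat, mat)
    min(dm[upper.tri(dm)])
  }
  gc_ok <- gc_rule_mat(mat, profile)
  cont <- max(longest_run_cpp(mat))
  selfc <- is_self_complementary(tags)
  crossv <- cross_complement_violations(tags)
  dup <- tags[duplicated(tags)]
  pass <- (min_d >= profile$d) && all(gc_ok) &&
    (cont <= profile$continuity_max) && length(dup) == 0L
  if (profile$complementarity %in% c("self", "cross"))
    pass <- pass && !any(selfc)
  if (profile$complementarity == "cross")
    pass <- pass && nrow(crossv) == 0L
  structure(
    list(pass = pass, min_pairwise_distance = min_d, gc_ok = gc_ok,
         continuity = cont, self_complementary = selfc,
         cross_violations = crossv, duplicated = dup,
         n_tags = m, profile = profile),
    class = "tag_set_report")
}

#' @export
print.tag_set_report <- function(x, ...) {
  cat("Tag set validation: ", if (x$pass) "PASS" else "FAIL", "\n",
      "  tags                  : ", x$n_tags, "\n",
      "  min pairwise distance : ", x$min_pairwise_distance,
      " (required >= ", x$profile$d, ")\n",
      "  GC rule violations    : ", sum(!x$gc_ok), "\n",
      "  continuity            : ", x$continuity,
      " (max ", x$profile$continuity_max, ")\n",
      "  self-complementary    : ", sum(x$self_complementary), "\n",
      "  cross-complement pairs: ", nrow(x$cross_violations), "\n",
      sep = "")
  invisible(x)
}
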