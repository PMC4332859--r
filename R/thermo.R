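# Nearest-neighbor melting temperature and the Tm-gap set quality metric.

#' Nearest-neighbor thermodynamic model
#'
#' Loads a nearest-neighbor parameter table (duplex formation enthalpy and
#' entropy per dinucleotide stack, plus terminal initiation terms) together
#' with the reaction conditions used for melting-temperature prediction.
#' The packaged default is the unified oligonucleotide parameter set at
#' 1 M NaCl reference conditions.
#'
#' The two-state Tm of a non-self-complementary duplex is
#' \deqn{T_m = \Delta H / (\Delta S + R \ln(C_T/4)) - 273.15}
#' with \eqn{\Delta H} in cal/mol summed over the stacks of the sequence
#' plus initiation terms, \eqn{R = 1.987} cal/(mol K), and \eqn{C_T} the
#' total strand concentration. The entropy is salt-corrected by
#' \eqn{0.368 (n-1) \ln[\mathrm{Na^+}]} cal/(mol K) for an n-mer.
#'
#' @param strand_conc total strand concentration C_T in mol/L.
#' @param na_conc monovalent Na+ concentration in mol/L.
#' @param param_path path to a JSON parameter file; defaults to the
#'   packaged unified table. The file maps each of the 10 unique
#'   Watson-Crick stacks to `[dH (kcal/mol), dS (cal/(mol K))]` and gives
#'   `initiation` terms for G.C and A.T terminal pairs.
#' @return an object of class `"thermo_model"`.
#' @examples
#' thermo_model()
#' @export
thermo_model <- function(strand_conc = 0.25e-6, na_conc = 0.05,
                         param_path = NULL) {
  if (strand_conc <= 0) stop("'strand_conc' must be > 0", call. = FALSE)
  if (na_conc <= 0) stop("'na_conc' must be > 0", call. = FALSE)
  if (is.null(param_path))
    param_path <- system.file("extdata", "nn_unified.json",
                              package = "edittags", mustWork = TRUE)
  p <- jsonlite::read_json(param_path, simplifyVector = TRUE)
  stacks <- p$stacks
  need <- c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG")
  if (!all(need %in% names(stacks)))
    stop("parameter table must define the 10 unique stacks: missing ",
         paste(setdiff(need, names(stacks)), collapse = ", "), call. = FALSE)
  # expand to all 16 dinucleotides via reverse-complement equivalence
  all16 <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  full <- lapply(setNames(all16, all16), function(s) {
    if (s %in% names(stacks)) stacks[[s]]
    else stacks[[reverse_complement(s)]]
  })
  structure(
    list(stacks = full, initiation = p$initiation,
         strand_conc = strand_conc, na_conc = na_conc,
         R = 1.987, param_path = param_path),
    class = "thermo_model")
}

#' @export
print.thermo_model <- function(x, ...) {
  cat("Nearest-neighbor thermodynamic model\n",
      "  strand concentration C_T : ", format(x$strand_conc), " M\n",
      "  [Na+]                    : ", format(x$na_conc), " M\n",
      "  parameter file           : ", basename(x$param_path), "\n", sep = "")
  invisible(x)
}

#' Nearest-neighbor melting temperature of a tag
#'
#' Predicted two-state melting temperature of the tag hybridized to its
#' perfect complement, in degrees Celsius. Uses the `C_T/4` form for
#' non-self-complementary duplexes; valid designed sets contain no
#' self-complementary tags, so a warning is emitted if one is scored
#' (its true Tm would use `C_T` instead).
#'
#' @param u DNA sequence(s) of length >= 2; vectorized.
#' @param model a [thermo_model()].
#' @return numeric vector of temperatures in degrees C.
#' @examples
#' model <- thermo_model()
#' melting_temperature("GCGCGC", model) > melting_temperature("ATATAT", model)
#' @export
melting_temperature <- function(u, model = thermo_model()) {
  u <- check_tags(u)
  if (any(nchar(u) < 2L))
    stop("sequence too short for the nearest-neighbor model (need >= 2 nt)",
         call. = FALSE)
  if (any(is_self_complementary(u)))
    warning("self-complementary tag scored with the C_T/4 two-state form; ",
            "its duplex is self-pairing and the value is approximate",
            call. = FALSE)
  vapply(u, function(s) {
    n <- nchar(s)
    di <- substring(s, 1:(n - 1L), 2:n)
    dh <- sum(vapply(model$stacks[di], `[`, numeric(1), 1L))   # kcal/mol
    ds <- sum(vapply(model$stacks[di], `[`, numeric(1), 2L))   # cal/(mol K)
    ends <- substring(s, c(1L, n), c(1L, n))
    for (e in ends) {
      key <- if (e %in% c("G", "C")) "GC" else "AT"
      dh <- dh + model$initiation[[key]][1L]
      ds <- ds + model$initiation[[key]][2L]
    }
    ds <- ds + 0.368 * (n - 1L) * log(model$na_conc)
    1000 * dh / (ds + model$R * log(model$strand_conc / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Melting-temperature gap of a tag set
#'
#' The absolute difference between the largest and smallest nearest-
#' neighbor melting temperature over the members of the set. Tags in a
#' pooled hybridization behave most uniformly when this gap is small, so
#' a smaller Tm gap indicates a better set.
#'
#' @param S a [tag_set()] or character vector; non-empty, tags >= 2 nt.
#' @param model a [thermo_model()].
#' @return a non-negative temperature difference in degrees C.
#' @examples
#' tm_gap(c("ACGTAC", "GGATCA"), thermo_model())
#' @export
tm_gap <- function(S, model = thermo_model()) {
  tags <- if (inherits(S, "tag_set")) S$tags else S
  if (length(tags) == 0L) stop("empty set has no Tm gap", call. = FALSE)
  tm <- melting_temperature(tags, model)
  abs(max(tm) - min(tm))
}
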