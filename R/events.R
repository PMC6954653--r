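#' The ISCN structural event taxonomy
#'
#' The closed set of 19 ISCN change abbreviations the model represents,
#' with their display names. Whole-chromosome gains and losses (`+c`/`-c`)
#' are modelled separately as numerical `gain`/`loss` events.
#'
#' @return data.frame with columns `abbreviation`, `name`, `n_chromosomes`
#'   (allowed chromosome-group arity), `band_level` (whether the event
#'   carries breakpoints).
#' @export
event_kinds <- function() {
  data.frame(
    abbreviation = c("add", "del", "der", "dic", "dup", "fis", "fra", "hsr",
                     "ins", "inv", "i", "mar", "neo", "qdp", "r", "tas", "t",
                     "trc", "trp"),
    name = c("Addition", "Deletion", "Derivative Chromosome",
             "Dicentric Chromosome", "Duplication", "Fission", "Fragile Site",
             "Homogeneously Staining Region", "Insertion", "Inversion",
             "Isochromosome", "Marker Chromosome", "Neocentromere",
             "Quadruplication", "Ring Chromosome", "Telomeric Association",
             "Translocation", "Tricentric Chromosome", "Triplication"),
    n_chromosomes = c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L,
                      NA, 1L, 1L, 0L, 1L, 1L, 1L, 2L, 2L,
                      3L, 1L),  # NA: ins takes 1 or 2
    band_level = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# kinds that carry breakpoints and so can be drawn by the generator
band_level_kinds <- function() {
  k <- event_kinds()
  k$abbreviation[k$band_level]
}

# chromosome-count delta per event occurrence (ISCN convention; see vignette)
event_count_delta <- function(kind) {
  switch(kind,
         gain = 1L, loss = -1L,
         fis = 1L, dic = -1L, tas = -1L, trc = -2L, mar = 1L,
         del = NA_integer_,  # resolved by level at the call site
         0L)
}

new_event <- function(kind, level, chromosomes, breakpoints = character(0),
                      multiplicity = 1L, constituents = NULL, field = NULL,
                      implicit = FALSE) {
  structure(
    list(kind = kind, level = level, chromosomes = chromosomes,
         breakpoints = breakpoints, multiplicity = as.integer(multiplicity),
         constituents = constituents, field = field, implicit = implicit),
    class = "iscn_event"
  )
}

#' @export
print.iscn_event <- function(x, ...) {
  cat(sprintf("<event> %s%s\n", x$field %||% x$kind,
              if (x$multiplicity > 1L) sprintf(" x%d", x$multiplicity) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# count delta of one event (times its multiplicity)
event_delta <- function(e) {
  d <- event_count_delta(e$kind)
  if (is.na(d)) d <- if (e$level == "chromosome") -1L else 0L
  d * e$multiplicity
}
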