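# Defined karyotype classes as decision procedures. Each class is a named
# membership predicate plus its parents in the subsumption lattice; queries
# that a description-logic reasoner would answer by classification are
# answered here by predicate evaluation and lattice reachability.

structural_class_name <- function(kind) {
  kinds <- event_kinds()
  nm <- kinds$name[kinds$abbreviation == kind]
  paste0("StructuralAbnormal", gsub(" ", "", nm))
}

build_registry <- function() {
  classes <- list()
  def <- function(name, predicate, parents = character(0)) {
    classes[[name]] <<- list(name = name, predicate = predicate,
                             parents = parents)
  }

  for (p in 1:4) {
    nm <- c("HaploidKaryotype", "DiploidKaryotype", "TriploidKaryotype",
            "TetraploidKaryotype")[p]
    local({
      pp <- p
      def(nm, function(k) k$base$ploidy == pp)
    })
  }

  def("MaleKaryotype", function(k) sex_of(k) == "male")
  def("FemaleKaryotype", function(k) sex_of(k) == "female")

  is_numerical <- function(k) {
    any(vapply(k$events, function(e) {
      e$kind %in% c("gain", "loss") ||
        (e$kind == "del" && e$level == "chromosome")
    }, logical(1)))
  }
  def("NumericalAbnormalKaryotype", is_numerical)

  autosomes <- as.character(1:22)
  allosomes <- c("X", "Y", "N")
  def("NumericalAbnormalAutosomalGain",
      function(k) any(vapply(autosomes, function(c) numerical_delta(k, c) > 0L,
                             logical(1))),
      parents = "NumericalAbnormalKaryotype")
  def("NumericalAbnormalAutosomalLoss",
      function(k) any(vapply(autosomes, function(c) numerical_delta(k, c) < 0L,
                             logical(1))),
      parents = "NumericalAbnormalKaryotype")
  def("NumericalAbnormalAllosomalGain",
      function(k) any(vapply(allosomes, function(c) numerical_delta(k, c) > 0L,
                             logical(1))),
      parents = "NumericalAbnormalKaryotype")
  def("NumericalAbnormalAllosomalLoss",
      function(k) any(vapply(allosomes, function(c) numerical_delta(k, c) < 0L,
                             logical(1))),
      parents = "NumericalAbnormalKaryotype")

  def("StructuralAbnormalKaryotype",
      function(k) any(vapply(k$events, function(e) e$level == "band",
                             logical(1))))
  for (kind in band_level_kinds()) {
    local({
      kk <- kind
      def(structural_class_name(kk),
          function(k) kk %in% flat_event_kinds(k),
          parents = "StructuralAbnormalKaryotype")
    })
  }

  classes
}

the_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_registry()
    cache
  }
})

#' The defined-class registry
#'
#' Ploidy classes (haploid through tetraploid), derivation-based sex
#' classes, numerical-abnormality classes (any whole-chromosome gain/loss,
#' with autosomal/allosomal gain/loss sub-classes) and structural
#' abnormality with one sub-class per band-level event kind.
#'
#' @return named list of classes, each with `name`, `predicate`, `parents`.
#' @examples
#' length(class_registry())  # >= 17
#' @export
class_registry <- function() the_registry()

get_class <- function(c) {
  if (is.list(c) && !is.null(c$predicate)) return(c)
  reg <- class_registry()
  if (is.character(c) && length(c) == 1L && c %in% names(reg)) return(reg[[c]])
  iscn_stop(sprintf("unknown defined class '%s'", c), "iscn_lookup_error")
}

#' Sex of a karyotype, by derivation
#'
#' A karyotype is male iff its base complement is the normal male one
#' (contains a Y and no unknown allosome), female iff the base is all-X.
#' A base containing `N` — an allosome of unknown kind, as in 45,X read as
#' derived from 46,XN — is neither, and returns `"undetermined"`.
#'
#' @param k a `karyotype`.
#' @return `"male"`, `"female"` or `"undetermined"`.
#' @examples
#' sex_of(parse_iscn("45,X,-Y"))  # "male": derived from 46,XY
#' sex_of(parse_iscn("45,X"))     # "undetermined": derived from 46,XN
#' @export
sex_of <- function(k) {
  chars <- strsplit(k$base$sex_complement, "", fixed = TRUE)[[1]]
  if ("N" %in% chars) "undetermined"
  else if ("Y" %in% chars) "male"
  else "female"
}

#' Class membership of a karyotype
#'
#' @param k a `karyotype`.
#' @param class a class name or a registry entry.
#' @return logical scalar.
#' @examples
#' is_member(parse_iscn("45,X,-Y"), "NumericalAbnormalKaryotype")  # TRUE
#' @export
is_member <- function(k, class) {
  isTRUE(get_class(class)$predicate(k))
}

#' Classify a karyotype against every defined class
#'
#' @param k a `karyotype`.
#' @return character vector of the names of all classes the karyotype is a
#'   member of (closed under parent edges by construction).
#' @examples
#' classify_karyotype(parse_iscn("47,XX,+21"))
#' @export
classify_karyotype <- function(k) {
  reg <- class_registry()
  names(reg)[vapply(reg, function(c) isTRUE(c$predicate(k)), logical(1))]
}

the_named_karyotypes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <- list(
        # congenital syndromes carry the unknown-allosome base unless the
        # designation itself fixes the sex
        DownSyndrome = parse_iscn("47,XN,+21"),
        TurnerSyndrome = parse_iscn("45,X"),
        PraderWilliSyndrome = parse_iscn("46,XN,del(15)(q11q12)"),
        k46_XX = parse_iscn("46,XX"),
        k46_XY = parse_iscn("46,XY"),
        k46_XN = parse_iscn("46,XN"),
        k45_X_minus_Y = parse_iscn("45,X,-Y")
      )
    }
    cache
  }
})

#' Named karyotypes
#'
#' A small registry of named karyotypes: the diploid bases and example
#' syndromes (trisomy 21 / Down, Turner, Prader-Willi), each defined by an
#' ISCN designation.
#'
#' @return named list of `karyotype` objects.
#' @export
named_karyotypes <- function() the_named_karyotypes()

#' Subsumption query
#'
#' Is `sub` subsumed by the defined class `sup`? For a named karyotype,
#' this asks whether its definition is a member of `sup`; for a defined
#' class, whether `sup` is reachable through parent edges (reflexively).
#'
#' @param sub a named-karyotype name, a defined-class name, or a
#'   `karyotype`.
#' @param sup a defined-class name.
#' @return logical scalar.
#' @examples
#' is_superclass("DownSyndrome", "DiploidKaryotype")  # TRUE
#' @export
is_superclass <- function(sub, sup) {
  sup <- get_class(sup)
  if (inherits(sub, "karyotype")) return(is_member(sub, sup))
  nk <- named_karyotypes()
  if (is.character(sub) && sub %in% names(nk)) {
    return(is_member(nk[[sub]], sup))
  }
  reg <- class_registry()
  if (is.character(sub) && sub %in% names(reg)) {
    frontier <- sub
    seen <- character(0)
    while (length(frontier)) {
      if (sup$name %in% frontier) return(TRUE)
      seen <- c(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(reg[frontier], `[[`, "parents"))),
                          seen)
    }
    return(FALSE)
  }
  iscn_stop(sprintf("'%s' is neither a named karyotype nor a defined class",
                    sub), "iscn_lookup_error")
}
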