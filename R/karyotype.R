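# Derived quantities over the event-based karyotype model. A karyotype is a
# base complement (ploidy x 23 chromosomes with a sex complement over
# {X, Y, N}) plus interpretative change events; counts and copy numbers are
# computed, never stored.

#' Chromosome count of a base karyotype
#'
#' @param base the `base` component of a `karyotype` (ploidy + sex
#'   complement), or a whole `karyotype`.
#' @return integer, 23 x ploidy.
#' @examples
#' base_count(parse_iscn("46,XX"))  # 46
#' @export
base_count <- function(base) {
  if (inherits(base, "karyotype")) base <- base$base
  23L * base$ploidy
}

#' Total chromosome count of a karyotype
#'
#' The base count plus the per-event count deltas: whole-chromosome gains
#' and losses count +1/-1 per copy, fission +1, dicentric and telomeric
#' association -1 (two chromosomes fuse into one), tricentric -2, each
#' marker +1; all other events leave the count unchanged.
#'
#' @param k a `karyotype`.
#' @return integer chromosome count.
#' @examples
#' chromosome_count(parse_iscn("45,X,-Y"))  # 45
#' @export
chromosome_count <- function(k) {
  base_count(k$base) + sum(vapply(k$events, event_delta, integer(1)), 0L)
}

#' Copy number of one chromosome type
#'
#' Baseline copies from the base complement (ploidy copies per autosome;
#' allosomes as in the sex complement) adjusted by the events. Numerical
#' gains/losses move the named chromosome's count. The count-changing
#' structural events are attributed so that copies stay conserved: a
#' fission adds one unit to its chromosome; a dicentric or telomeric
#' association removes one unit from its second-named chromosome; a
#' tricentric removes one from each of its second and third; markers are
#' tracked under the pseudo-name `"mar"`, the unknown allosome under `"N"`.
#'
#' @param k a `karyotype`.
#' @param chromosome `"1"`..`"22"`, `"X"`, `"Y"`, `"N"` or `"mar"`.
#' @return integer copy number.
#' @examples
#' copy_number(parse_iscn("45,X,-Y"), "Y")   # 0
#' copy_number(parse_iscn("47,XX,+21"), "21")  # 3
#' @export
copy_number <- function(k, chromosome) {
  c <- as.character(chromosome)
  if (!c %in% c(CHROMOSOME_NAMES, "N", "mar")) {
    iscn_stop(sprintf("unknown chromosome '%s'", chromosome),
              "iscn_domain_error")
  }
  n <- if (c == "mar") 0L
       else if (is_autosome(c)) k$base$ploidy
       else sum(strsplit(k$base$sex_complement, "")[[1]] == c)
  for (e in k$events) {
    m <- e$multiplicity
    if (e$kind == "gain" && e$chromosomes == c) n <- n + m
    else if (e$kind %in% c("loss") && e$chromosomes == c) n <- n - m
    else if (e$kind == "del" && e$level == "chromosome" && e$chromosomes == c)
      n <- n - m
    else if (e$kind == "mar" && c == "mar") n <- n + m
    else if (e$kind == "fis" && e$chromosomes[1] == c) n <- n + m
    else if (e$kind %in% c("dic", "tas"))
      n <- n - m * sum(e$chromosomes[2] == c)
    else if (e$kind == "trc")
      n <- n - m * sum(e$chromosomes[2:3] == c)
  }
  n
}

#' Bands affected by a structural event
#'
#' For interval events on a single chromosome (interstitial deletion,
#' duplication, triplication, quadruplication, inversion) the affected set
#' is every band between the two breakpoints, endpoints included. A
#' one-breakpoint deletion is terminal: breakpoint to that arm's telomere.
#' An isochromosome affects every band of the arm its breakpoint names.
#' All other band-level events affect exactly their breakpoint bands.
#'
#' @param e an `iscn_event` with `level == "band"`.
#' @param map a `band_map`.
#' @param res resolution at which intervals are enumerated (default 850,
#'   the finest level, so every stored band is addressable).
#' @return character vector of band labels in pter-to-qter order (set
#'   semantics; no duplicates).
#' @examples
#' e <- parse_event("del(1)(p31p21)", default_band_map())
#' affected_bands(e, default_band_map())  # 1p31 1p22 1p21
#' @export
affected_bands <- function(e, map, res = 850L) {
  if (e$level != "band") {
    iscn_stop("affected_bands is defined for band-level events only",
              "iscn_domain_error")
  }
  interval_kinds <- c("del", "dup", "trp", "qdp", "inv")
  bp <- e$breakpoints
  if (e$kind %in% interval_kinds && length(bp) == 2L &&
      length(e$chromosomes) == 1L) {
    return(bands_between(map, bp[1], bp[2], res = res))
  }
  if (e$kind == "del" && length(bp) == 1L) {
    entry <- band_entry(map, bp[1])
    leaves <- arm_leaves(map, entry$chromosome, entry$arm, res = res)
    i <- match(bp[1], leaves)
    # p arm: telomere side is the start; q arm: the end
    return(if (entry$arm == "p") leaves[seq_len(i)]
           else leaves[i:length(leaves)])
  }
  if (e$kind == "i" && length(bp) >= 1L) {
    entry <- band_entry(map, bp[1])
    return(arm_leaves(map, entry$chromosome, entry$arm, res = res))
  }
  unique(bp)
}

#' Validate a karyotype against the band map
#'
#' Returns findings (never throws): declared-vs-computed count mismatch,
#' unknown bands, breakpoints on chromosomes the event does not name,
#' arity violations and negative copy numbers.
#'
#' @param k a `karyotype`.
#' @param map a `band_map`.
#' @return data.frame with columns `severity`, `code`, `message`; zero
#'   rows iff the karyotype is internally consistent.
#' @examples
#' nrow(validate_karyotype(parse_iscn("45,X,-Y")))  # 0
#' @export
validate_karyotype <- function(k, map = default_band_map()) {
  findings <- list()
  note <- function(severity, code, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, code = code, message = message,
      stringsAsFactors = FALSE)
  }
  if (!is.null(k$declared_total) && !is.na(k$declared_total) &&
      k$declared_total != chromosome_count(k)) {
    note("error", "count_mismatch",
         sprintf("declared total %d but events compute %d",
                 k$declared_total, chromosome_count(k)))
  }
  for (e in k$events) {
    if (e$level == "chromosome" && length(e$breakpoints)) {
      note("error", "structure",
           sprintf("chromosome-level event '%s' carries breakpoints", e$field))
    }
    if (e$level == "band" && length(e$breakpoints) == 0L) {
      note("error", "structure",
           sprintf("band-level event '%s' has no breakpoint", e$field))
    }
    for (b in e$breakpoints) {
      if (!band_exists(map, b)) {
        note("error", "unknown_band",
             sprintf("band '%s' in '%s' does not exist", b, e$field))
      } else {
        ch <- band_entry(map, b)$chromosome
        if (!ch %in% e$chromosomes) {
          note("error", "structure",
               sprintf("breakpoint '%s' is on a chromosome '%s' does not name",
                       b, e$field))
        }
      }
    }
  }
  for (c in c(CHROMOSOME_NAMES, "N")) {
    if (copy_number(k, c) < 0L) {
      note("error", "negative_copies",
           sprintf("copy number of chromosome %s is negative", c))
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(severity = character(0), code = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

# flatten event kinds, descending into derivative containers
flat_event_kinds <- function(k) {
  out <- character(0)
  for (e in k$events) {
    if (e$level == "band") {
      out <- c(out, e$kind)
      if (!is.null(e$constituents)) {
        out <- c(out, vapply(e$constituents, `[[`, character(1), "kind"))
      }
    }
  }
  out
}

# net numerical copy delta (gain/loss and whole-chromosome del only) per name
numerical_delta <- function(k, chromosome) {
  d <- 0L
  for (e in k$events) {
    if (length(e$chromosomes) != 1L || e$chromosomes != chromosome) next
    if (e$kind == "gain") d <- d + e$multiplicity
    else if (e$kind == "loss" ||
             (e$kind == "del" && e$level == "chromosome"))
      d <- d - e$multiplicity
  }
  d
}

# JSON-friendly record of a karyotype (used by the CLI)
karyotype_record <- function(k, map = default_band_map()) {
  list(
    canonical = canonical_iscn(k),
    base = list(ploidy = k$base$ploidy,
                sex_complement = k$base$sex_complement,
                count = base_count(k$base)),
    events = lapply(Filter(function(e) !e$implicit, k$events), function(e) {
      list(kind = e$kind, level = e$level,
           chromosomes = as.list(e$chromosomes),
           breakpoints = as.list(e$breakpoints),
           multiplicity = e$multiplicity, field = e$field)
    }),
    computed_total = chromosome_count(k)
  )
}
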