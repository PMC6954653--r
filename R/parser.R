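# Regular-expression dialect notes: breakpoint designations inside an event
# group are arm letter + dotted number ("q21", "q21.31"); groups never nest,
# so a depth counter suffices for top-level comma splitting.

split_top_level <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == "(") depth <- depth + 1L
    else if (c == ")") depth <- depth - 1L
    else if (c == "," && depth == 0L) cuts <- c(cuts, i)
    if (depth < 0L) {
      iscn_stop("unbalanced parentheses", "iscn_parse_error")
    }
  }
  if (depth != 0L) iscn_stop("unbalanced parentheses", "iscn_parse_error")
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(i) {
    if (starts[i] > ends[i]) "" else paste(chars[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

#' Tokenize an ISCN designation
#'
#' Splits an ISCN string on top-level commas (commas inside parentheses
#' belong to breakpoint lists) after discarding all whitespace, which is
#' insignificant in this dialect. The first field must be the declared
#' chromosome total, the second the observed sex-chromosome complement.
#'
#' Multi-cell clones (`/`), uncertainty (`?`) and approximate counts (`~`)
#' are legal ISCN but outside the supported dialect and are rejected with
#' an unsupported-dialect error.
#'
#' @param iscn an ISCN designation, e.g. `"46,XY,del(15)(q11q12)"`.
#' @return list with `declared_total`, `sex_field`, `raw_event_fields`.
#' @export
tokenize_iscn <- function(iscn) {
  if (!is.character(iscn) || length(iscn) != 1L || is.na(iscn) ||
      !nzchar(trimws(iscn))) {
    iscn_stop("empty designation", "iscn_parse_error")
  }
  s <- gsub("[[:space:]]+", "", iscn)
  if (grepl("/", s, fixed = TRUE)) {
    iscn_stop("multi-cell clone notation ('/') is not supported",
              "iscn_unsupported_error")
  }
  if (grepl("[?~]", s)) {
    iscn_stop("uncertain or approximate notation ('?', '~') is not supported",
              "iscn_unsupported_error")
  }
  fields <- split_top_level(s)
  if (length(fields) < 2L) {
    iscn_stop("a designation needs at least a total and a sex field",
              "iscn_parse_error")
  }
  if (!grepl("^[0-9]+$", fields[1])) {
    iscn_stop(sprintf("chromosome total '%s' is not an integer", fields[1]),
              "iscn_parse_error")
  }
  total <- as.integer(fields[1])
  if (total < 1L) iscn_stop("chromosome total must be >= 1", "iscn_parse_error")
  if (!grepl("^[XYN]+$", fields[2])) {
    iscn_stop(sprintf("sex field '%s' must be letters from X, Y, N", fields[2]),
              "iscn_parse_error")
  }
  list(declared_total = total,
       sex_field = fields[2],
       raw_event_fields = if (length(fields) > 2L) fields[-(1:2)] else character(0))
}

ABBREV_RE <- "add|del|der|dic|dup|fis|fra|hsr|ins|inv|mar|neo|qdp|tas|trc|trp|i|r|t"

extract_groups <- function(s) {
  m <- gregexpr("\\(([^()]*)\\)", s)[[1]]
  if (m[1] == -1L) return(character(0))
  gsub("^\\(|\\)$", "", regmatches(s, gregexpr("\\(([^()]*)\\)", s))[[1]])
}

parse_breakpoint_part <- function(chromosome, part, map, field) {
  m <- gregexpr("[pq][0-9]+(\\.[0-9]+)?", part)[[1]]
  designations <- regmatches(part, gregexpr("[pq][0-9]+(\\.[0-9]+)?", part))[[1]]
  if (length(designations) == 0L ||
      paste(designations, collapse = "") != part) {
    iscn_stop(sprintf("cannot read breakpoints '%s' in '%s'", part, field),
              "iscn_parse_error")
  }
  labels <- vapply(paste0(chromosome, designations), canonical_label,
                   character(1), USE.NAMES = FALSE)
  missing <- is.na(labels) | !labels %in% map$entries$label
  if (any(missing)) {
    iscn_stop(sprintf("band '%s%s' does not exist in '%s'",
                      chromosome, designations[which(missing)[1]], field),
              "iscn_validation_error")
  }
  labels
}

#' Parse one raw ISCN event field
#'
#' Dispatches on the field prefix: `+c`/`-c` for whole-chromosome gain or
#' loss, `+mar`/`mar` for a marker chromosome, otherwise one of the 19
#' event abbreviations followed by a chromosome group `(c)`/`(c1;c2)` and
#' breakpoint groups `(b1b2)`/`(b1;b2)`. A derivative chromosome
#' (`der(1)t(1;3)(p22;q21)`) is parsed as a container whose chromosomes and
#' breakpoints are the union over its constituent events. `del(c)` with no
#' breakpoint group is accepted as a whole-chromosome deletion. Every
#' breakpoint is validated against the band map.
#'
#' @param field one raw event token, e.g. `"del(15)(q11q12)"`.
#' @param map a `band_map`.
#' @return an `iscn_event`.
#' @export
parse_event <- function(field, map) {
  f <- gsub("[[:space:]]+", "", field)
  if (!nzchar(f)) iscn_stop("empty event field", "iscn_parse_error")

  if (f %in% c("mar", "+mar")) {
    return(new_event("mar", "chromosome", character(0), field = "+mar"))
  }

  m <- regmatches(f, regexec("^([+-])([0-9]{1,2}|[XYxy])$", f))[[1]]
  if (length(m)) {
    chrom <- toupper(m[3])
    if (!chrom %in% map$chromosomes) {
      iscn_stop(sprintf("chromosome '%s' does not exist", m[3]),
                "iscn_validation_error")
    }
    kind <- if (m[2] == "+") "gain" else "loss"
    return(new_event(kind, "chromosome", chrom, field = paste0(m[2], chrom)))
  }

  m <- regmatches(f, regexec(paste0("^(", ABBREV_RE, ")(\\(.*)$"), f))[[1]]
  if (length(m) == 0L) {
    iscn_stop(sprintf("unsupported or unknown event '%s'", field),
              "iscn_unsupported_error")
  }
  abbrev <- m[2]
  rest <- m[3]

  if (abbrev == "der") return(parse_der(rest, map, f))

  if (!grepl("^(\\([^()]*\\))+$", rest)) {
    iscn_stop(sprintf("malformed event groups in '%s'", field),
              "iscn_parse_error")
  }
  groups <- extract_groups(rest)
  chroms <- toupper(strsplit(groups[1], ";", fixed = TRUE)[[1]])
  if (length(chroms) == 0L || !all(chroms %in% map$chromosomes)) {
    iscn_stop(sprintf("invalid chromosome group '(%s)' in '%s'",
                      groups[1], field), "iscn_validation_error")
  }
  kinds <- event_kinds()
  want <- kinds$n_chromosomes[kinds$abbreviation == abbrev]
  ok_arity <- if (abbrev == "ins") length(chroms) %in% 1:2
              else length(chroms) == want
  if (!ok_arity) {
    iscn_stop(sprintf("'%s' takes %s chromosome(s), got %d in '%s'",
                      abbrev, if (abbrev == "ins") "1 or 2" else want,
                      length(chroms), field), "iscn_structure_error")
  }

  breakpoints <- character(0)
  for (g in groups[-1]) {
    parts <- strsplit(g, ";", fixed = TRUE)[[1]]
    if (length(parts) == length(chroms)) {
      for (i in seq_along(parts)) {
        if (!nzchar(parts[i])) next
        breakpoints <- c(breakpoints,
                         parse_breakpoint_part(chroms[i], parts[i], map, field))
      }
    } else if (length(parts) == 1L && length(chroms) == 1L) {
      breakpoints <- c(breakpoints,
                       parse_breakpoint_part(chroms[1], parts[1], map, field))
    } else {
      iscn_stop(sprintf("breakpoint group '(%s)' does not match %d chromosome(s) in '%s'",
                        g, length(chroms), field), "iscn_structure_error")
    }
  }

  if (abbrev == "del" && length(breakpoints) == 0L) {
    # whole-chromosome deletion form; numerically equivalent to "-c"
    return(new_event("del", "chromosome", chroms,
                     field = paste0("del(", chroms, ")")))
  }
  if (length(breakpoints) == 0L) {
    iscn_stop(sprintf("event '%s' needs at least one breakpoint", field),
              "iscn_structure_error")
  }
  new_event(abbrev, "band", chroms, breakpoints, field = f)
}

parse_der <- function(rest, map, field) {
  m <- regmatches(rest, regexec("^\\(([^()]*)\\)(.*)$", rest))[[1]]
  chroms <- toupper(strsplit(m[2], ";", fixed = TRUE)[[1]])
  if (length(chroms) == 0L || !all(chroms %in% map$chromosomes)) {
    iscn_stop(sprintf("invalid chromosome group in '%s'", field),
              "iscn_validation_error")
  }
  spec <- m[3]
  if (!nzchar(spec)) {
    iscn_stop(sprintf("derivative '%s' needs at least one constituent event", field),
              "iscn_structure_error")
  }
  # split the trailing specification where a letter follows a ')'
  chunks <- strsplit(gsub("\\)(?=[a-z])", ")\x1f", spec, perl = TRUE),
                     "\x1f", fixed = TRUE)[[1]]
  constituents <- lapply(chunks, parse_event, map = map)
  for (ce in constituents) {
    if (ce$kind %in% c("gain", "loss", "mar", "der")) {
      iscn_stop(sprintf("'%s' cannot appear inside a derivative in '%s'",
                        ce$field, field), "iscn_structure_error")
    }
  }
  new_event("der", "band",
            unique(c(chroms, unlist(lapply(constituents, `[[`, "chromosomes")))),
            unique(unlist(lapply(constituents, `[[`, "breakpoints"))),
            constituents = constituents, field = field)
}

# ---- base-karyotype inference ------------------------------------------------

# multiset helpers over allosome letters
ms_remove <- function(x, drop) {
  for (d in drop) {
    i <- match(d, x)
    if (is.na(i)) {
      iscn_stop(sprintf("sex field inconsistent with allosome events (no '%s' to remove)", d),
                "iscn_consistency_error")
    }
    x <- x[-i]
  }
  x
}

sort_allosomes <- function(x) x[order(match(x, c("X", "Y", "N")))]

numerical_events_of <- function(events, chrom_filter = NULL) {
  keep <- vapply(events, function(e) {
    e$kind %in% c("gain", "loss") ||
      (e$kind == "del" && e$level == "chromosome")
  }, logical(1))
  events[keep]
}

#' Parse a full ISCN designation into a karyotype
#'
#' Tokenizes, parses every event field, infers the base karyotype (the
#' notional starting complement the observed karyotype is derived from) and
#' checks the declared total against the computed one.
#'
#' Base inference reverses the allosomal gain/loss events against the
#' observed sex field: `45,X,-Y` has observed complement X and a lost Y, so
#' its base is the normal male complement 46,XY. When the adjusted
#' complement is still shorter than the ploidy (e.g. `45,X` with no
#' events), the base is padded with `N` — an allosome of unknown kind — and
#' an implicit whole-chromosome loss of `N` is recorded, mirroring the
#' congenital-loss reading in which such a karyotype derives from 46,XN and
#' can be reasoned neither male nor female.
#'
#' Identical event fields accumulate into one event with a multiplicity.
#'
#' @param iscn an ISCN designation.
#' @param map a `band_map` (defaults to the packaged one).
#' @return an object of class `karyotype`: `base` (ploidy + sex
#'   complement), `events`, `declared_total`, `computed_total`.
#' @examples
#' k <- parse_iscn("45,X,-Y")
#' chromosome_count(k)  # 45
#' @export
parse_iscn <- function(iscn, map = default_band_map()) {
  pd <- tokenize_iscn(iscn)
  events <- lapply(pd$raw_event_fields, parse_event, map = map)

  # merge repeated identical fields into multiplicity
  if (length(events)) {
    fields <- vapply(events, `[[`, character(1), "field")
    keep <- !duplicated(fields)
    counts <- table(fields)
    events <- events[keep]
    for (i in seq_along(events)) {
      events[[i]]$multiplicity <- as.integer(counts[[events[[i]]$field]])
    }
  }

  observed <- strsplit(pd$sex_field, "", fixed = TRUE)[[1]]
  num <- numerical_events_of(events)
  gained <- unlist(lapply(num, function(e) {
    if (e$kind == "gain" && e$chromosomes %in% c("X", "Y", "N"))
      rep(e$chromosomes, e$multiplicity) else character(0)
  }))
  lost <- unlist(lapply(num, function(e) {
    if (e$kind %in% c("loss", "del") && e$chromosomes %in% c("X", "Y", "N"))
      rep(e$chromosomes, e$multiplicity) else character(0)
  }))
  adjusted <- c(ms_remove(observed, gained), lost)

  explicit_delta <- sum(vapply(events, event_delta, integer(1)), 0L)
  implied_base <- pd$declared_total - explicit_delta
  ploidy <- max(1L, min(4L, as.integer(round(implied_base / 23))))

  implicit <- list()
  if (length(adjusted) < ploidy) {
    deficit <- ploidy - length(adjusted)
    base_chars <- sort_allosomes(c(adjusted, rep("N", deficit)))
    implicit <- list(new_event("loss", "chromosome", "N",
                               multiplicity = deficit, field = "-N",
                               implicit = TRUE))
  } else if (length(adjusted) > ploidy) {
    # keep one of each distinct allosome first (prefer X, then Y, then N),
    # surplus copies become implicit gains
    base_chars <- character(0)
    pool <- sort_allosomes(adjusted)
    for (a in c("X", "Y", "N")) {
      if (length(base_chars) < ploidy && a %in% pool) {
        base_chars <- c(base_chars, a)
        pool <- pool[-match(a, pool)]
      }
    }
    while (length(base_chars) < ploidy && length(pool)) {
      base_chars <- c(base_chars, pool[1])
      pool <- pool[-1]
    }
    base_chars <- sort_allosomes(base_chars)
    for (a in unique(pool)) {
      implicit <- c(implicit,
                    list(new_event("gain", "chromosome", a,
                                   multiplicity = sum(pool == a),
                                   field = paste0("+", a), implicit = TRUE)))
    }
  } else {
    base_chars <- sort_allosomes(adjusted)
  }

  base <- list(ploidy = ploidy, sex_complement = paste(base_chars, collapse = ""))
  k <- structure(
    list(base = base, events = c(events, implicit),
         declared_total = pd$declared_total, computed_total = NA_integer_),
    class = "karyotype"
  )
  k$computed_total <- chromosome_count(k)
  if (k$computed_total != pd$declared_total) {
    iscn_stop(sprintf("declared total %d but events compute %d",
                      pd$declared_total, k$computed_total),
              "iscn_consistency_error")
  }
  k
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("<karyotype> %s  (base %d,%s; %d event field(s))\n",
              canonical_iscn(x), base_count(x$base), x$base$sex_complement,
              sum(!vapply(x$events, `[[`, logical(1), "implicit"))))
  invisible(x)
}

#' Emit the canonical ISCN string of a karyotype
#'
#' Normalized form: no whitespace, total = computed count, observed sex
#' complement reconstructed from the base and the allosomal events, event
#' fields sorted by chromosome then event kind, one field per event
#' occurrence. Implicit unknown-allosome events (the `N` bookkeeping behind
#' e.g. `45,X`) are folded into the sex field, never printed as fields.
#' `parse_iscn()` of the result reproduces the karyotype.
#'
#' @param k a `karyotype`.
#' @return a single ISCN string.
#' @examples
#' canonical_iscn(parse_iscn("45, X,-Y"))  # "45,X,-Y"
#' @export
canonical_iscn <- function(k) {
  chars <- strsplit(k$base$sex_complement, "", fixed = TRUE)[[1]]
  for (e in k$events) {
    if (e$kind == "gain" && e$chromosomes %in% c("X", "Y", "N")) {
      chars <- c(chars, rep(e$chromosomes, e$multiplicity))
    } else if (e$kind %in% c("loss", "del") && e$level == "chromosome" &&
               e$chromosomes %in% c("X", "Y", "N")) {
      chars <- ms_remove(chars, rep(e$chromosomes, e$multiplicity))
    }
  }
  sex <- paste(sort_allosomes(chars), collapse = "")

  visible <- Filter(function(e) !e$implicit, k$events)
  if (length(visible)) {
    chrom_key <- vapply(visible, function(e) {
      if (length(e$chromosomes)) match(e$chromosomes[1], c(CHROMOSOME_NAMES, "N"))
      else 99L  # markers sort last
    }, integer(1))
    kind_key <- vapply(visible, `[[`, character(1), "kind")
    field_key <- vapply(visible, `[[`, character(1), "field")
    visible <- visible[order(chrom_key, kind_key, field_key)]
    fields <- unlist(lapply(visible, function(e) rep(e$field, e$multiplicity)))
  } else {
    fields <- character(0)
  }
  paste(c(k$computed_total, sex, fields), collapse = ",")
}
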