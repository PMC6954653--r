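# Seeded random-karyotype generator. Each karyotype is assembled as ISCN
# text from a diploid base and randomly drawn events, then run through the
# parser, so by construction every output parses, validates cleanly and
# round-trips.

#' Generator configuration
#'
#' Defaults: uniform weights over all band-level event kinds, numerical
#' (whole-chromosome gain/loss) event probability 0.3, at most 3 events per
#' karyotype. These are the study conditions for the property tests and the
#' scaling benchmark; they are deliberately simple rather than emulating
#' any tumour-type aberration spectrum.
#'
#' @param seed integer seed.
#' @param n number of karyotypes.
#' @param event_kind_weights named non-negative weights over band-level
#'   event kinds; at least one must be positive.
#' @param max_events_per_karyotype maximum events per karyotype.
#' @param numerical_event_probability probability that a drawn event is a
#'   whole-chromosome gain or loss rather than a structural event.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n = 100L,
                             event_kind_weights = NULL,
                             max_events_per_karyotype = 3L,
                             numerical_event_probability = 0.3) {
  kinds <- band_level_kinds()
  if (is.null(event_kind_weights)) {
    event_kind_weights <- stats::setNames(rep(1, length(kinds)), kinds)
  }
  if (!all(names(event_kind_weights) %in% kinds)) {
    iscn_stop("event_kind_weights has unknown kind names", "iscn_config_error")
  }
  w <- stats::setNames(rep(0, length(kinds)), kinds)
  w[names(event_kind_weights)] <- event_kind_weights
  if (any(w < 0) || !any(w > 0)) {
    iscn_stop("event_kind_weights must be non-negative with at least one positive",
              "iscn_config_error")
  }
  if (numerical_event_probability < 0 || numerical_event_probability > 1) {
    iscn_stop("numerical_event_probability must be in [0, 1]",
              "iscn_config_error")
  }
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 event_kind_weights = w,
                 max_events_per_karyotype = as.integer(max_events_per_karyotype),
                 numerical_event_probability = numerical_event_probability),
            class = "generator_config")
}

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# draw one structural event field as ISCN text; only chromosomes currently
# present in the karyotype are eligible targets
draw_structural_field <- function(cfg, map, bands_by_chrom, present) {
  w <- cfg$event_kind_weights
  kind <- sample(names(w), 1L, prob = w)
  chroms_all <- intersect(names(bands_by_chrom), present)
  eligible <- function(min_bands) {
    names(bands_by_chrom)[vapply(bands_by_chrom, length, 0L) >= min_bands]
  }
  pick_chrom <- function(min_bands = 1L, exclude = character(0)) {
    ok <- setdiff(intersect(chroms_all, eligible(min_bands)), exclude)
    sample(ok, 1L)
  }
  pick_bands <- function(ch, k) {
    sample(bands_by_chrom[[ch]], k, replace = FALSE)
  }
  designation <- function(label) sub("^[0-9XY]+", "", label)

  if (kind %in% c("add", "fra", "hsr", "neo", "fis", "i")) {
    ch <- pick_chrom()
    sprintf("%s(%s)(%s)", kind, ch, designation(pick_bands(ch, 1L)))
  } else if (kind %in% c("dup", "trp", "qdp", "inv", "r")) {
    ch <- pick_chrom(2L)
    b <- pick_bands(ch, 2L)
    b <- b[order(match(b, bands_by_chrom[[ch]]))]
    sprintf("%s(%s)(%s%s)", kind, ch, designation(b[1]), designation(b[2]))
  } else if (kind == "del") {
    ch <- pick_chrom(2L)
    if (stats::runif(1) < 0.5) {
      sprintf("del(%s)(%s)", ch, designation(pick_bands(ch, 1L)))
    } else {
      b <- pick_bands(ch, 2L)
      b <- b[order(match(b, bands_by_chrom[[ch]]))]
      sprintf("del(%s)(%s%s)", ch, designation(b[1]), designation(b[2]))
    }
  } else if (kind %in% c("t", "dic", "tas")) {
    c1 <- pick_chrom()
    c2 <- pick_chrom(exclude = c1)
    sprintf("%s(%s;%s)(%s;%s)", kind, c1, c2,
            designation(pick_bands(c1, 1L)), designation(pick_bands(c2, 1L)))
  } else if (kind == "trc") {
    cs <- sample(chroms_all, 3L)
    sprintf("trc(%s;%s;%s)(%s;%s;%s)", cs[1], cs[2], cs[3],
            designation(pick_bands(cs[1], 1L)),
            designation(pick_bands(cs[2], 1L)),
            designation(pick_bands(cs[3], 1L)))
  } else if (kind == "ins") {
    c1 <- pick_chrom()
    c2 <- pick_chrom(2L, exclude = c1)
    b2 <- pick_bands(c2, 2L)
    b2 <- b2[order(match(b2, bands_by_chrom[[c2]]))]
    sprintf("ins(%s;%s)(%s;%s%s)", c1, c2,
            designation(pick_bands(c1, 1L)),
            designation(b2[1]), designation(b2[2]))
  } else if (kind == "der") {
    c1 <- pick_chrom()
    c2 <- pick_chrom(exclude = c1)
    sprintf("der(%s)t(%s;%s)(%s;%s)", c1, c1, c2,
            designation(pick_bands(c1, 1L)), designation(pick_bands(c2, 1L)))
  } else {
    iscn_stop(sprintf("no construction rule for kind '%s'", kind),
              "iscn_config_error")
  }
}

#' Generate random karyotypes
#'
#' Deterministic for a fixed seed; every returned karyotype validates
#' cleanly and its breakpoints name only bands that exist in the map.
#'
#' @param config a [generator_config()].
#' @param map a `band_map`.
#' @return list of `karyotype` objects of length `config$n`.
#' @examples
#' ks <- generate_karyotypes(generator_config(seed = 1, n = 5))
#' vapply(ks, canonical_iscn, "")
#' @export
generate_karyotypes <- function(config = generator_config(),
                                map = default_band_map()) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  ents <- map$entries
  bands_by_chrom <- split(ents$label, ents$chromosome)[
    intersect(CHROMOSOME_NAMES, ents$chromosome)]

  with_preserved_rng(config$seed, {
    lapply(seq_len(config$n), function(i) {
      complement <- sample(c("XX", "XY"), 1L)
      # `copies` tracks the full copy state (numerical events plus the
      # attribution of fusing/splitting structural ones) so no draw can
      # push a chromosome below zero; `allo` tracks the observed allosome
      # complement, which only numerical events move
      copies <- stats::setNames(rep(2L, 24L), CHROMOSOME_NAMES)
      copies["X"] <- if (complement == "XX") 2L else 1L
      copies["Y"] <- if (complement == "XY") 1L else 0L
      allo <- copies[c("X", "Y")]
      total <- 46L
      fields <- character(0)
      n_events <- sample(0:config$max_events_per_karyotype, 1L)
      for (j in seq_len(n_events)) {
        if (stats::runif(1) < config$numerical_event_probability) {
          gain <- stats::runif(1) < 0.5
          candidates <- if (gain) {
            CHROMOSOME_NAMES
          } else {
            ok <- copies > 0L
            # never lose the last sex chromosome: the observed complement
            # must stay non-empty
            if (allo["X"] + allo["Y"] <= 1L) ok[c("X", "Y")] <- FALSE
            CHROMOSOME_NAMES[ok]
          }
          ch <- sample(candidates, 1L)
          copies[ch] <- copies[ch] + if (gain) 1L else -1L
          if (ch %in% c("X", "Y")) allo[ch] <- allo[ch] + if (gain) 1L else -1L
          total <- total + if (gain) 1L else -1L
          fields <- c(fields, paste0(if (gain) "+" else "-", ch))
        } else {
          f <- draw_structural_field(config, map, bands_by_chrom,
                                     names(copies)[copies > 0L])
          e <- parse_event(f, map)
          total <- total + event_delta(e)
          if (e$kind %in% c("dic", "tas")) {
            copies[e$chromosomes[2]] <- copies[e$chromosomes[2]] - 1L
          } else if (e$kind == "trc") {
            copies[e$chromosomes[2]] <- copies[e$chromosomes[2]] - 1L
            copies[e$chromosomes[3]] <- copies[e$chromosomes[3]] - 1L
          } else if (e$kind == "fis") {
            copies[e$chromosomes[1]] <- copies[e$chromosomes[1]] + 1L
          }
          fields <- c(fields, f)
        }
      }
      sex_field <- paste(sort_allosomes(
        c(rep("X", allo["X"]), rep("Y", allo["Y"]))), collapse = "")
      iscn <- paste(c(total, sex_field, fields), collapse = ",")
      parse_iscn(iscn, map)
    })
  })
}

#' Write karyotypes as ISCN text
#'
#' One canonical ISCN designation per line.
#'
#' @param ks list of `karyotype` objects.
#' @param sink file path or connection.
#' @return the number of lines written, invisibly.
#' @export
write_iscn <- function(ks, sink = stdout()) {
  lines <- vapply(ks, canonical_iscn, character(1))
  writeLines(lines, con = sink)
  invisible(length(lines))
}
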