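# Four representations of band order behind one interface. Order is the one
# piece of chromosome structure a plain subclass hierarchy cannot express,
# so each backend materializes it differently; all interval-capable
# backends must agree exactly, with the enumeration backend as the oracle.

#' Names of the registered ordering backends
#' @export
BACKEND_NAMES <- c("no_order", "enumeration", "sequence_pattern",
                   "data_property")

# resolution at which backends answer: the finest level, so every stored
# band is addressable
BACKEND_RES <- 850L

#' Build a band-ordering backend
#'
#' * `no_order` stores band existence only; interval queries are a
#'   capability error.
#' * `enumeration` precomputes the inclusive interval for every
#'   same-chromosome band pair and answers by lookup.
#' * `sequence_pattern` stores next-links (the sequence design pattern's
#'   'next'/'rest') and answers by traversal.
#' * `data_property` assigns each band a strictly increasing integer
#'   position pter-to-qter and answers by numeric comparison.
#'
#' @param map a `band_map`.
#' @param name one of [BACKEND_NAMES].
#' @return an object of classes `order_backend` and `backend_<name>` with
#'   fields `name` and `supports_between`.
#' @examples
#' b <- build_backend(default_band_map(), "data_property")
#' backend_between(b, "1p31", "1p21")
#' @export
build_backend <- function(map, name) {
  if (!is.character(name) || length(name) != 1L || !name %in% BACKEND_NAMES) {
    iscn_stop(sprintf("unknown backend '%s'", name), "iscn_lookup_error")
  }
  b <- list(name = name, supports_between = name != "no_order", map = map)

  if (name == "enumeration") {
    intervals <- new.env(parent = emptyenv(), hash = TRUE)
    for (ch in unique(map$entries$chromosome)) {
      labels <- map$entries$label[map$entries$chromosome == ch]
      for (i in seq_along(labels)) {
        for (j in i:length(labels)) {
          val <- bands_between(map, labels[i], labels[j], res = BACKEND_RES)
          assign(paste(labels[i], labels[j], sep = "|"), val, envir = intervals)
        }
      }
    }
    b$intervals <- intervals
  } else if (name == "sequence_pattern") {
    nxt <- new.env(parent = emptyenv(), hash = TRUE)
    first <- character(0)
    for (ch in unique(map$entries$chromosome)) {
      leaves <- leaves_at(map, ch, BACKEND_RES)$label
      first[ch] <- leaves[1]
      for (i in seq_along(leaves)) {
        assign(leaves[i],
               if (i < length(leaves)) leaves[i + 1] else NA_character_,
               envir = nxt)
      }
    }
    b$nxt <- nxt
    b$first <- first
  } else if (name == "data_property") {
    pos <- new.env(parent = emptyenv(), hash = TRUE)
    ordered <- list()
    for (ch in unique(map$entries$chromosome)) {
      leaves <- leaves_at(map, ch, BACKEND_RES)$label
      for (i in seq_along(leaves)) assign(leaves[i], as.numeric(i), envir = pos)
      ordered[[ch]] <- leaves
    }
    b$pos <- pos
    b$ordered <- ordered
  }
  class(b) <- c(paste0("backend_", name), "order_backend")
  b
}

#' @export
print.order_backend <- function(x, ...) {
  cat(sprintf("<order_backend> %s (intervals %s)\n", x$name,
              if (x$supports_between) "supported" else "unsupported"))
  invisible(x)
}

# expand a (possibly coarse) band to its leaf range at the backend resolution
leaf_endpoints <- function(map, label) {
  e <- band_entry(map, label)
  leaves <- leaves_at(map, e$chromosome, BACKEND_RES)
  w <- which(leaves$leaf_start >= e$leaf_start & leaves$leaf_end <= e$leaf_end)
  if (!length(w)) w <- which(leaves$label == e$label)
  list(chromosome = e$chromosome, first = leaves$label[min(w)],
       last = leaves$label[max(w)], range = range(w))
}

#' Interval query through a backend
#'
#' Returns the same band interval as [bands_between()] at the finest
#' resolution, computed through the backend's own representation of order.
#'
#' @param backend an `order_backend`.
#' @param a,b band labels on the same chromosome.
#' @return character vector of band labels, pter-to-qter.
#' @export
backend_between <- function(backend, a, b) {
  UseMethod("backend_between")
}

#' @export
backend_between.backend_no_order <- function(backend, a, b) {
  iscn_stop("the no_order backend does not represent band order",
            "iscn_capability_error")
}

#' @export
backend_between.backend_enumeration <- function(backend, a, b) {
  map <- backend$map
  ea <- band_entry(map, a)
  eb <- band_entry(map, b)
  if (ea$chromosome != eb$chromosome) {
    iscn_stop("bands on different chromosomes", "iscn_domain_error")
  }
  key <- paste(ea$label, eb$label, sep = "|")
  if (!exists(key, envir = backend$intervals, inherits = FALSE)) {
    key <- paste(eb$label, ea$label, sep = "|")
  }
  get(key, envir = backend$intervals, inherits = FALSE)
}

#' @export
backend_between.backend_sequence_pattern <- function(backend, a, b) {
  map <- backend$map
  pa <- leaf_endpoints(map, a)
  pb <- leaf_endpoints(map, b)
  if (pa$chromosome != pb$chromosome) {
    iscn_stop("bands on different chromosomes", "iscn_domain_error")
  }
  # walk the next-links from the chromosome start: collecting begins at the
  # first endpoint band encountered and ends once both endpoint spans have
  # been passed, which yields the inclusive interval without ever
  # consulting numeric positions
  starts <- c(pa$first, pb$first)
  ends <- c(pa$last, pb$last)
  cur <- backend$first[[pa$chromosome]]
  out <- character(0)
  collecting <- FALSE
  repeat {
    if (!collecting && cur %in% starts) collecting <- TRUE
    if (collecting) {
      out <- c(out, cur)
      if (all(ends %in% out)) break
    }
    cur <- get(cur, envir = backend$nxt, inherits = FALSE)
    if (is.na(cur)) break
  }
  out
}

#' @export
backend_between.backend_data_property <- function(backend, a, b) {
  map <- backend$map
  pa <- leaf_endpoints(map, a)
  pb <- leaf_endpoints(map, b)
  if (pa$chromosome != pb$chromosome) {
    iscn_stop("bands on different chromosomes", "iscn_domain_error")
  }
  lo <- min(pa$range, pb$range)
  hi <- max(pa$range, pb$range)
  leaves <- backend$ordered[[pa$chromosome]]
  positions <- vapply(leaves, function(l) get(l, envir = backend$pos),
                      numeric(1))
  leaves[positions >= lo & positions <= hi]
}
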