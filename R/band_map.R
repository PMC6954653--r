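#' Idiogram resolution levels (bands per haploid set)
#'
#' The conventional detail levels of the human idiogram. Band visibility is
#' cumulative: a band visible at one level stays visible at every finer
#' level, where its sub-bands (if any) additionally appear.
#'
#' @export
BAND_RESOLUTIONS <- c(300L, 400L, 550L, 700L, 850L)

#' Human chromosome type names
#'
#' The 24 chromosome types of the human karyotype: autosomes 1-22 plus the
#' X and Y sex chromosomes (allosomes).
#'
#' @export
CHROMOSOME_NAMES <- c(as.character(1:22), "X", "Y")

#' Test whether a chromosome name denotes an autosome
#'
#' @param chromosome character vector of chromosome names.
#' @return logical vector, `TRUE` for "1".."22".
#' @export
is_autosome <- function(chromosome) {
  chromosome %in% as.character(1:22)
}

#' Canonicalize band or chromosome label text
#'
#' Strips whitespace, upper-cases the chromosome part and lower-cases the
#' arm letter, so `" 17 Q 21.31"` becomes `"17q21.31"`. Returns `NA` for
#' text that does not even look like a label.
#'
#' @param label character scalar.
#' @return canonical label text, or `NA_character_`.
#' @export
canonical_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    return(NA_character_)
  }
  s <- gsub("[[:space:]]+", "", label)
  m <- regmatches(s, regexec("^([0-9]{1,2}|[XxYy])(?:([PQpq])([0-9]+(?:\\.[0-9]+)?)?)?$", s))[[1]]
  if (length(m) == 0L) return(NA_character_)
  chrom <- toupper(m[2])
  if (!chrom %in% CHROMOSOME_NAMES) return(NA_character_)
  paste0(chrom, tolower(m[3]), m[4])
}

#' Load a chromosome band map from a band-table TSV
#'
#' Reads the tab-separated band table (columns `chromosome`, `arm`, `band`,
#' `parent`, `resolutions`; one row per band, rows in pter-to-qter order per
#' chromosome, sub-band rows immediately after their parent) and builds a
#' validated ordered partonomy of the 24 human chromosome types, their p/q
#' arms and their bands.
#'
#' The `resolutions` column holds semicolon-separated idiogram levels; the
#' smallest listed level is the level at which the band first becomes
#' visible, and visibility is cumulative towards finer levels.
#'
#' @param source path to a band-table TSV (defaults to the packaged table).
#' @return an object of class `band_map` with components `entries` (one row
#'   per band: label, chromosome, arm, designation, parent label, first
#'   visible resolution, leaf index range) and `chromosomes`.
#' @examples
#' map <- load_band_map()
#' band_exists(map, "1p36")
#' @export
load_band_map <- function(source = system.file("extdata", "band_map.tsv",
                                               package = "iscnkit")) {
  tab <- utils::read.delim(source, header = TRUE, colClasses = "character",
                           strip.white = TRUE)
  needed <- c("chromosome", "arm", "band", "parent", "resolutions")
  if (!all(needed %in% names(tab))) {
    iscn_stop(sprintf("band table must have columns: %s",
                      paste(needed, collapse = ", ")), "iscn_format_error")
  }
  tab[is.na(tab)] <- ""
  n <- nrow(tab)
  if (n == 0L) iscn_stop("band table is empty", "iscn_format_error")

  if (!all(tab$chromosome %in% CHROMOSOME_NAMES)) {
    bad <- setdiff(unique(tab$chromosome), CHROMOSOME_NAMES)
    iscn_stop(sprintf("unknown chromosome(s): %s", paste(bad, collapse = ", ")),
              "iscn_format_error")
  }
  if (!all(tab$arm %in% c("p", "q"))) {
    iscn_stop("arm must be 'p' or 'q'", "iscn_format_error")
  }
  label <- paste0(tab$chromosome, tab$arm, tab$band)
  if (anyDuplicated(label)) {
    iscn_stop(sprintf("duplicate band label(s): %s",
                      paste(unique(label[duplicated(label)]), collapse = ", ")),
              "iscn_format_error")
  }

  res_min <- vapply(strsplit(tab$resolutions, ";", fixed = TRUE), function(r) {
    r <- suppressWarnings(as.integer(r))
    if (length(r) == 0L || anyNA(r) || !all(r %in% BAND_RESOLUTIONS)) {
      iscn_stop("invalid resolutions field", "iscn_format_error")
    }
    min(r)
  }, integer(1))

  # parent resolution: "" means the band hangs directly off the arm
  parent_label <- ifelse(tab$parent == "", NA_character_,
                         paste0(tab$chromosome, tab$arm, tab$parent))
  for (i in seq_len(n)) {
    pl <- parent_label[i]
    if (is.na(pl)) next
    j <- match(pl, label)
    if (is.na(j)) {
      iscn_stop(sprintf("parent band '%s' of '%s' not found", pl, label[i]),
                "iscn_format_error")
    }
    if (j >= i) {
      iscn_stop(sprintf("band '%s' appears before its parent '%s'",
                        label[i], pl), "iscn_format_error")
    }
    # dotted designation must extend the parent designation
    if (!startsWith(tab$band[i], paste0(tab$parent[i], "."))) {
      iscn_stop(sprintf("sub-band '%s' does not extend parent designation '%s'",
                        label[i], tab$parent[i]), "iscn_format_error")
    }
    if (res_min[i] <= res_min[j]) {
      iscn_stop(sprintf("sub-band '%s' visible at or below its parent's level",
                        label[i]), "iscn_format_error")
    }
  }

  entries <- data.frame(
    label = label, chromosome = tab$chromosome, arm = tab$arm,
    designation = tab$band, parent = parent_label, res_min = res_min,
    row = seq_len(n), stringsAsFactors = FALSE
  )

  # per-chromosome ordering checks and leaf indexing
  has_child <- label %in% parent_label
  entries$leaf_start <- NA_integer_
  entries$leaf_end <- NA_integer_
  p_leaves <- integer(0)
  for (ch in unique(entries$chromosome)) {
    sub <- entries[entries$chromosome == ch, ]
    if (!any(sub$arm == "p") || !any(sub$arm == "q")) {
      iscn_stop(sprintf("chromosome %s lacks a p or q band", ch),
                "iscn_format_error")
    }
    if (is.unsorted(match(sub$arm, c("p", "q")))) {
      iscn_stop(sprintf("chromosome %s: p-arm rows must precede q-arm rows", ch),
                "iscn_format_error")
    }
    # top-level bands: numerically descending on p (towards the centromere),
    # ascending on q (away from it)
    for (arm in c("p", "q")) {
      top <- sub[sub$arm == arm & is.na(sub$parent), ]
      v <- as.numeric(top$designation)
      ok <- if (arm == "p") !is.unsorted(rev(v), strictly = TRUE)
            else !is.unsorted(v, strictly = TRUE)
      if (!ok) {
        iscn_stop(sprintf("chromosome %s%s bands out of pter->qter order", ch, arm),
                  "iscn_format_error")
      }
    }
    leaves <- sub$label[!has_child[sub$row]]
    idx <- seq_along(leaves)
    entries$leaf_start[match(leaves, entries$label)] <- idx
    entries$leaf_end[match(leaves, entries$label)] <- idx
    p_leaves[ch] <- sum(entries$arm[match(leaves, entries$label)] == "p")
  }
  # parents inherit the index range of their descendant leaves
  for (i in rev(seq_len(n))) {
    pl <- entries$parent[i]
    if (is.na(pl)) next
    j <- match(pl, entries$label)
    entries$leaf_start[j] <- min(entries$leaf_start[j], entries$leaf_start[i],
                                 na.rm = TRUE)
    entries$leaf_end[j] <- max(entries$leaf_end[j], entries$leaf_end[i],
                               na.rm = TRUE)
  }
  # sub-band runs must be contiguous under their parent
  for (i in which(has_child)) {
    kids <- entries[!is.na(entries$parent) & entries$parent == entries$label[i], ]
    span <- max(kids$leaf_end) - min(kids$leaf_start) + 1L
    if (span != sum(kids$leaf_end - kids$leaf_start + 1L)) {
      iscn_stop(sprintf("sub-bands of '%s' are not contiguous", entries$label[i]),
                "iscn_format_error")
    }
  }

  structure(
    list(entries = entries,
         chromosomes = CHROMOSOME_NAMES,
         p_leaf_count = p_leaves,
         source = source),
    class = "band_map"
  )
}

#' @export
print.band_map <- function(x, ...) {
  cat(sprintf("<band_map> %d chromosome types, %d band entries (%s)\n",
              length(unique(x$entries$chromosome)), nrow(x$entries),
              basename(x$source)))
  invisible(x)
}

the_default_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_band_map()
    cache
  }
})

#' Packaged band map
#'
#' Returns (and caches) the band map loaded from the packaged band table.
#'
#' @return a `band_map` object.
#' @export
default_band_map <- function() the_default_map()

band_entry <- function(map, label) {
  cl <- canonical_label(label)
  i <- if (is.na(cl)) NA_integer_ else match(cl, map$entries$label)
  if (is.na(i)) {
    iscn_stop(sprintf("unknown band '%s'", label), "iscn_lookup_error")
  }
  map$entries[i, ]
}

#' Does a chromosome, arm or band exist?
#'
#' @param map a `band_map`.
#' @param label any text; malformed text yields `FALSE`, never an error.
#' @return `TRUE` iff the canonicalized label names a chromosome, an arm or
#'   a band entry of the map.
#' @examples
#' band_exists(default_band_map(), "1p35")  # TRUE
#' band_exists(default_band_map(), "1p99")  # FALSE
#' @export
band_exists <- function(map, label) {
  cl <- canonical_label(label)
  if (is.na(cl)) return(FALSE)
  if (cl %in% map$chromosomes) return(TRUE)
  if (grepl("^([0-9]+|[XY])[pq]$", cl)) {
    return(substr(cl, 1L, nchar(cl) - 1L) %in% map$chromosomes)
  }
  cl %in% map$entries$label
}

#' Sub-bands of a band
#'
#' All bands whose parent chain includes the given band, in pter-to-qter
#' order. Leaf bands return an empty vector.
#'
#' @param map a `band_map`.
#' @param band a band label, e.g. `"17q21"`.
#' @return character vector of band labels.
#' @examples
#' sub_bands(default_band_map(), "17q21")
#' @export
sub_bands <- function(map, band) {
  e <- band_entry(map, band)
  out <- character(0)
  frontier <- e$label
  while (length(frontier)) {
    kids <- map$entries$label[!is.na(map$entries$parent) &
                              map$entries$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  ent <- map$entries[match(out, map$entries$label), ]
  out[order(ent$leaf_start, ent$leaf_end - ent$leaf_start)]
}

#' Is a band visible at a resolution level?
#'
#' Visibility is cumulative: once a band appears at some level it remains
#' visible at every finer level.
#'
#' @param map a `band_map`.
#' @param band a band label.
#' @param res one of [BAND_RESOLUTIONS].
#' @return logical scalar.
#' @export
seen_at_resolution <- function(map, band, res) {
  if (!res %in% BAND_RESOLUTIONS) {
    iscn_stop(sprintf("invalid resolution level %s", res), "iscn_domain_error")
  }
  e <- band_entry(map, band)
  res >= e$res_min
}

#' Compare two bands in pter-to-qter order
#'
#' @param map a `band_map`.
#' @param a,b band labels on the same chromosome.
#' @return -1 if `a` precedes `b`, 0 iff the same band, +1 if `a` follows.
#' @examples
#' compare_bands(default_band_map(), "1p31", "1p21")  # -1
#' @export
compare_bands <- function(map, a, b) {
  ea <- band_entry(map, a)
  eb <- band_entry(map, b)
  if (ea$chromosome != eb$chromosome) {
    iscn_stop(sprintf("bands '%s' and '%s' are on different chromosomes",
                      ea$label, eb$label), "iscn_domain_error")
  }
  if (ea$label == eb$label) return(0L)
  if (ea$leaf_start != eb$leaf_start) {
    return(if (ea$leaf_start < eb$leaf_start) -1L else 1L)
  }
  # nested bands sharing a start: the narrower (deeper) band sorts first
  if (ea$leaf_end < eb$leaf_end) -1L else 1L
}

# bands visible and undivided at `res` on one chromosome, pter->qter
leaves_at <- function(map, chromosome, res) {
  sub <- map$entries[map$entries$chromosome == chromosome, ]
  visible <- sub$res_min <= res
  child_visible_of <- unique(sub$parent[visible & !is.na(sub$parent)])
  sub <- sub[visible & !(sub$label %in% child_visible_of), ]
  sub[order(sub$leaf_start), ]
}

#' Bands spanned by an inclusive interval
#'
#' The bands lying between two breakpoints on one chromosome, endpoints
#' included, at a given idiogram resolution. The result is symmetric in the
#' two endpoints and may span the centromere. An endpoint that is divided
#' into sub-bands at `res` is expanded to its first/last visible
#' descendant; an endpoint not yet visible at `res` raises a resolution
#' error.
#'
#' @param map a `band_map`.
#' @param a,b band labels on the same chromosome.
#' @param res resolution level at which to enumerate (default 300).
#' @return character vector of band labels in pter-to-qter order.
#' @examples
#' bands_between(default_band_map(), "1p31", "1p21")  # 1p31 1p22 1p21
#' @export
bands_between <- function(map, a, b, res = 300L) {
  ea <- band_entry(map, a)
  eb <- band_entry(map, b)
  if (ea$chromosome != eb$chromosome) {
    iscn_stop(sprintf("bands '%s' and '%s' are on different chromosomes",
                      ea$label, eb$label), "iscn_domain_error")
  }
  if (!res %in% BAND_RESOLUTIONS) {
    iscn_stop(sprintf("invalid resolution level %s", res), "iscn_domain_error")
  }
  leaves <- leaves_at(map, ea$chromosome, res)
  span <- function(e) {
    if (e$res_min > res) {
      iscn_stop(sprintf("band '%s' is not visible at the %d-band level",
                        e$label, res), "iscn_resolution_error")
    }
    w <- which(leaves$leaf_start >= e$leaf_start & leaves$leaf_end <= e$leaf_end)
    if (!length(w)) {
      # the band itself is the visible leaf at this resolution
      w <- which(leaves$label == e$label)
    }
    if (!length(w)) {
      iscn_stop(sprintf("band '%s' cannot be expanded at the %d-band level",
                        e$label, res), "iscn_resolution_error")
    }
    range(w)
  }
  ra <- span(ea)
  rb <- span(eb)
  leaves$label[min(ra, rb):max(ra, rb)]
}

# leaves of one arm at a resolution, pter->qter (used for terminal events)
arm_leaves <- function(map, chromosome, arm, res = 850L) {
  leaves <- leaves_at(map, chromosome, res)
  leaves$label[leaves$arm == arm]
}
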