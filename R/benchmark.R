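# Scaling harness: classify seeded random karyotypes while resolving every
# band-interval query through each ordering backend, report wall time.
# Correctness (identical classifications and interval sets across the
# interval-capable backends) is asserted before any timing is reported;
# absolute times are reported, never asserted.

# order-sensitive polynomial checksum over a character vector; all
# arithmetic stays below 2^53 so the result is exact and platform-stable
checksum_strings <- function(strings) {
  M <- 2147483647  # 2^31 - 1
  per <- vapply(strings, function(s) {
    b <- utf8ToInt(s)
    if (!length(b)) 0 else sum(b * seq_along(b)) %% M
  }, numeric(1), USE.NAMES = FALSE)
  h <- 0
  for (x in per) h <- (h * 31 + x) %% M
  sprintf("%08x", h)
}

# classify one karyotype and resolve the interval of every band-level event
# through the backend; no_order marks interval results unsupported
backend_workload <- function(k, backend) {
  classes <- classify_karyotype(k)
  intervals <- character(0)
  for (e in k$events) {
    if (e$level != "band") next
    bp <- e$breakpoints
    if (e$kind %in% c("del", "dup", "trp", "qdp", "inv") &&
        length(bp) == 2L && length(e$chromosomes) == 1L) {
      if (backend$supports_between) {
        intervals <- c(intervals,
                       paste(backend_between(backend, bp[1], bp[2]),
                             collapse = ","))
      } else {
        intervals <- c(intervals, "unsupported")
      }
    } else {
      intervals <- c(intervals, paste(sort(unique(bp)), collapse = ","))
    }
  }
  list(classes = paste(sort(classes), collapse = ";"),
       intervals = intervals)
}

#' Benchmark the ordering backends
#'
#' For each backend and each sample size, classifies that many seeded
#' random karyotypes resolving all band-interval queries through the
#' backend and records the wall time. Before timing is reported the
#' classification results of all backends, and the interval results of the
#' interval-capable ones, are asserted identical.
#'
#' @param n_list ascending sample sizes (default 10, 100, 1000, 10000).
#' @param seed integer seed for the karyotype generator.
#' @param map a `band_map`.
#' @param backends backend names to run (default all four).
#' @return data.frame with columns `backend`, `n`, `seconds`,
#'   `classifications_checksum`, `intervals_supported`.
#' @export
benchmark_backends <- function(n_list = c(10L, 100L, 1000L, 10000L),
                               seed = 1L,
                               map = default_band_map(),
                               backends = BACKEND_NAMES) {
  if (is.unsorted(n_list, strictly = TRUE)) {
    iscn_stop("n_list must be strictly ascending", "iscn_config_error")
  }
  built <- lapply(backends, build_backend, map = map)
  names(built) <- backends
  rows <- list()
  for (n in n_list) {
    ks <- generate_karyotypes(generator_config(seed = seed, n = n), map)
    results <- list()
    times <- numeric(0)
    for (bn in backends) {
      t <- system.time({
        results[[bn]] <- lapply(ks, backend_workload, backend = built[[bn]])
      })[["elapsed"]]
      times[bn] <- t
    }
    # correctness gate: identical classifications everywhere, identical
    # intervals among the interval-capable backends
    class_strings <- lapply(results, function(r) vapply(r, `[[`, "", "classes"))
    for (bn in backends[-1]) {
      if (!identical(class_strings[[bn]], class_strings[[backends[1]]])) {
        iscn_stop(sprintf("backend '%s' classifications diverge at n=%d", bn, n),
                  "iscn_consistency_error")
      }
    }
    capable <- backends[vapply(built[backends], `[[`, logical(1),
                               "supports_between")]
    if (length(capable) > 1L) {
      ref <- lapply(results[[capable[1]]], `[[`, "intervals")
      for (bn in capable[-1]) {
        if (!identical(lapply(results[[bn]], `[[`, "intervals"), ref)) {
          iscn_stop(sprintf("backend '%s' intervals diverge at n=%d", bn, n),
                    "iscn_consistency_error")
        }
      }
    }
    for (bn in backends) {
      payload <- c(class_strings[[bn]],
                   unlist(lapply(results[[bn]], `[[`, "intervals")))
      rows[[length(rows) + 1L]] <- data.frame(
        backend = bn, n = n, seconds = unname(times[bn]),
        classifications_checksum = checksum_strings(payload),
        intervals_supported = built[[bn]]$supports_between,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
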