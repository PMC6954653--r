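# shared fixtures: the packaged band map and an independent row-scan oracle
# over the raw band table (used to check interval queries without going
# through bands_between)
the_map <- iscnkit::default_band_map()

# brute-force interval oracle: scan the TSV rows of one chromosome in file
# (pter->qter) order, drop rows hidden at the resolution, drop parents whose
# sub-bands are visible, and slice between the two labels inclusively
oracle_between <- function(a, b, res = 300L) {
  tsv <- utils::read.delim(system.file("extdata", "band_map.tsv",
                                       package = "iscnkit"),
                           colClasses = "character")
  tsv$label <- paste0(tsv$chromosome, tsv$arm, tsv$band)
  chrom <- sub("^([0-9]+|[XY]).*$", "\\1", a)
  rows <- tsv[tsv$chromosome == chrom, ]
  res_min <- vapply(strsplit(rows$resolutions, ";"),
                    function(r) min(as.integer(r)), integer(1))
  visible <- res_min <= res
  divided <- rows$label %in% paste0(rows$chromosome, rows$arm,
                                    rows$parent)[visible]
  leaves <- rows$label[visible & !divided]
  i <- match(a, leaves)
  j <- match(b, leaves)
  leaves[min(i, j):max(i, j)]
}
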