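# In-code fixtures: a small tag-count table written to a temp file.

write_toy_tagcounts <- function(path = tempfile(fileext = ".tsv"),
                                rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      chrom = "chr1",
      pos = c(100L, 140L, 5000L, 5050L, 9000L),
      region_id = c("rA", "rA", "rB", "rB", "rC"),
      site_id = c("s1", "s2", "s3", "s4", "s5"),
      mspi_fwd = c(10L, 3L, 8L, 4L, 3L),
      mspi_rev = c(2L, 2L, 0L, 9L, 2L),
      hpaii_lib1_fwd = c(5L, 1L, 0L, 0L, 7L),
      hpaii_lib1_rev = c(2L, 4L, 0L, 1L, 0L),
      hpaii_lib2_fwd = c(0L, 0L, 3L, 2L, 1L),
      hpaii_lib2_rev = c(1L, 0L, 4L, 2L, 0L),
      stringsAsFactors = FALSE)
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
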