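#' Read CNV calls in the PennCNV text dialect
#'
#' Parses lines of the form
#' `chr2:129457798-129461606  numsnp=5  length=3,809  state2,cn=1  SAMPLE
#' startsnp=rsA  endsnp=rsB` (comma-grouped lengths tolerated). Each
#' record is validated: `length` must equal `end - start + 1` and the copy
#' number must differ from 2; violations raise an error naming the line.
#'
#' @param path text file of calls; an empty file yields zero calls.
#' @return calls data.frame (`sample_id`, `chromosome`, `start`, `end`,
#'   `copy_number`, `num_snps`, `start_probe`, `end_probe`).
#' @export
read_penncnv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_calls())
  pat <- paste0("^chr([^:\\s]+):(\\d+)-(\\d+)\\s+numsnp=(\\d+)\\s+",
                "length=([\\d,]+)\\s+state\\d+,cn=(\\d+)\\s+(\\S+)\\s+",
                "startsnp=(\\S+)\\s+endsnp=(\\S+)\\s*$")
  m <- regmatches(lines, regexec(pat, lines, perl = TRUE))
  bad <- which(lengths(m) == 0)
  if (length(bad))
    stop(sprintf("malformed PennCNV record at line %d: %s",
                 bad[1], lines[bad[1]]))
  f <- function(i) vapply(m, `[`, character(1), i + 1L)
  start <- as.numeric(f(2)); end <- as.numeric(f(3))
  len <- as.numeric(gsub(",", "", f(5)))
  cn <- as.integer(f(6))
  chk <- which(len != end - start + 1)
  if (length(chk))
    stop(sprintf("line %d: length=%s does not equal end - start + 1 = %d",
                 chk[1], f(5)[chk[1]], as.integer(end[chk[1]] - start[chk[1]] + 1)))
  if (any(cn == 2L))
    stop(sprintf("line %d: cn=2 records are not CNV calls",
                 which(cn == 2L)[1]))
  empty_calls(sample_id = f(7), chromosome = f(1), start = start, end = end,
              copy_number = cn, num_snps = as.integer(f(4)),
              start_probe = f(8), end_probe = f(9))
}

#' Write CNV calls in the PennCNV text dialect
#'
#' Inverse of [read_penncnv()]; lengths are comma-grouped and the PennCNV
#' state index is derived from the copy number (CN 0/1/3/4 map to states
#' 1/2/5/6).
#'
#' @param calls calls data.frame.
#' @param path output file.
#' @export
write_penncnv <- function(calls, path) {
  state_of <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)
  lines <- sprintf(
    "chr%s:%d-%d\tnumsnp=%d\tlength=%s\tstate%d,cn=%d\t%s\tstartsnp=%s\tendsnp=%s",
    calls$chromosome, as.integer(calls$start), as.integer(calls$end),
    calls$num_snps,
    formatC(as.integer(calls$end - calls$start + 1), big.mark = ",",
            format = "d"),
    state_of[as.character(calls$copy_number)], calls$copy_number,
    calls$sample_id, calls$start_probe, calls$end_probe)
  writeLines(lines, path)
}

#' Write segments as BED with class annotation
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so `start_bed = start - 1`, `end_bed = end`. Columns: chrom, start,
#' end, segment id, score (carrier count), class.
#'
#' @param sm a `segment_matrix`.
#' @param path output file; an empty matrix yields a header-only file.
#' @export
write_segments_bed <- function(sm, path) {
  stopifnot(inherits(sm, "segment_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tsegment_id\tn_carriers\tclass", con)
  if (nrow(sm$segments)) {
    n_car <- round(sm$carrier_freq * length(sm$sample_ids))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                       sm$segments$chromosome,
                       as.integer(sm$segments$start - 1),
                       as.integer(sm$segments$end),
                       sm$segments$segment_id, as.integer(n_car),
                       sm$class), con)
  }
}

#' Read a segments BED file back to 1-based inclusive coordinates
#'
#' @param path BED file written by [write_segments_bed()].
#' @return data.frame with `chromosome`, `start`, `end` (1-based
#'   inclusive), `segment_id`, `class`.
#' @export
read_segments_bed <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", header = FALSE,
                          col.names = c("chromosome", "start", "end",
                                        "segment_id", "n_carriers", "class"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character"))
  if (!nrow(df))
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), segment_id = character(0),
                      class = character(0), stringsAsFactors = FALSE))
  data.frame(chromosome = df$chromosome, start = df$start + 1L,
             end = df$end, segment_id = df$segment_id, class = df$class,
             stringsAsFactors = FALSE)
}

#' Write / read the samples-by-segments copy-number matrix as TSV
#'
#' Rows are samples, columns segments; the first column is `sample_id`.
#'
#' @param sm a `segment_matrix`.
#' @param path output file.
#' @export
write_segment_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "segment_matrix"))
  df <- data.frame(sample_id = sm$sample_ids, sm$cn, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_segment_matrix
#' @return `read_segment_matrix()` returns a list with `cn` (integer
#'   matrix) and `sample_ids`.
#' @export
read_segment_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  cn <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(cn) <- "integer"
  rownames(cn) <- df$sample_id
  list(cn = cn, sample_ids = as.character(df$sample_id))
}

#' Tabular readers/writers for phenotype, covariate and label tables
#'
#' Plain UTF-8 TSV with a header row; missing values are written as `.`
#' and read back as `NA`.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE)
}
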