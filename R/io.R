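#' File format helpers
#'
#' Readers and writers for the plain-text formats the pipeline exchanges:
#' narrowPeak / BED6 peak and read intervals, chrom sizes, count tables,
#' GMT gene sets, JASPAR-style PWM text, and FASTA (via Biostrings).
#' All genomic intervals are 0-based half-open on disk (BED convention)
#' and in memory.
#'
#' @name acetylink-io
NULL

#' Read a narrowPeak (BED6+4) or BED6 peak file
#'
#' narrowPeak carries the summit as an offset from `start` in column 10;
#' for plain BED6 input the summit defaults to the interval midpoint.
#' A summit offset of -1 (MACS convention for "not called") also falls
#' back to the midpoint.
#'
#' @param path Path to a narrowPeak or BED6 file.
#' @param sample Optional sample id recorded in the `sample` column.
#' @return A data.frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `summit` (absolute bp), `score`, `sample`.
#' @export
read_narrowpeak <- function(path, sample = NA_character_) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 6) {
    stop("peak file ", path, " has ", ncol(tab), " columns; need BED6 or narrowPeak")
  }
  start <- as.integer(tab[[2]])
  end <- as.integer(tab[[3]])
  if (ncol(tab) >= 10) {
    off <- as.integer(tab[[10]])
    summit <- ifelse(off >= 0, start + off, start + (end - start) %/% 2L)
    score <- as.numeric(tab[[7]])  # signalValue
  } else {
    summit <- start + (end - start) %/% 2L
    score <- as.numeric(tab[[5]])
  }
  data.frame(peak_id = as.character(tab[[4]]), chrom = as.character(tab[[1]]),
             start = start, end = end, summit = as.integer(summit),
             score = score, sample = sample, stringsAsFactors = FALSE)
}

#' Write peaks as narrowPeak
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `peak_id`, `summit`,
#'   and optionally `score`.
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  score <- if ("score" %in% names(peaks)) peaks$score else 0
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    0L, ".", score, -1, -1, peaks$summit - peaks$start)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read aligned-read intervals from a BED file
#'
#' @param path BED3+ file of read intervals (0-based half-open).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed_reads <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  data.frame(chrom = as.character(tab[[1]]), start = as.integer(tab[[2]]),
             end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
}

#' Read a two-column chrom sizes table
#'
#' @param path TSV of chromosome name and length (bp).
#' @return Named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), as.character(tab[[1]]))
}

#' Read a count table (features x samples, header of sample ids)
#'
#' @param path TSV with a leading feature-id column and one column per sample.
#' @return Integer matrix with feature rownames and sample colnames.
#' @export
read_count_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a count or signal table as TSV
#'
#' @param mat Matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param id_col Name of the leading feature-id column.
#' @export
write_count_table <- function(mat, path, id_col = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV with stable column order
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(lapply(df, function(x) if (is.list(x)) vapply(x, paste, "", collapse = ",") else x),
                      stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- names(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#'
#' @param path GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", substr(ln, 1, 60))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read peak sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
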