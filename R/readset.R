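#' Read sets and library designs
#'
#' A `read_set` is the in-memory form of one sequenced selection pool: a
#' character vector of uppercase DNA sequences with read identifiers, plus a
#' pool label. Per-base qualities, when present in the source FASTQ, are
#' ignored downstream and not retained.
#'
#' @param sequences character vector of DNA sequences (A/C/G/T/N).
#' @param pool_id non-empty pool label, e.g. `"butylone_P5"`.
#' @param read_ids optional read identifiers; defaults to `read_1 ... read_n`.
#' @return An object of class `read_set`: a list with elements `pool_id`,
#'   `read_ids` and `sequences`.
#' @export
read_set <- function(sequences, pool_id, read_ids = NULL) {
  stopifnot(is.character(sequences))
  if (!is.character(pool_id) || length(pool_id) != 1L || !nzchar(pool_id))
    stop("pool_id must be a non-empty string")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop(sprintf("%d sequence(s) contain characters outside A/C/G/T/N (first at index %d)",
                 sum(bad), which(bad)[1L]))
  if (is.null(read_ids)) {
    read_ids <- if (length(sequences)) paste0("read_", seq_along(sequences)) else character()
  }
  stopifnot(length(read_ids) == length(sequences))
  structure(
    list(pool_id = pool_id, read_ids = as.character(read_ids), sequences = sequences),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> pool '%s': %d reads\n", x$pool_id, length(x$sequences)))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$sequences)

#' Stem-loop library geometry
#'
#' Describes the fixed architecture of the selection library: each strand is
#' `total_length` nt, with a randomized region of `random_length` nt flanked
#' by a forward flank (forward primer region plus 5' stem) and a reverse
#' flank (3' stem plus reverse primer region).
#'
#' @param forward_flank,reverse_flank DNA strings; must be non-empty.
#' @param random_length length of the randomized loop in nt.
#' @param total_length full strand length in nt; must equal
#'   `nchar(forward_flank) + random_length + nchar(reverse_flank)`.
#' @return An object of class `library_design`.
#' @seealso [default_library_design()]
#' @export
library_design <- function(forward_flank, reverse_flank, random_length = 30L,
                           total_length = nchar(forward_flank) + random_length +
                             nchar(reverse_flank)) {
  forward_flank <- toupper(forward_flank)
  reverse_flank <- toupper(reverse_flank)
  stopifnot(nzchar(forward_flank), nzchar(reverse_flank))
  if (grepl("[^ACGT]", paste0(forward_flank, reverse_flank)))
    stop("flank sequences must contain only A/C/G/T")
  random_length <- as.integer(random_length)
  total_length <- as.integer(total_length)
  if (nchar(forward_flank) + random_length + nchar(reverse_flank) != total_length)
    stop("flank lengths + random_length must equal total_length")
  structure(
    list(forward_flank = forward_flank, reverse_flank = reverse_flank,
         random_length = random_length, total_length = total_length),
    class = "library_design"
  )
}

#' Default stand-in library design
#'
#' A 73-nt stem-loop design with a 30-nt random loop flanked by an 8-bp stem
#' and primer-binding regions. The primer and stem sequences are synthetic
#' stand-ins (the study's own primer sequences live in supplementary material
#' that is user-supplied when analyzing real reads); the two stems are exact
#' reverse complements so generated strands can fold into the intended
#' stem-loop.
#'
#' @return A [library_design()] with 22-nt forward and 21-nt reverse flanks.
#' @export
default_library_design <- function() {
  # 14-nt fwd primer + 8-nt stem | 30 nt random | revcomp stem + 13-nt rev primer
  library_design(
    forward_flank = "ACGCTTAGCAGGACGGAGGCTC",
    reverse_flank = "GAGCCTCCTGGTCCGTTAGGT",
    random_length = 30L,
    total_length  = 73L
  )
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf("<library_design> %d nt = %d-nt fwd flank + %d-nt random + %d-nt rev flank\n",
              x$total_length, nchar(x$forward_flank), x$random_length,
              nchar(x$reverse_flank)))
  invisible(x)
}

#' Read sequences from FASTQ or FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()]; gzip-compressed
#' files are handled transparently. Qualities in FASTQ input are parsed for
#' validation but dropped, since downstream pool analysis ignores them.
#'
#' @param path path to a (optionally gzipped) FASTQ or FASTA file.
#' @param pool_id pool label for the resulting [read_set()]; defaults to the
#'   file name without extensions.
#' @return A [read_set()].
#' @export
read_fastq <- function(path, pool_id = NULL) {
  .read_seqfile(path, "fastq", pool_id)
}

#' @rdname read_fastq
#' @export
read_fasta <- function(path, pool_id = NULL) {
  .read_seqfile(path, "fasta", pool_id)
}

.read_seqfile <- function(path, format, pool_id) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(pool_id))
    pool_id <- sub("\\.(fastq|fq|fasta|fa)(\\.gz)?$", "", basename(path))
  if (format == "fastq") .validate_fastq(path)
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) stop(sprintf("malformed %s file '%s': %s",
                                     format, path, conditionMessage(e)))
  )
  ids <- names(dss)
  if (is.null(ids)) ids <- paste0("read_", seq_along(dss))
  # keep only the identifier token, drop FASTQ/FASTA description suffixes
  ids <- sub("\\s.*$", "", ids)
  read_set(unname(as.character(dss)), pool_id = pool_id, read_ids = ids)
}

# structural check of 4-line FASTQ records (Biostrings is lenient about
# truncation); reports the index of the offending record
.validate_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed fastq file '%s': truncated record %d",
                 path, length(lines) %/% 4L + 1L))
  if (length(lines) == 0L) return(invisible())
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("malformed fastq file '%s': sequence/quality length mismatch in record %d",
                 path, bad[1L]))
  invisible()
}

#' Write a read set as FASTQ
#'
#' Writes standard 4-line-per-record FASTQ. Because qualities are not
#' retained in a [read_set()], every base gets a constant Q30 placeholder
#' (`'?'`), which downstream analysis ignores.
#'
#' @param reads a [read_set()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  n <- length(reads$sequences)
  if (n == 0L) return(invisible(path))
  qual <- vapply(nchar(reads$sequences), function(k) strrep("?", k), character(1))
  rec <- character(4L * n)
  rec[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$read_ids)
  rec[seq(2L, by = 4L, length.out = n)] <- reads$sequences
  rec[seq(3L, by = 4L, length.out = n)] <- "+"
  rec[seq(4L, by = 4L, length.out = n)] <- qual
  writeLines(rec, con)
  invisible(path)
}
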