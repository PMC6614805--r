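#' Trim selection-pool reads to their randomized region
#'
#' Locates the forward and reverse flanks of the library design in each read
#' and extracts the randomized loop between them. A read is kept only when
#' the forward flank matches, the reverse flank matches immediately after
#' the extracted region, and the extracted region has exactly
#' `design$random_length` bases; everything else is discarded and counted.
#' Matching is on the sense strand only (no reverse-complement rescue) and
#' exact by default; `max_mismatch > 0` allows up to that many Hamming
#' mismatches per flank (no indels).
#'
#' @param reads a [read_set()].
#' @param design a [library_design()].
#' @param max_mismatch maximum Hamming mismatches tolerated in each flank
#'   (default 0 = exact).
#' @return A list with elements `reads` (a [read_set()] of random regions
#'   only) and `report` (`list(input, kept, discarded)`).
#' @export
trim_to_random_region <- function(reads, design, max_mismatch = 0L) {
  stopifnot(inherits(reads, "read_set"), inherits(design, "library_design"))
  ff <- design$forward_flank; rf <- design$reverse_flank
  lr <- design$random_length
  n <- length(reads$sequences)
  if (n == 0L) {
    return(list(
      reads = read_set(character(), pool_id = reads$pool_id),
      report = list(input = 0L, kept = 0L, discarded = 0L)
    ))
  }
  if (max_mismatch == 0L) {
    pos <- regexpr(ff, reads$sequences, fixed = TRUE)
    s <- as.integer(pos) + nchar(ff)            # region start (1-based)
    regions <- substr(reads$sequences, s, s + lr - 1L)
    rf_obs <- substr(reads$sequences, s + lr, s + lr + nchar(rf) - 1L)
    keep <- pos > 0L & nchar(regions) == lr & rf_obs == rf
  } else {
    keep <- logical(n)
    regions <- character(n)
    for (i in seq_len(n)) {
      hit <- .flank_extract(reads$sequences[i], ff, rf, lr, max_mismatch)
      if (!is.na(hit)) { keep[i] <- TRUE; regions[i] <- hit }
    }
  }
  kept <- read_set(regions[keep], pool_id = reads$pool_id,
                   read_ids = reads$read_ids[keep])
  list(reads = kept,
       report = list(input = n, kept = sum(keep), discarded = n - sum(keep)))
}

# first position where ff matches within max_mismatch, with rf matching
# (within max_mismatch) right after the lr-base region; NA when no such site
.flank_extract <- function(seq, ff, rf, lr, max_mismatch) {
  nseq <- nchar(seq); nff <- nchar(ff); nrf <- nchar(rf)
  last_start <- nseq - (nff + lr + nrf) + 1L
  if (last_start < 1L) return(NA_character_)
  sv <- strsplit(seq, "", fixed = TRUE)[[1L]]
  fv <- strsplit(ff, "", fixed = TRUE)[[1L]]
  rv <- strsplit(rf, "", fixed = TRUE)[[1L]]
  for (p in seq_len(last_start)) {
    if (sum(sv[p:(p + nff - 1L)] != fv) > max_mismatch) next
    rs <- p + nff + lr
    if (sum(sv[rs:(rs + nrf - 1L)] != rv) > max_mismatch) next
    return(substr(seq, p + nff, p + nff + lr - 1L))
  }
  NA_character_
}

#' Count unique sequences in a trimmed pool
#'
#' Collapses exact duplicate random-region sequences and reports, per unique
#' sequence, its read count, its fraction of the trimmed pool, and reads per
#' million (rpm). Entries are ranked by reads descending with ties broken
#' lexicographically by sequence, so ranked output is deterministic.
#'
#' @param trimmed a [read_set()] of random regions (all the same length).
#' @return An object of class `pool_counts`: list with `pool_id`,
#'   `total_reads`, `random_length` and `entries` (data.frame with columns
#'   `sequence`, `reads`, `fraction`, `rpm`, `rank`).
#' @export
count_pool <- function(trimmed) {
  stopifnot(inherits(trimmed, "read_set"))
  n <- length(trimmed$sequences)
  if (n == 0L) stop("empty pool: no trimmed reads to count")
  lens <- unique(nchar(trimmed$sequences))
  if (length(lens) != 1L)
    stop("trimmed reads must all have the same length")
  dt <- data.table::data.table(sequence = trimmed$sequences)
  dt <- dt[, list(reads = .N), by = "sequence"]
  data.table::setorderv(dt, c("reads", "sequence"), order = c(-1L, 1L))
  entries <- as.data.frame(dt)
  entries$fraction <- entries$reads / n
  entries$rpm <- entries$fraction * 1e6
  entries$rank <- seq_len(nrow(entries))
  structure(
    list(pool_id = trimmed$pool_id, total_reads = n,
         random_length = lens, entries = entries),
    class = "pool_counts"
  )
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("<pool_counts> pool '%s': %d reads, %d unique sequences\n",
              x$pool_id, x$total_reads, nrow(x$entries)))
  cat(sprintf("  top sequence: %s (%.4g%%)\n",
              x$entries$sequence[1L], 100 * x$entries$fraction[1L]))
  invisible(x)
}

#' Abundance of a motif-defined sequence family
#'
#' A family is the set of unique sequences whose random region contains the
#' given motif as an exact substring at any offset (sense strand only). The
#' family fraction is the summed pool fraction of those sequences.
#'
#' @param pool a [count_pool()] result.
#' @param motif DNA motif, no longer than the random region.
#' @return Dimensionless family fraction in `[0, 1]`.
#' @export
family_fraction <- function(pool, motif) {
  stopifnot(inherits(pool, "pool_counts"))
  motif <- toupper(motif)
  if (nchar(motif) > pool$random_length)
    stop("motif is longer than the random region")
  hit <- grepl(motif, pool$entries$sequence, fixed = TRUE)
  sum(pool$entries$fraction[hit])
}

#' Combine selection pools by molar weights
#'
#' Models mixing pools in given molar proportions: the combined fraction of
#' every sequence is the weighted mean of its per-pool fractions,
#' `sum_k w_k f_ik / sum_k w_k`. Equal weights model equimolar mixing (the
#' usual "100 pmole each" combination of parallel pools). Read counts are
#' summed for reference, but the combined `fraction` column is defined by
#' the weights, not by pooled read counts.
#'
#' @param pools list of [count_pool()] results with equal random-region
#'   lengths.
#' @param weights non-negative molar weights, one per pool; at least one
#'   must be positive. Default: equal.
#' @param pool_id label for the combined pool.
#' @return A `pool_counts` object.
#' @export
combine_pools <- function(pools, weights = rep(1, length(pools)),
                          pool_id = "combined") {
  stopifnot(length(pools) >= 1L, length(weights) == length(pools))
  lapply(pools, function(p) stopifnot(inherits(p, "pool_counts")))
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with a positive sum")
  lens <- unique(vapply(pools, `[[`, integer(1), "random_length"))
  if (length(lens) != 1L)
    stop("pools have mismatched random-region lengths")
  w <- weights / sum(weights)
  parts <- mapply(function(p, wk) {
    data.table::data.table(sequence = p$entries$sequence,
                           wf = p$entries$fraction * wk,
                           reads = p$entries$reads)
  }, pools, w, SIMPLIFY = FALSE)
  dt <- data.table::rbindlist(parts)
  dt <- dt[, list(fraction = sum(wf), reads = sum(reads)), by = "sequence"]
  data.table::setorderv(dt, c("fraction", "sequence"), order = c(-1L, 1L))
  entries <- as.data.frame(dt)[, c("sequence", "reads", "fraction")]
  entries$rpm <- entries$fraction * 1e6
  entries$rank <- seq_len(nrow(entries))
  structure(
    list(pool_id = pool_id,
         total_reads = sum(vapply(pools, `[[`, numeric(1), "total_reads")),
         random_length = lens, entries = entries),
    class = "pool_counts"
  )
}

#' Summarize the abundance distribution of a pool
#'
#' Percentiles (5th, 50th, 95th) of the per-unique-sequence fraction
#' distribution, computed by linear interpolation between closest order
#' statistics (the convention of `stats::quantile(type = 7)`), plus the
#' maximum fraction and the number of unique sequences. This is the summary
#' underlying box-and-whisker views of pool diversity across rounds.
#'
#' @param pool a [count_pool()] result.
#' @return An object of class `pool_summary`: list with `percentiles`
#'   (named numeric, `p5`, `p50`, `p95`), `max_fraction`, `n_unique`.
#' @export
pool_summary <- function(pool) {
  stopifnot(inherits(pool, "pool_counts"))
  f <- pool$entries$fraction
  if (!length(f)) stop("empty pool")
  q <- stats::quantile(f, probs = c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  structure(
    list(percentiles = c(p5 = q[1L], p50 = q[2L], p95 = q[3L]),
         max_fraction = max(f), n_unique = length(f)),
    class = "pool_summary"
  )
}

#' @export
print.pool_summary <- function(x, ...) {
  cat(sprintf("<pool_summary> %d unique sequences; fractions p5=%.3g p50=%.3g p95=%.3g max=%.3g\n",
              x$n_unique, x$percentiles[["p5"]], x$percentiles[["p50"]],
              x$percentiles[["p95"]], x$max_fraction))
  invisible(x)
}

#' Motif-family trajectory across ordered selection rounds
#'
#' Computes, for each round in order, the motif-family fraction and the
#' median per-unique-sequence fraction, tracking enrichment of a family
#' (e.g. the SCA2.1 family, defined by a 20-nt motif) over selection.
#'
#' @param pools ordered list of [count_pool()] results (round order).
#' @param motif family-defining DNA motif.
#' @return An object of class `family_trajectory`: data.frame with columns
#'   `round_id`, `family_fraction`, `median_fraction`; attribute `motif`.
#' @export
enrichment_trajectory <- function(pools, motif) {
  stopifnot(length(pools) >= 1L)
  out <- data.frame(
    round_id = vapply(pools, `[[`, character(1), "pool_id"),
    family_fraction = vapply(pools, family_fraction, numeric(1), motif = motif),
    median_fraction = vapply(pools, function(p)
      stats::median(p$entries$fraction), numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(out, motif = toupper(motif),
            class = c("family_trajectory", "data.frame"))
}

#' The SCA2.1 family-defining motif
#'
#' The 20-nt motif whose presence anywhere in the 30-nt random region
#' defines membership in the SCA2.1 aptamer family (the class-specific
#' synthetic-cathinone binder tracked across selection rounds).
#' @export
sca21_motif <- "AGTGGGGTTCGGGTGGAGTT"
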