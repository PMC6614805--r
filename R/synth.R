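#' Specification of one synthetic selection pool
#'
#' Describes a pool to be generated by [make_pool()]: total read count, the
#' library design, motif-carrying families spiked at controlled fractions
#' on top of a uniform-random background, and the fraction of reads to
#' corrupt (flank truncation) so trimming has something to discard. A seed
#' is mandatory: every generated pool is fully deterministic.
#'
#' Families are given either as a full random-region sequence or as a
#' shorter motif, in which case one representative member is built by
#' embedding the motif in seeded random padding. Background reads are
#' i.i.d. uniform random regions; no sequencing-error or PCR-bias model is
#' applied.
#'
#' @param round_id pool label (e.g. `"S6"`).
#' @param n_reads total reads to generate.
#' @param families list of `list(sequence = <motif or full region>,
#'   fraction = <target abundance>)`; fractions must sum to < 1.
#' @param design a [library_design()].
#' @param malformed_fraction fraction of reads whose forward flank is
#'   truncated (these fail trimming).
#' @param seed integer RNG seed (mandatory).
#' @return Object of class `pool_spec`.
#' @export
pool_spec <- function(round_id, n_reads, families = list(),
                      design = default_library_design(),
                      malformed_fraction = 0, seed) {
  if (missing(seed)) stop("seed is mandatory for synthetic pools")
  stopifnot(n_reads >= 1, malformed_fraction >= 0, malformed_fraction < 1,
            inherits(design, "library_design"))
  fr <- vapply(families, function(f) f$fraction, numeric(1))
  if (length(fr) && (any(fr < 0) || sum(fr) > 1))
    stop("family fractions must be non-negative and sum to at most 1")
  structure(
    list(round_id = as.character(round_id), n_reads = as.integer(n_reads),
         families = families, design = design,
         malformed_fraction = malformed_fraction, seed = as.integer(seed)),
    class = "pool_spec"
  )
}

# n i.i.d. uniform random DNA strings of the given length, vectorized:
# one column-wise paste over a (n x len) character matrix
.random_regions <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n, len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# embed a motif in random padding to make one full-length family region
.family_region <- function(seqdef, random_length) {
  seqdef <- toupper(seqdef)
  k <- nchar(seqdef)
  if (k > random_length) stop("family sequence longer than random region")
  if (k == random_length) return(seqdef)
  pad <- random_length - k
  left <- sample.int(pad + 1L, 1L) - 1L
  paste0(.random_regions(1L, left), seqdef, .random_regions(1L, pad - left))
}

#' Generate a synthetic selection pool
#'
#' Draws read category counts from a multinomial over (families,
#' background), builds full-length strands by wrapping each random region
#' in the design flanks, corrupts `malformed_fraction` of reads by
#' truncating the forward flank, and shuffles read order. The returned
#' truth manifest records, per family, the representative sequence, the
#' target fraction, the drawn read count and the count surviving
#' corruption, so expected downstream statistics are exactly computable.
#'
#' @param spec a [pool_spec()].
#' @param path optional FASTQ output path (`.gz` for gzip); when `NULL` the
#'   reads stay in memory only.
#' @return List with `reads` (a [read_set()] of full-length strands) and
#'   `manifest` (list; see Details).
#' @export
make_pool <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "pool_spec"))
  out <- .with_seed(spec$seed, {
    des <- spec$design
    n <- spec$n_reads
    k <- length(spec$families)
    fam_regions <- vapply(spec$families, function(f)
      .family_region(f$sequence, des$random_length), character(1))
    fr <- vapply(spec$families, function(f) f$fraction, numeric(1))
    probs <- c(fr, 1 - sum(fr))
    counts <- drop(stats::rmultinom(1L, n, probs))
    regions <- c(
      if (k) rep(fam_regions, counts[seq_len(k)]) else character(),
      .random_regions(counts[k + 1L], des$random_length)
    )
    category <- rep.int(c(seq_len(k), 0L), counts)   # 0 = background
    ord <- sample.int(n)
    regions <- regions[ord]
    category <- category[ord]
    strands <- paste0(des$forward_flank, regions, des$reverse_flank)
    n_bad <- as.integer(round(spec$malformed_fraction * n))
    bad <- if (n_bad) sample.int(n, n_bad) else integer()
    if (n_bad) {
      # drop the first half of the forward flank: trimming must discard these
      cut <- nchar(des$forward_flank) %/% 2L
      strands[bad] <- substring(strands[bad], cut + 1L)
    }
    malformed <- logical(n)
    malformed[bad] <- TRUE
    fam_drawn <- if (k) counts[seq_len(k)] else integer()
    fam_kept <- if (k) vapply(seq_len(k), function(j)
      sum(category == j & !malformed), integer(1)) else integer()
    list(strands = strands, malformed = malformed,
         fam_regions = fam_regions, fam_drawn = fam_drawn, fam_kept = fam_kept)
  })
  reads <- read_set(out$strands, pool_id = spec$round_id)
  manifest <- list(
    round_id = spec$round_id,
    n_reads = spec$n_reads,
    seed = spec$seed,
    design = list(forward_flank = spec$design$forward_flank,
                  reverse_flank = spec$design$reverse_flank,
                  random_length = spec$design$random_length,
                  total_length = spec$design$total_length),
    families = if (length(spec$families)) lapply(seq_along(spec$families), function(j) {
      list(sequence = out$fam_regions[j],
           motif = toupper(spec$families[[j]]$sequence),
           target_fraction = spec$families[[j]]$fraction,
           drawn_reads = out$fam_drawn[j],
           kept_reads = out$fam_kept[j])
    }) else list(),
    n_malformed = sum(out$malformed),
    n_wellformed = spec$n_reads - sum(out$malformed)
  )
  if (!is.null(path)) write_fastq(reads, path)
  list(reads = reads, manifest = manifest)
}

#' Generate an ordered series of selection rounds
#'
#' One synthetic pool per round, with family fractions following the given
#' per-round trajectory (e.g. the combined-pool, S3 and S6 family
#' fractions of an enrichment series). Per-round seeds are derived
#' deterministically from the base seed.
#'
#' @param round_ids character vector of round labels, in order.
#' @param n_reads per-round read counts (recycled).
#' @param motif family-defining motif spiked in every round.
#' @param fractions per-round family target fractions.
#' @param design a [library_design()].
#' @param malformed_fraction per-round corrupted-read fraction (recycled).
#' @param seed base seed; round r uses `seed + r - 1`.
#' @return List with `pools` (list of [make_pool()] results, in round
#'   order) and `truth` (data.frame `round_id`, `target_fraction`,
#'   `drawn_fraction`).
#' @export
make_round_series <- function(round_ids, n_reads, motif, fractions,
                              design = default_library_design(),
                              malformed_fraction = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  r <- length(round_ids)
  stopifnot(length(fractions) == r)
  n_reads <- rep_len(n_reads, r)
  malformed_fraction <- rep_len(malformed_fraction, r)
  pools <- lapply(seq_len(r), function(i) {
    fams <- if (fractions[i] > 0)
      list(list(sequence = motif, fraction = fractions[i])) else list()
    make_pool(pool_spec(round_ids[i], n_reads[i], families = fams,
                        design = design,
                        malformed_fraction = malformed_fraction[i],
                        seed = seed + i - 1L))
  })
  drawn <- vapply(pools, function(p) {
    if (length(p$manifest$families))
      p$manifest$families[[1L]]$kept_reads / p$manifest$n_wellformed
    else 0
  }, numeric(1))
  list(pools = pools,
       truth = data.frame(round_id = as.character(round_ids),
                          target_fraction = fractions,
                          drawn_fraction = drawn,
                          stringsAsFactors = FALSE))
}

#' Forward-simulate a binding assay with known truth
#'
#' Generates one synthetic assay dataset by delegating to the package's own
#' forward models, adding seeded Gaussian noise, and returning the
#' generating parameters as a truth manifest.
#'
#' Models:
#' \describe{
#'   \item{`langmuir`}{gel-elution curve; parameters `K_D` (uM),
#'     `theta_max`; schedule `conc` (uM).}
#'   \item{`one_site_itc`}{ITC isotherm from [one_site_params()] +
#'     [itc_experiment()].}
#'   \item{`racemic_itc`}{ITC isotherm from [racemic_params()] +
#'     [itc_experiment()].}
#'   \item{`dye_displacement`}{target titration into a dye/aptamer mix;
#'     target and dye compete for the aptamer (solved with
#'     [solve_equilibrium_racemic()]); returns `conc`, `A670`, `A775`.
#'     Parameters: `K_D_dye`, `K_D_target` (uM), `dye_conc`,
#'     `aptamer_conc` (uM), and absorbance endpoints for the two dye
#'     states: `a670_bound`, `a670_displaced` (aptamer-bound monomer is
#'     low at 670 nm, displaced dimer high) and `a775_bound`,
#'     `a775_displaced` (bound monomer high at 775 nm).}
#' }
#'
#' @param model one of `"langmuir"`, `"one_site_itc"`, `"racemic_itc"`,
#'   `"dye_displacement"`.
#' @param parameters named list of generating parameters (see Details).
#' @param schedule named list: `conc` for curve models, or `exp` (an
#'   [itc_experiment()]) for ITC models.
#' @param noise_sd Gaussian noise SD, in the data's own units.
#' @param seed integer seed (mandatory).
#' @return List with `data` (data.frame) and `truth` (the parameters plus
#'   model and seed).
#' @export
make_assay <- function(model, parameters, schedule, noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(noise_sd >= 0)
  truth <- c(list(model = model, noise_sd = noise_sd, seed = seed), parameters)
  data <- switch(
    model,
    langmuir = {
      conc <- schedule$conc
      theta <- langmuir_theta(conc, parameters$K_D, parameters$theta_max)
      if (noise_sd > 0)
        theta <- theta + .with_seed(seed, stats::rnorm(length(conc), 0, noise_sd))
      data.frame(conc_uM = conc, theta = theta)
    },
    one_site_itc = {
      p <- one_site_params(parameters$N, parameters$K_D, parameters$dH,
                           baseline = parameters$baseline %||% 0)
      as.data.frame(simulate_isotherm(p, schedule$exp, noise_sd = noise_sd,
                                      seed = seed))
    },
    racemic_itc = {
      p <- racemic_params(parameters$N, parameters$K_D_minus,
                          parameters$K_D_plus, parameters$dH_minus,
                          parameters$dH_plus,
                          fraction_minus = parameters$fraction_minus %||% 0.5,
                          baseline = parameters$baseline %||% 0)
      as.data.frame(simulate_isotherm(p, schedule$exp, noise_sd = noise_sd,
                                      seed = seed))
    },
    dye_displacement = {
      conc <- schedule$conc
      bound_dye <- vapply(conc, function(cc) {
        solve_equilibrium_racemic(
          M_t = parameters$aptamer_conc,
          L1_t = parameters$dye_conc, L2_t = cc,
          K_D1 = parameters$K_D_dye, K_D2 = parameters$K_D_target)[1L]
      }, numeric(1))
      fb <- bound_dye / parameters$dye_conc          # fraction of dye bound
      A775 <- parameters$a775_displaced + (parameters$a775_bound - parameters$a775_displaced) * fb
      A670 <- parameters$a670_displaced + (parameters$a670_bound - parameters$a670_displaced) * fb
      if (noise_sd > 0) {
        eps <- .with_seed(seed, stats::rnorm(2L * length(conc), 0, noise_sd))
        A670 <- A670 + eps[seq_along(conc)]
        A775 <- A775 + eps[length(conc) + seq_along(conc)]
      }
      data.frame(conc_uM = conc, A670 = A670, A775 = A775)
    },
    stop(sprintf("unknown assay model '%s'", model))
  )
  list(data = data, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a generator truth manifest as YAML
#'
#' Serializes the truth manifest of [make_pool()] (or any list-shaped
#' manifest) so generated FASTQ files travel with their ground truth.
#'
#' @param manifest a manifest list.
#' @param path output path (conventionally `.yaml`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}
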