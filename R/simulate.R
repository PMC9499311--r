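# Stochastic cells-by-positions simulator.
#
# The generative picture: sequencing signal amplitude at a position is
# the number of cells still carrying a lesion there, i.e. the data are a
# superposition of independent single-cell experiments on a 2-D grid
# (cells x positions). Per cell and dipyrimidine position a lesion forms
# with probability damage_prob; a lesion is repair-competent with
# probability theta; competent lesions repair at a time drawn from
# Weibull(shape m, scale tau) -- the unique law whose CDF times theta
# reproduces the KJMA repair fraction.

#' Simulation configuration
#'
#' Default study conditions: 2,000 cells, 200 regions of 200 positions,
#' damage probability 0.05 per dipyrimidine site (a high acute UV dose),
#' damage sampling at 0/20/60/120 minutes and excision sampling at
#' 5/20/60 minutes, ground-truth parameters drawn uniformly from
#' m in \[0.8, 3\], tau in \[30, 150\] minutes, theta in \[0.5, 0.95\],
#' and no sequencing noise (so analytic checks stay exact; enable
#' `noise = "poisson"` for count-resampling noise).
#'
#' @param n_cells Cells per simulated population.
#' @param n_regions Number of regions.
#' @param positions_per_region Lesion-eligible positions per region.
#' @param damage_prob Lesion probability per cell and position.
#' @param sample_times Damage sampling times (minutes); must include 0.
#' @param xr_times Excision-repair sampling times (minutes).
#' @param xr_window Width (minutes) of the excision capture window.
#' @param noise `"none"` or `"poisson"`.
#' @param m_range,tau_range,theta_range Uniform priors for ground truth.
#' @param seed Integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_cells = 2000L, n_regions = 200L,
                       positions_per_region = 200L, damage_prob = 0.05,
                       sample_times = c(0, 20, 60, 120),
                       xr_times = c(5, 20, 60), xr_window = 10,
                       noise = c("none", "poisson"),
                       m_range = c(0.8, 3), tau_range = c(30, 150),
                       theta_range = c(0.5, 0.95), seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_cells >= 1L, n_regions >= 1L, positions_per_region >= 1L,
            damage_prob > 0, damage_prob <= 1, 0 %in% sample_times,
            all(theta_range > 0), all(theta_range <= 1),
            all(m_range > 0), all(tau_range > 0), xr_window > 0)
  structure(list(n_cells = as.integer(n_cells),
                 n_regions = as.integer(n_regions),
                 positions_per_region = as.integer(positions_per_region),
                 damage_prob = damage_prob,
                 sample_times = sort(sample_times), xr_times = sort(xr_times),
                 xr_window = xr_window, noise = noise,
                 m_range = m_range, tau_range = tau_range,
                 theta_range = theta_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one region's cell population
#'
#' Independent draws per cell and position: lesion ~ Bernoulli
#' (`damage_prob`); given a lesion, repair competence ~ Bernoulli
#' (`theta`); given competence, repair time ~ Weibull(shape `m`, scale
#' `tau`). Incompetent lesions never repair (`Inf`).
#'
#' @param m,tau,theta Ground-truth KJMA parameters of the region.
#' @param n_cells,n_positions Grid dimensions.
#' @param damage_prob Lesion probability per cell and position.
#' @return A list of class `"population_grid"`: `lesions` (logical
#'   `n_cells x n_positions`) and `repair_time` (numeric, minutes; `NA`
#'   where there is no lesion, `Inf` for never-repaired lesions).
#' @export
simulate_population <- function(m, tau, theta, n_cells, n_positions,
                                damage_prob = 0.05) {
  stopifnot(m > 0, tau > 0, theta >= 0, theta <= 1, n_cells >= 1L,
            n_positions >= 1L)
  n <- n_cells * n_positions
  lesions <- matrix(stats::runif(n) < damage_prob, n_cells, n_positions)
  rt <- matrix(NA_real_, n_cells, n_positions)
  idx <- which(lesions)
  if (length(idx)) {
    competent <- stats::runif(length(idx)) < theta
    times <- rep(Inf, length(idx))
    if (any(competent))
      times[competent] <- stats::rweibull(sum(competent), shape = m,
                                          scale = tau)
    rt[idx] <- times
  }
  structure(list(lesions = lesions, repair_time = rt,
                 params = c(m = m, tau = tau, theta = theta)),
            class = "population_grid")
}

#' Per-position damage counts at the sample times
#'
#' The count at position `i` and time `t` is the number of cells whose
#' lesion at `i` is still unrepaired (repair time `> t`). With
#' `noise = "poisson"` each count is Poisson-resampled, emulating
#' sequencing-depth noise.
#'
#' @param grid A [simulate_population] result.
#' @param sample_times Times in minutes.
#' @param noise `"none"` or `"poisson"`.
#' @return Integer matrix, positions x times (columns named `t<time>`).
#' @export
sample_damage_counts <- function(grid, sample_times = c(0, 20, 60, 120),
                                 noise = c("none", "poisson")) {
  noise <- match.arg(noise)
  stopifnot(inherits(grid, "population_grid"))
  rt <- grid$repair_time
  counts <- vapply(sample_times,
                   function(t) colSums(!is.na(rt) & rt > t),
                   numeric(ncol(rt)))
  if (ncol(rt) == 1L) counts <- matrix(counts, nrow = 1L)
  if (noise == "poisson")
    counts <- matrix(stats::rpois(length(counts), counts),
                     nrow(counts), ncol(counts))
  colnames(counts) <- paste0("t", sample_times)
  counts
}

#' Per-region excision (XR-style) counts
#'
#' The excision assay captures repair events in progress: the count at
#' time `t` is the number of lesions whose repair time falls in the
#' window `(t - window/2, t + window/2]`. For small windows the expected
#' count is proportional to the KJMA repair rate at `t` times the window
#' width.
#'
#' @param grid A [simulate_population] result.
#' @param xr_times Snapshot times, minutes.
#' @param window Window width, minutes, `> 0`.
#' @param noise `"none"` or `"poisson"`.
#' @return Named numeric vector of counts, one per time.
#' @export
sample_xr_counts <- function(grid, xr_times = c(5, 20, 60), window = 10,
                             noise = c("none", "poisson")) {
  noise <- match.arg(noise)
  stopifnot(inherits(grid, "population_grid"), window > 0)
  rt <- grid$repair_time[is.finite(grid$repair_time)]
  counts <- vapply(xr_times,
                   function(t) sum(rt > t - window / 2 & rt <= t + window / 2),
                   numeric(1L))
  if (noise == "poisson") counts <- stats::rpois(length(counts), counts)
  stats::setNames(counts, paste0("t", xr_times))
}

#' Simulate a cohort of regions through the full damage-to-repair path
#'
#' For each region: draw ground-truth parameters from the configured
#' priors, simulate the cell population, sample damage counts, sum them
#' over positions, transform to repair fractions against the time-0 sum
#' ([region_repair_fraction]) and rectify ([rectify]); also sample
#' excision counts. Grids are discarded region by region, so memory
#' stays flat in the number of regions.
#'
#' @param config A [sim_config].
#' @return List with `truth` (`region_id`, `m`, `tau`, `theta`,
#'   `n_lesions`), `courses` (long `data.frame`: `region_id`, `time`,
#'   `raw`, `value`), and `xr` (`region_id`, `time`, `value`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pos_times <- config$sample_times[config$sample_times > 0]
  truth <- list(); courses <- list(); xr <- list()
  for (i in seq_len(config$n_regions)) {
    m <- stats::runif(1, config$m_range[1], config$m_range[2])
    tau <- stats::runif(1, config$tau_range[1], config$tau_range[2])
    theta <- stats::runif(1, config$theta_range[1], config$theta_range[2])
    grid <- simulate_population(m, tau, theta, config$n_cells,
                                config$positions_per_region,
                                config$damage_prob)
    counts <- sample_damage_counts(grid, config$sample_times, config$noise)
    sums <- colSums(counts)
    id <- sprintf("region_%03d", i)
    if (sums[1L] <= 0) next  # undamaged region: excluded from fitting
    raw <- region_repair_fraction(sums[1L], sums[-1L])
    courses[[length(courses) + 1L]] <- data.frame(
      region_id = id, time = pos_times, raw = as.numeric(raw),
      value = rectify(as.numeric(raw)))
    xr_counts <- sample_xr_counts(grid, config$xr_times, config$xr_window,
                                  config$noise)
    xr[[length(xr) + 1L]] <- data.frame(
      region_id = id, time = config$xr_times, value = as.numeric(xr_counts))
    truth[[length(truth) + 1L]] <- data.frame(
      region_id = id, m = m, tau = tau, theta = theta,
      n_lesions = sum(grid$lesions))
  }
  list(truth = do.call(rbind, truth),
       courses = do.call(rbind, courses),
       xr = do.call(rbind, xr))
}

#' Generate a synthetic genome, TU annotation and landmark table
#'
#' Random chromosome sequences with a controllable pyrimidine fraction,
#' TUs of varying length placed with gaps on alternating strands, a
#' centromere at each chromosome's midpoint and a telomere at its end.
#' All coordinates are consistent with tracks emitted by
#' [write_synthetic_experiment].
#'
#' @param n_tu Number of transcription units.
#' @param tu_length_range,gap_range Uniform ranges (nt).
#' @param pyr_frac Fraction of pyrimidine bases (C or T).
#' @param n_chrom Number of chromosomes to spread the TUs over.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `tus`
#'   ([GenomicRanges::GRanges] with `tu_id`), `chrom_sizes` (named
#'   integer) and `meres` (`data.frame`: `chrom`, `centromere_pos`,
#'   `telomere_pos`).
#' @export
generate_genome <- function(n_tu = 50L, tu_length_range = c(600L, 3000L),
                            gap_range = c(300L, 1000L), pyr_frac = 0.5,
                            n_chrom = 2L) {
  stopifnot(n_tu >= 1L, pyr_frac > 0, pyr_frac < 1, n_chrom >= 1L)
  per_chrom <- ceiling(n_tu / n_chrom)
  tus <- list(); seqs <- character(n_chrom); sizes <- integer(n_chrom)
  chroms <- paste0("chrSim", seq_len(n_chrom))
  tu_i <- 0L
  for (ci in seq_len(n_chrom)) {
    pos <- 0L; ranges <- list()
    while (tu_i < min(n_tu, ci * per_chrom)) {
      tu_i <- tu_i + 1L
      gap <- sample(gap_range[1]:gap_range[2], 1L)
      len <- sample(tu_length_range[1]:tu_length_range[2], 1L)
      start0 <- pos + gap
      ranges[[length(ranges) + 1L]] <- data.frame(
        start0 = start0, end0 = start0 + len,
        strand = if (tu_i %% 2L == 0L) "-" else "+",
        tu_id = sprintf("TU%03d", tu_i))
      pos <- start0 + len
    }
    size <- pos + sample(gap_range[1]:gap_range[2], 1L)
    sizes[ci] <- size
    base_p <- c(A = (1 - pyr_frac) / 2, C = pyr_frac / 2,
                G = (1 - pyr_frac) / 2, T = pyr_frac / 2)
    seqs[ci] <- paste(sample(names(base_p), size, replace = TRUE,
                             prob = base_p), collapse = "")
    tab <- do.call(rbind, ranges)
    tab$chrom <- chroms[ci]
    tus[[ci]] <- tab
  }
  names(sizes) <- chroms
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
  tab <- do.call(rbind, tus)
  tus <- GenomicRanges::GRanges(
    factor(tab$chrom, levels = chroms),
    IRanges::IRanges(tab$start0 + 1L, tab$end0),
    strand = tab$strand, tu_id = tab$tu_id,
    seqlengths = sizes)
  meres <- data.frame(chrom = chroms,
                      centromere_pos = as.integer(round(sizes / 2)),
                      telomere_pos = unname(sizes))
  list(genome = genome, tus = tus, chrom_sizes = sizes, meres = meres)
}

#' Generate feature tables tied to (or independent of) ground truth
#'
#' Builds per-region features as monotone functions of a chosen
#' ground-truth parameter plus Gaussian noise (after z-scaling the
#' signal, so `noise_sd` is in signal-sd units), plus pure-noise null
#' features for specificity checks. The default map mimics the directions
#' reported for real data: a transcription-rate-like feature increasing
#' with the repair speed `1/tau`, and a TU-length-like feature.
#'
#' @param truth `data.frame` with columns `region_id`, `m`, `tau`,
#'   `theta` (as from [simulate_cohort]).
#' @param effects Named list; each element is
#'   `list(param = <"m"|"tau"|"theta">, fun = <monotone function>)`.
#' @param noise_sd Noise standard deviation in units of the (z-scaled)
#'   signal sd.
#' @param n_null Number of independent standard-normal null features.
#' @param seed Optional integer seed.
#' @return `data.frame` keyed by `region_id` with one column per
#'   feature (null features named `null_1`, ...).
#' @export
generate_features <- function(truth,
                              effects = list(
                                transcription_rate = list(param = "tau",
                                                          fun = function(x) 1 / x),
                                tu_length = list(param = "m", fun = identity)),
                              noise_sd = 0.1, n_null = 1L, seed = NULL) {
  stopifnot(all(c("region_id", "m", "tau", "theta") %in% names(truth)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  out <- data.frame(region_id = truth$region_id)
  for (nm in names(effects)) {
    ef <- effects[[nm]]
    sig <- ef$fun(truth[[ef$param]])
    sig <- as.numeric(scale(sig))
    out[[nm]] <- sig + stats::rnorm(n, 0, noise_sd)
  }
  for (j in seq_len(n_null))
    out[[paste0("null_", j)]] <- stats::rnorm(n)
  out
}

#' Write a complete synthetic experiment to disk
#'
#' Emits, under `dir`: `genome.fa`, `tus.bed` (BED6), `meres.tsv`,
#' per-time damage bedGraph files `cpd_t<min>_<strand>.bedGraph`,
#' an XR table `xr.tsv`, a feature table `features.tsv` and the
#' ground-truth table `truth.tsv`. Lesion-eligible positions are the
#' actual dipyrimidine sites of each TU's annotated strand, so signal,
#' sequence and annotation coordinates agree; all files are plain text.
#'
#' @param dir Output directory (created if needed).
#' @param genome A [generate_genome] result.
#' @param config A [sim_config]; `positions_per_region` caps the number
#'   of dipyrimidine sites used per TU.
#' @return Invisibly, a list with the `truth` table and file paths.
#' @export
write_synthetic_experiment <- function(dir, genome = generate_genome(),
                                       config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  tus <- genome$tus
  truth <- list(); tracks <- list(); xr <- list()
  for (i in seq_along(tus)) {
    tu <- tus[i]
    chrom <- as.character(GenomicRanges::seqnames(tu))
    str <- as.character(GenomicRanges::strand(tu))
    seq <- substr(as.character(genome$genome[[chrom]]),
                  GenomicRanges::start(tu), GenomicRanges::end(tu))
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    set <- if (str == "+") c("C", "T") else c("A", "G")
    hit <- chars %in% set
    sites <- which(hit[-length(hit)] & hit[-1L])  # first base of the pair
    if (length(sites) > config$positions_per_region)
      sites <- sort(sample(sites, config$positions_per_region))
    if (length(sites) < 2L) next
    m <- stats::runif(1, config$m_range[1], config$m_range[2])
    tau <- stats::runif(1, config$tau_range[1], config$tau_range[2])
    theta <- stats::runif(1, config$theta_range[1], config$theta_range[2])
    grid <- simulate_population(m, tau, theta, config$n_cells,
                                length(sites), config$damage_prob)
    counts <- sample_damage_counts(grid, config$sample_times, config$noise)
    pos_genome <- GenomicRanges::start(tu) + sites - 1L  # 1-based site start
    for (j in seq_along(config$sample_times)) {
      key <- paste0("t", config$sample_times[j], "_", str)
      tracks[[key]] <- rbind(tracks[[key]], data.frame(
        chrom = chrom, start0 = pos_genome - 1L, end0 = pos_genome + 1L,
        value = counts[, j]))
    }
    id <- S4Vectors::mcols(tu)$tu_id
    xr_counts <- sample_xr_counts(grid, config$xr_times, config$xr_window,
                                  config$noise)
    xr[[length(xr) + 1L]] <- data.frame(region_id = id,
                                        time = config$xr_times,
                                        value = as.numeric(xr_counts))
    truth[[length(truth) + 1L]] <- data.frame(region_id = id, m = m,
                                              tau = tau, theta = theta)
  }
  truth <- do.call(rbind, truth)

  fa_path <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome$genome, fa_path)
  bed_path <- file.path(dir, "tus.bed")
  write_bed6(tus, S4Vectors::mcols(tus)$tu_id, bed_path)
  meres_path <- file.path(dir, "meres.tsv")
  utils::write.table(genome$meres, meres_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  track_paths <- character()
  for (key in names(tracks)) {
    fname <- paste0("cpd_", gsub("\\+", "plus", gsub("-", "minus", key)),
                    ".bedGraph")
    p <- file.path(dir, fname)
    tab <- tracks[[key]][order(tracks[[key]]$chrom, tracks[[key]]$start0), ]
    utils::write.table(tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    track_paths[key] <- p
  }
  xr_path <- file.path(dir, "xr.tsv")
  utils::write.table(do.call(rbind, xr), xr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  feat_path <- file.path(dir, "features.tsv")
  utils::write.table(generate_features(truth), feat_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(truth = truth,
                 paths = c(genome = fa_path, tus = bed_path,
                           meres = meres_path, xr = xr_path,
                           features = feat_path, truth = truth_path,
                           track_paths)))
}
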