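#' Simulation configuration for synthetic 2DE datasets
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' reproduce the study conditions of a silver-stained human liver cytosol
#' 2DE experiment: a universe of 389 master spots, 18 gels split into two
#' groups of 11 and 7, 3 spots exclusive to the first group and 12 to the
#' second, ~96% of normalized spot intensities below 0.02 relative units
#' (with 2% at 0.02-0.04 and 1% above 0.1), and a technical-replicate
#' coefficient of variation around 0.5.
#'
#' @param n_spots_universe number of master spot columns (default 389).
#' @param cluster_sizes integer vector of gels per planted cluster
#'   (default `c(11, 7)`).
#' @param shared_spot_fraction fraction of the universe present in every
#'   cluster prototype. The default 0.68 puts ~271 spots on a typical gel,
#'   the observed per-gel mean of the emulated experiment.
#' @param specific_spot_counts per-cluster counts of cluster-exclusive spots
#'   (default `c(3, 12)`).
#' @param flip_rate probability of toggling each presence bit per gel
#'   (measurement noise on the binary matrix).
#' @param intensity_class_fractions probabilities over the four normalized
#'   intensity classes `<0.02`, `0.02-0.04`, `0.04-0.1`, `>0.1`; must sum
#'   to 1. The third class fraction is not separately reported in the
#'   emulated study; its default 0.01 is the value that makes the printed
#'   fractions sum to 1.
#' @param replicate_cv target coefficient of variation of a spot's
#'   normalized intensity across technical replicates.
#' @param dropout_rate probability that a present spot goes undetected in a
#'   given technical replicate.
#' @param seed integer seed fixing all generator output bit-for-bit.
#'   Derived stage seeds (`seed + 0..3`) keep the stages independently
#'   reproducible.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(seed = 42)
#' cfg$n_spots_universe
simulation_config <- function(n_spots_universe = 389,
                              cluster_sizes = c(11L, 7L),
                              shared_spot_fraction = 0.68,
                              specific_spot_counts = c(3L, 12L),
                              flip_rate = 0.02,
                              intensity_class_fractions = c(0.96, 0.02, 0.01, 0.01),
                              replicate_cv = 0.5,
                              dropout_rate = 0.1,
                              seed = 1L) {
  cfg <- list(
    n_spots_universe = as.integer(n_spots_universe),
    cluster_sizes = as.integer(cluster_sizes),
    shared_spot_fraction = shared_spot_fraction,
    specific_spot_counts = as.integer(specific_spot_counts),
    flip_rate = flip_rate,
    intensity_class_fractions = intensity_class_fractions,
    replicate_cv = replicate_cv,
    dropout_rate = dropout_rate,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  probs <- c(cfg$shared_spot_fraction, cfg$flip_rate, cfg$dropout_rate,
             cfg$intensity_class_fractions)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$intensity_class_fractions) - 1) > 1e-9)
    stop("intensity_class_fractions must sum to 1")
  if (length(cfg$intensity_class_fractions) != 4L)
    stop("intensity_class_fractions must have 4 elements")
  if (any(cfg$cluster_sizes < 1L)) stop("cluster_sizes must all be >= 1")
  if (length(cfg$specific_spot_counts) != length(cfg$cluster_sizes))
    stop("specific_spot_counts must have one entry per cluster")
  if (cfg$replicate_cv < 0) stop("replicate_cv must be nonnegative")
  n_shared <- round(cfg$shared_spot_fraction * cfg$n_spots_universe)
  if (n_shared + sum(cfg$specific_spot_counts) > cfg$n_spots_universe)
    stop("shared + cluster-exclusive spots exceed the spot universe")
  invisible(cfg)
}

#' Cluster prototype presence vectors
#'
#' Draws, for each planted cluster, a binary vector over the spot universe.
#' A common block of `round(shared_spot_fraction * n_spots_universe)` spots
#' is present in every prototype; each cluster additionally receives its
#' configured number of exclusive spots, disjoint across clusters. The
#' remaining universe positions are absent everywhere (room for the
#' cross-gel union columns a real master-gel alignment accumulates).
#'
#' @param config a [simulation_config()].
#' @return Integer 0/1 matrix, one row per cluster, `n_spots_universe`
#'   columns named `spot_1 ...`.
#' @export
make_prototypes <- function(config) {
  validate_simulation_config(config)
  k <- length(config$cluster_sizes)
  n <- config$n_spots_universe
  n_shared <- round(config$shared_spot_fraction * n)
  withr::with_seed(config$seed, {
    perm <- sample.int(n)
    shared <- perm[seq_len(n_shared)]
    proto <- matrix(0L, nrow = k, ncol = n,
                    dimnames = list(paste0("cluster_", seq_len(k)),
                                    paste0("spot_", seq_len(n))))
    proto[, shared] <- 1L
    offset <- n_shared
    for (c in seq_len(k)) {
      nc <- config$specific_spot_counts[c]
      if (nc > 0L) {
        proto[c, perm[offset + seq_len(nc)]] <- 1L
        offset <- offset + nc
      }
    }
    proto
  })
}

#' Simulate a binary presence/absence gel matrix with planted clusters
#'
#' Stacks each cluster prototype `cluster_sizes[c]` times and then flips
#' every bit independently with probability `flip_rate`, emulating
#' presence-call noise between gels of the same group. With
#' `flip_rate = 0` each gel row equals its cluster prototype exactly.
#'
#' @param config a [simulation_config()].
#' @return A list of class `gel_simulation`:
#'   \describe{
#'     \item{binary}{0/1 integer matrix, `sum(cluster_sizes)` gel rows by
#'       `n_spots_universe` spot columns.}
#'     \item{truth}{list with `partition` (named integer vector of planted
#'       cluster labels) and `prototypes` (the [make_prototypes()] matrix).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' sim <- simulate_binary_dataset(simulation_config(flip_rate = 0, seed = 7))
#' dim(sim$binary)
simulate_binary_dataset <- function(config) {
  validate_simulation_config(config)
  proto <- make_prototypes(config)
  sizes <- config$cluster_sizes
  n_gels <- sum(sizes)
  rows <- rep(seq_along(sizes), sizes)
  mat <- proto[rows, , drop = FALSE]
  gel_ids <- sprintf("gel_%02d", seq_len(n_gels))
  rownames(mat) <- gel_ids
  if (config$flip_rate > 0) {
    flips <- withr::with_seed(config$seed + 1L,
      matrix(stats::rbinom(length(mat), 1L, config$flip_rate), nrow = n_gels))
    mat <- abs(mat - flips)
  }
  storage.mode(mat) <- "integer"
  partition <- stats::setNames(rows, gel_ids)
  structure(list(binary = mat,
                 truth = list(partition = partition, prototypes = proto),
                 config = config),
            class = "gel_simulation")
}

# Class medians for the four normalized-intensity classes. The lowest-class
# median is solved per gel so the expected per-gel total is 1 before
# renormalisation, which keeps the realised class fractions on target.
intensity_class_medians <- function(n_class1, counts_other) {
  m_upper <- c(0.028, 0.065, 0.15)
  upper_mass <- sum(counts_other * m_upper)
  m1 <- (1 - upper_mass) / max(n_class1, 1L)
  c(max(m1, 1e-5), m_upper)
}

#' Simulate normalized spot intensities for a binary gel matrix
#'
#' For each present spot an intensity class is drawn from
#' `intensity_class_fractions`; a value is then drawn from a lognormal
#' centred (in median) inside that class, and each gel row is renormalized
#' so its present spots sum to exactly 1. Absent spots are `NA`.
#'
#' The class medians are 0.028, 0.065 and 0.15 for the three upper classes;
#' the lowest-class median is chosen per gel so that the pre-normalisation
#' total has expectation 1, keeping class membership essentially unmoved by
#' the final renormalisation. The within-class lognormal sdlog is 0.15;
#' replicate-level variability is modelled separately by
#' [simulate_replicate_set()].
#'
#' @param binary 0/1 matrix, gels in rows (e.g. `simulate_binary_dataset()$binary`).
#' @param config a [simulation_config()].
#' @return Numeric matrix of the same shape as `binary`: normalized
#'   intensities at present cells (each row summing to 1), `NA` elsewhere.
#' @export
simulate_intensities <- function(binary, config) {
  validate_simulation_config(config)
  if (is.null(dim(binary)) || nrow(binary) == 0L || ncol(binary) == 0L)
    stop("`binary` must be a nonempty matrix")
  if (any(rowSums(binary) == 0L))
    stop("cannot normalize a gel with zero present spots")
  out <- matrix(NA_real_, nrow(binary), ncol(binary), dimnames = dimnames(binary))
  withr::with_seed(config$seed + 2L, {
    for (i in seq_len(nrow(binary))) {
      present <- which(binary[i, ] == 1L)
      cls <- sample.int(4L, length(present), replace = TRUE,
                        prob = config$intensity_class_fractions)
      counts <- tabulate(cls, nbins = 4L)
      med <- intensity_class_medians(counts[1L], counts[2:4])
      vals <- med[cls] * exp(stats::rnorm(length(present), 0, 0.15))
      out[i, present] <- vals / sum(vals)
    }
  })
  out
}

#' Simulate a technical-replicate intensity set for one gel
#'
#' Emulates repeated 2DE runs of the same sample: a base intensity profile
#' is drawn once, then each replicate perturbs it with multiplicative
#' lognormal noise whose coefficient of variation equals `replicate_cv`,
#' drops each present spot with probability `dropout_rate` (spot
#' non-detection), and renormalizes the detected spots to sum to 1.
#' The lognormal sigma carries the standard `c4(n)` small-sample
#' correction so that sample CVs computed across the `n_replicates` runs
#' center on `replicate_cv` rather than below it.
#'
#' @param config a [simulation_config()]; the base profile uses the first
#'   cluster prototype.
#' @param n_replicates number of technical runs (default 4).
#' @return Numeric matrix, `n_replicates` rows by `n_spots_universe`
#'   columns; `NA` marks spots undetected in that run.
#' @export
simulate_replicate_set <- function(config, n_replicates = 4L) {
  validate_simulation_config(config)
  if (n_replicates < 2L) stop("need at least 2 replicates")
  proto <- make_prototypes(config)[1L, ]
  base <- simulate_intensities(matrix(proto, nrow = 1,
                                      dimnames = list("base", names(proto))),
                               config)[1L, ]
  # c4(n) unbiasing: sample SDs from n replicates underestimate the
  # generating sigma, so inflate it to put *measured* CVs on target
  c4 <- sqrt(2 / (n_replicates - 1)) *
    gamma(n_replicates / 2) / gamma((n_replicates - 1) / 2)
  sdlog <- sqrt(log(1 + config$replicate_cv^2)) / c4
  withr::with_seed(config$seed + 3L, {
    out <- matrix(NA_real_, n_replicates, length(base),
                  dimnames = list(sprintf("rep_%d", seq_len(n_replicates)),
                                  names(base)))
    present <- which(!is.na(base))
    for (r in seq_len(n_replicates)) {
      noise <- exp(stats::rnorm(length(present), -sdlog^2 / 2, sdlog))
      vals <- base[present] * noise
      keep <- stats::runif(length(present)) >= config$dropout_rate
      if (!any(keep)) keep[1L] <- TRUE  # never an empty run
      vals[!keep] <- NA_real_
      out[r, present] <- vals / sum(vals, na.rm = TRUE)
    }
    out
  })
}

#' Place synthetic spot centers on a gel
#'
#' Uniform rejection sampling over the usable gel area (an inner margin of
#' `4 * psf_sigma` from each edge) with a minimum center-to-center
#' separation of `3 * psf_sigma`, so neighbouring spots stay resolvable.
#'
#' @param n_spots number of spots to place.
#' @param image_size `c(rows, cols)` of the target image.
#' @param psf_sigma Gaussian point-spread sigma, pixels.
#' @param amplitude_range range of peak amplitudes (relative units in
#'   `[0, 1]`), drawn uniformly.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget per spot.
#' @return data.frame with columns `spot_id`, `x`, `y` (0-based pixel
#'   centers), `sigma`, `amplitude`.
#' @export
place_spots <- function(n_spots, image_size, psf_sigma = 2,
                        amplitude_range = c(0.2, 0.6), seed = 1L,
                        max_tries = 5000L) {
  stopifnot(psf_sigma > 0, n_spots >= 0)
  margin <- 4 * psf_sigma
  lo <- margin
  hi_y <- image_size[1L] - 1 - margin
  hi_x <- image_size[2L] - 1 - margin
  if (hi_x <= lo || hi_y <= lo) stop("image too small for the margin")
  min_sep2 <- (3 * psf_sigma)^2
  withr::with_seed(seed, {
    xs <- ys <- numeric(0)
    for (i in seq_len(n_spots)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        x <- stats::runif(1, lo, hi_x)
        y <- stats::runif(1, lo, hi_y)
        if (length(xs) == 0L || min((xs - x)^2 + (ys - y)^2) >= min_sep2) {
          xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
        }
      }
      if (!placed) stop("could not place ", n_spots, " spots at separation ",
                        3 * psf_sigma, " px; enlarge the image")
    }
    amp <- stats::runif(n_spots, amplitude_range[1L], amplitude_range[2L])
    data.frame(spot_id = seq_len(n_spots), x = xs, y = ys,
               sigma = psf_sigma, amplitude = amp)
  })
}

#' Render a synthetic gel image from ground-truth spots
#'
#' Builds `background + sum of 2D Gaussian bumps + N(0, noise_sd)` on the
#' relative intensity scale `[0, 1]`, clips to that range, and (for the
#' default dark-on-light polarity of a silver-stain scan) inverts the
#' field so spots appear dark on a light background. The input table is
#' the ground truth for benchmarking [detect_spots()].
#'
#' @param spots data.frame with columns `x`, `y` (0-based centers),
#'   `sigma`, `amplitude` — e.g. from [place_spots()].
#' @param image_size `c(rows, cols)`.
#' @param background_level constant background, relative units.
#' @param noise_sd additive Gaussian noise sd, relative units.
#' @param seed integer seed for the noise.
#' @param bit_depth stored bit depth of the result.
#' @param polarity see [gel_image()].
#' @param sample_id,replicate_id identifiers stored on the image.
#' @return A [gel_image()].
#' @export
#' @examples
#' tr <- place_spots(5, c(64, 64), psf_sigma = 2, seed = 3)
#' img <- render_gel_image(tr, c(64, 64), noise_sd = 0)
render_gel_image <- function(spots, image_size, background_level = 0.05,
                             noise_sd = 0, seed = 1L, bit_depth = 16,
                             polarity = "dark-on-light",
                             sample_id = "synthetic", replicate_id = "1") {
  nr <- image_size[1L]; nc <- image_size[2L]
  if (nrow(spots) > 0) {
    bad <- spots$x < 0 | spots$x > nc - 1 | spots$y < 0 | spots$y > nr - 1
    if (any(bad))
      stop("spot center(s) outside image bounds: spot ",
           paste(spots$spot_id[bad], collapse = ", "))
    if (any(spots$sigma <= 0)) stop("psf sigma must be positive")
  }
  field <- matrix(background_level, nr, nc)
  for (i in seq_len(nrow(spots))) {
    s <- spots$sigma[i]
    r <- ceiling(5 * s)
    cx <- spots$x[i]; cy <- spots$y[i]
    rows <- max(1L, floor(cy + 1 - r)):min(nr, ceiling(cy + 1 + r))
    cols <- max(1L, floor(cx + 1 - r)):min(nc, ceiling(cx + 1 + r))
    dy2 <- ((rows - 1) - cy)^2
    dx2 <- ((cols - 1) - cx)^2
    bump <- spots$amplitude[i] *
      exp(-outer(dy2, dx2, "+") / (2 * s^2))
    field[rows, cols] <- field[rows, cols] + bump
  }
  if (noise_sd > 0) {
    field <- field + withr::with_seed(seed,
      matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc))
  }
  field <- pmin(pmax(field, 0), 1)
  if (polarity == "dark-on-light") field <- 1 - field
  gel_image(field * (2^bit_depth - 1), bit_depth = bit_depth,
            sample_id = sample_id, replicate_id = replicate_id,
            polarity = polarity)
}
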