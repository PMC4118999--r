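#' Least-squares 2D similarity transform (scale, rotation, translation)
#'
#' Closed-form (SVD) fit of `y ~ s R x + t` from paired coordinates.
#'
#' @param x,y two-column matrices of paired source / target points.
#' @return list with `scale`, `rotation` (2x2), `translation` (length 2).
#' @keywords internal
fit_similarity <- function(x, y) {
  stopifnot(nrow(x) >= 2L, nrow(x) == nrow(y))
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  s <- svd(crossprod(yc, xc))
  d <- diag(c(1, sign(det(s$u %*% t(s$v)))))
  R <- s$u %*% d %*% t(s$v)
  varx <- sum(xc^2)
  sc <- if (varx > 0) sum(diag(d) * s$d) / varx else 1
  list(scale = sc, rotation = R, translation = as.numeric(my - sc * R %*% mx))
}

apply_similarity <- function(tf, x) {
  sweep(tcrossprod(x, tf$rotation) * tf$scale, 2, tf$translation, "+")
}

# consensus (best-of-N minimal samples) similarity estimate between two
# spot clouds; candidate correspondences are nearest-neighbour guesses.
estimate_registration <- function(gel_xy, master_xy, tolerance,
                                  n_samples = 200L, seed = 1L) {
  guess_nn <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      which.min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)
    }, integer(1))
  }
  nn <- guess_nn(gel_xy, master_xy)
  best <- NULL; best_inliers <- -1L
  withr::with_seed(seed, {
    for (it in seq_len(n_samples)) {
      pick <- sample.int(nrow(gel_xy), 2L)
      if (stats::dist(gel_xy[pick, ])[1] < 1e-9) next
      tf <- fit_similarity(gel_xy[pick, , drop = FALSE],
                           master_xy[nn[pick], , drop = FALSE])
      moved <- apply_similarity(tf, gel_xy)
      d2 <- vapply(seq_len(nrow(moved)), function(i)
        min((master_xy[, 1] - moved[i, 1])^2 +
            (master_xy[, 2] - moved[i, 2])^2), numeric(1))
      inl <- sum(d2 <= tolerance^2)
      if (inl > best_inliers) { best_inliers <- inl; best <- tf }
    }
  })
  if (is.null(best)) return(NULL)
  # refit on consensus set
  moved <- apply_similarity(best, gel_xy)
  nn2 <- guess_nn(moved, master_xy)
  d2 <- rowSums((master_xy[nn2, , drop = FALSE] - moved)^2)
  inl <- which(d2 <= tolerance^2)
  if (length(inl) >= 2L)
    best <- fit_similarity(gel_xy[inl, , drop = FALSE],
                           master_xy[nn2[inl], , drop = FALSE])
  best
}

#' Match a gel's spots to the master gel
#'
#' Pairs gel spots with master spots by greedy one-to-one assignment in
#' ascending Euclidean pixel distance (ties broken by ascending gel then
#' master spot id), keeping only pairs within `tolerance`. Optionally a
#' similarity transform (translation + rotation + scale) is first estimated
#' by consensus over random minimal samples and applied to the gel spots —
#' an automatic stand-in for the manual gel-to-master alignment of a gel
#' editor; it is off by default for spot lists already in a shared frame.
#'
#' @param spots,master `spot_list` objects (see [detect_spots()]); `master`
#'   must be nonempty.
#' @param tolerance matching radius, pixels.
#' @param pre_register logical; estimate and apply a similarity transform
#'   before matching.
#' @param seed seed for the consensus registration sampling.
#' @return A `spot_correspondence`: list with `gel_id`, `pairs`
#'   (data.frame `gel_spot_id`, `master_spot_id`, `distance`),
#'   `unmatched_gel_spots` (data.frame of ids and, when registered,
#'   transformed coordinates), and `transform` (or `NULL`).
#' @export
match_to_master <- function(spots, master, tolerance = 3,
                            pre_register = FALSE, seed = 1L) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (nrow(master) == 0L) stop("master spot list is empty")
  gel_id <- attr(spots, "gel_id") %||% ""
  empty_pairs <- data.frame(gel_spot_id = integer(0),
                            master_spot_id = integer(0),
                            distance = numeric(0))
  if (nrow(spots) == 0L)
    return(structure(list(gel_id = gel_id, pairs = empty_pairs,
                          unmatched_gel_spots = data.frame(
                            gel_spot_id = integer(0), x = numeric(0),
                            y = numeric(0)),
                          transform = NULL),
                     class = "spot_correspondence"))
  gxy <- cbind(spots$x, spots$y)
  mxy <- cbind(master$x, master$y)
  tf <- NULL
  if (pre_register && nrow(spots) >= 2L) {
    tf <- estimate_registration(gxy, mxy, tolerance, seed = seed)
    if (!is.null(tf)) gxy <- apply_similarity(tf, gxy)
  }
  dmat <- sqrt(outer(gxy[, 1], mxy[, 1], "-")^2 +
               outer(gxy[, 2], mxy[, 2], "-")^2)
  idx <- which(dmat <= tolerance, arr.ind = TRUE)
  ord <- order(dmat[idx], spots$spot_id[idx[, 1L]], master$spot_id[idx[, 2L]])
  idx <- idx[ord, , drop = FALSE]
  used_g <- logical(nrow(spots)); used_m <- logical(nrow(master))
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    g <- idx[i, 1L]; m <- idx[i, 2L]
    if (!used_g[g] && !used_m[m]) { used_g[g] <- used_m[m] <- TRUE; keep[i] <- TRUE }
  }
  idx <- idx[keep, , drop = FALSE]
  pairs <- data.frame(gel_spot_id = spots$spot_id[idx[, 1L]],
                      master_spot_id = master$spot_id[idx[, 2L]],
                      distance = dmat[idx])
  un <- which(!used_g)
  structure(list(
    gel_id = gel_id, pairs = pairs,
    unmatched_gel_spots = data.frame(gel_spot_id = spots$spot_id[un],
                                     x = gxy[un, 1L], y = gxy[un, 2L]),
    transform = tf),
    class = "spot_correspondence")
}

# greedy centroid agglomeration of unmatched spots across gels; clusters
# recurring in >= 2 distinct gels become union columns.
agglomerate_unmatched <- function(un, tolerance) {
  cent_x <- cent_y <- numeric(0)
  members <- list()
  for (i in seq_len(nrow(un))) {
    if (length(cent_x) > 0) {
      d2 <- (cent_x - un$x[i])^2 + (cent_y - un$y[i])^2
      j <- which.min(d2)
    }
    if (length(cent_x) > 0 && d2[j] <= tolerance^2) {
      members[[j]] <- rbind(members[[j]], un[i, ])
      cent_x[j] <- mean(members[[j]]$x)
      cent_y[j] <- mean(members[[j]]$y)
    } else {
      members[[length(members) + 1L]] <- un[i, , drop = FALSE]
      cent_x <- c(cent_x, un$x[i]); cent_y <- c(cent_y, un$y[i])
    }
  }
  members
}

#' Assemble binary presence/absence and normalized intensity matrices
#'
#' Columns are the master gel's spots (`M<id>`); optionally, unmatched gel
#' spots that co-locate (within `tolerance`, greedy centroid agglomeration)
#' across at least two distinct gels open additional union columns
#' (`U<n>`), which is how a master-gel alignment accumulates more columns
#' than any single gel carries. `d[i, j] = 1` exactly when gel `i` has a
#' spot assigned to column `j`. The intensity matrix holds each gel's
#' normalized intensities (per-gel normalisation over its matched spots)
#' at matched cells and `NA` elsewhere.
#'
#' @param correspondences list of `spot_correspondence` objects, one per
#'   gel (include the master matched to itself for its own row).
#' @param master the master `spot_list`.
#' @param spotlists list of the gels' `spot_list`s, same order as
#'   `correspondences`.
#' @param union_columns logical; add recurrent-unmatched union columns.
#' @param tolerance agglomeration radius for union columns, pixels.
#' @return list with `binary` (0/1 integer matrix, gels x columns) and
#'   `intensity` (numeric matrix, `NA` at absent cells).
#' @export
build_matrices <- function(correspondences, master, spotlists,
                           union_columns = TRUE, tolerance = 3) {
  gel_ids <- vapply(correspondences, `[[`, character(1), "gel_id")
  if (anyDuplicated(gel_ids))
    stop("duplicate gel_id across correspondences: ",
         paste(unique(gel_ids[duplicated(gel_ids)]), collapse = ", "))
  stopifnot(length(spotlists) == length(correspondences))
  master_cols <- paste0("M", master$spot_id)
  # per-gel assignment: spot_id -> column name
  assign <- lapply(correspondences, function(co) {
    stats::setNames(paste0("M", co$pairs$master_spot_id),
                    as.character(co$pairs$gel_spot_id))
  })
  if (union_columns) {
    un_all <- do.call(rbind, lapply(seq_along(correspondences), function(i) {
      u <- correspondences[[i]]$unmatched_gel_spots
      if (nrow(u) == 0L) return(NULL)
      cbind(gel = i, u)
    }))
    if (!is.null(un_all) && nrow(un_all) > 0) {
      clusters <- agglomerate_unmatched(un_all, tolerance)
      recurrent <- Filter(function(m) length(unique(m$gel)) >= 2L, clusters)
      for (j in seq_along(recurrent)) {
        cl <- recurrent[[j]]
        col <- paste0("U", j)
        # one spot per gel per union column (first by spot id)
        for (g in unique(cl$gel)) {
          sid <- min(cl$gel_spot_id[cl$gel == g])
          assign[[g]][as.character(sid)] <- col
        }
      }
    }
  }
  all_cols <- c(master_cols,
                sort(unique(unlist(lapply(assign, function(a)
                  grep("^U", a, value = TRUE))))))
  n <- length(correspondences)
  binary <- matrix(0L, n, length(all_cols),
                   dimnames = list(gel_ids, all_cols))
  intensity <- matrix(NA_real_, n, length(all_cols),
                      dimnames = list(gel_ids, all_cols))
  for (i in seq_len(n)) {
    a <- assign[[i]]
    if (length(a) == 0L) next
    binary[i, a] <- 1L
    sl <- normalize_intensities(spotlists[[i]],
                                matched_ids = as.integer(names(a)))
    norm <- stats::setNames(sl$normalized_intensity, as.character(sl$spot_id))
    intensity[i, a] <- norm[names(a)]
  }
  list(binary = binary, intensity = intensity)
}

#' Apply a manual spot-edit patch to a spot list
#'
#' Replays manual curation (spot additions and deletions) recorded as a
#' table rather than interactively. `patch` rows with `action == "delete"`
#' remove the given `spot_id`; rows with `action == "add"` append a spot at
#' `(x, y, sigma)`, measuring its raw intensity from `image` when given.
#'
#' @param spots a `spot_list`.
#' @param patch data.frame with columns `action`, `spot_id`, `x`, `y`, `sigma`.
#' @param image optional [gel_image()] used to measure added spots.
#' @return the edited `spot_list`.
#' @export
apply_spot_patch <- function(spots, patch, image = NULL) {
  for (i in seq_len(nrow(patch))) {
    p <- patch[i, ]
    if (p$action == "delete") {
      spots <- spots[spots$spot_id != p$spot_id, , drop = FALSE]
    } else if (p$action == "add") {
      raw <- NA_real_
      if (!is.null(image))
        raw <- measure_spot_intensity(
          image, spot_region(p$x, p$y, p$sigma, dim(image$pixels)))
      id <- if (is.na(p$spot_id)) max(c(0L, spots$spot_id)) + 1L else p$spot_id
      spots <- rbind(spots, data.frame(
        spot_id = id, x = p$x, y = p$y, sigma = p$sigma,
        response = NA_real_, raw_intensity = raw,
        normalized_intensity = NA_real_))
    } else stop("unknown patch action: ", p$action)
  }
  new_spot_list(spots, attr(spots, "gel_id") %||% "",
                attr(spots, "detection_params"))
}
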