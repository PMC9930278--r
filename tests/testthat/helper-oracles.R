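# Shared fixtures and independent oracle implementations used across the
# suite. Oracles are deliberately naive (brute force / closed form) and
# share no code with the package internals they check.

small_config <- function(...) {
  defaults <- list(image_size = c(700L, 680L), colony_count_mean = 14,
                   petite_prob = 0.3, artifact_arc_range = c(0L, 0L),
                   touching_pair_fraction = 0, seed = 1L)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

random_box <- function(lim = 100, max_side = 30) {
  x0 <- runif(1, 0, lim - 2); y0 <- runif(1, 0, lim - 2)
  c(x0, y0, x0 + runif(1, 0.5, max_side), y0 + runif(1, 0.5, max_side))
}

random_detections <- function(n, lim = 100, classes = COLONY_CLASSES,
                              max_side = 30) {
  if (n == 0L) return(detection_table())
  b <- t(vapply(seq_len(n), function(i) random_box(lim, max_side), numeric(4L)))
  detection_table(b[, 1L], b[, 2L], b[, 3L], b[, 4L],
                  sample(classes, n, replace = TRUE), runif(n))
}

# Transitive-closure merger: build the boolean eligibility matrix (same
# class unless class-agnostic, IOS above threshold), compute its transitive
# closure with Floyd-Warshall, union each connected component into one box
# with the maximum member score, and repeat on the component boxes until
# nothing merges. Shares no code or scan order with nmm().
nmm_oracle <- function(dets, params = nmm_params()) {
  d <- dets[dets$score >= params$score_threshold, , drop = FALSE]
  if (nrow(d) == 0L) return(detection_table())
  d <- canonical_dets(d)
  repeat {
    n <- nrow(d)
    adj <- diag(TRUE, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (!params$class_agnostic && d$cls[i] != d$cls[j]) next
      ios <- box_ios(do.call(bbox, as.list(as.numeric(d[i, 1:4]))),
                     do.call(bbox, as.list(as.numeric(d[j, 1:4]))))
      if (ios > params$ios_threshold) adj[i, j] <- TRUE
    }
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, k] && adj[k, j]) adj[i, j] <- TRUE
    }
    comp <- rep(NA_integer_, n)
    nc <- 0L
    for (i in seq_len(n)) {
      if (is.na(comp[i])) {
        nc <- nc + 1L
        comp[adj[i, ]] <- nc
      }
    }
    merged <- do.call(rbind, lapply(seq_len(nc), function(cid) {
      m <- d[comp == cid, , drop = FALSE]
      data.frame(x_min = min(m$x_min), y_min = min(m$y_min),
                 x_max = max(m$x_max), y_max = max(m$y_max),
                 cls = m$cls[1L], score = max(m$score), stringsAsFactors = FALSE)
    }))
    merged <- canonical_dets(merged)
    if (nrow(merged) == nrow(d)) break
    d <- merged
  }
  canonical_dets(detection_table(d$x_min, d$y_min, d$x_max, d$y_max, d$cls, d$score))
}

canonical_dets <- function(d) {
  d <- d[order(d$x_min, d$y_min, d$x_max, d$y_max, d$cls, d$score), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# Exact area under the monotone-interpolated precision-recall curve, from
# score-ordered TP flags; the continuous counterpart of the 101-point sum.
ap_exact_oracle <- function(scores, tp, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (length(tp) == 0L) return(0)
  ord <- order(-scores)
  tp <- tp[ord]
  cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
  prec <- cum_tp / (cum_tp + cum_fp)
  rec <- cum_tp / n_gt
  prec_env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * prec_env)
}

# Central-moment eccentricity of a pixel region, computed from first
# principles (covariance eigenvalues of pixel coordinates).
ecc_oracle <- function(xs, ys) {
  cov_m <- stats::cov(cbind(xs, ys)) * (length(xs) - 1) / length(xs)
  ev <- sort(eigen(cov_m, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  sqrt(1 - ev[2L] / ev[1L])
}
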