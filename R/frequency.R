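# Per-plate Petite frequency and the binomial sampling-error model. If
# Petite colony formation is a Bernoulli process with probability P, the
# frequency observed on a plate of k colonies has standard deviation
# sqrt(P (1 - P) / k); prediction errors smaller than this envelope are
# below the noise floor of the assay itself.

#' Petite frequency of a plate from its detections
#'
#' Counts detections by class and reports the Petite fraction
#' \code{P = n_petite / (n_grande + n_petite)} together with the binomial
#' standard deviation \code{sqrt(P (1 - P) / k)}. A plate with no colonies
#' has no frequency: \code{P} and \code{sigma} are \code{NA} (with a
#' warning), never 0/0.
#'
#' @param dets Detection data frame (classes \code{grande}/\code{petite}).
#' @param image_id Plate identifier carried into the result.
#' @return One-row data frame of class \code{frequency_result}:
#'   \code{image_id, n_grande, n_petite, k, petite_freq, binom_std}.
#' @export
petite_frequency <- function(dets, image_id = "plate") {
  validate_detections(dets)
  ng <- sum(dets$cls == "grande")
  np <- sum(dets$cls == "petite")
  k <- ng + np
  if (k == 0L) {
    warning("no colonies detected on '", image_id, "': Petite frequency is undefined")
    p <- NA_real_; s <- NA_real_
  } else {
    p <- np / k
    s <- sqrt(p * (1 - p) / k)
  }
  structure(data.frame(image_id = as.character(image_id), n_grande = ng,
                       n_petite = np, k = k, petite_freq = p, binom_std = s,
                       stringsAsFactors = FALSE),
            class = c("frequency_result", "data.frame"))
}

#' Binomial sampling envelope around a true Petite frequency
#'
#' The interval \code{P +/- sqrt(P (1 - P) / k)} clipped to \[0, 1\]: the
#' one-standard-deviation band of frequencies expected when sampling k
#' colonies from a Bernoulli process with probability P.
#'
#' @param P_true True Petite probability in \[0, 1\].
#' @param k Number of colonies sampled; must be at least 1.
#' @return Numeric \code{c(low, high)}.
#' @export
binomial_envelope <- function(P_true, k) {
  if (P_true < 0 || P_true > 1) stop("P_true must lie in [0, 1]")
  if (k < 1) stop("k must be at least 1")
  s <- sqrt(P_true * (1 - P_true) / k)
  c(low = max(0, P_true - s), high = min(1, P_true + s))
}

#' Absolute Petite-frequency error
#'
#' @param pred,truth [petite_frequency()] results with \code{k > 0}.
#' @return \code{|P_pred - P_true|} in \[0, 1\].
#' @export
frequency_error <- function(pred, truth) {
  if (is.na(pred$petite_freq) || is.na(truth$petite_freq)) {
    stop("frequency error is undefined when either plate has no colonies")
  }
  abs(pred$petite_freq - truth$petite_freq)
}

#' Batch Petite-frequency error
#'
#' Joins predicted and ground-truth frequency tables by \code{image_id}
#' and summarizes the per-plate absolute errors.
#'
#' @param pred,truth Data frames with \code{image_id} and
#'   \code{petite_freq} columns (rows from [petite_frequency()]).
#' @return List with \code{per_image} (data frame \code{image_id, error}),
#'   \code{mean_error} and \code{sd_error}.
#' @export
frequency_error_batch <- function(pred, truth) {
  m <- merge(pred[c("image_id", "petite_freq")],
             truth[c("image_id", "petite_freq")],
             by = "image_id", suffixes = c("_pred", "_true"))
  if (nrow(m) == 0L) stop("no shared image_id between prediction and truth tables")
  if (any(is.na(m$petite_freq_pred)) || any(is.na(m$petite_freq_true))) {
    stop("frequency error is undefined for plates with no colonies")
  }
  err <- abs(m$petite_freq_pred - m$petite_freq_true)
  list(per_image = data.frame(image_id = m$image_id, error = err,
                              stringsAsFactors = FALSE),
       mean_error = mean(err),
       sd_error = if (length(err) > 1L) stats::sd(err) else NA_real_)
}
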