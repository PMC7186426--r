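# Extended Infomax ICA (natural-gradient, kurtosis-switching).
#
# The extended variant is required because EEG mixtures contain both
# super-Gaussian sources (blinks, muscle bursts) and sub-Gaussian ones
# (oscillations, line noise); the sign matrix K switches the nonlinearity
# per component based on the running kurtosis estimate.

#' Fit an Infomax ICA decomposition
#'
#' Runs extended Infomax ICA on a recording: the data are centred, sphered
#' by the inverse matrix square root of the channel covariance, and the
#' square unmixing matrix is learnt by the natural-gradient rule
#' \eqn{\Delta W \propto (I - K\,\tanh(u)u^T - uu^T)\,W} over random sample
#' blocks, with annealed learning rate.  Deterministic given \code{seed}.
#'
#' @param rec an \code{eeg_recording} with many more samples than channels
#' @param seed integer seed controlling block shuffling
#' @param max_iter maximum number of passes over the data
#' @param tol stop when the squared weight change per pass falls below this
#' @param lrate initial learning rate; default \code{0.00065/log(n_channels)}
#' @return object of class \code{ica_decomposition} with elements
#'   \code{unmixing} (components x channels), \code{mixing}
#'   (channels x components), \code{activations} (components x samples),
#'   \code{center}, \code{seed}, \code{rejected} (empty integer vector)
#' @export
fit_ica <- function(rec, seed = 1, max_iter = 512, tol = 1e-7, lrate = NULL) {
  X <- rec$data
  nch <- nrow(X)
  n <- ncol(X)
  if (n < 10 * nch) stop_dfhm("too few samples (", n, ") for ", nch, " channels")
  ctr <- rowMeans(X)
  Xc <- X - ctr
  C <- tcrossprod(Xc) / (n - 1)
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-9 * max(eg$values)) {
    cm <- suppressWarnings(stats::cor(t(Xc)))
    diag(cm) <- 0
    dup <- which(abs(cm) > 0.9999, arr.ind = TRUE)
    offenders <- unique(rec$channel_names[dup[, 1]])
    stop_dfhm("rank-deficient data; near-duplicate channels: ",
              if (length(offenders)) paste(offenders, collapse = ", ")
              else "(no single pair identifiable)")
  }
  sph <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  Xw <- sph %*% Xc

  if (is.null(lrate)) lrate <- 0.00065 / log(nch)
  block <- ceiling(sqrt(n / 3))
  W <- diag(nch)
  signs <- rep(1, nch)
  I_blk <- block * diag(nch)
  oldW <- W
  olddelta <- NULL
  kurt_every <- 1          # re-estimate source kurtosis once per pass
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      perm <- sample.int(n)
      for (b in seq(1, n - block + 1, by = block)) {
        u <- W %*% Xw[, perm[b:(b + block - 1)], drop = FALSE]
        y <- tanh(u)
        W <- W + lrate * (I_blk - (signs * y) %*% t(u) - tcrossprod(u)) %*% W
        if (!all(is.finite(W)) || max(abs(W)) > 1e8) break
      }
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) {   # blow-up: restart
        lrate <- lrate * 0.5
        W <- diag(nch)
        oldW <- W
        olddelta <- NULL
        next
      }
      if (it %% kurt_every == 0) {
        sub_idx <- sample.int(n, min(n, 6000))
        act <- W %*% Xw[, sub_idx, drop = FALSE]
        k <- apply(act, 1, function(a) mean((a - mean(a))^4) / stats::var(a)^2 - 3)
        signs <- ifelse(k > 0, 1, -1)
      }
      delta <- W - oldW
      change <- sum(delta^2)
      if (change < tol) break
      if (!is.null(olddelta)) {
        angle <- sum(delta * olddelta) / sqrt(sum(delta^2) * sum(olddelta^2))
        if (angle < cos(60 * pi / 180)) lrate <- lrate * 0.98
      }
      olddelta <- delta
      oldW <- W
    }
  })
  unmixing <- W %*% sph
  mixing <- solve(unmixing)
  activations <- unmixing %*% Xc
  # order components by back-projected variance, largest first
  pvar <- colSums(mixing^2) * apply(activations, 1, stats::var)
  ord <- order(pvar, decreasing = TRUE)
  unmixing <- unmixing[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  activations <- activations[ord, , drop = FALSE]
  structure(list(unmixing = unmixing, mixing = mixing,
                 activations = activations, center = ctr,
                 channel_names = rec$channel_names, fs = rec$fs,
                 rejected = integer(0), seed = seed),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat("<ica_decomposition> ", nrow(x$unmixing), " components over ",
      length(x$channel_names), " channels (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Artifact-evidence scores per ICA component
#'
#' Three per-component metrics used by the automatic rejection policy:
#' \code{lf_frac}, the fraction of activation spectral power below 3 Hz
#' (blinks and slow movement artifacts live there); \code{frontal_frac},
#' the fraction of absolute mixing weight on frontal electrodes (blink
#' topography); and \code{kurtosis} of the activation (transient artifacts
#' are heavy-tailed).
#'
#' @param decomp an \code{ica_decomposition}
#' @param montage montage supplying the frontal electrode set
#' @return data frame with columns component, lf_frac, frontal_frac, kurtosis
#' @export
component_scores <- function(decomp, montage = default_montage()) {
  fs <- decomp$fs
  frontal <- intersect(frontal_electrodes(montage), decomp$channel_names)
  n <- ncol(decomp$activations)
  freqs <- (seq_len(n) - 1) * fs / n
  lf <- freqs < 3 | freqs > fs - 3        # two-sided bins below 3 Hz
  scores <- t(apply(decomp$activations, 1, function(a) {
    p <- abs(stats::fft(a))^2
    lf_frac <- sum(p[lf]) / sum(p)
    k <- mean((a - mean(a))^4) / stats::var(a)^2 - 3
    c(lf_frac = lf_frac, kurtosis = k)
  }))
  fr_idx <- match(frontal, decomp$channel_names)
  w <- abs(decomp$mixing)
  frontal_frac <- colSums(w[fr_idx, , drop = FALSE]) / colSums(w)
  data.frame(component = seq_len(nrow(decomp$unmixing)),
             lf_frac = scores[, "lf_frac"],
             frontal_frac = frontal_frac,
             kurtosis = scores[, "kurtosis"])
}

#' Default automatic component-rejection policy
#'
#' A component is rejected when it looks like a blink/movement artifact
#' (low-frequency power fraction and frontal topography concentration both
#' above threshold) or is extremely heavy-tailed (kurtosis above threshold).
#'
#' @param lf_frac,frontal_frac,kurtosis rejection thresholds
#' @return a policy list for \code{\link{reject_components}}
#' @export
auto_rejection_policy <- function(lf_frac = 0.55, frontal_frac = 0.5,
                                  kurtosis = 20) {
  list(type = "auto", lf_frac = lf_frac, frontal_frac = frontal_frac,
       kurtosis = kurtosis)
}

#' Manual component-rejection policy
#' @param reject integer vector of component indices to remove
#' @return a policy list for \code{\link{reject_components}}
#' @export
manual_rejection_policy <- function(reject) {
  list(type = "manual", reject = as.integer(reject))
}

#' Remove artifact components and reconstruct the recording
#'
#' @param rec the \code{eeg_recording} the decomposition was fitted on
#' @param decomp an \code{ica_decomposition}
#' @param policy a policy from \code{\link{auto_rejection_policy}} or
#'   \code{\link{manual_rejection_policy}}
#' @param montage montage used for topography scoring under the automatic
#'   policy
#' @return the recording reconstructed from retained components only; the
#'   set of rejected indices is stored in \code{attr(, "rejected")}
#' @export
reject_components <- function(rec, decomp, policy = auto_rejection_policy(),
                              montage = default_montage()) {
  ncomp <- nrow(decomp$unmixing)
  if (identical(policy$type, "manual")) {
    rej <- policy$reject
    if (any(rej < 1 | rej > ncomp)) stop_dfhm("component index out of range")
  } else {
    sc <- component_scores(decomp, montage)
    rej <- sc$component[(sc$lf_frac > policy$lf_frac &
                           sc$frontal_frac > policy$frontal_frac) |
                          sc$kurtosis > policy$kurtosis]
  }
  keep <- setdiff(seq_len(ncomp), rej)
  if (length(keep) == 0) stop_dfhm("policy rejected all components")
  clean <- decomp$mixing[, keep, drop = FALSE] %*%
    decomp$activations[keep, , drop = FALSE] + decomp$center
  rownames(clean) <- rec$channel_names
  rec$data <- clean
  attr(rec, "rejected") <- as.integer(rej)
  rec
}
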