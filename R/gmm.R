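#' Multispectral Gaussian-mixture tissue clustering
#'
#' Clusters the per-voxel feature vectors formed by concatenating the
#' min-max normalised, brain-extracted channels (FLAIR and whichever of
#' T1W/T2W/T2*W are present) into `k` tissue classes with a Gaussian
#' mixture fitted by expectation-maximisation. Covariances are diagonal.
#' Initialisation is a k-means partition under the given seed; if a
#' component collapses (vanishing weight or variance) the fit restarts from
#' a new k-means start, up to `restarts` times. The per-iteration
#' log-likelihood trace is returned; EM guarantees it is non-decreasing.
#'
#' The class whose T1W mean is highest is designated the NAWM prior (white
#' matter is the brightest tissue on T1); without a T1W channel the largest
#' mixture component is used, NAWM being the modal tissue in brain tissue
#' excluding the cortex.
#'
#' @param scan A [multi_sequence_scan()] (or a named list of congruent 3D
#'   arrays to use as channels).
#' @param brain_mask Logical 3D array of voxels to cluster (>= `10 * k`).
#' @param k Number of tissue classes (default 4: CSF, cortex/GM, NAWM, WMH).
#' @param seed RNG seed controlling initialisation; the fit is deterministic
#'   given the seed.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param restarts Maximum restarts after component collapse.
#' @return An object of class `gmm_segmentation`: `means` (k x d), `vars`
#'   (k x d), `weights`, `posteriors` (n x k, rows sum to 1), `labels`
#'   (3D integer array, `NA` outside mask), `loglik_trace`, `channels`,
#'   `nawm_class`, `mask`, `converged`.
#' @export
gaussian_cluster <- function(scan, brain_mask, k = 4, seed = 1L,
                             max_iter = 200L, tol = 1e-6, restarts = 10L) {
  chans <- if (inherits(scan, "multi_sequence_scan")) {
    nm <- c("flair", "t1w", "t2w", "t2star")
    Filter(Negate(is.null), setNames(lapply(nm, function(n) scan[[n]]), nm))
  } else if (is.list(scan) && !is.null(names(scan))) {
    scan
  } else abort("`scan` must be a multi_sequence_scan or a named list of arrays.")
  if (length(chans) < 1L) abort("At least one channel is required.")
  if (k < 2) abort("`k` must be >= 2.")
  brain_mask <- as_binary_mask(brain_mask)
  n <- sum(brain_mask)
  if (n < 10 * k)
    abort(sprintf("Brain mask has %d voxels; need at least 10*k = %d.", n, 10 * k))
  X <- vapply(chans, function(v) {
    x <- v[brain_mask]
    rng <- range(x)
    if (rng[1] == rng[2]) rep(0.5, length(x))
    else (x - rng[1]) / (rng[2] - rng[1])
  }, numeric(n))
  colnames(X) <- names(chans)
  d <- ncol(X)
  min_var <- 1e-8
  min_w <- 1e-6

  fit_once <- function(attempt) {
    km <- with_seed(seed + attempt - 1L,
                    suppressWarnings(kmeans(X, centers = k, nstart = 10L,
                                            iter.max = 50L)))
    mu <- km$centers
    wts <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
    vars <- do.call(rbind, lapply(seq_len(k), function(j) {
      idx <- km$cluster == j
      if (sum(idx) < 2) rep(0.01, d)
      else pmax(apply(X[idx, , drop = FALSE], 2, function(c) mean((c - mean(c))^2)),
                min_var)
    }))
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      logd <- vapply(seq_len(k), function(j) {
        z2 <- sweep(X, 2, mu[j, ])^2
        -sum(log(2 * pi * vars[j, ])) / 2 -
          rowSums(sweep(z2, 2, 2 * vars[j, ], "/")) + log(wts[j])
      }, numeric(n))
      m <- apply(logd, 1, max)
      lse <- m + log(rowSums(exp(logd - m)))
      ll <- sum(lse)
      trace <- c(trace, ll)
      resp <- exp(logd - lse)
      nk <- colSums(resp)
      wts_new <- nk / n
      if (any(wts_new < min_w)) return(list(collapsed = TRUE))
      mu_new <- sweep(crossprod(resp, X), 1, nk, "/")
      vars_new <- do.call(rbind, lapply(seq_len(k), function(j) {
        dev2 <- sweep(X, 2, mu_new[j, ])^2
        colSums(resp[, j] * dev2) / nk[j]
      }))
      if (any(vars_new < min_var)) return(list(collapsed = TRUE))
      mu <- mu_new; vars <- vars_new; wts <- wts_new
      if (it > 1 &&
          abs(trace[it] - trace[it - 1]) <= tol * (abs(trace[it - 1]) + 1e-12))
        return(list(collapsed = FALSE, mu = mu, vars = vars, wts = wts,
                    resp = resp, trace = trace, converged = TRUE))
    }
    list(collapsed = FALSE, mu = mu, vars = vars, wts = wts, resp = resp,
         trace = trace, converged = FALSE)
  }

  # run a few independent starts and keep the best likelihood; further
  # attempts only recover from component collapse
  n_init <- 2L
  res <- NULL
  good <- 0L
  for (attempt in seq_len(max(n_init, restarts))) {
    cand <- fit_once(attempt)
    if (cand$collapsed) next
    good <- good + 1L
    if (is.null(res) ||
        cand$trace[length(cand$trace)] > res$trace[length(res$trace)])
      res <- cand
    if (good >= n_init) break
  }
  if (is.null(res))
    abort(sprintf("EM degenerate (component collapse) in all %d restarts.", restarts))

  labels <- array(NA_integer_, dim = dim(brain_mask))
  labels[brain_mask] <- max.col(res$resp, ties.method = "first")
  colnames(res$mu) <- colnames(X)
  colnames(res$vars) <- colnames(X)
  nawm_class <- if ("t1w" %in% colnames(X)) which.max(res$mu[, "t1w"])
                else which.max(res$wts)
  structure(
    list(means = res$mu, vars = res$vars, weights = res$wts,
         posteriors = res$resp, labels = labels,
         loglik_trace = res$trace, channels = colnames(X),
         nawm_class = nawm_class, mask = brain_mask,
         converged = res$converged),
    class = "gmm_segmentation")
}

#' @export
print.gmm_segmentation <- function(x, ...) {
  cat(sprintf(
    "<gmm_segmentation> k = %d on channels %s; %d voxels; loglik %.4g after %d EM iterations%s\n",
    length(x$weights), paste(x$channels, collapse = "+"), nrow(x$posteriors),
    x$loglik_trace[length(x$loglik_trace)], length(x$loglik_trace),
    if (x$converged) "" else " (iteration cap reached)"))
  cat(sprintf("  NAWM class: %d (weight %.3f)\n", x$nawm_class,
              x$weights[x$nawm_class]))
  invisible(x)
}

#' Hard-label mask of one mixture class
#'
#' @param gmm A [gaussian_cluster()] result.
#' @param class Class index (default the designated NAWM class).
#' @return Logical 3D array.
#' @export
gmm_class_mask <- function(gmm, class = gmm$nawm_class) {
  if (!inherits(gmm, "gmm_segmentation")) abort("`gmm` must come from gaussian_cluster().")
  m <- array(FALSE, dim = dim(gmm$labels))
  m[!is.na(gmm$labels) & gmm$labels == class] <- TRUE
  m
}

#' One-call WMH segmentation and damage metric
#'
#' Runs a chosen segmentation route on a scan and computes the damage
#' metric from its masks:
#' * `"threshold"` — [segment_flair_threshold()] with a robust (median/MAD)
#'   NAWM reference estimated from the brain mask;
#' * `"mcmxxxvi"` — colour fusion + minimum-variance quantisation
#'   ([segment_mcmxxxvi()]);
#' * `"cluster"` — [gaussian_cluster()] provides the NAWM class, whose
#'   intensity statistics then drive the FLAIR threshold for WMH.
#'
#' @param scan A [multi_sequence_scan()].
#' @param brain_mask For `"threshold"` and `"mcmxxxvi"`, the tissue in which
#'   NAWM/WMH are sought (brain tissue excluding the cortex). For
#'   `"cluster"`, the whole brain-extracted region (ICV), so that the four
#'   mixture classes can map onto CSF, cortex, NAWM and WMH.
#' @param icv Logical ICV mask (for head-size normalisation).
#' @param method Segmentation route.
#' @param sequence Sequence used for the metric's intensities.
#' @param exclusion Optional exclusion mask.
#' @param ... Passed to the segmentation function (`k_sd`, `k`, `margin`,
#'   `seed`, ...).
#' @return List with `result` (a `wm_damage_result`) and `masks`
#'   (a validated [tissue_mask_set()]).
#' @export
wm_damage_pipeline <- function(scan, brain_mask, icv,
                               method = c("threshold", "mcmxxxvi", "cluster"),
                               sequence = c("FLAIR", "T2W"),
                               exclusion = NULL, ...) {
  method <- match.arg(method)
  sequence <- match.arg(sequence)
  brain_mask <- as_binary_mask(brain_mask)
  icv <- as_binary_mask(icv)
  seg <- switch(method,
    threshold = segment_flair_threshold(scan, brain_mask,
                                        exclusion = exclusion, ...),
    mcmxxxvi = {
      s <- segment_mcmxxxvi(scan, brain_mask, ...)
      list(nawm = s$wm, wmh_total = s$wmh_total,
           wmh_intense = s$wmh_intense,
           wmh_less_intense = s$wmh_less_intense)
    },
    cluster = {
      g <- gaussian_cluster(scan, brain_mask, ...)
      nawm0 <- gmm_class_mask(g)
      st <- intensity_stats(scan$flair, nawm0)
      s <- segment_flair_threshold(scan, brain_mask, nawm_stats = st,
                                   exclusion = exclusion)
      s$nawm <- nawm0 & !s$wmh_total
      s
    })
  masks <- tissue_mask_set(icv = icv,
                           nawm = seg$nawm, wmh_total = seg$wmh_total,
                           wmh_intense = seg$wmh_intense,
                           wmh_less_intense = seg$wmh_less_intense,
                           exclusion = exclusion)
  list(result = wm_damage_from_scan(scan, masks, sequence = sequence),
       masks = masks)
}
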