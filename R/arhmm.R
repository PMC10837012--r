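#' Principal component reduction of the measurement matrix
#'
#' Fits PCA on stacked valid measurement vectors and keeps the smallest
#' number of components whose cumulative explained-variance ratio reaches
#' `variance_target`, capped at `cap`. For the mating recordings the
#' first 30 components explain over 90 percent of the variance, and
#' modeling 30 dimensions instead of 59 shrinks the AR parameter count by
#' roughly 75 percent.
#'
#' @param frames Matrix of valid measurement vectors (frames x 59).
#' @param variance_target Cumulative explained-variance fraction to reach.
#' @param cap Upper bound on the number of kept components.
#' @return A `pca_model`: list with `mean`, `rotation` (orthonormal
#'   loadings, one column per component), `explained_variance_ratio`,
#'   `n_kept`.
#' @export
fit_pca <- function(frames, variance_target = 0.9, cap = 30L) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 2L) stop("need at least 2 frames for PCA", call. = FALSE)
  if (any(!is.finite(frames))) stop("frames contain non-finite values", call. = FALSE)
  p <- stats::prcomp(frames, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  if (tot == 0) stop("degenerate PCA: constant data", call. = FALSE)
  evr <- p$sdev^2 / tot
  n_kept <- min(cap, which(cumsum(evr) >= variance_target - 1e-12)[1L])
  structure(list(mean = p$center, rotation = p$rotation,
                 explained_variance_ratio = evr, n_kept = as.integer(n_kept)),
            class = "pca_model")
}

#' Project measurements onto kept principal components
#' @param model A [fit_pca()] model.
#' @param frames Matrix of measurement vectors.
#' @param n_components Number of components (default the model's `n_kept`).
#' @return frames x n_components score matrix.
#' @export
pca_project <- function(model, frames, n_components = model$n_kept) {
  sweep(as.matrix(frames), 2L, model$mean) %*%
    model$rotation[, seq_len(n_components), drop = FALSE]
}

#' Reconstruct measurements from principal-component scores
#' @param model A [fit_pca()] model.
#' @param scores Score matrix from [pca_project()].
#' @return Reconstruction in the original measurement space.
#' @export
pca_backproject <- function(model, scores) {
  scores <- as.matrix(scores)
  sweep(scores %*% t(model$rotation[, seq_len(ncol(scores)), drop = FALSE]),
        2L, model$mean, `+`)
}

#' Configuration of the sticky AR-HMM sampler
#'
#' @param K_max State-count truncation of the weak-limit approximation.
#' @param ar_lag AR order L (default 1: at 10 Hz one lag captures the
#'   fast within-module dynamics).
#' @param kappa Self-transition bias added to the diagonal of the
#'   transition Dirichlet prior; larger kappa yields longer modules.
#' @param alpha Transition Dirichlet concentration.
#' @param k0 Scale of the matrix-normal column precision prior (weak).
#' @param s0 Scale of the inverse-Wishart scale matrix.
#' @param nu0 Inverse-Wishart degrees of freedom; default `d + 2` is
#'   substituted at fit time when `NULL`.
#' @param n_iter Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before retaining states.
#' @param seed Integer seed.
#' @return An `arhmm_config` list.
#' @export
arhmm_config <- function(K_max = 10L, ar_lag = 1L, kappa = 100, alpha = 1,
                         k0 = 0.01, s0 = 1, nu0 = NULL,
                         n_iter = 100L, burn_in = 50L, seed = 1L) {
  if (K_max < 2L) stop("K_max must be at least 2", call. = FALSE)
  if (ar_lag < 1L) stop("ar_lag must be at least 1", call. = FALSE)
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter", call. = FALSE)
  structure(list(K_max = as.integer(K_max), ar_lag = as.integer(ar_lag),
                 kappa = kappa, alpha = alpha, k0 = k0, s0 = s0, nu0 = nu0,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "arhmm_config")
}

# Draw Sigma ~ IW(nu, S) and Beta | Sigma ~ MN(M, Sigma, Kn^{-1}).
draw_mniw <- function(M, Kn, S, nu) {
  d <- nrow(M); p <- ncol(M)
  W <- stats::rWishart(1L, nu, solve(S))[, , 1L]
  Sigma <- solve(W)
  Sigma <- (Sigma + t(Sigma)) / 2
  Ls <- t(chol(Sigma))
  Kinv <- solve(Kn)
  Kinv <- (Kinv + t(Kinv)) / 2
  U <- chol(Kinv)
  Beta <- M + Ls %*% matrix(stats::rnorm(d * p), d, p) %*% U
  list(Beta = Beta, Sigma = Sigma)
}

#' Draw sticky Dirichlet transition rows
#'
#' Samples each transition row j from
#' `Dirichlet(alpha + counts[j, ] + kappa * e_j)`: the self-transition
#' bias kappa inflates the diagonal pseudo-count, so the expected
#' self-transition probability `(alpha + kappa + n_jj) / (K alpha + kappa
#' + n_j.)` increases strictly with kappa.
#'
#' @param counts K x K matrix of observed transition counts.
#' @param alpha Dirichlet concentration.
#' @param kappa Self-transition bias (nonnegative).
#' @return Row-stochastic K x K matrix.
#' @export
draw_transition_rows <- function(counts, alpha, kappa) {
  K <- nrow(counts)
  out <- matrix(0, K, K)
  for (j in seq_len(K)) {
    shape <- alpha + counts[j, ]
    shape[j] <- shape[j] + kappa
    g <- stats::rgamma(K, shape = shape, rate = 1)
    if (sum(g) == 0) g <- rep(1, K)
    out[j, ] <- g / sum(g)
  }
  out
}

# Build the lagged regression design for one sequence: responses Y
# (rows L+1..T) against stacked lags plus an intercept.
build_design <- function(Y, L) {
  T_ <- nrow(Y); d <- ncol(Y)
  if (T_ <= L) stop("sequence must be longer than the AR lag", call. = FALSE)
  idx <- (L + 1L):T_
  X <- matrix(0, length(idx), d * L + 1L)
  for (l in seq_len(L)) X[, ((l - 1L) * d + 1L):(l * d)] <- Y[idx - l, , drop = FALSE]
  X[, d * L + 1L] <- 1
  list(Y = Y[idx, , drop = FALSE], X = X)
}

#' Fit the sticky AR-HMM by Gibbs sampling
#'
#' Bayesian inference for a switching vector-autoregression with a
#' sticky hidden Markov chain, the model that defines and distinguishes
#' behavioral modules. Each sweep alternates (a) exact forward-filter
#' backward-sampling of the label sequences given the current parameters
#' and (b) conjugate draws of each state's AR parameters
#' (matrix-normal-inverse-Wishart) and of the transition rows (Dirichlet
#' with the kappa bias added to the diagonal count). The prior mean of
#' the first lag matrix is the identity (posture persists frame to
#' frame); sequences are expected z-scored so the prior scales condition
#' well.
#'
#' @param recordings List of numeric matrices (frames x dimensions), one
#'   per uninterrupted sequence (invalid frames split a recording into
#'   chunks rather than being imputed).
#' @param config An [arhmm_config()].
#' @return An `arhmm_posterior`: list with `A` (per-state list of lag
#'   matrices), `b`, `Sigma`, `trans`, `init`, `labels` (MAP label vector
#'   per sequence, from the single best retained sweep), `loglik_trace`,
#'   `best_iter`, `config`.
#' @export
gibbs_fit <- function(recordings, config = arhmm_config()) {
  if (!is.list(recordings)) recordings <- list(recordings)
  recordings <- lapply(recordings, as.matrix)
  d <- ncol(recordings[[1L]])
  L <- config$ar_lag
  K <- config$K_max
  p <- d * L + 1L
  designs <- lapply(recordings, build_design, L = L)
  nu0 <- if (is.null(config$nu0)) d + 2L else config$nu0
  M0 <- cbind(diag(d), matrix(0, d, p - d))  # identity on the first lag
  K0 <- diag(config$k0, p)
  S0 <- diag(config$s0, d)
  M0K0 <- M0 %*% K0
  M0K0M0 <- M0K0 %*% t(M0)

  set.seed(config$seed)
  # initialize labels by k-means on the observations (ignoring dynamics)
  allY <- do.call(rbind, lapply(designs, `[[`, "Y"))
  km <- tryCatch(stats::kmeans(allY, centers = K, nstart = 1L, iter.max = 20L),
                 error = function(e) NULL)
  if (is.null(km)) {
    labels <- lapply(designs, function(dd) sample.int(K, nrow(dd$Y), replace = TRUE))
  } else {
    splits <- cumsum(vapply(designs, function(dd) nrow(dd$Y), integer(1L)))
    cl <- km$cluster
    labels <- Map(function(a, b) cl[a:b], c(1L, splits[-length(splits)] + 1L), splits)
  }

  best_ll <- -Inf
  best <- NULL
  trace <- numeric(config$n_iter)
  Beta <- array(0, c(d, p, K))
  Sigma <- array(0, c(d, d, K))

  for (it in seq_len(config$n_iter)) {
    # (b) conjugate parameter draws given labels
    for (k in seq_len(K)) {
      Sxx <- matrix(0, p, p); Syx <- matrix(0, d, p); Syy <- matrix(0, d, d)
      n_k <- 0L
      for (r in seq_along(designs)) {
        sel <- labels[[r]] == k
        if (!any(sel)) next
        Xk <- designs[[r]]$X[sel, , drop = FALSE]
        Yk <- designs[[r]]$Y[sel, , drop = FALSE]
        Sxx <- Sxx + crossprod(Xk)
        Syx <- Syx + crossprod(Yk, Xk)
        Syy <- Syy + crossprod(Yk)
        n_k <- n_k + sum(sel)
      }
      Kn <- K0 + Sxx
      Mn <- (M0K0 + Syx) %*% solve(Kn)
      Sn <- S0 + Syy + M0K0M0 - Mn %*% Kn %*% t(Mn)
      Sn <- (Sn + t(Sn)) / 2
      draw <- draw_mniw(Mn, Kn, Sn, nu0 + n_k)
      Beta[, , k] <- draw$Beta
      Sigma[, , k] <- draw$Sigma
    }

    # transition and initial-state draws
    counts <- matrix(0, K, K)
    first <- numeric(K)
    for (r in seq_along(labels)) {
      z <- labels[[r]]
      if (length(z) > 1L)
        for (t in 2L:length(z)) counts[z[t - 1L], z[t]] <- counts[z[t - 1L], z[t]] + 1
      first[z[1L]] <- first[z[1L]] + 1
    }
    trans <- draw_transition_rows(counts, config$alpha, config$kappa)
    g <- stats::rgamma(K, shape = config$alpha + first, rate = 1)
    init <- g / sum(g)

    # (a) label sequences by forward-filter backward-sampling
    ll_total <- 0
    for (r in seq_along(designs)) {
      obs_ll <- arhmm_obs_loglik(designs[[r]]$Y, designs[[r]]$X, Beta, Sigma)
      if (any(!is.finite(obs_ll)))
        stop("non-finite observation log-likelihood; check input scaling", call. = FALSE)
      z <- ffbs_sample(obs_ll, trans, init)
      labels[[r]] <- z
      T_ <- length(z)
      ll_total <- ll_total + sum(obs_ll[cbind(seq_len(T_), z)]) +
        log(init[z[1L]]) +
        if (T_ > 1L) sum(log(trans[cbind(z[-T_], z[-1L])])) else 0
    }
    trace[it] <- ll_total
    if (it > config$burn_in && ll_total > best_ll) {
      best_ll <- ll_total
      best <- list(Beta = Beta, Sigma = Sigma, trans = trans, init = init,
                   labels = labels, iter = it)
    }
  }
  if (is.null(best)) stop("no retained sweep; increase n_iter", call. = FALSE)

  # repackage parameters state by state, padding labels to full length
  A <- vector("list", K); b <- vector("list", K); Sg <- vector("list", K)
  for (k in seq_len(K)) {
    A[[k]] <- lapply(seq_len(L), function(l)
      best$Beta[, ((l - 1L) * d + 1L):(l * d), k, drop = FALSE][, , 1L])
    b[[k]] <- best$Beta[, p, k]
    Sg[[k]] <- best$Sigma[, , k]
  }
  full_labels <- lapply(best$labels, function(z) c(rep(z[1L], L), z))
  structure(list(A = A, b = b, Sigma = Sg, trans = best$trans,
                 init = best$init, labels = full_labels,
                 loglik_trace = trace, best_iter = best$iter,
                 best_loglik = best_ll, config = config),
            class = "arhmm_posterior")
}

#' @export
print.arhmm_posterior <- function(x, ...) {
  used <- sort(unique(unlist(x$labels)))
  cat(sprintf("arhmm_posterior: K_max %d (%d states used), lag %d, kappa %.3g\n",
              x$config$K_max, length(used), x$config$ar_lag, x$config$kappa))
  cat(sprintf("  best joint log-likelihood %.6g at sweep %d of %d\n",
              x$best_loglik, x$best_iter, x$config$n_iter))
  invisible(x)
}

#' Group label runs into module blocks
#'
#' A module block is a maximal run of one hidden state. Frame indices in
#' the result are 0-based with half-open `[start, end)` bounds, matching
#' the file conventions.
#'
#' @param labels Integer label vector for one recording; `NA` entries
#'   (invalid frames) are collected under `failed_module`.
#' @param frame_rate Frames per second.
#' @param recording_id Identifier stored with each block.
#' @param failed_module Module id assigned to invalid frames.
#' @return Data frame with `recording`, `module`, `start`, `end`,
#'   `n_frames`, `duration_s`; blocks tile the recording.
#' @export
extract_blocks <- function(labels, frame_rate = 10, recording_id = "rec",
                           failed_module = 0L) {
  if (length(labels) == 0L) stop("labels must be nonempty", call. = FALSE)
  z <- ifelse(is.na(labels), failed_module, labels)
  r <- rle(z)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  data.frame(recording = recording_id, module = r$values,
             start = start, end = end, n_frames = r$lengths,
             duration_s = r$lengths / frame_rate,
             stringsAsFactors = FALSE)
}

#' Flag major modules by usage
#'
#' @param blocks Block table ([extract_blocks()] output, possibly several
#'   recordings row-bound).
#' @param usage_threshold Minimum mean fraction of frames for a module to
#'   count as major (default 1 percent).
#' @param exclude Module ids never flagged (default the failed-frame id 0).
#' @return Data frame with `module`, `usage`, `major`.
#' @export
major_modules <- function(blocks, usage_threshold = 0.01, exclude = 0L) {
  total <- sum(blocks$n_frames)
  agg <- stats::aggregate(n_frames ~ module, data = blocks, FUN = sum)
  agg$usage <- agg$n_frames / total
  agg$major <- agg$usage >= usage_threshold & !(agg$module %in% exclude)
  agg[order(-agg$usage), c("module", "usage", "major")]
}

# Kolmogorov-Smirnov distance between two samples (sup ecdf difference).
ks_distance <- function(x, y) {
  g <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(g) - stats::ecdf(y)(g)))
}

#' Tune the self-transition bias against changepoint block sizes
#'
#' Fits the model at each kappa in `kappa_grid` and selects the value
#' whose module-duration distribution is closest (smallest
#' Kolmogorov-Smirnov distance on log durations) to the reference
#' changepoint block-duration distribution: increasing kappa lowers the
#' module transition probability and lengthens module durations, so this
#' sweep matches the model's time scale to the model-free estimate.
#'
#' @param recordings List of matrices as in [gibbs_fit()].
#' @param config Base [arhmm_config()]; its `kappa` is overridden.
#' @param kappa_grid Nonempty vector of positive kappa values.
#' @param reference_durations Changepoint block durations in seconds.
#' @return List with `kappa` (best value), `sweep` (data frame: kappa,
#'   ks_distance, median_duration_s, n_blocks), `fits` (per-kappa
#'   posteriors, named by kappa).
#' @export
tune_kappa <- function(recordings, config, kappa_grid, reference_durations) {
  if (length(kappa_grid) == 0L) stop("kappa_grid must be nonempty", call. = FALSE)
  if (length(reference_durations) == 0L) stop("reference durations empty", call. = FALSE)
  rows <- list(); fits <- list()
  for (kap in kappa_grid) {
    cfg <- config
    cfg$kappa <- kap
    fit <- tryCatch(gibbs_fit(recordings, cfg), error = function(e) {
      warning(sprintf("kappa %.4g excluded: %s", kap, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(fit) || any(!is.finite(fit$loglik_trace))) next
    durs <- unlist(lapply(seq_along(fit$labels), function(r)
      extract_blocks(fit$labels[[r]], recording_id = as.character(r))$duration_s))
    rows[[length(rows) + 1L]] <- data.frame(
      kappa = kap,
      ks_distance = ks_distance(log(durs), log(reference_durations)),
      median_duration_s = stats::median(durs),
      n_blocks = length(durs))
    fits[[as.character(kap)]] <- fit
  }
  if (length(rows) == 0L) stop("tuning error: every kappa diverged", call. = FALSE)
  sweep <- do.call(rbind, rows)
  list(kappa = sweep$kappa[which.min(sweep$ks_distance)], sweep = sweep,
       fits = fits)
}

#' Write / read an AR-HMM model checkpoint
#'
#' Stores the per-state AR parameters, transition matrix and (optionally)
#' the PCA model as a single JSON document with documented array layouts.
#'
#' @param fit An `arhmm_posterior`.
#' @param path Output file.
#' @param pca Optional [fit_pca()] model stored alongside.
#' @return `write_model_json` the path, invisibly; `read_model_json` the
#'   parsed checkpoint list with matrices restored.
#' @export
write_model_json <- function(fit, path, pca = NULL) {
  ck <- list(
    format = "wormmodes-arhmm-1",
    K_max = fit$config$K_max, ar_lag = fit$config$ar_lag,
    kappa = fit$config$kappa, d = length(fit$b[[1L]]),
    A = lapply(fit$A, function(st) lapply(st, unclass)),
    b = fit$b, Sigma = fit$Sigma, trans = fit$trans, init = fit$init,
    best_iter = fit$best_iter, best_loglik = fit$best_loglik
  )
  if (!is.null(pca))
    ck$pca <- list(mean = pca$mean, rotation = pca$rotation,
                   explained_variance_ratio = pca$explained_variance_ratio,
                   n_kept = pca$n_kept)
  jsonlite::write_json(ck, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_mat <- function(m) do.call(rbind, lapply(m, unlist))
  ck$A <- lapply(ck$A, function(st) lapply(st, to_mat))
  ck$b <- lapply(ck$b, unlist)
  ck$Sigma <- lapply(ck$Sigma, to_mat)
  ck$trans <- to_mat(ck$trans)
  ck$init <- unlist(ck$init)
  for (f in c("format", "K_max", "ar_lag", "kappa", "d", "best_iter",
              "best_loglik"))
    ck[[f]] <- unlist(ck[[f]])
  if (!is.null(ck$pca))
    ck$pca <- list(mean = unlist(ck$pca$mean),
                   rotation = to_mat(ck$pca$rotation),
                   explained_variance_ratio =
                     unlist(ck$pca$explained_variance_ratio),
                   n_kept = unlist(ck$pca$n_kept))
  ck
}

#' Z-score columns of a measurement matrix
#'
#' @param mat Numeric matrix.
#' @param center,scale Optional precomputed column centers / sds (to apply
#'   one recording's scaling to another).
#' @return Scaled matrix with attributes `center` and `scale`.
#' @export
zscore_columns <- function(mat, center = NULL, scale = NULL) {
  mat <- as.matrix(mat)
  if (is.null(center)) center <- colMeans(mat)
  if (is.null(scale)) {
    scale <- apply(mat, 2L, stats::sd)
    scale[scale == 0] <- 1
  }
  out <- sweep(sweep(mat, 2L, center), 2L, scale, `/`)
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Match inferred states to ground-truth states
#'
#' Greedy one-to-one assignment maximizing label overlap (a small-K
#' stand-in for the Hungarian algorithm; exact for the module counts used
#' here when overlap is dominated by the diagonal). Used only to evaluate
#' recovery on synthetic data, where true labels exist.
#'
#' @param inferred,truth Integer label vectors of equal length.
#' @return List with `map` (named vector inferred -> truth), `accuracy`
#'   (fraction of frames correct after mapping).
#' @export
match_states <- function(inferred, truth) {
  stopifnot(length(inferred) == length(truth))
  ti <- sort(unique(inferred)); tt <- sort(unique(truth))
  overlap <- table(factor(inferred, levels = ti), factor(truth, levels = tt))
  map <- stats::setNames(rep(NA_integer_, length(ti)), ti)
  ov <- as.matrix(overlap)
  for (step in seq_len(min(nrow(ov), ncol(ov)))) {
    j <- which(ov == max(ov), arr.ind = TRUE)[1L, ]
    if (ov[j[1L], j[2L]] < 0) break
    map[rownames(ov)[j[1L]]] <- as.integer(colnames(ov)[j[2L]])
    ov[j[1L], ] <- -1
    ov[, j[2L]] <- -1
  }
  mapped <- map[as.character(inferred)]
  list(map = map, accuracy = mean(!is.na(mapped) & mapped == truth))
}
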