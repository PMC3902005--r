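#' Estimate the null standard deviation
#'
#' The two-group model takes the null component of `Z` as Gaussian with
#' mean 0 and unknown scale, estimated from the center of the distribution
#' where true connections contribute essentially nothing. The default
#' (`"central-mle"`) starts from the median absolute deviation about the
#' fixed null mean 0 (rescaled by `1 / qnorm(0.75)` for Gaussian
#' consistency) and refines it by maximum likelihood for a zero-mean
#' Gaussian truncated to the central region `|z| <= trunc_mult * MAD
#' scale`; the refinement removes the upward bias the raw MAD inherits
#' from non-null mass in the tails. `"central-mad"` returns the unrefined
#' MAD estimate.
#'
#' @param z numeric vector or matrix of Z statistics (at least 100 finite
#'   entries).
#' @param method `"central-mle"` (default) or `"central-mad"`.
#' @param trunc_mult half-width of the central fitting region in initial
#'   scale units, default 2 (about 95% of the null mass, still essentially
#'   free of well-separated non-null mass).
#' @return the estimated null standard deviation (positive scalar).
#' @export
estimate_null_sigma <- function(z, method = c("central-mle", "central-mad"),
                                trunc_mult = 2) {
  method <- match.arg(method)
  z <- tested_values(z)
  if (length(z) < 100) {
    stop("need at least 100 finite entries to estimate the null scale",
         call. = FALSE)
  }
  if (length(unique(z)) == 1) {
    stop("degenerate null scale: all entries identical", call. = FALSE)
  }
  s0 <- median(abs(z)) / qnorm(0.75)
  if (method == "central-mad") {
    if (!is.finite(s0) || s0 <= 0) {
      stop("degenerate null scale", call. = FALSE)
    }
    return(s0)
  }
  # MLE of sigma for N(0, sigma^2) truncated to [-a, a]
  trunc_mle <- function(a) {
    zc <- z[abs(z) <= a]
    if (length(zc) < 50 || sum(zc != 0) < 2) return(NA_real_)
    nll <- function(log_s) {
      s <- exp(log_s)
      -sum(dnorm(zc, 0, s, log = TRUE)) +
        length(zc) * log(2 * pnorm(a / s) - 1)
    }
    opt <- stats::optimize(nll, interval = log(c(a / 50, a * 5)))
    exp(opt$minimum)
  }
  # initialize from a low quantile (little non-null mass below it even for
  # substantial non-null proportions) and iterate the fitting window
  s <- unname(stats::quantile(abs(z), 0.25)) / qnorm(0.625)
  if (!is.finite(s) || s <= 0) s <- s0
  for (it in 1:20) {
    s_new <- trunc_mle(trunc_mult * s)
    if (!is.finite(s_new) || s_new <= 0) break
    done <- abs(s_new - s) < 1e-8 * s
    s <- s_new
    if (done) break
  }
  if (!is.finite(s) || s <= 0) s <- s0
  if (!is.finite(s) || s <= 0) {
    stop("degenerate null scale", call. = FALSE)
  }
  s
}

#' Estimate the non-null proportion
#'
#' The fraction `eps` of truly connected stimulus-response pairs, a
#' parameter of the two-group mixture, is estimated before the local FDR
#' statistics are computed. The default is the Storey estimator: two-sided
#' p-values are formed from the null `N(0, sigma^2)`, and
#' `eps = 1 - #\{p > lambda\} / ((1 - lambda) p_total)`, clipped to
#' `[0, 1 - 1e-6]`. With `lambda = 0.5`, p-values above 0.5 come almost
#' exclusively from nulls, so their count calibrates the null proportion.
#'
#' @param z numeric vector or matrix of Z statistics.
#' @param sigma null standard deviation (e.g. from
#'   [estimate_null_sigma()]).
#' @param lambda Storey tuning parameter in (0, 1), default 0.5.
#' @return estimated non-null proportion in `[0, 1)`.
#' @export
estimate_epsilon <- function(z, sigma, lambda = 0.5) {
  z <- tested_values(z)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (lambda <= 0 || lambda >= 1) {
    stop("`lambda` must be in (0, 1)", call. = FALSE)
  }
  p <- 2 * stats::pnorm(-abs(z) / sigma)
  eps <- 1 - sum(p > lambda) / ((1 - lambda) * length(p))
  min(max(eps, 0), 1 - 1e-6)
}

#' Estimate the marginal mixture density
#'
#' Gaussian kernel density estimate of the marginal density `f` of the Z
#' statistics (the denominator of the local FDR statistic), with
#' Silverman's rule-of-thumb bandwidth by default. The returned evaluator
#' is strictly positive on the observed range and integrates to 1 within
#' numerical-quadrature error.
#'
#' @param z numeric vector or matrix of Z statistics (at least 100 finite
#'   entries).
#' @param bw bandwidth: a number or a rule name understood by
#'   [stats::density()] (default `"nrd0"`, Silverman's rule).
#' @param n_grid grid size for the kernel density evaluation.
#' @return a function `f(x)` evaluating the density estimate (linear
#'   interpolation on the grid, constant extrapolation beyond it), with
#'   attributes `bw`, `n` and `grid_range`.
#' @export
estimate_marginal_density <- function(z, bw = "nrd0", n_grid = 2048) {
  z <- tested_values(z)
  if (length(z) < 100) {
    stop("need at least 100 finite entries to estimate the marginal density",
         call. = FALSE)
  }
  if (sd(z) == 0) stop("zero-variance input", call. = FALSE)
  d <- density(z, bw = bw, n = n_grid, cut = 4)
  f <- approxfun(d$x, pmax(d$y, .Machine$double.xmin), rule = 2)
  attr(f, "bw") <- d$bw
  attr(f, "n") <- length(z)
  attr(f, "grid_range") <- range(d$x)
  class(f) <- c("marginal_density", class(f))
  f
}

#' Local false discovery rate statistics
#'
#' For each stimulus-response pair, the local FDR statistic
#' `T = (1 - eps) f0(Z) / f(Z)`, the estimated posterior probability that
#' the pair is null given its Z value: values near 1 favor "no response",
#' values near 0 favor a genuine connection. The ratio can numerically
#' exceed 1 (density-estimation error); it is clipped to `[0, 1]`.
#'
#' @param z numeric vector or matrix of Z statistics.
#' @param epsilon non-null proportion (from [estimate_epsilon()]).
#' @param sigma null standard deviation (from [estimate_null_sigma()]).
#' @param f marginal density evaluator (from
#'   [estimate_marginal_density()]).
#' @param loo when `z` are the same observations the density was fitted
#'   on (the usual case), evaluate the kernel estimate leave-one-out:
#'   each point's own kernel mass `K(0)/(n h)` is removed before forming
#'   the ratio. A point's own kernel otherwise inflates `f` at exactly
#'   the isolated tail values being tested, biasing `T` low. The
#'   correction is capped at half the raw estimate so that an isolated
#'   far outlier — where the kernel estimate is dominated by the point
#'   itself and carries no neighborhood information — keeps a positive
#'   density and a near-zero `T` rather than underflowing. Default
#'   `TRUE`; ignored if `f` lacks the needed `bw`/`n` attributes.
#' @return object shaped like `z` with `T` values in `[0, 1]`; masked
#'   (diagonal) entries of a `response_matrix` are `NA`.
#' @export
local_fdr_statistics <- function(z, epsilon, sigma, f, loo = TRUE) {
  if (epsilon < 0 || epsilon >= 1) stop("`epsilon` must be in [0, 1)",
                                        call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  fz <- f(as.numeric(z))
  bw <- attr(f, "bw")
  n_fit <- attr(f, "n")
  if (loo && !is.null(bw) && !is.null(n_fit) && n_fit > 1) {
    fz <- pmax((n_fit * fz - dnorm(0) / bw) / (n_fit - 1), fz / 2)
  }
  if (any(fz <= 0)) {
    warning("marginal density underflow; substituting numerical floor",
            call. = FALSE)
    fz <- pmax(fz, .Machine$double.xmin)
  }
  t_stat <- pmin(1, (1 - epsilon) * dnorm(as.numeric(z), 0, sigma) / fz)
  out <- z
  out[] <- t_stat
  msk <- mask_of(z)
  if (!is.null(msk)) out[msk] <- NA_real_
  out
}

#' Select significant pairs by ranked local FDR
#'
#' The `T` statistics are ranked from smallest to largest and the cut is
#' the largest `k` such that the mean of the `k` smallest statistics is at
#' most `level`: the average local FDR over the selected set — an estimate
#' of the expected false discovery proportion among them — stays below the
#' target. Ties are broken by (row, column) position so the selection is
#' deterministic.
#'
#' @param t_stat numeric vector or matrix of local FDR statistics (`NA` =
#'   untested, never selected).
#' @param level target false discovery rate in (0, 1), default 0.05.
#' @return list with `cut_index` (number selected), `mask` (logical, same
#'   shape as `t_stat`), `threshold` (largest selected `T`, `NA` if none)
#'   and `n_tests`.
#' @export
select_significant <- function(t_stat, level = 0.05) {
  if (level < 0 || level >= 1) stop("`level` must be in [0, 1)", call. = FALSE)
  tv <- as.numeric(t_stat)
  idx <- seq_along(tv)
  if (is.matrix(t_stat)) {
    # row-major tie-break key: (row, column)
    rc <- arrayInd(idx, dim(t_stat))
    key <- (rc[, 1] - 1) * ncol(t_stat) + rc[, 2]
  } else {
    key <- idx
  }
  keep <- which(!is.na(tv))
  ord <- keep[order(tv[keep], key[keep])]
  k <- 0L
  if (length(ord)) {
    cm <- cumsum(tv[ord]) / seq_along(ord)
    pass <- which(cm <= level)
    if (length(pass)) k <- max(pass)
  }
  mask <- t_stat
  mask[] <- FALSE
  storage.mode(mask) <- "logical"
  if (k > 0) mask[ord[seq_len(k)]] <- TRUE
  list(cut_index = k, mask = mask,
       threshold = if (k > 0) tv[ord[k]] else NA_real_,
       n_tests = length(keep))
}

#' Run the full local FDR procedure on a response matrix
#'
#' Composes the four estimation steps — null scale, non-null proportion,
#' marginal density, local FDR statistics — and the ranked selection rule,
#' recording every estimator setting for provenance. Diagonal entries of a
#' `response_matrix` built with `diagonal = "zero"` are excluded from
#' estimation and ranking.
#'
#' @param z a `response_matrix` (or any numeric matrix/vector of Z
#'   statistics).
#' @param level target false discovery rate, default 0.05.
#' @param lambda Storey parameter for [estimate_epsilon()].
#' @param bw bandwidth for [estimate_marginal_density()].
#' @return a `local_fdr_result` list: `epsilon_hat`, `sigma_hat`, `T`,
#'   `cut_index`, `significant_mask`, `threshold`, `level`, `n_tests`,
#'   `settings`.
#' @examples
#' zm <- generate_z_mixture(mixture_spec(epsilon = 0.05, seed = 1))
#' res <- run_fdr(zm$z, level = 0.05)
#' res$cut_index
#' @export
run_fdr <- function(z, level = 0.05, lambda = 0.5, bw = "nrd0") {
  sigma_hat <- estimate_null_sigma(z)
  epsilon_hat <- estimate_epsilon(z, sigma_hat, lambda = lambda)
  f_hat <- estimate_marginal_density(z, bw = bw)
  t_stat <- local_fdr_statistics(z, epsilon_hat, sigma_hat, f_hat)
  sel <- select_significant(t_stat, level = level)
  structure(list(
    epsilon_hat = epsilon_hat,
    sigma_hat = sigma_hat,
    T = t_stat,
    cut_index = sel$cut_index,
    significant_mask = sel$mask,
    threshold = sel$threshold,
    level = level,
    n_tests = sel$n_tests,
    settings = list(lambda = lambda, bw = attr(f_hat, "bw"),
                    sigma_estimator = "central-MAD",
                    epsilon_estimator = "storey",
                    diagonal = attr(z, "diagonal") %||% "include")
  ), class = "local_fdr_result")
}

#' @export
print.local_fdr_result <- function(x, ...) {
  cat("<local_fdr_result> level ", x$level, ": ", x$cut_index, " of ",
      x$n_tests, " pairs significant (eps_hat = ",
      signif(x$epsilon_hat, 3), ", sigma_hat = ", signif(x$sigma_hat, 3),
      ")\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# values entering estimation: drop masked diagonal of a response_matrix
tested_values <- function(z) {
  v <- as.numeric(z)
  msk <- mask_of(z)
  if (!is.null(msk)) v <- v[!msk]
  v <- v[is.finite(v)]
  v
}

# logical index of masked (untested) entries, or NULL
mask_of <- function(z) {
  if (is.matrix(z) && identical(attr(z, "diagonal"), "zero")) {
    msk <- matrix(FALSE, nrow(z), ncol(z))
    diag(msk) <- TRUE
    msk
  } else {
    NULL
  }
}
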