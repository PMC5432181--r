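# Complexity bounds, outlier diagnostics, and theoretical complexity via
# truncated negative-binomial fitting of the cluster-cardinality histogram.
#
# Model: the number of clusters of cardinality x is Nseq(x) ~ C * NB_{p,s}(x),
# where NB is the (untruncated) negative binomial mass function. C then
# estimates the total library complexity including the unobserved zero class;
# the fit is "truncated" in that only x >= x_min (default 2: singletons
# excluded) enters the least-squares objective.

#' Cluster-cardinality histogram
#'
#' @param x A `deal_result` or a clusters tibble with a `cardinality` column,
#'   or a bare integer vector of cardinalities.
#' @return A `cardinality_histogram` tibble: `cardinality`, `n_clusters`.
#'   Conservation: `sum(cardinality * n_clusters)` equals the number of reads
#'   clustered.
#' @export
cardinality_histogram <- function(x) {
  card <- if (inherits(x, "deal_result")) x$clusters$cardinality
          else if (is.data.frame(x)) x$cardinality
          else as.integer(x)
  tab <- table(card)
  out <- tibble::tibble(cardinality = as.integer(names(tab)),
                        n_clusters = as.integer(tab))
  class(out) <- c("cardinality_histogram", class(out))
  out
}

#' Minimal (lower-bound) complexity
#'
#' The number of clusters with cardinality two or greater. Singletons collect
#' both genuine rare sequences and reads carrying errors not associated with
#' a quality drop (uncorrectable), so they are excluded from the lower bound.
#'
#' @param h A [cardinality_histogram()].
#' @return Integer count.
#' @export
minimal_complexity <- function(h) {
  sum(h$n_clusters[h$cardinality >= 2L])
}

#' Detect high-cardinality outlier clusters
#'
#' Flags clusters whose log-cardinality exceeds median + `z_cut` * MAD over
#' all clusters (a MAD floor of log(2)/2 guards degenerate histograms). A
#' single dominant outlier typically originates from undigested plasmid
#' vector backbone; if the backbone sequence is supplied, outliers are
#' annotated by a >= 90% identity ungapped match to it. A high outlier count
#' indicates an unbalanced library.
#'
#' @param clusters Clusters tibble (from a `deal_result`).
#' @param backbone Optional contaminant/backbone sequence for annotation.
#' @param z_cut Robust z cutoff (default 3.5).
#' @return Tibble of outlier clusters with `log_card_z` and, if `backbone`
#'   is given, a logical `is_backbone` column.
#' @export
detect_outliers <- function(clusters, backbone = NULL, z_cut = 3.5) {
  stopifnot(nrow(clusters) > 0)
  lx <- log(clusters$cardinality)
  med <- median(lx)
  sc <- max(mad(lx), log(2) / 2)
  z <- (lx - med) / sc
  out <- clusters[z > z_cut, , drop = FALSE]
  out$log_card_z <- z[z > z_cut]
  if (!is.null(backbone) && nrow(out) > 0) {
    # containment test robust to the scFv pseudo-read junction: fraction of
    # consensus 20-mers present in the backbone (either strand)
    ref <- unname(backbone)
    kmers <- function(s, k = 20L) {
      if (nchar(s) < k) return(character(0))
      substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
    }
    bb <- c(kmers(ref), kmers(revcomp(ref)))
    out$is_backbone <- vapply(out$consensus, function(cs) {
      km <- kmers(cs)
      length(km) > 0 && mean(km %in% bb) >= 0.5
    }, logical(1), USE.NAMES = FALSE)
  }
  out
}

#' Remove outlier clusters from a histogram
#'
#' Backbone contamination is not library diversity, so outlier clusters are
#' excluded before fitting.
#'
#' @param h A [cardinality_histogram()].
#' @param outliers The [detect_outliers()] result.
#' @return The reduced histogram.
#' @export
exclude_outliers <- function(h, outliers) {
  if (nrow(outliers) == 0) return(h)
  drop <- table(outliers$cardinality)
  i <- match(as.integer(names(drop)), h$cardinality)
  h$n_clusters[i] <- h$n_clusters[i] - as.integer(drop)
  out <- h[h$n_clusters > 0, , drop = FALSE]
  class(out) <- class(h)
  out
}

#' Fit a truncated negative binomial to the cardinality histogram
#'
#' Minimizes `sum_x (Nseq(x) - C * dnbinom(x, size = s, prob = p))^2` over
#' `x` in `[x_min, x_max]` by nonlinear least squares (Levenberg-Marquardt),
#' multi-started over a coarse (p, s) grid. The mass function is the
#' untruncated negative binomial, so C estimates the total complexity
#' including the unobserved zero class.
#'
#' @param h A [cardinality_histogram()] (outliers excluded upstream).
#' @param x_min Smallest cardinality entering the fit (default 2: the
#'   unreliable singleton class is excluded).
#' @param x_max Largest cardinality entering the fit (default: all).
#' @return A `negbin_fit` object: `p`, `s`, `C`, `fit_range`, `rss`,
#'   `residuals` tibble, `observed_clusters`, `n_points`, `converged_starts`.
#' @export
fit_truncated_negbin <- function(h, x_min = 2L, x_max = NULL) {
  x_max <- x_max %||% max(h$cardinality)
  d <- h[h$cardinality >= x_min & h$cardinality <= x_max, , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 distinct cardinality values in [", x_min, ", ",
         x_max, "] to fit; found ", nrow(d), call. = FALSE)
  x <- d$cardinality
  n <- d$n_clusters

  starts <- expand.grid(p = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        s = c(0.5, 1, 1.5, 3, 6))
  # unconstrained parametrization: C = exp(lC), s = exp(ls), p = plogis(lp)
  resid_fn <- function(par) {
    n - exp(par[1]) * dnbinom(x, size = exp(par[2]), prob = plogis(par[3]))
  }
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    p0 <- starts$p[i]; s0 <- starts$s[i]
    c0 <- sum(n) / max(sum(dnbinom(x, size = s0, prob = p0)), 1e-12)
    fit <- suppressWarnings(tryCatch(
      minpack.lm::nls.lm(
        par = c(lC = log(c0), ls = log(s0), lp = qlogis(p0)),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    ))
    if (is.null(fit) || !fit$info %in% 1:4) next
    n_conv <- n_conv + 1L
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("truncated NB fit failed to converge from all ", nrow(starts),
         " starts (best grid residuals unavailable)", call. = FALSE)
  cf <- best$fit$par
  p_hat <- plogis(cf[["lp"]]); s_hat <- exp(cf[["ls"]]); C_hat <- exp(cf[["lC"]])
  fitted_n <- C_hat * dnbinom(x, size = s_hat, prob = p_hat)
  structure(list(
    p = p_hat, s = s_hat, C = C_hat,
    fit_range = c(x_min = as.integer(x_min), x_max = as.integer(x_max)),
    rss = best$rss,
    residuals = tibble::tibble(cardinality = x, observed = n,
                               fitted = fitted_n,
                               residual = n - fitted_n),
    observed_clusters = sum(h$n_clusters),
    n_points = nrow(d),
    converged_starts = n_conv
  ), class = "negbin_fit")
}

#' @export
print.negbin_fit <- function(x, ...) {
  cat("Truncated negative-binomial complexity fit\n")
  cat(sprintf("  p = %.4f, s = %.4f\n", x$p, x$s))
  cat(sprintf("  C (theoretical complexity) = %.4g\n", x$C))
  cat(sprintf("  fit range x in [%d, %d], %d points, RSS = %.4g\n",
              x$fit_range[1], x$fit_range[2], x$n_points, x$rss))
  cat(sprintf("  observed clusters = %d (C/observed = %.3f)\n",
              x$observed_clusters, x$C / x$observed_clusters))
  invisible(x)
}

#' @rdname fit_truncated_negbin
#' @param x A `negbin_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.negbin_fit <- function(x, ...) {
  tibble::tibble(term = c("p", "s", "C"),
                 estimate = c(x$p, x$s, x$C))
}

#' @rdname fit_truncated_negbin
#' @exportS3Method generics::glance
glance.negbin_fit <- function(x, ...) {
  tibble::tibble(C = x$C, p = x$p, s = x$s, rss = x$rss,
                 n_points = x$n_points,
                 observed_clusters = x$observed_clusters,
                 c_over_observed = x$C / x$observed_clusters)
}

#' Library complexity summary table
#'
#' The five-column summary: total reads analyzed, the maximal complexity cap
#' (user-supplied transformant count, if known), the DEAL cluster count, the
#' minimal complexity (cardinality >= 2), and the theoretical complexity from
#' the truncated NB fit.
#'
#' @param deal A `deal_result`.
#' @param fit A `negbin_fit` (optional).
#' @param max_complexity Transformant-count upper cap (optional).
#' @return A one-row tibble.
#' @export
complexity_summary <- function(deal, fit = NULL, max_complexity = NA_real_) {
  h <- cardinality_histogram(deal)
  tibble::tibble(
    total_reads = deal$n_reads,
    maximal_complexity = max_complexity,
    deal_clusters = deal$complexity,
    minimal_complexity = minimal_complexity(h),
    theoretical_complexity = if (is.null(fit)) NA_real_ else fit$C
  )
}

#' @rdname cardinality_histogram
#' @param deal A `deal_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.deal_result <- function(x, ...) {
  x$clusters[, c("cluster_id", "seed", "consensus", "cardinality")]
}

#' @rdname cardinality_histogram
#' @exportS3Method generics::glance
glance.deal_result <- function(x, ...) {
  h <- cardinality_histogram(x)
  tibble::tibble(
    n_reads = x$n_reads,
    seed_complexity = x$seed_complexity,
    complexity = x$complexity,
    minimal_complexity = minimal_complexity(h),
    singletons = sum(h$n_clusters[h$cardinality == 1L]),
    max_cardinality = max(h$cardinality)
  )
}
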