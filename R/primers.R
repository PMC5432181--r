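# Primer-class assignment and chain/VDJ assortment diagnostics.

.mismatch_count <- function(windows, primer) {
  # IUPAC-aware anchored mismatch count: a position matches if the base-set
  # intersection of read base and primer base is non-empty
  pb <- .iupac_bits[as.integer(charToRaw(primer)) + 1L]
  vapply(windows, function(w) {
    wb <- .iupac_bits[as.integer(charToRaw(w)) + 1L]
    if (length(wb) != length(pb)) return(NA_integer_)
    sum(bitwAnd(wb, pb) == 0L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Assign sequences to a primer class
#'
#' Compares an anchored window at the 5' or 3' end of each sequence against
#' every recognition sequence of that direction, and assigns the class with
#' the fewest mismatches. Sequences whose best class exceeds `max_mismatch`,
#' or that tie between classes, are unclassified (`"UC"`) — ties are not
#' broken arbitrarily to avoid inflating any class. Degenerate (IUPAC) bases
#' in recognition sequences match any of their expansions.
#'
#' @param sequences Character vector of (consensus) sequences.
#' @param lib A [primer_library()]. Reverse recognition sequences are in
#'   sense-strand orientation (as they appear at the 3' end).
#' @param end `"5prime"` (forward classes) or `"3prime"` (reverse classes).
#' @param offset Constant bases between the sequence end and the primer site
#'   (e.g. a restriction-site anchor); the recognition window starts after
#'   them. The built-in construct geometry uses 10 at the 5' end and 8 at
#'   the 3' end.
#' @return Character vector of class names or `"UC"`.
#' @export
assign_primer <- function(sequences, lib, end = c("5prime", "3prime"),
                          offset = 0L) {
  end <- match.arg(end)
  classes <- if (end == "5prime") lib$forward else lib$reverse
  L <- nchar(sequences)
  mm <- matrix(NA_integer_, length(sequences), length(classes))
  for (ci in seq_along(classes)) {
    pr <- classes[[ci]]
    pl <- nchar(pr)
    win <- if (end == "5prime") {
      substr(sequences, offset + 1L, offset + pl)
    } else {
      substr(sequences, L - offset - pl + 1L, L - offset)
    }
    ok <- nchar(win) == pl
    cnt <- rep(NA_integer_, length(sequences))
    cnt[ok] <- .mismatch_count(win[ok], pr)
    mm[, ci] <- cnt
  }
  best <- suppressWarnings(apply(mm, 1, min, na.rm = TRUE))
  n_best <- rowSums(mm == best, na.rm = TRUE)
  cls <- names(classes)[apply(mm, 1, which.min)]
  cls[!is.finite(best) | best > lib$max_mismatch | n_best > 1] <- "UC"
  cls
}

#' Observed vs expected primer-pair assortment
#'
#' Builds the joint distribution of (forward, reverse) class assignments and
#' compares it with the product of the marginals — the expected distribution
#' under independent chain (or VDJ) assortment. Unclassified (`UC`)
#' assignments appear in the observed table but are excluded from the
#' marginals and the expectation.
#'
#' @param assignments Tibble/data frame with columns `fwd` and `rev`
#'   (class names or `"UC"`).
#' @return An `assortment_table` list: `observed` (joint frequencies over all
#'   pairs, UC included), `expected` (product of classified marginals),
#'   `log2_ratio` (classified cells), `chisq` (descriptive statistic),
#'   `n_pairs`, `n_classified`.
#' @export
assortment <- function(assignments) {
  stopifnot(all(c("fwd", "rev") %in% names(assignments)))
  fwd <- assignments$fwd; rev <- assignments$rev
  n <- length(fwd)
  classified <- fwd != "UC" & rev != "UC"
  if (!any(classified))
    stop("all pairs unclassified; cannot form an assortment table",
         call. = FALSE)
  obs_all <- table(fwd, rev) / n

  fc <- fwd[classified]; rc <- rev[classified]
  m_f <- table(fc) / length(fc)
  m_r <- table(rc) / length(rc)
  expected <- outer(as.numeric(m_f), as.numeric(m_r))
  dimnames(expected) <- list(names(m_f), names(m_r))
  obs_c <- table(factor(fc, names(m_f)), factor(rc, names(m_r))) / length(fc)
  log2_ratio <- log2(pmax(as.numeric(obs_c), 1e-12) /
                       pmax(as.numeric(expected), 1e-12))
  log2_ratio <- matrix(log2_ratio, nrow(expected), ncol(expected),
                       dimnames = dimnames(expected))
  chisq <- sum((as.numeric(obs_c) - expected)^2 / pmax(expected, 1e-12)) *
    length(fc)
  structure(list(
    observed = obs_all, observed_classified = obs_c, expected = expected,
    log2_ratio = log2_ratio, chisq = chisq,
    n_pairs = n, n_classified = sum(classified)
  ), class = "assortment_table")
}

#' @export
print.assortment_table <- function(x, ...) {
  cat("Primer-pair assortment (", x$n_classified, "/", x$n_pairs,
      " pairs classified)\n", sep = "")
  cat("  max |log2(obs/exp)| =", round(max(abs(x$log2_ratio)), 3), "\n")
  cat("  chi-square (descriptive) =", round(x$chisq, 1), "\n")
  invisible(x)
}
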