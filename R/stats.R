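# Exact contingency-table tests, adjusted standardized residual post-hoc,
# one-way ANOVA (raw and summary forms), Dunnett many-to-one comparisons and
# Bonferroni correction.

#' Build a labelled contingency table
#'
#' @param counts Matrix (or object coercible to one) of non-negative
#'   integer counts, at least 2x2, grand total > 0.
#' @param row_labels,col_labels Optional dimension labels.
#' @return An integer matrix with dimnames.
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  m <- as.matrix(counts)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("contingency table must be at least 2x2", call. = FALSE)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("contingency table entries must be non-negative integers",
         call. = FALSE)
  if (sum(m) <= 0)
    stop("contingency table grand total must be positive", call. = FALSE)
  storage.mode(m) <- "integer"
  if (!is.null(row_labels)) rownames(m) <- row_labels
  if (!is.null(col_labels)) colnames(m) <- col_labels
  m
}

#' Read a labelled contingency table from TSV
#'
#' First column holds row labels; remaining columns are counts.
#' @param path Path to the TSV.
#' @return An integer matrix with dimnames.
#' @export
read_contingency_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  contingency_table(as.matrix(d[, -1, drop = FALSE]),
                    row_labels = d[[1]])
}

mt_exact_test <- function(p, method, table, replicates = NA_integer_,
                          seed = NA_integer_, std_error = NA_real_,
                          degenerate = FALSE, n_tables = NA_real_) {
  structure(list(p.value = p, method = method, table = table,
                 replicates = replicates, seed = seed,
                 std.error = std_error, degenerate = degenerate,
                 n.tables = n_tables),
            class = "mt_exact_test")
}

#' @export
print.mt_exact_test <- function(x, ...) {
  cat("Exact contingency test (", x$method, ")\n", sep = "")
  cat("  p =", format(x$p.value, digits = 4))
  if (x$method == "monte-carlo")
    cat("  (", x$replicates, " replicates, SE ",
        format(x$std.error, digits = 3), ", seed ", x$seed, ")", sep = "")
  if (isTRUE(x$degenerate)) cat("  [degenerate margin]")
  cat("\n")
  invisible(x)
}

# Relative tolerance on the "no more probable than observed" comparison, to
# avoid floating-point misclassification of tied tables (log scale).
POINT_PROB_TOL <- 1e-9

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all margin-fixed 2x2 tables whose point
#' probability does not exceed that of the observed table. Computation is
#' exact in log space; no approximation and no continuity correction. The
#' mid-p variant is deliberately not offered.
#'
#' @param table A 2x2 count matrix (see \code{\link{contingency_table}}).
#' @return An object of class \code{mt_exact_test}. A table with a zero
#'   row or column margin returns p = 1 flagged as degenerate.
#' @examples
#' fisher_exact_2x2(matrix(c(65, 35, 58, 57), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  m <- contingency_table(table)
  if (nrow(m) != 2L || ncol(m) != 2L)
    stop("fisher_exact_2x2 expects a 2x2 table", call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0L) || any(cs == 0L))
    return(mt_exact_test(1, "full-enumeration", m, degenerate = TRUE))
  lo <- max(0L, rs[1L] - cs[2L])
  hi <- min(rs[1L], cs[1L])
  a <- lo:hi
  lp <- stats::dhyper(a, cs[1L], cs[2L], rs[1L], log = TRUE)
  lobs <- stats::dhyper(m[1L, 1L], cs[1L], cs[2L], rs[1L], log = TRUE)
  p <- min(1, sum(exp(lp[lp <= lobs + POINT_PROB_TOL])))
  mt_exact_test(p, "full-enumeration", m, n_tables = length(a))
}

# Run code under a local seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# log point probability constant: P(table) = exp(base + -sum(lfactorial(n_ij)))
fh_log_base <- function(rs, cs) {
  sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(sum(rs))
}

# Number of two-column tables with the given margins: the coefficient of
# x^c1 in prod_i (1 + x + ... + x^{r_i}), by polynomial convolution. Used
# to decide between enumeration and Monte Carlo without a trial run.
fh_count_2col <- function(rs, c1) {
  dp <- c(1, numeric(c1))
  for (r in rs) {
    cs <- cumsum(dp)
    k <- 0:c1
    lo <- k - pmin(r, k)
    dp <- cs[k + 1] - c(0, cs)[ifelse(lo > 0, lo, 0) + 1]
  }
  dp[c1 + 1]
}

# Enumerate all tables with the given margins, accumulating the total
# probability and the probability of tables no more probable than lobs.
# Aborts (complete = FALSE) once more than `cap` tables have been visited.
fh_enumerate <- function(rs, cs, lobs, cap) {
  r <- length(rs); cc <- length(cs)
  base <- fh_log_base(rs, cs)
  env <- new.env(parent = emptyenv())
  env$count <- 0; env$p <- 0; env$tot <- 0; env$aborted <- FALSE
  rec_row <- function(ri, colrem, lneg) {
    if (env$aborted) return()
    if (ri == r) {  # last row forced by the remaining column sums
      env$count <- env$count + 1
      if (env$count > cap) { env$aborted <- TRUE; return() }
      lp <- base + lneg - sum(lfactorial(colrem))
      pr <- exp(lp)
      env$tot <- env$tot + pr
      if (lp <= lobs + POINT_PROB_TOL) env$p <- env$p + pr
      return()
    }
    fill <- function(j, rem, colrem, lneg) {
      if (env$aborted) return()
      if (j == cc) {
        if (rem <= colrem[cc]) {
          colrem[cc] <- colrem[cc] - rem
          rec_row(ri + 1L, colrem, lneg - lfactorial(rem))
        }
        return()
      }
      for (x in 0:min(rem, colrem[j])) {
        cr <- colrem; cr[j] <- cr[j] - x
        fill(j + 1L, rem - x, cr, lneg - lfactorial(x))
      }
    }
    fill(1L, rs[ri], colrem, lneg)
  }
  rec_row(1L, cs, 0)
  list(p = env$p, total = env$tot, count = env$count,
       complete = !env$aborted)
}

#' Freeman-Halton exact test for an r x c table
#'
#' Generalises Fisher's exact test: the two-sided p-value is the total
#' probability, under the multivariate hypergeometric distribution with
#' fixed margins, of all tables whose point probability does not exceed the
#' observed one (with a 1e-9 relative tolerance on the comparison).
#' When a bounded recursive enumeration finds at most \code{max_enumeration}
#' margin-fixed tables the p-value is computed by full enumeration;
#' otherwise tables are sampled with fixed margins (sequential cell filling
#' from conditional hypergeometrics, via \code{\link[stats]{r2dtable}}) and
#' the add-one estimator p = (1 + #\{prob <= observed\}) / (1 + replicates)
#' is reported with its standard error.
#'
#' @param table Count matrix, at least 2x2.
#' @param max_enumeration Largest number of margin-fixed tables enumerated
#'   exactly (default 2e5).
#' @param mc_replicates Monte Carlo replicates for larger tables
#'   (default 1e5, minimum 1000).
#' @param seed Seed recorded and used for the Monte Carlo path.
#' @return An object of class \code{mt_exact_test}.
#' @export
freeman_halton_exact <- function(table, max_enumeration = 2e5,
                                 mc_replicates = 1e5, seed = 1L) {
  m <- contingency_table(table)
  if (mc_replicates < 1000)
    stop("mc_replicates must be at least 1000", call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0L) || any(cs == 0L)) {
    keep_r <- rs > 0L; keep_c <- cs > 0L
    if (sum(keep_r) < 2L || sum(keep_c) < 2L)
      return(mt_exact_test(1, "full-enumeration", m, degenerate = TRUE))
    # zero margins carry no information; drop them and test the rest
    res <- freeman_halton_exact(m[keep_r, keep_c, drop = FALSE],
                                max_enumeration, mc_replicates, seed)
    res$table <- m
    res$degenerate <- TRUE
    return(res)
  }
  lobs <- fh_log_base(rs, cs) - sum(lfactorial(m))
  n_tab <- if (ncol(m) == 2L) fh_count_2col(rs, cs[1L])
           else if (nrow(m) == 2L) fh_count_2col(cs, rs[1L])
           else NA_real_
  enum <- if (!is.na(n_tab) && n_tab > max_enumeration) list(complete = FALSE)
          else fh_enumerate(rs, cs, lobs, cap = max_enumeration)
  if (enum$complete) {
    return(mt_exact_test(min(1, enum$p), "full-enumeration", m,
                         n_tables = enum$count))
  }
  with_local_seed(seed, {
    tabs <- stats::r2dtable(mc_replicates, rs, cs)
    base <- fh_log_base(rs, cs)
    lps <- base - vapply(tabs, function(t) sum(lfactorial(t)), 0)
    hits <- sum(lps <= lobs + POINT_PROB_TOL)
    phat <- (1 + hits) / (1 + mc_replicates)
    se <- sqrt(phat * (1 - phat) / mc_replicates)
    mt_exact_test(phat, "monte-carlo", m, replicates = mc_replicates,
                  seed = seed, std_error = se)
  })
}

#' Adjusted standardized residual post-hoc analysis
#'
#' For each cell, the adjusted standardized residual
#' r_ij = (O_ij - E_ij) / sqrt(E_ij (1 - row_i/N)(1 - col_j/N))
#' with E_ij = row_i col_j / N, approximately standard normal under
#' independence; the two-sided p-value comes from the standard normal and
#' the per-cell effect size is phi_ij = r_ij / sqrt(N). Cells in a zero row
#' or column total are reported as undefined (NA).
#'
#' @param table Count matrix, at least 2x2.
#' @return Object of class \code{mt_residuals} with matrices
#'   \code{observed}, \code{expected}, \code{residuals}, \code{p.value},
#'   \code{phi} and the grand total \code{n}.
#' @examples
#' tab <- matrix(c(1, 8, 42, 43), 2, byrow = TRUE,
#'               dimnames = list(c("V", "H"), c("case", "control")))
#' adjusted_residuals(rbind(tab, other = c(57, 64)))
#' @export
adjusted_residuals <- function(table) {
  m <- contingency_table(table)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  E <- outer(rs, cs) / n
  denom <- sqrt(E * outer(1 - rs / n, 1 - cs / n))
  r <- (m - E) / denom
  r[E == 0 | denom == 0] <- NA_real_
  p <- 2 * stats::pnorm(-abs(r))
  phi <- r / sqrt(n)
  structure(list(observed = m, expected = E, residuals = r,
                 p.value = p, phi = phi, n = n),
            class = "mt_residuals")
}

#' @export
print.mt_residuals <- function(x, digits = 3, ...) {
  cat("Adjusted standardized residuals (N =", x$n, ")\n")
  print(round(x$residuals, digits))
  invisible(x)
}

mt_anova <- function(groups, ss_between, ss_within, df_between, df_within,
                     degenerate = FALSE) {
  f <- if (degenerate) NA_real_ else
    (ss_between / df_between) / (ss_within / df_within)
  p <- if (degenerate) NA_real_ else
    stats::pf(f, df_between, df_within, lower.tail = FALSE)
  structure(list(groups = groups, statistic = f,
                 df = c(df_between, df_within), p.value = p,
                 ss = c(between = ss_between, within = ss_within),
                 degenerate = degenerate),
            class = "mt_anova")
}

#' @export
print.mt_anova <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df[1], ", ", x$df[2], ") = ",
      format(x$statistic, digits = 4), ", p = ",
      format(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' One-way ANOVA from group summaries
#'
#' Recovers the exact analysis of variance from per-group sample sizes,
#' means and standard deviations: SSB = sum n_i (m_i - m.)^2 with
#' m. = sum n_i m_i / N, SSW = sum (n_i - 1) s_i^2, F = MSB/MSW with
#' (k - 1, N - k) degrees of freedom. Useful when only printed summaries
#' are available.
#'
#' @param n Integer vector of group sizes (each >= 2).
#' @param mean Numeric vector of group means.
#' @param sd Numeric vector of group standard deviations (>= 0).
#' @return Object of class \code{mt_anova}. When every group has zero
#'   variance the result is flagged degenerate with undefined p.
#' @examples
#' anova_oneway_summary(n = c(100, 100, 100, 115),
#'                      mean = c(0.58, 0.63, 0.70, 0.48),
#'                      sd = c(0.61, 0.66, 0.70, 0.58))
#' @export
anova_oneway_summary <- function(n, mean, sd) {
  if (length(n) != length(mean) || length(n) != length(sd))
    stop("n, mean and sd must have equal length", call. = FALSE)
  if (length(n) < 2L) stop("at least two groups are required", call. = FALSE)
  if (any(n < 2L)) stop("every group needs n >= 2", call. = FALSE)
  if (any(sd < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  N <- sum(n); k <- length(n)
  gm <- sum(n * mean) / N
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  groups <- data.frame(n = n, mean = mean, sd = sd)
  mt_anova(groups, ssb, ssw, k - 1L, N - k, degenerate = ssw == 0)
}

#' One-way ANOVA from raw data
#'
#' @param groups List of numeric vectors, one per group (k >= 2, each
#'   n >= 2).
#' @return Object of class \code{mt_anova}; algebraically identical to
#'   \code{\link{anova_oneway_summary}} on the exact group summaries.
#' @export
anova_oneway_raw <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of at least two numeric vectors",
         call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  anova_oneway_summary(n = vapply(groups, length, 0L),
                       mean = vapply(groups, mean, 0),
                       sd = vapply(groups, stats::sd, 0))
}

#' Dunnett's two-tailed many-to-one comparisons
#'
#' Compares each treatment group to a single shared control with
#' t_i = (m_i - m_0) / sqrt(MSE (1/n_i + 1/n_0)), MSE pooled over all
#' groups (df = N - k). Family-wise adjusted two-tailed p-values
#' p_i = P(max_j |T_j| >= |t_i|) are estimated under the joint null by
#' Monte Carlo using the shared-control construction
#' T_j = (Z_j - Z_0) / (S sqrt(1/n_j + 1/n_0)) with Z_j ~ N(0, 1/n_j) and
#' S^2 ~ chi^2_df / df, which realises the equicorrelated multivariate t
#' with rho_ij = sqrt(lambda_i lambda_j), lambda_i = n_i/(n_i + n_0), and
#' handles unbalanced designs naturally.
#'
#' @param groups List of numeric vectors (k >= 2 including the control).
#' @param control_index Index of the control group within \code{groups}.
#' @param mc_replicates Monte Carlo replicates (minimum 1e5).
#' @param seed Seed recorded and used for the simulation.
#' @return Object of class \code{mt_dunnett}: a comparison table with t
#'   statistics, adjusted p-values and their Monte Carlo standard errors,
#'   plus the pooled MSE, degrees of freedom, correlation structure and
#'   seed.
#' @export
dunnett_two_tailed <- function(groups, control_index = 1L,
                               mc_replicates = 1e5, seed = 1L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of at least two numeric vectors",
         call. = FALSE)
  if (mc_replicates < 1e5)
    stop("mc_replicates must be at least 1e5", call. = FALSE)
  ns <- vapply(groups, length, 0L)
  if (ns[control_index] < 2L)
    stop("control group needs n >= 2", call. = FALSE)
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)
  k <- length(groups); N <- sum(ns); df <- N - k
  means <- vapply(groups, mean, 0)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  mse <- ssw / df
  trt <- setdiff(seq_len(k), control_index)
  n0 <- ns[control_index]
  tstat <- (means[trt] - means[control_index]) /
    sqrt(mse * (1 / ns[trt] + 1 / n0))
  lambda <- ns[trt] / (ns[trt] + n0)
  rho <- sqrt(outer(lambda, lambda)); diag(rho) <- 1
  res <- with_local_seed(seed, {
    z0 <- stats::rnorm(mc_replicates, sd = sqrt(1 / n0))
    s <- sqrt(stats::rchisq(mc_replicates, df) / df)
    maxabs <- rep(-Inf, mc_replicates)
    for (j in seq_along(trt)) {
      zj <- stats::rnorm(mc_replicates, sd = sqrt(1 / ns[trt[j]]))
      tj <- abs(zj - z0) / (s * sqrt(1 / ns[trt[j]] + 1 / n0))
      maxabs <- pmax(maxabs, tj)
    }
    p <- vapply(abs(tstat),
                function(t) (1 + sum(maxabs >= t)) / (1 + mc_replicates), 0)
    se <- sqrt(p * (1 - p) / mc_replicates)
    list(p = p, se = se)
  })
  comparisons <- data.frame(
    group = if (!is.null(names(groups))) names(groups)[trt] else trt,
    control = if (!is.null(names(groups))) names(groups)[control_index]
              else control_index,
    estimate = means[trt] - means[control_index],
    t = tstat,
    p.adjust = res$p,
    mc.std.error = res$se,
    stringsAsFactors = FALSE)
  structure(list(comparisons = comparisons, df = df, mse = mse,
                 lambda = lambda, correlation = rho,
                 method = "monte-carlo", replicates = mc_replicates,
                 seed = seed),
            class = "mt_dunnett")
}

#' @export
print.mt_dunnett <- function(x, ...) {
  cat("Dunnett many-to-one comparisons (df =", x$df,
      ", MC replicates =", x$replicates, ", seed =", x$seed, ")\n")
  print(x$comparisons, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Bonferroni correction
#'
#' Adjusted p = min(1, p * m); m may exceed the number of p-values supplied
#' (e.g. correcting a single post-hoc cell p-value for all rows tested).
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param m Number of tests, at least \code{length(pvalues)}.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(pvalues))
    stop("m must be at least the number of p-values", call. = FALSE)
  stats::p.adjust(pvalues, method = "bonferroni", n = m)
}
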