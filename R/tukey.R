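# Studentized range distribution and Tukey's HSD.
#
# The HSD machinery is implemented from first principles: the CDF of the
# studentized range Q_{k,df} is evaluated by Gauss-Legendre quadrature of the
# classical double integral
#   P(Q <= q) = int_0^inf f_s(s) * P(range of k N(0,1) <= q*s) ds
# where s ~ sqrt(chi^2_df / df) and
#   P(R <= w) = k * int phi(u) [Phi(u) - Phi(u - w)]^(k-1) du.
# It is cross-validated in the test suite against stats::ptukey and a
# permutation oracle.

# CDF of the range of k iid standard normals, vectorized over w.
normal_range_cdf <- function(w, k, nodes = 128L) {
  gl <- pracma::gaussLegendre(nodes, -9, 9)
  u <- gl$x
  phi_u <- stats::dnorm(u)
  Phi_u <- stats::pnorm(u)
  vapply(w, function(wi) {
    if (wi <= 0) return(0)
    inner <- (Phi_u - stats::pnorm(u - wi))^(k - 1)
    k * sum(gl$w * phi_u * inner)
  }, numeric(1))
}

#' Studentized range distribution function
#'
#' CDF of the studentized range of `nmeans` groups with `df` error degrees of
#' freedom, computed by numerical integration of its defining double
#' integral.
#'
#' @param q Quantile(s), the studentized range statistic.
#' @param nmeans Number of group means `k >= 2`.
#' @param df Error degrees of freedom, `> 0`.
#' @return `P(Q <= q)`, same length as `q`.
#' @export
ptukey_sr <- function(q, nmeans, df) {
  if (!is_count(nmeans) || nmeans < 2) stop_tq("topoquant_invalid_parameter", "nmeans must be an integer >= 2")
  if (!is_num1(df) || df <= 0) stop_tq("topoquant_invalid_parameter", "df must be > 0")
  # scale factor s = sqrt(chi^2_df / df): concentrated near 1 for large df
  lo <- max(0, 1 - 12 / sqrt(2 * df))
  hi <- 1 + 12 / sqrt(2 * df)
  gl <- pracma::gaussLegendre(160L, lo, hi)
  s <- gl$x
  log_fs <- (df / 2) * log(df) + (df - 1) * log(s) - df * s^2 / 2 -
    (df / 2 - 1) * log(2) - lgamma(df / 2)
  fs <- exp(log_fs)
  vapply(q, function(qi) {
    if (!is.finite(qi)) return(as.numeric(qi > 0))
    if (qi <= 0) return(0)
    min(1, sum(gl$w * fs * normal_range_cdf(qi * s, nmeans)))
  }, numeric(1))
}

# Compact letter display by insert-and-absorb: start with one letter column
# holding every group, split a column for each significantly different pair
# it contains, drop columns that became subsets of others. Guarantees that
# two groups share a letter iff no significant difference separates them.
cld_insert_absorb <- function(groups, sig_pairs) {
  cols <- list(groups)
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs$group1[r]; b <- sig_pairs$group2[r]
      nxt <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          nxt <- c(nxt, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          nxt <- c(nxt, list(col))
        }
      }
      cols <- Filter(length, nxt)
      # absorb subsets (and duplicates)
      keep <- rep(TRUE, length(cols))
      for (i in seq_along(cols)) {
        for (j in seq_along(cols)) {
          if (i == j || !keep[i] || !keep[j]) next
          if (all(cols[[i]] %in% cols[[j]]) &&
              (length(cols[[i]]) < length(cols[[j]]) || j < i)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order columns by their highest-ranked member, then assign letters
  first_pos <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first_pos)]
  lab <- if (length(cols) <= 26) letters[seq_along(cols)] else {
    as.vector(outer(letters, c("", letters), function(a, b) paste0(b, a)))[seq_along(cols)]
  }
  out <- vapply(groups, function(g) {
    paste(lab[vapply(cols, function(col) g %in% col, logical(1))], collapse = "")
  }, character(1))
  names(out) <- groups
  out
}

#' Compare groups by Tukey's HSD or a two-sample t-test
#'
#' For `method = "tukey"`, runs a one-way ANOVA, computes Tukey-Kramer
#' pairwise p-values from the studentized range distribution
#' ([ptukey_sr()]), and labels the groups with a compact letter display
#' (groups sharing a letter are not significantly different at `alpha`).
#' Groups are ordered by mean, descending; ties are broken by label. Two
#' replicates per group are accepted (with a low-replication warning), since
#' gel experiments often run n = 2. For `method = "student_t"` or
#' `"welch_t"`, exactly two groups are compared with the corresponding
#' t-test.
#'
#' @param samples Named list of numeric vectors, one per group.
#' @param method `"tukey"`, `"welch_t"`, or `"student_t"`.
#' @param alpha Significance level in (0, 1).
#' @return An object of class `"group_comparison"`: list with `groups`
#'   (data.frame `group`, `n`, `mean`, `sd`, `letters`), `pairwise`
#'   (data.frame `group1`, `group2`, `diff`, `p_adj`, `significant`),
#'   `method`, `alpha`, and for Tukey `df_error` and `mse`.
#' @examples
#' compare_groups(list(a = c(1, 1.1), b = c(2, 2.1)), method = "student_t")
#' @export
compare_groups <- function(samples, method = c("tukey", "welch_t", "student_t"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (!is.list(samples) || length(samples) < 2L) {
    stop_tq("topoquant_invalid_design_error", "need at least 2 groups")
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop_tq("topoquant_invalid_design_error", "groups must be named")
  }
  if (!is_num1(alpha) || alpha <= 0 || alpha >= 1) {
    stop_tq("topoquant_invalid_parameter", "alpha must be in (0, 1)")
  }
  ns <- lengths(samples)
  means <- vapply(samples, mean, numeric(1))
  sds <- vapply(samples, stats::sd, numeric(1))
  # order: mean descending, label ascending for ties
  ord <- order(-means, names(samples))
  samples <- samples[ord]; ns <- ns[ord]; means <- means[ord]; sds <- sds[ord]
  gnames <- names(samples)
  k <- length(samples)
  df_error <- NA_real_; mse <- NA_real_

  if (method == "tukey") {
    if (any(ns < 2)) {
      stop_tq("topoquant_insufficient_replicates_error",
              "Tukey's HSD needs n >= 2 in every group")
    }
    if (min(ns) == 2) {
      warn_tq("topoquant_low_replication_warning",
              "group(s) with only 2 replicates: Tukey's HSD has little power")
    }
    N <- sum(ns)
    df_error <- N - k
    mse <- sum((ns - 1) * sds^2) / df_error
    pairs <- utils::combn(k, 2)
    pw <- data.frame(group1 = gnames[pairs[1, ]], group2 = gnames[pairs[2, ]],
                     diff = means[pairs[1, ]] - means[pairs[2, ]],
                     p_adj = NA_real_, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(pw))) {
      i <- pairs[1, r]; j <- pairs[2, r]
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      if (se == 0) {
        pw$p_adj[r] <- if (abs(pw$diff[r]) < .Machine$double.eps^0.5) 1 else 0
      } else {
        qstat <- abs(pw$diff[r]) / se
        pw$p_adj[r] <- 1 - ptukey_sr(qstat, nmeans = k, df = df_error)
      }
    }
  } else {
    if (k != 2L) {
      stop_tq("topoquant_invalid_design_error",
              sprintf("%s compares exactly 2 groups", method))
    }
    if (any(ns < 2)) {
      stop_tq("topoquant_insufficient_replicates_error", "t-tests need n >= 2 per group")
    }
    tt <- stats::t.test(samples[[1]], samples[[2]],
                        var.equal = (method == "student_t"))
    pw <- data.frame(group1 = gnames[1], group2 = gnames[2],
                     diff = means[1] - means[2], p_adj = tt$p.value,
                     stringsAsFactors = FALSE)
    df_error <- unname(tt$parameter)
  }
  pw$significant <- pw$p_adj < alpha
  letters_out <- cld_insert_absorb(gnames, pw[pw$significant, , drop = FALSE])
  groups <- data.frame(group = gnames, n = as.integer(ns), mean = means,
                       sd = sds, letters = unname(letters_out[gnames]),
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(groups = groups, pairwise = pw, method = method,
                 alpha = alpha, df_error = df_error, mse = mse),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s, alpha = %g)\n", x$method, x$alpha))
  if (x$method == "tukey") {
    cat(sprintf("  one-way ANOVA: MSE = %.4g on %g error df\n", x$mse, x$df_error))
  }
  print(x$groups, row.names = FALSE, digits = 4)
  cat("Pairwise:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  cat("Groups sharing a letter are not significantly different.\n")
  invisible(x)
}
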