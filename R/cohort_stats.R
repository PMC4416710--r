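#' Group summary (n, mean, sd)
#'
#' @param n subjects (>= 2).
#' @param mean variable mean.
#' @param sd standard deviation (>= 0).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stopf("n must be >= 2")
  if (sd < 0) stopf("sd must be >= 0")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Two-sample t-test from printed summary statistics
#'
#' Computes the two-tailed two-sample t-test from group summaries alone
#' (the form needed to reproduce a published cohort table). `"pooled"` uses
#' the pooled-variance statistic with df = n_a + n_b - 2; `"welch"` uses
#' the Welch statistic with Satterthwaite degrees of freedom.
#'
#' @param a,b [group_summary()] objects.
#' @param variant `"pooled"` or `"welch"`.
#' @return list with `t`, `df`, `p` (two-tailed), `variant`. If both SDs are
#'   zero with equal means the test is undefined and `t`/`p` are `NA`.
#' @export
t_test_from_summary <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$sd == 0 && b$sd == 0) {
    if (a$mean == b$mean)
      return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                  variant = variant, note = "undefined: zero variance, equal means"))
    return(list(t = Inf * sign(a$mean - b$mean), df = a$n + b$n - 2, p = 0,
                variant = variant))
  }
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), variant = variant)
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square comparison of a binary trait (e.g. gender) between two
#' groups, with or without Yates continuity correction.
#'
#' @param a_yes,a_no,b_yes,b_no non-negative cell counts.
#' @param correction `"none"` or `"yates"`.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_2x2 <- function(a_yes, a_no, b_yes, b_no,
                     correction = c("none", "yates")) {
  correction <- match.arg(correction)
  counts <- c(a_yes, a_no, b_yes, b_no)
  if (any(counts < 0)) stopf("counts must be non-negative")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correction == "yates"))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Reproduce a cohort comparison table from summaries
#'
#' Takes a table of per-group summaries (one row per continuous variable,
#' columns `variable`, `n_a`, `mean_a`, `sd_a`, `n_b`, `mean_b`, `sd_b`) and
#' returns both pooled and Welch two-tailed p-values side by side, rounded
#' to 4 significant figures.
#'
#' @param tab data.frame in the layout above, or a path to such a TSV.
#' @return data.frame with `t_pooled`, `p_pooled`, `t_welch`, `p_welch`.
#' @export
cohort_table <- function(tab) {
  if (is.character(tab)) tab <- utils::read.delim(tab)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    a <- group_summary(tab$n_a[i], tab$mean_a[i], tab$sd_a[i])
    b <- group_summary(tab$n_b[i], tab$mean_b[i], tab$sd_b[i])
    tp <- t_test_from_summary(a, b, "pooled")
    tw <- t_test_from_summary(a, b, "welch")
    data.frame(variable = tab$variable[i],
               t_pooled = signif(tp$t, 4), p_pooled = signif(tp$p, 4),
               t_welch = signif(tw$t, 4), p_welch = signif(tw$p, 4))
  })
  do.call(rbind, out)
}
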