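# Treatment comparisons of FD indices (Kruskal-Wallis, Conover-Iman post hoc
# with Benjamini-Hochberg correction) and bioassay nutrient-limitation calls.

#' Kruskal-Wallis test of an index across treatments
#'
#' Rank-based H with tie correction and the chi-square approximation on
#' g - 1 degrees of freedom (delegated to [stats::kruskal.test()]); identical
#' values across all groups give H = 0, p = 1.
#'
#' @param values numeric index values.
#' @param group treatment label per value.
#' @return list with elements `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stopf("need >= 2 groups")
  if (length(unique(values)) == 1) {
    return(list(H = 0, p = 1, df = nlevels(group) - 1L))
  }
  kt <- kruskal.test(values, group)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Conover-Iman post hoc pairwise comparisons
#'
#' t statistics on the pooled (mid)ranks,
#' `t = (Rbar_i - Rbar_j) / sqrt(S^2 * (N - 1 - H) / (N - g) * (1/n_i + 1/n_j))`
#' with `S^2 = (sum R^2 - N (N+1)^2 / 4) / (N - 1)` (tie-correct through the
#' midranks), two-sided p on N - g degrees of freedom, Benjamini-Hochberg
#' adjustment across all pairs, significance flags at `alpha`.
#'
#' @param values numeric index values.
#' @param group treatment label per value.
#' @param alpha significance threshold on the adjusted p (default 0.01).
#' @return data.frame `pair, group1, group2, statistic, p_raw, p_adjusted,
#'   significant`; groups with fewer than 2 observations are skipped with a
#'   note.
#' @export
conover_iman <- function(values, group, alpha = 0.01) {
  group <- factor(group)
  if (nlevels(group) < 2) stopf("need >= 2 groups")
  small <- names(which(table(group) < 2))
  if (length(small)) {
    message("skipping groups with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !group %in% small
    values <- values[keep]
    group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2) {
    message("fewer than 2 testable groups; no pairwise comparisons")
    out <- data.frame(pair = character(0), group1 = character(0),
                      group2 = character(0), statistic = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0))
    attr(out, "alpha") <- alpha
    return(out)
  }
  r <- rank(values)
  N <- length(r)
  g <- nlevels(group)
  H <- kruskal_wallis(values, group)$H
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  pooled_var <- S2 * (N - 1 - H) / (N - g)
  rbar <- tapply(r, group, mean)
  ns <- tabulate(group)
  pairs <- utils::combn(levels(group), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- match(pr[1], levels(group)); j <- match(pr[2], levels(group))
    se <- sqrt(pooled_var * (1 / ns[i] + 1 / ns[j]))
    stat <- (rbar[[i]] - rbar[[j]]) / se
    data.frame(pair = paste(pr, collapse = " vs "),
               group1 = pr[1], group2 = pr[2], statistic = stat,
               p_raw = 2 * pt(-abs(stat), df = N - g))
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Nutrient-limitation calls from a 4-day addition bioassay
#'
#' Per-replicate growth `g = ln(day4 / day0) / 4`; nutrient X is called
#' limiting when mean g(+X) exceeds mean g(control) by a one-sided Welch
#' two-sample test at `alpha`. N+P co-limitation is called when only the
#' combined +NP contrast is significant.
#'
#' @param table data.frame with columns `treatment` (control, +N, +P, +NP),
#'   `replicate`, `day0`, `day4`; all four treatments with >= 2 replicates.
#' @param alpha one-sided test level (default 0.05).
#' @return list: `limiting` (one of "N", "P", "N+P", "none"), `calls`
#'   (data.frame `treatment, growth_mean, p, significant`).
#' @export
bioassay_limitation <- function(table, alpha = 0.05) {
  need <- c("control", "+N", "+P", "+NP")
  missing <- setdiff(need, unique(table$treatment))
  if (length(missing)) stopf("missing bioassay treatment(s): %s",
                             paste(missing, collapse = ", "))
  if (any(table$day0 <= 0)) stopf("day-0 fluorescence must be positive")
  growth <- log(table$day4 / table$day0) / 4
  by_tr <- split(growth, table$treatment)
  if (any(vapply(by_tr[need], length, integer(1)) < 2)) {
    stopf("each treatment needs >= 2 replicates")
  }
  ctrl <- by_tr[["control"]]
  test_one <- function(x) {
    if (sd(x) == 0 && sd(ctrl) == 0) {
      return(if (mean(x) > mean(ctrl)) 0 else 1)
    }
    t.test(x, ctrl, alternative = "greater")$p.value
  }
  adds <- c("+N", "+P", "+NP")
  ps <- vapply(by_tr[adds], test_one, numeric(1))
  sig <- ps < alpha
  limiting <- if (sig[["+N"]]) "N"
              else if (sig[["+P"]]) "P"
              else if (sig[["+NP"]]) "N+P"
              else "none"
  calls <- data.frame(treatment = adds,
                      growth_mean = vapply(by_tr[adds], mean, numeric(1)),
                      p = ps, significant = sig)
  rownames(calls) <- NULL
  list(limiting = limiting, calls = calls,
       control_growth = mean(ctrl))
}
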