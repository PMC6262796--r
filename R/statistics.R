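# Group-comparison layer: mean +/- s.e.m. per group, one-way ANOVA with
# Tukey HSD pairwise comparisons, or Kruskal-Wallis with Dunn post hoc
# (Holm-adjusted by default), and the printed star convention.

#' Mean and standard error of the mean
#'
#' s.e.m. is the sample standard deviation (n-1 denominator) over the square
#' root of n; with a single value it is reported as `NA`.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @return list: `n`, `mean`, `sem`.
#' @export
mean_sem <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("mean_sem needs at least one finite value")
  list(n = length(v), mean = mean(v),
       sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else
         NA_real_)
}

#' Significance stars for an (adjusted) p-value
#'
#' `*` p<0.05, `**` p<0.01, `***` p<0.001, `****` p<0.0001; `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star codes.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***" else
      if (pi < 1e-2) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

# Dunn's post-hoc z tests after Kruskal-Wallis, with tie correction
.dunn_test <- function(values, groups, adjust = "holm") {
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  k <- length(lev)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2)
  pvals <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[[i]] + 1 / ni[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    2 * stats::pnorm(-abs(z))
  })
  list(pairs = pairs, p = stats::p.adjust(pvals, method = adjust))
}

#' Compare a metric across groups
#'
#' Parametric mode: one-way ANOVA (F, p) with Tukey HSD adjusted pairwise
#' p-values. Nonparametric mode: Kruskal-Wallis (H, p) with Dunn pairwise z
#' tests, Holm-adjusted by default. `"auto"` uses the parametric path unless
#' any group fails a Shapiro-Wilk normality test at alpha = 0.05 (groups too
#' small to test, n < 3, do not trigger the switch); the decision is
#' recorded in the result. Missing values are dropped per group with the
#' drop count recorded.
#'
#' @param groups named list of numeric vectors (one per genotype/condition).
#' @param mode `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param dunn_adjust p adjustment for Dunn tests: `"holm"` (default) or
#'   `"bonferroni"`.
#' @param metric metric name carried into the result.
#' @return object of class `group_comparison`: per-group summary table
#'   (n, mean, sem), omnibus statistic and p, pairwise adjusted p matrix,
#'   stars, the mode used and why.
#' @export
group_compare <- function(groups, mode = c("auto", "parametric",
                                           "nonparametric"),
                          dunn_adjust = c("holm", "bonferroni"),
                          metric = "metric") {
  mode <- match.arg(mode)
  dunn_adjust <- match.arg(dunn_adjust)
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be named")
  }
  dropped <- vapply(groups, function(g) sum(is.na(g)), integer(1))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 1L)) {
    stop(sprintf("group '%s' has no observations",
                 names(groups)[which(sizes < 1L)[1]]))
  }

  decision <- mode
  note <- NULL
  if (mode == "auto") {
    sw_p <- vapply(groups, function(g) {
      if (length(unique(g)) < 3L || length(g) < 3L) return(NA_real_)
      stats::shapiro.test(g)$p.value
    }, numeric(1))
    nonnormal <- !is.na(sw_p) & sw_p < 0.05
    decision <- if (any(nonnormal)) "nonparametric" else "parametric"
    note <- sprintf(
      "auto mode chose %s (Shapiro-Wilk alpha=0.05; failing groups: %s)",
      decision,
      if (any(nonnormal)) paste(names(groups)[nonnormal], collapse = ", ")
      else "none")
  }

  if (decision == "parametric" && any(sizes < 2L)) {
    stop(sprintf("group '%s' has fewer than 2 values; parametric mode needs >= 2",
                 names(groups)[which(sizes < 2L)[1]]))
  }

  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups)))

  lev <- names(groups)
  pw <- matrix(NA_real_, length(lev), length(lev),
               dimnames = list(lev, lev))

  if (decision == "parametric") {
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    omnibus <- list(test = "anova", statistic = an[1, "F value"],
                    p = an[1, "Pr(>F)"], df1 = an[1, "Df"],
                    df2 = an[2, "Df"])
    tk <- stats::TukeyHSD(fit)$group
    for (nm in rownames(tk)) {
      ab <- strsplit(nm, "-", fixed = TRUE)[[1]]
      pw[ab[1], ab[2]] <- pw[ab[2], ab[1]] <- tk[nm, "p adj"]
    }
  } else {
    kw <- stats::kruskal.test(value ~ group, data = df)
    omnibus <- list(test = "kruskal", statistic = unname(kw$statistic),
                    p = kw$p.value, df1 = unname(kw$parameter), df2 = NA)
    dn <- .dunn_test(df$value, df$group, adjust = dunn_adjust)
    for (j in seq_len(ncol(dn$pairs))) {
      a <- dn$pairs[1, j]; b <- dn$pairs[2, j]
      pw[a, b] <- pw[b, a] <- dn$p[j]
    }
  }

  summ <- do.call(rbind, lapply(names(groups), function(nm) {
    ms <- mean_sem(groups[[nm]])
    data.frame(group = nm, n = ms$n, mean = ms$mean, sem = ms$sem,
               dropped_na = dropped[[nm]])
  }))

  structure(list(metric = metric, mode = decision, note = note,
                 summary = summ, omnibus = omnibus,
                 omnibus_stars = p_stars(omnibus$p), pairwise = pw,
                 pairwise_stars = structure(p_stars(pw), dim = dim(pw),
                                            dimnames = dimnames(pw))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: %s (%s mode)\n", x$metric, x$mode))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-16s n=%-3d mean=%.4g +/- %.4g (s.e.m.)\n",
                s$group[i], s$n[i], s$mean[i], s$sem[i]))
  }
  st <- if (x$omnibus$test == "anova") {
    sprintf("ANOVA F(%d,%d) = %.4g", x$omnibus$df1, x$omnibus$df2,
            x$omnibus$statistic)
  } else {
    sprintf("Kruskal-Wallis H(%d) = %.4g", x$omnibus$df1,
            x$omnibus$statistic)
  }
  cat(sprintf("  %s, p = %.4g %s\n", st, x$omnibus$p, x$omnibus_stars))
  lev <- rownames(x$pairwise)
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j > i) {
      cat(sprintf("    %s vs %s: p_adj = %.4g %s\n", lev[i], lev[j],
                  x$pairwise[i, j], x$pairwise_stars[i, j]))
    }
  }
  invisible(x)
}
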