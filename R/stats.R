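#' Lateral root density
#'
#' Number of visible lateral roots divided by the primary root length,
#' reported per centimeter (lengths are given in mm and converted
#' internally).
#'
#' @param count Lateral root count(s), nonnegative.
#' @param length_mm Primary root length(s) in millimeters, positive.
#' @return Density in roots per cm.
#' @examples
#' lateral_root_density(10, 50) # 2 roots/cm
#' @export
lateral_root_density <- function(count, length_mm) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop("domain error: primary root length must be positive", call. = FALSE)
  }
  if (any(count < 0)) stop("lateral root count must be nonnegative",
                           call. = FALSE)
  count / (length_mm / 10)
}

as_group_list <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    if (is.null(names(values))) {
      names(values) <- paste0("g", seq_along(values))
    }
    return(values)
  }
  split(values, factor(groups, levels = unique(groups)))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way decomposition, fitted via [stats::aov()].
#' Accepts either a named list of numeric samples or a value vector with a
#' grouping vector. When all observations are identical the F statistic is
#' undefined and reported as `NaN` with a flag.
#'
#' @param values Named list of numeric samples, or numeric vector.
#' @param groups Grouping vector (ignored when `values` is a list).
#' @return List of class `anova_oneway`: `f_statistic`, `p_value`, `mse`,
#'   `df_between`, `df_error`, `group_means`, `group_n`, `degenerate`.
#' @export
anova_oneway <- function(values, groups = NULL) {
  g <- as_group_list(values, groups)
  if (length(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(g) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  y <- unlist(g, use.names = FALSE)
  f <- factor(rep(names(g), lengths(g)), levels = names(g))
  if (stats::var(y) == 0) {
    out <- list(f_statistic = NaN, p_value = NaN, mse = 0,
                df_between = length(g) - 1L,
                df_error = length(y) - length(g),
                group_means = vapply(g, mean, numeric(1)),
                group_n = lengths(g), degenerate = TRUE)
    class(out) <- "anova_oneway"
    return(out)
  }
  fit <- stats::aov(y ~ f)
  tab <- summary(fit)[[1]]
  out <- list(f_statistic = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
              mse = tab$`Mean Sq`[2],
              df_between = tab$Df[1], df_error = tab$Df[2],
              group_means = vapply(g, mean, numeric(1)),
              group_n = lengths(g), degenerate = FALSE)
  class(out) <- "anova_oneway"
  out
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g, MSE = %.4g\n",
              x$df_between, x$df_error, x$f_statistic, x$p_value, x$mse))
  invisible(x)
}

#' Duncan critical value (significant studentized range)
#'
#' The studentized-range quantile at Duncan's span-dependent protection
#' level: for a span of `p` ordered means the level is
#' 1 - (1 - alpha)^(p - 1), i.e. the quantile is
#' `qtukey((1 - alpha)^(p - 1), p, df)`. At p = 2 this reduces to the
#' plain studentized-range (equivalently pooled-t) comparison at level
#' alpha.
#'
#' @param p Span width (number of ordered means covered), >= 2.
#' @param df Error degrees of freedom.
#' @param alpha Test level (default 0.05).
#' @return The critical studentized range value(s).
#' @export
duncan_q <- function(p, df, alpha = 0.05) {
  stopifnot(all(p >= 2), df >= 1, alpha > 0, alpha < 1)
  q <- suppressWarnings(
    stats::qtukey((1 - alpha)^(p - 1), nmeans = p, df = df))
  # qtukey's inversion can fail for wide spans; fall back to root-finding
  # on the (accurate) distribution function
  bad <- which(!is.finite(q))
  for (i in bad) {
    pi <- p[i]
    lvl <- (1 - alpha)^(pi - 1)
    q[i] <- stats::uniroot(function(x) {
      stats::ptukey(x, nmeans = pi, df = df) - lvl
    }, lower = 1e-6, upper = 1e3, tol = 1e-10)$root
  }
  q
}

#' Duncan's multiple range test with compact letter display
#'
#' Post-hoc comparison of all group means after a one-way ANOVA. Means are
#' sorted; a span of p consecutive ordered means is significant when its
#' range exceeds the critical range
#' \deqn{R_p = q_{p} \sqrt{MSE / n}}
#' with q_p the Duncan quantile of [duncan_q()], and — the containment
#' rule — no enclosing span is non-significant. Two groups differ exactly
#' when the span between their rank positions is significant. For
#' unbalanced groups the harmonic mean of the group sizes replaces n (a
#' warning flag is set). Letters are assigned by insert-and-absorb over the
#' maximal non-significant spans: groups sharing a letter do not differ at
#' level alpha; groups sharing none do. Ties in means are broken by group
#' label order so output is deterministic.
#'
#' @inheritParams anova_oneway
#' @param alpha Significance level (default 0.05).
#' @return List of class `duncan_mrt`: the `anova` fit, `alpha`, `means`
#'   (sorted ascending), `letters` (named by group, in input group order),
#'   `significant` (logical k x k matrix of pairwise decisions, input
#'   order), `critical_ranges`, `unbalanced`.
#' @examples
#' set.seed(1)
#' duncan_mrt(list(a = rnorm(8), b = rnorm(8) + 3, c = rnorm(8) + 3.2))
#' @export
duncan_mrt <- function(values, groups = NULL, alpha = 0.05) {
  g <- as_group_list(values, groups)
  a <- anova_oneway(g)
  k <- length(g)
  input_order <- names(g)
  if (a$degenerate) {
    letters <- stats::setNames(rep("a", k), input_order)
    sig <- matrix(FALSE, k, k, dimnames = list(input_order, input_order))
    out <- list(anova = a, alpha = alpha, means = sort(a$group_means),
                letters = letters, significant = sig,
                critical_ranges = rep(NA_real_, k - 1L),
                unbalanced = length(unique(a$group_n)) > 1L)
    class(out) <- "duncan_mrt"
    return(out)
  }
  unbalanced <- length(unique(a$group_n)) > 1L
  n_eff <- if (unbalanced) {
    warning("unbalanced group sizes: using the harmonic mean of n in the ",
            "critical range", call. = FALSE)
    k / sum(1 / a$group_n)
  } else {
    a$group_n[[1]]
  }
  # sort ascending, ties broken by group label order (stable sort)
  ord <- order(a$group_means, seq_len(k))
  means <- a$group_means[ord]
  se <- sqrt(a$mse / n_eff)
  crit <- duncan_q(2:k, a$df_error, alpha) * se # critical range per span p
  # span significance with the containment rule: process widest first
  nonsig <- matrix(FALSE, k, k) # nonsig[i, j]: span i..j (sorted order)
  diag(nonsig) <- TRUE
  for (p in k:2) {
    for (i in seq_len(k - p + 1L)) {
      j <- i + p - 1L
      enclosing_ns <- (i > 1L && nonsig[i - 1L, j]) ||
        (j < k && nonsig[i, j + 1L])
      nonsig[i, j] <- enclosing_ns ||
        (means[j] - means[i] <= crit[p - 1L])
    }
  }
  # letters: one per maximal non-significant span (insert-and-absorb)
  spans <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1L]) j <- j + 1L
    spans[[i]] <- c(i, j)
  }
  spans <- unique(spans)
  maximal <- Filter(function(s) {
    !any(vapply(spans, function(t) {
      (t[1] <= s[1] && s[2] <= t[2]) && !identical(t, s)
    }, logical(1)))
  }, spans)
  maximal <- maximal[order(vapply(maximal, `[`, numeric(1), 1L))]
  lab <- rep("", k)
  for (s in seq_along(maximal)) {
    idx <- maximal[[s]][1]:maximal[[s]][2]
    lab[idx] <- paste0(lab[idx], letters[s])
  }
  letter_out <- stats::setNames(character(k), input_order)
  letter_out[ord] <- lab
  # pairwise decision matrix in input order
  sig <- matrix(FALSE, k, k, dimnames = list(input_order, input_order))
  pos <- match(seq_len(k), ord) # rank position of each input group
  for (u in seq_len(k - 1L)) {
    for (v in (u + 1L):k) {
      i <- min(pos[u], pos[v]); j <- max(pos[u], pos[v])
      sig[u, v] <- sig[v, u] <- !nonsig[i, j]
    }
  }
  out <- list(anova = a, alpha = alpha, means = means,
              letters = letter_out, significant = sig,
              critical_ranges = stats::setNames(crit, paste0("p", 2:k)),
              unbalanced = unbalanced)
  class(out) <- "duncan_mrt"
  out
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g)\n", x$alpha))
  print(x$anova)
  ord <- names(sort(x$anova$group_means))
  df <- data.frame(group = ord,
                   mean = unname(x$anova$group_means[ord]),
                   n = unname(x$anova$group_n[ord]),
                   letters = unname(x$letters[ord]))
  print(df, row.names = FALSE)
  if (x$unbalanced) cat("note: unbalanced n, harmonic-mean correction used\n")
  invisible(x)
}

#' Pearson correlation matrices of phenotype traits
#'
#' Product-moment correlations between trait columns, overall or per
#' genotype (pooling all treatment conditions within a genotype, as when
#' stress treatments are part of the observed variation). Cells with fewer
#' than 3 complete pairs or zero variance are undefined (`NA`), not 0.
#'
#' @param table Data frame of per-seedling records.
#' @param traits Trait columns to correlate (default: the numeric columns
#'   among [phenotype_traits()] plus `lateral_root_density` if present).
#' @param by `NULL` for one overall matrix, or a grouping column name
#'   (e.g. `"genotype"`) for one matrix per group.
#' @return For `by = NULL` a correlation matrix of class `cor_matrix`
#'   (attribute `"n"` = pairwise complete counts); otherwise a named list
#'   of such matrices.
#' @export
pearson_matrix <- function(table, traits = NULL, by = NULL) {
  if (is.null(traits)) {
    traits <- intersect(c(phenotype_traits(), "lateral_root_density"),
                        names(table))
  }
  stopifnot(all(traits %in% names(table)))
  one <- function(d) {
    x <- as.matrix(d[traits])
    p <- length(traits)
    r <- matrix(NA_real_, p, p, dimnames = list(traits, traits))
    n <- matrix(0L, p, p, dimnames = list(traits, traits))
    for (i in seq_len(p)) {
      for (j in i:p) {
        ok <- stats::complete.cases(x[, c(i, j), drop = FALSE])
        n[i, j] <- n[j, i] <- sum(ok)
        if (sum(ok) >= 3L) {
          xi <- x[ok, i]; xj <- x[ok, j]
          if (stats::sd(xi) > 0 && stats::sd(xj) > 0) {
            r[i, j] <- r[j, i] <- stats::cor(xi, xj)
          } else if (i == j) {
            r[i, j] <- NA_real_ # zero variance: undefined even on diagonal
          }
        }
      }
    }
    structure(r, n = n, class = c("cor_matrix", "matrix", "array"))
  }
  if (is.null(by)) return(one(table))
  groups <- split(table, table[[by]])
  lapply(groups, one)
}

#' @export
print.cor_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlation matrix (NA = undefined)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Correlation matrix as a long-format table
#'
#' @param r A `cor_matrix` (or plain correlation matrix).
#' @param group Optional group label column value.
#' @return Data frame with columns `trait1`, `trait2`, `r` (and `group`).
#' @export
cor_long <- function(r, group = NULL) {
  traits <- rownames(r)
  idx <- which(upper.tri(r, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(trait1 = traits[idx[, 1]], trait2 = traits[idx[, 2]],
                    r = r[idx], stringsAsFactors = FALSE)
  if (!is.null(group)) out <- cbind(group = group, out)
  out
}

#' Heatmap of a correlation matrix
#'
#' Renders a correlation matrix with the conventional diverging palette
#' (blue positive, red negative, white at 0) via \pkg{pheatmap}, in the
#' orientation used for genotype-wise trait-correlation panels.
#'
#' @param r A `cor_matrix`.
#' @param main Plot title.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_cor_heatmap <- function(r, main = "trait correlations", ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("pheatmap is required for heatmap rendering", call. = FALSE)
  }
  pal <- grDevices::colorRampPalette(c("#b2182b", "white", "#2166ac"))(101)
  ph <- pheatmap::pheatmap(unclass(r), cluster_rows = FALSE,
                           cluster_cols = FALSE, breaks = seq(-1, 1,
                                                              length.out = 102),
                           color = pal, main = main, ...)
  invisible(ph)
}
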