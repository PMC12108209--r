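# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration and textbook formulas.

default_calib <- function() rogfp_calibration(0.2, 1.4, 1, 0.4)

# Bisection inversion of the forward Nernst formula (independent of the
# closed-form inverse in the package).
bisect_oxd <- function(egsh, constants = rogfp_constants(),
                       tol = 1e-12) {
  f <- function(oxd) {
    constants$midpoint_potential -
      constants$nernst_slope * log10((1 - oxd) / oxd) - egsh
  }
  lo <- 1e-15; hi <- 1 - 1e-15
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force ROI mean: explicit loop over pixels with the center-in-circle
# rule.
brute_roi_mean <- function(img, pixel_size, cx, cy, radius, background = 0) {
  vals <- c()
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      x <- (j - 0.5) * pixel_size
      y <- (i - 0.5) * pixel_size
      if ((x - cx)^2 + (y - cy)^2 <= radius^2) vals <- c(vals, img[i, j])
    }
  }
  max(mean(vals) - background, 0)
}

# Textbook one-way ANOVA from explicit sums of squares.
brute_anova <- function(g) {
  y <- unlist(g); n <- lengths(g); N <- length(y); k <- length(g)
  gm <- mean(y)
  means <- vapply(g, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((g[[i]] - means[i])^2),
                    numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
       mse = ssw / (N - k), df_error = N - k)
}

# Brute-force Duncan pairwise decisions straight from the definition: a
# pair differs iff every span enclosing it (in sorted-mean order) has a
# range exceeding its critical range. Quantiles come directly from
# ptukey/qtukey at the span protection level.
brute_duncan_pairs <- function(g, alpha = 0.05) {
  a <- brute_anova(g)
  k <- length(g)
  means <- vapply(g, mean, numeric(1))
  n <- lengths(g)
  n_eff <- if (length(unique(n)) > 1L) k / sum(1 / n) else n[[1]]
  ord <- order(means, seq_len(k))
  ms <- means[ord]
  crit <- function(p) {
    lvl <- (1 - alpha)^(p - 1)
    q <- suppressWarnings(stats::qtukey(lvl, p, a$df_error))
    if (!is.finite(q)) {
      q <- stats::uniroot(function(x) stats::ptukey(x, p, a$df_error) - lvl,
                          c(1e-6, 1e3), tol = 1e-10)$root
    }
    q * sqrt(a$mse / n_eff)
  }
  sig <- matrix(FALSE, k, k, dimnames = list(names(g), names(g)))
  for (u in seq_len(k - 1)) {
    for (v in (u + 1):k) {
      i <- min(which(ord == u), which(ord == v))
      j <- max(which(ord == u), which(ord == v))
      all_exceed <- TRUE
      for (a1 in seq_len(i)) {
        for (b1 in j:k) {
          if (ms[b1] - ms[a1] <= crit(b1 - a1 + 1)) all_exceed <- FALSE
        }
      }
      sig[u, v] <- sig[v, u] <- all_exceed
    }
  }
  sig
}

# Pairwise "not significantly different" relation implied by a compact
# letter display.
letters_to_nonsig <- function(lett) {
  k <- length(lett)
  share <- matrix(FALSE, k, k, dimnames = list(names(lett), names(lett)))
  for (u in seq_len(k)) {
    for (v in seq_len(k)) {
      lu <- strsplit(lett[u], "")[[1]]
      lv <- strsplit(lett[v], "")[[1]]
      share[u, v] <- length(intersect(lu, lv)) > 0
    }
  }
  share
}

# Center ROI covering most of a stack (mirrors the package default).
default_center_roi_for_test <- function(stack) {
  d <- dim(stack$channels[[1]])
  px <- stack$pixel_size_um
  circular_roi(d[2] / 2 * px, d[1] / 2 * px, min(d) / 2 * px * 0.9)
}

# Small random Duncan instance with k groups.
random_groups <- function(k, n_range = c(4L, 9L), spread = 2) {
  n <- sample(seq(n_range[1], n_range[2]), k, replace = TRUE)
  stats::setNames(lapply(seq_len(k), function(i) {
    stats::rnorm(n[i], mean = stats::runif(1, 0, spread))
  }), paste0("g", seq_len(k)))
}
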