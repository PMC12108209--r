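test_that("lateral root density converts mm to cm and checks domains", {
  expect_equal(lateral_root_density(10, 50), 2)
  expect_equal(lateral_root_density(0, 33), 0)
  expect_equal(lateral_root_density(20, 100), lateral_root_density(10, 50))
  expect_error(lateral_root_density(3, 0), "domain error")
  expect_error(lateral_root_density(-1, 10), "nonnegative")
})

test_that("one-way ANOVA matches a sums-of-squares oracle", {
  # identical samples in both groups: no between-group variation
  g0 <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(anova_oneway(g0)$f_statistic, 0)
  # near-separated groups: p approaches 0
  g1 <- list(a = c(0, 0, 0) + c(1e-9, -1e-9, 0),
             b = c(1, 1, 1) + c(1e-9, -1e-9, 0))
  expect_lt(anova_oneway(g1)$p_value, 1e-12)
  # textbook 3-group case against brute-force sums of squares
  g <- list(a = c(6, 8, 4, 5, 3, 4), b = c(8, 12, 9, 11, 6, 8),
            c = c(13, 9, 11, 8, 7, 12))
  got <- anova_oneway(g)
  want <- brute_anova(g)
  expect_equal(got$f_statistic, want$f)
  expect_equal(got$p_value, want$p)
  expect_equal(got$mse, want$mse)
  expect_equal(got$df_error, want$df_error)
  # degenerate: all values identical
  dg <- anova_oneway(list(a = c(2, 2), b = c(2, 2)))
  expect_true(dg$degenerate && is.nan(dg$f_statistic))
})

test_that("Duncan quantiles match published table values", {
  # significant studentized range, alpha = 0.05 (3-decimal table values)
  published <- rbind(
    c(df = 10, p = 2, q = 3.151), c(df = 10, p = 3, q = 3.293),
    c(df = 10, p = 4, q = 3.376), c(df = 10, p = 5, q = 3.430),
    c(df = 20, p = 2, q = 2.950), c(df = 20, p = 3, q = 3.097),
    c(df = 20, p = 4, q = 3.190), c(df = 20, p = 5, q = 3.255))
  for (i in seq_len(nrow(published))) {
    expect_equal(duncan_q(published[i, "p"], published[i, "df"]),
                 published[i, "q"], tolerance = 0.001,
                 ignore_attr = TRUE)
  }
  # p = 2 uses the plain alpha-level studentized range (no protection)
  expect_equal(duncan_q(2, 15), stats::qtukey(0.95, 2, 15))
  # the root-finding fallback agrees with qtukey where both work
  expect_equal(duncan_q(3, 30), stats::qtukey(0.95^2, 3, 30),
               tolerance = 1e-6)
})

test_that("groups from one distribution usually share a letter", {
  # Duncan protects each span at 1-(1-alpha)^(p-1); with k = 3 null groups
  # the familywise error is ~10%, so most seeded null draws give one letter
  same <- vapply(1:20, function(s) {
    set.seed(s)
    d <- duncan_mrt(list(a = rnorm(8), b = rnorm(8), c = rnorm(8)))
    length(unique(d$letters)) == 1L
  }, logical(1))
  expect_gt(mean(same), 0.6)
})

test_that("two-group Duncan reduces to the pooled t-test decision", {
  set.seed(77)
  for (i in 1:25) {
    a <- rnorm(6, 0)
    b <- rnorm(6, runif(1, 0, 1.5))
    d <- duncan_mrt(list(a = a, b = b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_identical(unname(d$significant["a", "b"]),
                     unname(tt$p.value <= 0.05))
  }
})

test_that("well-separated groups get all-distinct letters", {
  set.seed(5)
  g <- lapply(c(0, 10, 20, 30), function(m) rnorm(8, m))
  names(g) <- letters[1:4]
  d <- duncan_mrt(g)
  expect_equal(sort(unname(d$letters)), c("a", "b", "c", "d"))
  expect_true(all(d$significant[upper.tri(d$significant)]))
})

test_that("pairwise decisions match the brute-force span oracle", {
  set.seed(123)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    g <- random_groups(k)
    d <- suppressWarnings(duncan_mrt(g))
    want <- brute_duncan_pairs(g)
    expect_identical(d$significant, want)
    # letter display encodes exactly the non-significant pairs
    share <- letters_to_nonsig(d$letters)
    for (u in seq_len(k - 1)) {
      for (v in (u + 1):k) {
        expect_identical(unname(share[u, v]), unname(!want[u, v]))
      }
    }
  }
})

test_that("unbalanced groups use the harmonic mean and warn", {
  set.seed(9)
  g <- list(a = rnorm(4), b = rnorm(9, 3), c = rnorm(6, 3.1))
  expect_warning(d <- duncan_mrt(g), "harmonic")
  expect_true(d$unbalanced)
  expect_identical(d$significant, brute_duncan_pairs(g))
})

test_that("identically drawn groups share one letter when means tie", {
  d <- duncan_mrt(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                       c = c(1, 2, 3, 4)))
  expect_equal(unname(d$letters), rep("a", 3))
})

test_that("pearson_matrix handles exact, degenerate and grouped cases", {
  x <- c(1, 2, 3, 4, 5)
  tab <- data.frame(genotype = "wt", root_ros = x, shoot_ros = -x,
                    root_vitality = x * 2)
  r <- pearson_matrix(tab, traits = c("root_ros", "shoot_ros",
                                      "root_vitality"))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(unname(r["root_ros", "shoot_ros"]), -1)
  expect_equal(unname(r["root_ros", "root_vitality"]), 1)
  expect_identical(r, t(r) |> structure(n = attr(r, "n"),
                                        class = class(r)))
  # zero variance -> undefined, not 0
  tab$flat <- 5
  r2 <- pearson_matrix(tab, traits = c("root_ros", "flat"))
  expect_true(is.na(r2["root_ros", "flat"]))
  expect_true(is.na(r2["flat", "flat"]))
  # insufficient n -> undefined
  r3 <- pearson_matrix(tab[1:2, ], traits = c("root_ros", "shoot_ros"))
  expect_true(is.na(r3["root_ros", "shoot_ros"]))
  # per-genotype grouping returns one matrix per genotype
  tab2 <- rbind(tab, transform(tab, genotype = "mut"))
  rs <- pearson_matrix(tab2, traits = c("root_ros", "shoot_ros"),
                       by = "genotype")
  expect_setequal(names(rs), c("wt", "mut"))
  # long format covers each unordered pair once
  lng <- cor_long(r, group = "wt")
  expect_equal(nrow(lng), 6L)
  expect_true(all(lng$group == "wt"))
})
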