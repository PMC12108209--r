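#' Trait names used by the phenotype simulator and reports
#' @return Character vector of the seven simulated seedling traits.
#' @export
phenotype_traits <- function() {
  c("root_superoxide", "root_ros", "shoot_ros",
    "root_vitality", "shoot_vitality",
    "primary_root_length", "lateral_root_count")
}

#' Correlation matrix from factor loadings
#'
#' Builds a trait correlation matrix from a loadings matrix L (traits x
#' factors) as L L' + diag(1 - rowSums(L^2)), which is positive
#' semidefinite by construction with unit diagonal. Row sums of squared
#' loadings must not exceed 1.
#'
#' @param loadings Numeric matrix, rows named by trait.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
factor_correlation <- function(loadings) {
  stopifnot(is.matrix(loadings), !is.null(rownames(loadings)))
  u <- 1 - rowSums(loadings^2)
  if (any(u < 0)) stop("squared loadings exceed 1", call. = FALSE)
  r <- loadings %*% t(loadings) + diag(u, nrow(loadings))
  dimnames(r) <- list(rownames(loadings), rownames(loadings))
  r
}

check_correlation <- function(r, traits) {
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-10)) ||
      any(abs(diag(r) - 1) > 1e-10)) {
    stop("spec error: correlation matrix must be symmetric with unit ",
         "diagonal", call. = FALSE)
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("spec error: correlation matrix is not positive semidefinite",
         call. = FALSE)
  }
  if (!setequal(rownames(r), traits)) {
    stop("spec error: correlation matrix traits do not match", call. = FALSE)
  }
  r[traits, traits]
}

#' Specification for the multi-genotype phenotype simulation
#'
#' Per genotype x treatment group, trait vectors are drawn from a
#' multivariate normal with the genotype's target correlation matrix
#' (Gaussian copula for the lateral-root count, which is rounded and
#' floored at 0). Group means are `means[[genotype]][[treatment]]`, a named
#' vector over [phenotype_traits()]; `correlations` is either one matrix
#' for all genotypes or a named list per genotype. A non-positive-
#' semidefinite correlation is an error — it is never silently repaired.
#'
#' @param genotypes,treatments Group labels.
#' @param means Nested list `means[[genotype]][[treatment]]` of named trait
#'   means (intensity traits on the percent-of-control scale, primary root
#'   length in mm, lateral roots as counts).
#' @param sds Named vector of trait standard deviations (same units).
#' @param correlations Correlation matrix, or named list of matrices per
#'   genotype.
#' @param n_per_group Seedlings per genotype x treatment group (default 45).
#' @param seed Integer seed.
#' @return An object of class `phenotype_sim_spec`.
#' @export
phenotype_sim_spec <- function(genotypes, treatments, means, sds,
                               correlations, n_per_group = 45L, seed = 1L) {
  traits <- phenotype_traits()
  stopifnot(n_per_group >= 2L, all(sds[traits] > 0))
  if (is.matrix(correlations)) {
    correlations <- stats::setNames(
      rep(list(correlations), length(genotypes)), genotypes)
  }
  correlations <- lapply(correlations, check_correlation, traits = traits)
  for (g in genotypes) {
    if (is.null(correlations[[g]])) {
      stop("spec error: no correlation matrix for genotype ", g,
           call. = FALSE)
    }
    for (tr in treatments) {
      m <- means[[g]][[tr]]
      if (is.null(m) || !all(traits %in% names(m))) {
        stop("spec error: missing means for ", g, " / ", tr, call. = FALSE)
      }
    }
  }
  structure(list(genotypes = genotypes, treatments = treatments,
                 means = means, sds = sds[traits],
                 correlations = correlations,
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "phenotype_sim_spec")
}

#' Simulation preset mirroring the glutathione-peroxidase mutant study design
#'
#' Nine genotypes (wild type Col-0 and the gpxl1-8 mutants), five
#' treatments (control, 50/100 mM NaCl, 100/200 mM mannitol), default 45
#' seedlings per group. Treatment effects encode the qualitative pattern of
#' long-term salt/osmotic stress on seedlings: superoxide and total ROS
#' rise (by tens of percent up to ~2x), vitality falls (down to ~30% of
#' control at 100 mM NaCl), mild NaCl promotes and stronger stress inhibits
#' primary root growth. Genotype effects encode elevated shoot ROS in all
#' mutants, elevated root superoxide in a subset, and altered root
#' architecture in another subset. Trait correlations come from a
#' two-factor model (an oxidative-load factor and a vigor factor): shoot
#' and root vitality strongly positively correlated, ROS negatively
#' correlated with vitality, and shoot ROS negatively coupled to lateral
#' rooting — with that ROS-lateral-root coupling removed in gpxl1/5/7 and
#' strengthened in gpxl4/6/8. Effect sizes are illustrative presets, not
#' fitted values.
#'
#' @param n_per_group Seedlings per group (default 45).
#' @param seed Integer seed.
#' @return A [phenotype_sim_spec()].
#' @export
phenotype_preset_gpxl <- function(n_per_group = 45L, seed = 1L) {
  traits <- phenotype_traits()
  genotypes <- c("Col-0", paste0("gpxl", 1:8))
  treatments <- c("control", "NaCl50", "NaCl100",
                  "mannitol100", "mannitol200")
  base <- c(root_superoxide = 100, root_ros = 100, shoot_ros = 100,
            root_vitality = 100, shoot_vitality = 100,
            primary_root_length = 60, lateral_root_count = 12)
  # treatment multipliers per trait
  tmult <- list(
    control     = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    NaCl50      = c(1.37, 1.55, 1.56, 0.74, 0.80, 1.10, 1.00),
    NaCl100     = c(1.59, 1.39, 2.27, 0.29, 0.60, 0.80, 0.90),
    mannitol100 = c(1.00, 1.35, 1.80, 0.45, 0.66, 0.85, 0.80),
    mannitol200 = c(1.50, 1.35, 1.80, 0.30, 0.54, 0.70, 0.70))
  tmult <- lapply(tmult, stats::setNames, traits)
  # genotype multipliers (relative to Col-0 under the same treatment)
  gmult <- stats::setNames(rep(list(stats::setNames(rep(1, 7), traits)),
                               length(genotypes)), genotypes)
  for (g in paste0("gpxl", 1:8)) gmult[[g]]["shoot_ros"] <- 1.30
  for (g in paste0("gpxl", c(3:8))) gmult[[g]]["shoot_vitality"] <- 0.85
  for (g in paste0("gpxl", c(2, 3, 4, 5, 7))) {
    gmult[[g]]["root_superoxide"] <- 1.40
  }
  for (g in paste0("gpxl", c(1, 3))) {
    gmult[[g]]["primary_root_length"] <- 0.85
  }
  for (g in paste0("gpxl", c(4, 6, 8))) {
    gmult[[g]]["primary_root_length"] <- 1.15
  }
  for (g in paste0("gpxl", c(5, 6, 8))) {
    gmult[[g]]["lateral_root_count"] <- 1.25
  }
  means <- lapply(genotypes, function(g) {
    stats::setNames(lapply(treatments, function(tr) {
      base * tmult[[tr]] * gmult[[g]]
    }), treatments)
  })
  names(means) <- genotypes
  sds <- c(root_superoxide = 18, root_ros = 18, shoot_ros = 18,
           root_vitality = 15, shoot_vitality = 15,
           primary_root_length = 8, lateral_root_count = 3.5)
  loadings <- function(lr_load) {
    # columns: oxidative-load factor, vigor factor
    rbind(root_superoxide     = c(0.60,  0.00),
          root_ros            = c(0.75, -0.15),
          shoot_ros           = c(0.75, -0.15),
          root_vitality       = c(-0.50, 0.75),
          shoot_vitality      = c(-0.50, 0.75),
          primary_root_length = c(-0.20, 0.40),
          lateral_root_count  = c(lr_load, 0.30))
  }
  cors <- lapply(genotypes, function(g) {
    lr <- if (g %in% paste0("gpxl", c(1, 5, 7))) 0 else
      if (g %in% paste0("gpxl", c(4, 6, 8))) -0.65 else -0.45
    factor_correlation(loadings(lr))
  })
  names(cors) <- genotypes
  phenotype_sim_spec(genotypes, treatments, means, sds, cors,
                     n_per_group = n_per_group, seed = seed)
}

#' Generate a seeded multi-genotype phenotype table
#'
#' Draws, per genotype x treatment group, `n_per_group` seedlings from a
#' multivariate normal with the genotype's trait correlation matrix (via
#' the Cholesky factor) shifted/scaled to the group means and trait sds.
#' The lateral-root count is a rounded Gaussian copula draw floored at 0;
#' the primary root length is floored at 1 mm (a surviving seedling has a
#' measurable root). Identical seeds give bit-identical tables.
#'
#' @param spec A [phenotype_sim_spec()].
#' @param path Optional CSV path; when given the table is written with a
#'   seed-bearing header comment.
#' @return Data frame with columns `genotype`, `treatment`, `replicate` and
#'   the seven traits of [phenotype_traits()].
#' @export
generate_phenotype_table <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "phenotype_sim_spec"))
  traits <- phenotype_traits()
  set.seed(spec$seed)
  rows <- list()
  for (g in spec$genotypes) {
    cf <- chol(spec$correlations[[g]] +
                 diag(1e-12, length(traits))) # guard exact semidefiniteness
    for (tr in spec$treatments) {
      z <- matrix(stats::rnorm(spec$n_per_group * length(traits)),
                  spec$n_per_group) %*% cf
      colnames(z) <- traits
      mu <- spec$means[[g]][[tr]][traits]
      x <- sweep(sweep(z, 2L, spec$sds[traits], `*`), 2L, mu, `+`)
      x[, "lateral_root_count"] <- pmax(round(x[, "lateral_root_count"]), 0)
      x[, "primary_root_length"] <- pmax(x[, "primary_root_length"], 1)
      for (v in c("root_superoxide", "root_ros", "shoot_ros",
                  "root_vitality", "shoot_vitality")) {
        x[, v] <- pmax(x[, v], 0)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, treatment = tr, replicate = seq_len(spec$n_per_group),
        x, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) write_table_csv(out, path, seed = spec$seed)
  out
}
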