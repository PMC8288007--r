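big_cohort <- function(n_per_site = 100L, seed = 21L) {
  simulate_cohort(cohort_config(
    n_seep = n_per_site, n_control = n_per_site,
    sex_split = list(control = c(F = n_per_site %/% 2L,
                                 M = n_per_site - n_per_site %/% 2L),
                     seep = c(F = n_per_site %/% 2L,
                              M = n_per_site - n_per_site %/% 2L)),
    seed = seed))
}

test_that("size factors are median-of-ratios with its exact small cases", {
  m <- matrix(c(2L, 2L, 4L, 4L), 2L, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(size_factors(m), c(a = 1 / sqrt(2), b = sqrt(2)))
  ident <- matrix(c(5L, 8L, 5L, 8L), 2L, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(size_factors(ident), c(a = 1, b = 1))
  ## scaling one column by c multiplies its factor by c relative to the rest
  ## (the geometric-mean reference absorbs a global constant)
  sim <- simulate_counts(fixture_cohort(),
                         gene_effects(paste0("g", 1:50), 200), seed = 1L)
  sf <- size_factors(sim$counts)
  scaled <- sim$counts
  scaled[, 3L] <- scaled[, 3L] * 5L
  sf2 <- size_factors(scaled)
  expect_equal(unname(sf2[3L] / sf2[1L]), unname(5 * sf[3L] / sf[1L]),
               tolerance = 1e-12)
  zeroy <- matrix(c(0L, 1L, 3L, 0L), 2L)
  expect_error(size_factors(zeroy), "all-positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_counts(fixture_cohort(),
                         gene_effects(paste0("g", 1:100), 150), seed = 2L)
  ours <- size_factors(sim$counts)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("NB GLM hits the Poisson oracle as dispersion vanishes", {
  cohort <- fixture_cohort()
  dm <- design_matrices(cohort)
  set.seed(31)
  y <- rpois(20L, exp(4 + 0.8 * dm$full[, "ph"]))
  off <- rnorm(20L, 0, 0.1)
  ours <- fit_nb_glm(y, dm$full, dispersion = 1e-12, offset = off)
  pois <- glm(y ~ dm$full - 1 + offset(off), family = poisson())
  expect_lt(max(abs(ours$beta - coef(pois))), 1e-6)
  expect_equal(ours$loglik, as.numeric(logLik(pois)), tolerance = 1e-8)
})

test_that("NB GLM at fixed dispersion matches an independent NB fitter", {
  skip_if_not_installed("MASS")
  cohort <- fixture_cohort()
  dm <- design_matrices(cohort)
  set.seed(32)
  y <- rnbinom(20L, mu = exp(4 + dm$full[, "ph"]), size = 1 / 0.3)
  ours <- fit_nb_glm(y, dm$full, dispersion = 0.3)
  ref <- glm(y ~ dm$full - 1, family = MASS::negative.binomial(theta = 1 / 0.3),
             control = glm.control(epsilon = 1e-12))
  expect_lt(max(abs(ours$beta - coef(ref))), 1e-6)
})

test_that("constant counts give the saturated intercept and closed-form loglik", {
  y <- rep(7L, 12L)
  fit <- fit_nb_glm(y, matrix(1, 12L, 1L), dispersion = 0.2)
  expect_equal(unname(fit$beta), log(7), tolerance = 1e-8)
  expect_equal(fit$loglik, sum(dnbinom(y, mu = 7, size = 5, log = TRUE)),
               tolerance = 1e-8)
})

test_that("the pH coefficient is recovered within sampling error", {
  cohort <- big_cohort()
  eff <- gene_effects("g1", baseline_mean = 80, dispersion = 0.3,
                      log2fc_ph = 1.5)
  sim <- simulate_counts(cohort, eff, seed = 33L)
  dm <- design_matrices(cohort)
  sf <- exp(log(sim$truth$depth_factors))
  fit <- fit_nb_glm(sim$counts[1L, ], dm$full, dispersion = 0.3,
                    offset = log(sf))
  expect_lt(abs(fit$beta[["ph"]] - 1.5 * log(2)), 3 * fit$se[["ph"]])
})

test_that("dispersion estimation brackets the truth", {
  x <- cbind(1, rep(0:1, each = 50L))
  ## Poisson data: small estimates nearly always
  small <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    estimate_dispersion(rpois(100L, 60), x)
  }, 0)
  expect_gte(mean(small <= 0.05), 0.95)
  ## alpha = 0.8 recovered in the right range
  x2 <- cbind(1, rep(0:1, each = 100L))
  est <- vapply(1:100, function(s) {
    set.seed(2000 + s)
    estimate_dispersion(rnbinom(200L, mu = 60, size = 1 / 0.8), x2)
  }, 0)
  expect_gt(median(est), 0.6)
  expect_lt(median(est), 1.0)
  expect_equal(estimate_dispersion(rep(0L, 20L), cbind(1, rep(0:1, 10L))),
               1e-8)
})

test_that("the pH LRT behaves on degenerate and scaled inputs", {
  cohort <- fixture_cohort()
  counts <- matrix(50L, 3L, 20L,
                   dimnames = list(c("c1", "c2", "c3"), cohort$individual_id))
  sf <- setNames(rep(1, 20L), cohort$individual_id)
  res <- lrt_ph(counts, cohort, sf)
  expect_equal(res$lrt_stat, rep(0, 3L), tolerance = 1e-6)
  expect_equal(res$p_value, rep(1, 3L), tolerance = 1e-6)
  ## statistic invariant to a global rescaling of size factors
  sim <- simulate_counts(cohort, gene_effects(paste0("g", 1:5), 100,
                                              log2fc_ph = 1), seed = 34L)
  r1 <- lrt_ph(sim$counts, cohort, size_factors(sim$counts))
  r2 <- lrt_ph(sim$counts, cohort, size_factors(sim$counts) * 7)
  expect_equal(r1$lrt_stat, r2$lrt_stat, tolerance = 1e-5)
  ## BH adjustment is monotone in p and bounded by 1
  ord <- order(r1$p_value)
  expect_true(all(diff(r1$adj_p[ord]) >= -1e-12))
  expect_true(all(r1$adj_p <= 1))
  expect_true(all(r1$adj_p >= r1$p_value - 1e-12))
})

test_that("Wald contrasts detect strong sex bias and ignore constants", {
  hits <- vapply(1:50, function(seed) {
    cohort <- simulate_cohort(cohort_config(seed = seed))
    eff <- gene_effects("g1", baseline_mean = 100, dispersion = 0.2,
                        log2fc_sex = 3)  # 8-fold male excess
    sim <- simulate_counts(cohort, eff, seed = seed)
    w <- wald_contrasts(sim$counts, cohort,
                        setNames(rep(1, 20L), cohort$individual_id))
    w$wald_p_sex < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  cohort <- fixture_cohort()
  const <- matrix(9L, 1L, 20L, dimnames = list("g1", cohort$individual_id))
  w <- wald_contrasts(const, cohort, setNames(rep(1, 20L), cohort$individual_id))
  expect_equal(w$wald_p_sex, 1)
  expect_equal(w$wald_p_ph, 1)
})

test_that("cohort-level ANCOVA reacts to a global seep shift only when present", {
  ## power: doubling every seep individual's counts
  sig <- vapply(1:20, function(seed) {
    cohort <- simulate_cohort(cohort_config(seed = seed))
    sim <- simulate_counts(cohort, gene_effects(paste0("g", 1:40), 200,
                                                dispersion = 0.1),
                           seed = seed)
    counts <- sim$counts
    counts[, cohort$site == "seep"] <- counts[, cohort$site == "seep"] * 2L
    ot <- overall_expression_tests(counts, cohort,
                                   sf = sim$truth$depth_factors)
    ot$ancova$p_value[ot$ancova$term == "ph"] < 0.01
  }, TRUE)
  expect_gte(mean(sig), 0.95)
  ## type-I error near nominal under the null (plain OLS on means)
  fp <- vapply(1:300, function(seed) {
    cohort <- simulate_cohort(cohort_config(seed = 5000L + seed))
    sim <- simulate_counts(cohort, gene_effects(paste0("g", 1:30), 200,
                                                dispersion = 0.2),
                           seed = seed)
    ot <- overall_expression_tests(sim$counts, cohort,
                                   sf = sim$truth$depth_factors)
    ot$ancova$p_value[ot$ancova$term == "ph"] < 0.05
  }, TRUE)
  expect_lt(abs(mean(fp) - 0.05), 0.04)
  ## shifting all body lengths by a constant changes no F statistic
  cohort <- fixture_cohort()
  sim <- simulate_counts(cohort, gene_effects(paste0("g", 1:30), 150),
                         seed = 35L)
  base <- overall_expression_tests(sim$counts, cohort)
  shifted_cohort <- transform(cohort, body_length_mm = body_length_mm + 40)
  shifted <- overall_expression_tests(sim$counts, shifted_cohort)
  expect_equal(base$ancova$f_value, shifted$ancova$f_value, tolerance = 1e-10)
  ## empty gene sets are skipped with a warning
  expect_warning(
    overall_expression_tests(sim$counts, cohort,
                             gene_sets = list(none = "absent_gene")),
    "empty")
})
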