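test_that("kinship matches hand matrix algebra and Gram-matrix properties", {
  dos <- rbind(c(0, 0, 1, 1), c(1, 1, 0, 0), c(0, 1, 0, 1))
  g <- tiny_genotypes(dos)
  K <- kinship_matrix(g)
  # hand computation: column means (1/3, 2/3, 1/3, 2/3); K = Xc Xc' / 4
  expect_equal(K[1, 1], 5 / 18, tolerance = 1e-12)
  expect_equal(K[2, 2], 5 / 18, tolerance = 1e-12)
  expect_equal(K[3, 3], 1 / 9, tolerance = 1e-12)
  expect_equal(K[1, 2], -2 / 9, tolerance = 1e-12)
  expect_equal(K[1, 3], -1 / 18, tolerance = 1e-12)
  expect_equal(K[2, 3], -1 / 18, tolerance = 1e-12)

  # clones: off-diagonal equals the diagonal entries
  g2 <- tiny_genotypes(rbind(c(0, 1, 0, 1), c(0, 1, 0, 1), c(1, 0, 1, 0)))
  K2 <- kinship_matrix(g2)
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)

  # random matrices: symmetric PSD
  set.seed(6)
  for (i in 1:5) {
    gr <- tiny_genotypes(matrix(rbinom(8 * 30, 1, 0.5), 8, 30))
    Kr <- kinship_matrix(gr)
    expect_lt(max(abs(Kr - t(Kr))), 1e-12)
    expect_gte(min(eigen(Kr, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  expect_error(kinship_matrix(tiny_genotypes(matrix(1, 3, 4))), "polymorphic")
})

test_that("mixed-model fit with fixed delta matches an explicit GLS oracle", {
  set.seed(61)
  n <- 12
  dos <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
  g <- tiny_genotypes(dos)
  K <- unclass(kinship_matrix(g))
  y <- rnorm(n) + dos[, 3]
  X <- cbind(1, rnorm(n), dos[, 3])
  delta <- 0.7

  eig <- eigen(K, symmetric = TRUE)
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  fit <- epiclock:::lmm_profile(log(delta), yt, Xt, pmax(eig$values, 0))
  sg2 <- fit$rss / (n - ncol(X))
  se <- sqrt(diag(chol2inv(chol(fit$XtX))) * sg2)

  # oracle: explicit inversion of V = K + delta I
  V <- K + delta * diag(n)
  Vi <- solve(V)
  bh <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% bh
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - ncol(X))
  se_o <- sqrt(diag(solve(t(X) %*% Vi %*% X)) * s2)
  expect_equal(as.numeric(fit$beta), as.numeric(bh), tolerance = 1e-8)
  expect_equal(as.numeric(se), as.numeric(se_o), tolerance = 1e-8)
})

test_that("with zero kinship the scan reduces exactly to per-marker OLS", {
  set.seed(62)
  n_strain <- 30
  dos <- matrix(rbinom(n_strain * 20, 1, 0.5), n_strain, 20)
  g <- tiny_genotypes(dos)
  sid <- g$strain_ids
  K0 <- matrix(0, n_strain, n_strain, dimnames = list(sid, sid))
  class(K0) <- c("kinship", class(K0))
  y <- setNames(rnorm(n_strain), sid)
  covar <- cbind(x1 = rnorm(n_strain))
  sc <- lmm_scan(y, covar, g, K0, strain_ids = sid, maf_min = 0)
  for (j in sample(20, 5)) {
    ols <- summary(lm(y ~ covar + dos[, j]))$coefficients
    expect_equal(sc$p[j], ols[3, 4], tolerance = 1e-6)
    expect_equal(sc$beta[j], ols[3, 1], tolerance = 1e-6)
  }
})

test_that("scan skips low-MAF markers and is invariant to trait rescaling", {
  set.seed(63)
  n_strain <- 25
  dos <- cbind(matrix(rbinom(n_strain * 10, 1, 0.5), n_strain, 10),
               c(1, rep(0, n_strain - 1)))  # MAF 1/25 < 0.05
  g <- tiny_genotypes(dos)
  K <- kinship_matrix(g)
  y <- setNames(rnorm(n_strain), g$strain_ids)
  sc <- lmm_scan(y, NULL, g, K, strain_ids = g$strain_ids)
  expect_true(sc$skipped[11])
  expect_true(is.na(sc$p[11]))
  sc2 <- lmm_scan(setNames(3.2 * y + 7, names(y)), NULL, g, K,
                  strain_ids = g$strain_ids)
  expect_equal(sc$p[!sc$skipped], sc2$p[!sc2$skipped], tolerance = 1e-8)
})

test_that("null-trait scan p-values are uniform under polygenic background", {
  set.seed(64)
  # 2 markers per chromosome at 1000 cM: R = 0.5, so markers are mutually
  # independent and the KS reference distribution applies. The null trait
  # carries the model's own covariance (u ~ N(0, sg2 K)) with no marker
  # effect: the kinship correction must keep the tests calibrated.
  cfg <- sim_config(n_strains = 40, replicates_per_strain = 2,
                    n_markers = 2000, n_chromosomes = 1000,
                    chromosome_length_cM = 1000, seed = 65)
  g <- simulate_ri_genotypes(cfg)
  strain_of <- rep(g$strain_ids, each = 2)
  K <- kinship_matrix(g)
  Ks <- K[strain_of, strain_of]
  eig <- eigen(Ks, symmetric = TRUE)
  u <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * rnorm(80))
  y <- setNames(as.numeric(u) + rnorm(80, 0, 0.7), sprintf("s%d", 1:80))
  sc <- lmm_scan(y, NULL, g, K, strain_ids = strain_of, mode = "null-delta")
  ks <- suppressWarnings(ks.test(sc$p[!sc$skipped], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Fisher combination matches closed forms and is monotone", {
  expect_equal(fisher_combine(0.05), 0.05, tolerance = 1e-12)
  X <- -2 * log(0.25)
  expect_equal(fisher_combine(c(0.5, 0.5)), exp(-X / 2) * (1 + X / 2),
               tolerance = 1e-10)
  expect_equal(fisher_combine(c(1, 1, 1)), 1, tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 0)), "floor")
  set.seed(66)
  for (i in 1:20) {
    p <- runif(4)
    q <- p; q[sample(4, 1)] <- q[sample(4, 1)] / 2
    expect_lte(fisher_combine(pmin(q, p)), fisher_combine(p) + 1e-15)
  }
})

test_that("meta scan combines per-trait scans marker-wise", {
  set.seed(67)
  n_strain <- 20
  dos <- matrix(rbinom(n_strain * 8, 1, 0.5), n_strain, 8)
  g <- tiny_genotypes(dos)
  K <- kinship_matrix(g)
  sids <- g$strain_ids
  scans <- lapply(1:3, function(i) {
    lmm_scan(setNames(rnorm(n_strain), sids), NULL, g, K, strain_ids = sids,
             maf_min = 0)
  })
  ms <- meta_scan(scans)
  j <- which(!is.na(ms$meta_p))[1]
  expect_equal(ms$meta_p[j],
               fisher_combine(sapply(scans, function(s) s$p[j])),
               tolerance = 1e-12)
})

test_that("p-to-LOD conversion reproduces printed pairs and inverts", {
  expect_equal(round(p_to_lod(3.5e-6), 1), 4.7)
  expect_equal(round(p_to_lod(9e-7), 1), 5.2)
  expect_equal(p_to_lod(0.5), qchisq(0.5, 1) / (2 * log(10)), tolerance = 1e-12)
  expect_equal(p_to_lod(0.5), 0.0988, tolerance = 1e-3)
  p <- c(1e-8, 1e-4, 0.01, 0.3, 0.9)
  expect_true(all(diff(p_to_lod(p)) < 0))
  expect_equal(lod_to_p(p_to_lod(p)), p, tolerance = 1e-10)
  expect_error(p_to_lod(0), "strictly")
  expect_error(p_to_lod(1), "strictly")
})

test_that("ANOVA heritability matches hand sums of squares", {
  expect_equal(anova_heritability(c(1, 1, 3, 3), c("A", "A", "B", "B")), 1)
  expect_equal(anova_heritability(c(1, 3, 1, 3), c("A", "A", "B", "B")), 0)
  expect_equal(anova_heritability(c(0, 2, 4, 6), c("A", "A", "B", "B")), 0.8,
               tolerance = 1e-12)
  expect_error(anova_heritability(c(1, 1, 1, 1), c("A", "A", "B", "B")), "constant")
  expect_error(anova_heritability(1:4, c("A", "B", "C", "D")), ">= 2")
})

test_that("marker-specific linkage matches a normal-equations oracle", {
  # balanced null: equal trait in both classes
  tr <- c(1, 1, 1, 2, 2, 2, 1, 1, 1, 2, 2, 2)
  gt <- rep(c(0, 1), each = 6)
  dt <- rep(c("CD", "HFD"), 6)
  fit <- marker_linkage(c(tr[1:6], tr[1:6]), gt, dt)
  expect_equal(fit$estimate, 0, tolerance = 1e-12)
  expect_gt(fit$p, 0.99)

  # hand-solvable design vs explicit normal equations
  set.seed(68)
  y <- rnorm(6); g6 <- c(0, 0, 0, 1, 1, 1); d6 <- c("CD", "HFD", "CD", "HFD", "CD", "HFD")
  got <- marker_linkage(y, g6, d6)
  X <- cbind(1, g6, as.numeric(d6 == "HFD"))
  bh <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% bh
  s2 <- sum(r^2) / 3
  se <- sqrt(diag(solve(t(X) %*% X)) * s2)
  expect_equal(got$estimate, bh[2], tolerance = 1e-10)
  expect_equal(got$se, unname(se[2]), tolerance = 1e-10)

  # heterozygotes are excluded before fitting
  y2 <- c(y, 100); g2 <- c(g6, 0.5); d2 <- c(d6, "CD")
  got2 <- marker_linkage(y2, g2, d2)
  expect_equal(got2$estimate, got$estimate, tolerance = 1e-12)
  expect_identical(got2$n, 6L)
  expect_error(marker_linkage(y, rep(0, 6), d6), "both homozygote")

  # planted genotype shift recovered within 3 SE
  set.seed(69)
  n <- 300
  gg <- rbinom(n, 1, 0.5); dd <- sample(c("CD", "HFD"), n, TRUE)
  yy <- 0.1 * gg + 0.05 * (dd == "HFD") + rnorm(n, 0, 0.2)
  rec <- marker_linkage(yy, gg, dd)
  expect_lt(abs(rec$estimate - 0.1), 3 * rec$se)
})

test_that("random-intercept weight model matches OLS when mice are exchangeable", {
  set.seed(70)
  m <- 60
  mouse <- rep(sprintf("M%02d", 1:m), each = 2)
  age <- rep(c(0.5, 1.5), m)
  diet <- rep(sample(c("CD", "HFD"), m, TRUE), each = 2)
  geno <- rep(rbinom(m, 1, 0.5), each = 2)
  # zero between-mouse variance
  w <- 30 + 2 * age + 3 * (diet == "HFD") - 1 * geno + rnorm(2 * m, 0, 0.5)
  got <- random_intercept_weight_model(w, age, diet, geno, mouse)
  ols <- coef(lm(w ~ age + factor(diet) + geno))
  expect_equal(got$estimate, unname(ols), tolerance = 1e-3)
})

test_that("balanced-design fixed effects equal their closed-form estimators", {
  # balanced two-occasion design: GLS = stratum-wise OLS, so the age effect
  # is the mean within-mouse difference and the genotype effect the
  # difference of genotype-group means of mouse means (diet orthogonal)
  set.seed(71)
  m <- 40
  mouse <- rep(sprintf("M%02d", 1:m), each = 2)
  age <- rep(c(0, 1), m)
  geno_m <- rep(c(0, 1), m / 2)
  diet_m <- rep(c("CD", "HFD"), each = m / 2)
  geno <- rep(geno_m, each = 2)
  diet <- rep(diet_m, each = 2)
  u <- rnorm(m, 0, 2)
  w <- 30 + 1.5 * age - 1.8 * geno + 2.5 * (diet == "HFD") +
    rep(u, each = 2) + rnorm(2 * m, 0, 0.4)
  got <- random_intercept_weight_model(w, age, diet, geno, mouse)
  d_i <- tapply(w, mouse, function(v) v[2] - v[1])
  age_hat <- mean(d_i)
  mbar <- tapply(w, mouse, mean)
  geno_hat <- mean(mbar[geno_m == 1]) - mean(mbar[geno_m == 0])
  expect_equal(got$estimate[got$term == "age"], age_hat, tolerance = 1e-6)
  expect_equal(got$estimate[got$term == "genotype"], unname(geno_hat), tolerance = 1e-6)

  # planted genotype effect recovered within 3 SE at scale
  set.seed(72)
  m2 <- 200
  mouse2 <- rep(sprintf("N%03d", 1:m2), each = 4)
  age2 <- rep(c(4, 6, 12, 18), m2)
  geno2 <- rep(rbinom(m2, 1, 0.5), each = 4)
  diet2 <- rep(sample(c("CD", "HFD"), m2, TRUE), each = 4)
  w2 <- 28 + 0.4 * age2 + 5 * (diet2 == "HFD") - 1.8 * geno2 +
    rep(rnorm(m2, 0, 2.5), each = 4) + rnorm(4 * m2, 0, 1.2)
  got2 <- random_intercept_weight_model(w2, age2, diet2, geno2, mouse2)
  gi <- got2[got2$term == "genotype", ]
  expect_lt(abs(gi$estimate - (-1.8)), 3 * gi$se)
})

test_that("the planted EAA locus is the top scan hit near the causal marker", {
  cfg <- sim_config(seed = 81)
  g <- simulate_ri_genotypes(cfg)
  ch <- simulate_cohort(cfg, g)
  covar <- cbind(diet = as.numeric(ch$samples$diet == "HFD"), bwf = ch$samples$bwf)
  trait <- ch$truth$eaa_offset
  K <- kinship_matrix(g)
  sc <- lmm_scan(trait, covar, g, K, strain_ids = ch$samples$strain_id)
  expect_lte(abs(which.min(sc$p) - cfg$eaa_qtl_marker_index), 2)
})
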