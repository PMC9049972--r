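test_that("principal components recover planted low-rank structure", {
  # rank-1 matrix: PC1 carries all the variance
  u <- seq(0, 1, length.out = 10)
  v <- runif(8, 0.2, 0.8)
  beta <- 0.4 + 0.1 * outer(u - mean(u), v - mean(v))
  dimnames(beta) <- list(sprintf("s%d", 1:10), sprintf("cg%d", 1:8))
  pc <- compute_pcs(methylome(beta), n_components = 2)
  expect_equal(pc$variance_fraction[1], 1, tolerance = 1e-10)

  # duplicated samples share scores
  beta2 <- rbind(beta, beta[1, , drop = FALSE])
  rownames(beta2)[11] <- "dup"
  pc2 <- compute_pcs(methylome(beta2), n_components = 2)
  expect_equal(pc2$scores["dup", ], pc2$scores["s1", ], tolerance = 1e-10)

  # planted 2-factor matrix: top-2 score subspace matches the factors
  set.seed(9)
  n <- 40; m <- 60
  f <- qr.Q(qr(scale(matrix(rnorm(n * 2), n, 2), scale = FALSE)))
  load <- matrix(rnorm(2 * m), 2, m)
  x <- 0.5 + 0.05 * f %*% load
  dimnames(x) <- list(sprintf("s%d", 1:n), sprintf("cg%d", 1:m))
  pc3 <- compute_pcs(methylome(x), n_components = 2)
  proj <- f %*% solve(crossprod(f)) %*% crossprod(f, scale(pc3$scores, scale = FALSE))
  angle <- max(abs(scale(pc3$scores, scale = FALSE) - proj))
  expect_lt(angle, 1e-8)
  expect_error(compute_pcs(methylome(beta), n_components = 50), "exceeds")
})

ewas_toy <- function(n = 10, n_cpg = 3, seed = 44, beta_builder = NULL) {
  set.seed(seed)
  samples <- sample_table(data.frame(
    sample_id = sprintf("s%d", 1:n),
    strain_id = rep(c("A", "B"), length.out = n),
    sex = "F",
    diet = rep(c("CD", "CD", "HFD", "HFD"), length.out = n),
    age = seq(0.5, 2.5, length.out = n) + rnorm(n, 0, 0.05),
    bw0 = 30, bw1 = 33, bwf = rnorm(n, 40, 4), batch = "b1",
    stringsAsFactors = FALSE
  ))
  longevity <- longevity_table(data.frame(
    strain_id = rep(c("A", "B"), each = 2), diet = rep(c("CD", "HFD"), 2),
    n_deaths = 8, median_ls = c(800, 720, 650, 570),
    stringsAsFactors = FALSE
  ))
  beta <- if (is.null(beta_builder)) {
    matrix(runif(n * n_cpg, 0.2, 0.8), n, n_cpg)
  } else {
    beta_builder(samples)
  }
  dimnames(beta) <- list(samples$sample_id, sprintf("cg%d", seq_len(ncol(beta))))
  list(meth = methylome(beta), samples = samples, longevity = longevity)
}

test_that("an exact planted age signal is recovered with near-zero error", {
  toy <- ewas_toy(n = 30, beta_builder = function(s) {
    cbind(0.2 + 0.1 * s$age, matrix(runif(30 * 2, 0.3, 0.7), 30, 2))
  })
  pcs <- compute_pcs(toy$meth, n_components = 1)
  tab <- fit_site_regressions(toy$meth, toy$samples, toy$longevity, pcs)
  expect_equal(tab$estimate_age[1], 0.1, tolerance = 1e-6)
  expect_lt(tab$p_age[1], 1e-12)
})

test_that("site regressions match a hand-written normal-equations oracle", {
  toy <- ewas_toy(n = 10, n_cpg = 5)
  pcs <- compute_pcs(toy$meth, n_components = 1)
  tab <- fit_site_regressions(toy$meth, toy$samples, toy$longevity, pcs)

  key <- paste(toy$samples$strain_id, toy$samples$diet)
  lkey <- paste(toy$longevity$strain_id, toy$longevity$diet)
  X <- cbind(1, toy$samples$age, toy$longevity$median_ls[match(key, lkey)],
             as.numeric(toy$samples$diet == "HFD"), toy$samples$bwf,
             pcs$scores[, 1])
  for (j in 1:5) {
    y <- toy$meth$beta[, j]
    bh <- solve(t(X) %*% X, t(X) %*% y)
    r <- y - X %*% bh
    s2 <- sum(r^2) / (nrow(X) - ncol(X))
    ses <- sqrt(diag(solve(t(X) %*% X)) * s2)
    tt <- bh / ses
    pp <- 2 * pt(abs(tt), nrow(X) - ncol(X), lower.tail = FALSE)
    expect_equal(tab$estimate_age[j], bh[2], tolerance = 1e-10)
    expect_equal(tab$se_age[j], ses[2], tolerance = 1e-10)
    expect_equal(tab$p_age[j], pp[2], tolerance = 1e-10)
    expect_equal(tab$estimate_diet[j], bh[4], tolerance = 1e-10)
    expect_equal(tab$p_bwf[j], pp[5], tolerance = 1e-10)
  }
})

test_that("rank-deficient designs and missing lifespan rows are handled", {
  toy <- ewas_toy(n = 12)
  # collapse lifespan onto diet -> collinear with the diet indicator
  toy$longevity$median_ls <- ifelse(toy$longevity$diet == "HFD", 600, 700)
  lt2 <- toy$longevity
  expect_error(
    fit_site_regressions(toy$meth, toy$samples, lt2,
                         compute_pcs(toy$meth, 1)),
    "collinear"
  )
  # a strain with no longevity row drops its samples with a message
  set.seed(45)
  n <- 18
  samples <- sample_table(data.frame(
    sample_id = sprintf("s%d", 1:n),
    strain_id = rep(c("A", "B", "C"), length.out = n), sex = "F",
    diet = rep(c("CD", "CD", "CD", "HFD", "HFD", "HFD"), length.out = n),
    age = seq(0.5, 2.5, length.out = n) + rnorm(n, 0, 0.05),
    bw0 = 30, bw1 = 33, bwf = rnorm(n, 40, 4), batch = "b1",
    stringsAsFactors = FALSE
  ))
  longevity <- longevity_table(data.frame(
    strain_id = rep(c("A", "B"), each = 2), diet = rep(c("CD", "HFD"), 2),
    n_deaths = 8, median_ls = c(800, 720, 650, 570), stringsAsFactors = FALSE
  ))
  beta <- matrix(runif(n * 4, 0.2, 0.8), n, 4,
                 dimnames = list(samples$sample_id, sprintf("cg%d", 1:4)))
  meth2 <- methylome(beta)
  expect_message(
    tab <- fit_site_regressions(meth2, samples, longevity,
                                compute_pcs(meth2, 1)),
    "dropping"
  )
  expect_identical(attr(tab, "n_used"), 12L)
})

test_that("DMC classification applies an inclusive Bonferroni cutoff by sign", {
  tab <- structure(
    data.frame(
      cpg_id = c("a", "b", "c", "d"),
      estimate_age = c(0.2, -0.3, 0.1, 0.5),
      se_age = 0.1, p_age = c(0.05 / 4, 0.05 / 4 + 1e-12, 0.9, 1e-8),
      estimate_lifespan = 0, se_lifespan = 1, p_lifespan = 1,
      estimate_diet = 0, se_diet = 1, p_diet = 1,
      estimate_bwf = 0, se_bwf = 1, p_bwf = c(1, 1, 1e-9, 1),
      stringsAsFactors = FALSE
    ),
    class = c("ewas_table", "data.frame")
  )
  out <- classify_dmcs(tab, alpha = 0.05, n_tests = 4)
  expect_identical(out$class, c("age-gain", "age-ns", "age-ns", "age-gain"))
  expect_identical(out$weight_dmc, c(FALSE, FALSE, TRUE, FALSE))
  # all p = 1 -> nothing classified
  tab$p_age <- 1; tab$p_bwf <- 1
  out2 <- classify_dmcs(tab, n_tests = 4)
  expect_true(all(out2$class == "age-ns"))
  # Bonferroni monotonicity: larger denominators never add DMCs
  for (nt in c(4, 40, 400)) {
    cls <- classify_dmcs(tab, n_tests = nt)
    expect_true(all(cls$class == "age-ns"))
  }
  expect_error(classify_dmcs(tab, n_tests = 2), "n_tests")
})

test_that("planted age-DMCs are recovered with correct signs", {
  dat <- simulate_study(sim_config(seed = 21))
  tab <- classify_dmcs(
    fit_site_regressions(dat$meth, dat$samples, dat$longevity,
                         compute_pcs(dat$meth)),
    n_tests = 2000
  )
  truth_cls <- dat$truth$class[match(tab$cpg_id, dat$truth$cpg_ids)]
  recall <- mean(tab$class[truth_cls != "age-ns"] != "age-ns")
  expect_gte(recall, 0.8)
  hits <- tab$class != "age-ns" & truth_cls != "age-ns"
  expect_identical(tab$class[hits],
                   ifelse(dat$truth$slope[match(tab$cpg_id[hits], dat$truth$cpg_ids)] > 0,
                          "age-gain", "age-loss"))
  # age estimates unbiased on the planted (logit-slope derived) signal:
  # check the sign pattern rather than the scale, which is attenuated by
  # the logistic link
  est <- tab$estimate_age[truth_cls == "age-gain"]
  expect_gt(mean(est > 0), 0.95)
})

test_that("DMC overlap counts match brute-force enumeration", {
  set.seed(77)
  n <- 300
  tab <- data.frame(
    cpg_id = sprintf("cg%d", 1:n),
    class = sample(c("age-gain", "age-loss", "age-ns"), n, TRUE),
    weight_dmc = sample(c(TRUE, FALSE), n, TRUE),
    diet_dmc = sample(c(TRUE, FALSE), n, TRUE),
    ls_dmc = sample(c(TRUE, FALSE), n, TRUE)
  )
  out <- overlap_dmcs(tab)
  mem <- cbind(age = tab$class != "age-ns", weight = tab$weight_dmc,
               diet = tab$diet_dmc, ls = tab$ls_dmc)
  for (i in seq_len(nrow(out))) {
    want <- as.logical(out[i, c("age", "weight", "diet", "ls")])
    expect_identical(out$count[i],
                     sum(colSums(t(mem) == want) == 4L))
  }
  # marginals are consistent with region sums
  expect_identical(sum(out$count[out$age]), sum(mem[, "age"]))
  # disjoint and identical planted sets
  tab2 <- tab; tab2$weight_dmc <- tab2$class != "age-ns"
  tab2$diet_dmc <- FALSE; tab2$ls_dmc <- FALSE
  out2 <- overlap_dmcs(tab2)
  full <- out2$count[out2$age & out2$weight & !out2$diet & !out2$ls]
  expect_identical(full, sum(tab2$class != "age-ns"))
})

test_that("null simulation attains nominal type-I error for the age test", {
  cfg <- sim_config(n_strains = 20, replicates_per_strain = 10, n_cpgs = 5000,
                    n_age_gain = 0, n_age_loss = 0, weight_effect = 0,
                    lifespan_effect = 0, diet_aug = 0,
                    eaa_qtl_effect = 0, eaa_noise_sd = 0, batch_sd = 0,
                    seed = 33)
  dat <- simulate_study(cfg)
  tab <- fit_site_regressions(dat$meth, dat$samples, dat$longevity,
                              compute_pcs(dat$meth))
  frac <- mean(tab$p_age < 0.05)
  band <- qnorm(0.995) * sqrt(0.05 * 0.95 / 5000)
  expect_lt(abs(frac - 0.05), band)
})
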