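test_that("pedigree kinship reproduces textbook coefficients", {
  fam <- six_member_fam()
  kin <- pedigree_kinship(fam)
  phi <- as.matrix(kin$phi)
  dimnames(phi) <- list(kin$ids, kin$ids)
  expect_equal(phi["dad", "kid1"], 0.25)    # parent-offspring
  expect_equal(phi["dad", "mum"], 0)        # two founders
  expect_equal(phi["kid1", "kid2"], 0.25)   # full sibs
  expect_equal(phi["kid1", "half"], 0.125)  # half sibs
  expect_equal(phi["lone", "kid1"], 0)
  expect_equal(unname(diag(phi)), rep(0.5, 6))
  # independent oracle: allele-dropping simulation
  set.seed(5)
  gd <- gene_drop_kinship(fam, reps = 6000)
  expect_equal(unname(phi), gd, tolerance = 0.02)
})

test_that("pedigree loops are rejected", {
  fam <- data.frame(family_id = "F", participant_id = c("a", "b"),
                    father_id = c("b", "a"), mother_id = c(NA, NA),
                    sex = "male", phenotype = -9)
  expect_error(pedigree_kinship(fam), "own ancestors")
})

test_that("genotype PCs separate simulated subpopulations and are orthogonal", {
  cfg <- sim_config(n_individuals = 600, founder_allele_freq = 0.01,
                    n_genome_variants = 400, n_region_variants = 12,
                    trait_panel = default_trait_panel()[1:2, ],
                    n_subpops = 2, subpop_delta = 0.6, seed = 21)
  sim <- simulate_cohort(cfg)
  pcs <- genotype_pcs(sim$genome, 4)
  pop <- sim$truth$subpop
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  gram <- crossprod(pcs)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  expect_equal(ncol(genotype_pcs(sim$genome, 0)), 0)
  # constant columns are dropped with a warning, not an error
  gm2 <- sim$genome
  gm2$dosage[, 3] <- 1
  expect_warning(genotype_pcs(gm2, 2), "constant")
})

test_that("unrelated selection drops the younger of a related pair, then case-linked controls", {
  fam <- six_member_fam()
  kin <- pedigree_kinship(fam)
  ages <- c(dad = 60, mum = 58, kid1 = 30, kid2 = 50, half = 20, lone = 40)
  # all controls: sib pair (30, 50) -> the 30-year-old goes; kid2 related to
  # dad (0.25) -> younger of that pair goes too
  groups <- setNames(rep("control", 6), fam$participant_id)
  kept <- select_unrelated(kin, ages[kin$ids], groups, case_level = "case")
  expect_false("kid1" %in% kept)
  expect_true("lone" %in% kept)
  phi <- as.matrix(kin$phi); dimnames(phi) <- list(kin$ids, kin$ids)
  expect_true(all(phi[kept, kept][upper.tri(diag(length(kept)))] <= 0.125))
  # a control related to a case is removed even if unrelated to controls
  groups2 <- setNames(c("case", rep("control", 5)), fam$participant_id)
  kept2 <- select_unrelated(kin, ages[kin$ids], groups2, case_level = "case")
  expect_true("dad" %in% kept2)          # the case stays
  expect_false(any(c("kid1", "kid2", "half") %in% kept2)) # its children go
  expect_true(all(c("mum", "lone") %in% kept2))
  # unrelated singletons are all kept
  fam3 <- data.frame(family_id = paste0("S", 1:3),
                     participant_id = c("x", "y", "z"),
                     father_id = NA, mother_id = NA, sex = "male",
                     phenotype = -9)
  kin3 <- pedigree_kinship(fam3)
  expect_setequal(select_unrelated(kin3, c(10, 20, 30),
                                   rep("control", 3), case_level = "case"),
                  c("x", "y", "z"))
})

test_that("unrelated selection is invariant to input row order", {
  sim <- small_sim()
  kin <- pedigree_kinship(sim$fam)
  gr <- assign_groups(sim$cohort)
  groups <- as.character(gr$group[match(kin$ids, gr$participant_id)])
  ages <- sim$cohort$age[match(kin$ids, sim$cohort$participant_id)]
  kept1 <- select_unrelated(kin, ages, groups,
                            case_level = "asymptomatic_carrier")
  set.seed(3)
  perm <- sample(length(kin$ids))
  kin2 <- kinship_matrix(kin$phi[perm, perm], kin$ids[perm], "pedigree")
  kept2 <- select_unrelated(kin2, ages[perm], groups[perm],
                            case_level = "asymptomatic_carrier")
  expect_setequal(kept1, kept2)
})

test_that("with identity relatedness the mixed model collapses to OLS", {
  set.seed(8)
  n <- 120
  covar <- data.frame(age = rnorm(n, 40, 10), sex = factor(
    sample(c("female", "male"), n, TRUE)))
  outcome <- rbinom(n, 1, 0.3)
  y <- 2 + 0.1 * covar$age + 1.5 * (covar$sex == "male") - 0.8 * outcome +
    rnorm(n)
  kin <- kinship_matrix(Matrix::Diagonal(n) * 0.5, paste0("i", 1:n),
                        "pedigree")
  fit <- fit_lmm(y, covar, outcome, kin)
  ols <- lm(y ~ age + sex + outcome, data = cbind(covar, outcome = outcome))
  expect_equal(fit$coefficients$beta, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(coef(summary(ols))[, 2]), tolerance = 1e-6)
  # REML objective at the optimum beats the bracket endpoints
  expect_lte(min(fit$grid_nll), fit$grid_nll[1] + 1e-8)
  expect_lte(min(fit$grid_nll), fit$grid_nll[length(fit$grid_nll)] + 1e-8)
})

test_that("rotated weighted fit equals explicit GLS at a fixed variance ratio", {
  set.seed(13)
  fam <- do.call(rbind, lapply(1:10, function(f) data.frame(
    family_id = paste0("F", f),
    participant_id = paste0("F", f, "_", 1:5),
    father_id = c(NA, NA, rep(paste0("F", f, "_1"), 3)),
    mother_id = c(NA, NA, rep(paste0("F", f, "_2"), 3)),
    sex = "female", phenotype = -9)))
  kin <- pedigree_kinship(fam)
  n <- 50
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  K <- as.matrix(2 * kin$phi)
  y <- drop(X %*% c(1, 0.5, -1)) +
    drop(chol(0.8 * K + 0.6 * diag(n)) %*% rnorm(n))
  eig <- kinship_eigen(kin)
  Xt <- as.matrix(Matrix::crossprod(eig$U, X))
  yt <- as.numeric(Matrix::crossprod(eig$U, y))
  for (lam in c(0.25, 1, 4)) {
    w <- 1 / (lam * eig$d + 1)
    beta_rot <- solve(crossprod(Xt, Xt * w), crossprod(Xt, yt * w))
    Vi <- solve(lam * K + diag(n))
    beta_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    expect_equal(drop(beta_rot), drop(beta_gls), tolerance = 1e-8)
  }
})

test_that("the mixed model recovers a known trait effect under family variance", {
  # outcome effect -5.7 with genuine kinship variance; the estimate should
  # fall within 2 SE of the truth in almost all replicates
  fam <- do.call(rbind, lapply(1:120, function(f) data.frame(
    family_id = paste0("F", f),
    participant_id = paste0("F", f, "_", 1:4),
    father_id = c(NA, NA, rep(paste0("F", f, "_1"), 2)),
    mother_id = c(NA, NA, rep(paste0("F", f, "_2"), 2)),
    sex = "female", phenotype = -9)))
  kin <- pedigree_kinship(fam)
  n <- length(kin$ids)
  K <- as.matrix(2 * kin$phi)
  R <- chol(6^2 * K + 8^2 * diag(n))
  cover <- 0
  nrep <- 30
  for (s in seq_len(nrep)) {
    set.seed(100 + s)
    covar <- data.frame(age = rnorm(n, 40, 12))
    outcome <- rbinom(n, 1, 0.25)
    y <- 90 + 0.1 * covar$age - 5.7 * outcome + drop(crossprod(R, rnorm(n)))
    fit <- fit_lmm(y, covar, outcome, kin)
    oc <- outcome_coef(fit)
    cover <- cover + (abs(oc$beta - (-5.7)) <= 2 * oc$se)
  }
  expect_gte(cover, round(0.85 * nrep))
})

test_that("logistic fits report Wald statistics, ORs and separation flags", {
  set.seed(30)
  n <- 4000
  covar <- data.frame(age = rnorm(n, 40, 10))
  x <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-2 + 0.7 * x))
  fit <- fit_logistic(y, covar, x)
  expect_false(fit$flagged)
  expect_equal(fit$or, exp(fit$beta))
  expect_lt(abs(fit$beta - 0.7), 4 * fit$se)
  glmfit <- glm(y ~ age + x, family = binomial(), data = cbind(covar, x = x))
  expect_equal(fit$beta, unname(coef(glmfit)["x"]), tolerance = 1e-6)
  expect_equal(fit$se, unname(coef(summary(glmfit))["x", 2]),
               tolerance = 1e-5)
  # complete separation -> flagged, missing p
  ys <- as.integer(x >= 1)
  fs <- fit_logistic(ys, covar, x)
  expect_true(fs$flagged)
  expect_true(is.na(fs$p))
  expect_error(fit_logistic(rep(1, n), covar, x), "both classes")
})

test_that("logistic null z-statistics are calibrated", {
  set.seed(31)
  n <- 3000
  big <- 0
  for (s in 1:25) {
    covar <- data.frame(age = rnorm(n, 40, 10))
    y <- rbinom(n, 1, 0.05)
    x <- rbinom(n, 2, 0.25)     # independent of y
    fit <- fit_logistic(y, covar, x)
    big <- big + (abs(fit$beta / fit$se) >= 4)
  }
  expect_lte(big, 1)
})
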