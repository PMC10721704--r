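# Assemble a small two-group analysis block (asymptomatic carriers vs
# asymptomatic non-carriers) from the shared simulated cohort.
screen_block <- function() {
  sim <- small_sim()
  coh <- sim$cohort
  gr <- assign_groups(coh)
  kin <- pedigree_kinship(sim$fam)
  grp <- gr$group[match(coh$participant_id, gr$participant_id)]
  rows <- which(grp %in% c("asymptomatic_carrier", "asymptomatic_noncarrier"))
  ki <- match(coh$participant_id[rows], kin$ids)
  list(
    cohort = coh, groups = gr, kinship = kin, rows = rows,
    outcome = as.integer(grp[rows] == "asymptomatic_carrier"),
    covariates = data.frame(age = coh$age[rows], age2 = coh$age[rows]^2,
                            sex = factor(coh$sex[rows])),
    kin_sub = kinship_matrix(kin$phi[ki, ki], kin$ids[ki], "pedigree"))
}

test_that("rank-normalization follows the Blom formula and its invariances", {
  # closed form at n = 3: qnorm((r - 3/8) / 3.25)
  expect_equal(rank_normalize(c(1, 2, 3)),
               c(-0.869424, 0, 0.869424), tolerance = 1e-6)
  set.seed(1)
  x <- rexp(1000)
  z <- rank_normalize(x)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(var(z) - 1), 0.05)
  # invariant under monotone transforms of the input
  expect_equal(rank_normalize(log(x)), z)
  # ties share their average rank; missing values stay missing
  zt <- rank_normalize(c(5, 5, 1, NA))
  expect_equal(zt[1], zt[2])
  expect_true(is.na(zt[4]))
  expect_error(rank_normalize(c(2, 2, 2)), "equal")
  expect_error(rank_normalize(c(1, NA, NA)), "two non-missing")
})

test_that("empirical q-values follow the pooled-null formula", {
  # observed rank 1, smaller than every pooled permutation p -> q = 1/B
  B <- 200
  perm <- matrix(runif(B * 5, 0.2, 1), B, 5)
  p <- c(0.001, 0.3, 0.5, 0.7, 0.9)
  q <- empirical_q(p, perm)
  expect_equal(q[1], 1 / B)
  # all observed p = 1 -> all q = 1
  expect_equal(empirical_q(rep(1, 5), perm), rep(1, 5))
  # q is monotone nondecreasing in p
  set.seed(2)
  perm2 <- matrix(runif(B * 20), B, 20)
  p2 <- sort(runif(20))
  q2 <- empirical_q(p2, perm2)
  expect_true(all(diff(q2) >= 0))
  expect_true(all(q2 >= 0 & q2 <= 1))
  # hand-computed Storey plug-in on a tiny case
  perm3 <- matrix(c(0.05, 0.2, 0.6, 0.8, 0.3, 0.9), nrow = 2) # B=2, T=3
  p3 <- c(0.1, 0.25, 0.95)
  # counts in pool <= p: 1, 2, 6; observed counts: 1, 2, 3
  expect_equal(empirical_q(p3, perm3, method = "storey"),
               cummax(pmin(1, c(0.5 / 1, 1 / 2, 3 / 3))))
  # pooled empirical p-value variant
  expect_equal(empirical_q(p3, perm3, method = "pooled_p"),
               c(1 / 6, 2 / 6, 1))
  # missing observed p propagates, and does not disturb the others
  expect_equal(empirical_q(c(p3, NA), perm3)[4], NA_real_)
})

test_that("null traits give uniform screen p-values", {
  blk <- screen_block()
  set.seed(77)
  n <- length(blk$outcome)
  Y <- matrix(rnorm(n * 150), n, 150,
              dimnames = list(NULL, paste0("t", 1:150)))
  res <- run_step1_matrix <- permutation_q(
    Y, list(covariates = blk$covariates, outcome = blk$outcome,
            kinship = blk$kin_sub), B = 100, seed = 5)$results
  ks <- ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a trait equal to the outcome collapses to p ~ 0, constants are skipped", {
  blk <- screen_block()
  Y <- cbind(perfect = blk$outcome + 0,
             flat = rep(1, length(blk$outcome)))
  expect_warning(
    res <- penescreen:::lmm_trait_screen(Y, blk$covariates, blk$outcome,
                                         blk$kin_sub)$results,
    "flat")
  expect_lt(res$p[1], 1e-12)
  expect_true(is.na(res$p[2]))
})

test_that("permutation q-values are reproducible and order-invariant", {
  blk <- screen_block()
  set.seed(9)
  n <- length(blk$outcome)
  Y <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("t", 1:6)))
  Y[, 3] <- Y[, 3] - 0.8 * blk$outcome
  fixed <- list(covariates = blk$covariates, outcome = blk$outcome,
                kinship = blk$kin_sub)
  r1 <- permutation_q(Y, fixed, B = 100, seed = 11)
  r2 <- permutation_q(Y, fixed, B = 100, seed = 11)
  expect_identical(r1$results$q, r2$results$q)
  perm <- c(4, 2, 6, 1, 3, 5)
  r3 <- permutation_q(Y[, perm], fixed, B = 100, seed = 11)
  expect_equal(r3$results$q[match(r1$results$trait, r3$results$trait)],
               r1$results$q)
})

test_that("directional confirmation separates protective from direct effects", {
  sim <- small_sim()
  coh <- sim$cohort
  gr <- assign_groups(coh)
  kin <- pedigree_kinship(sim$fam)
  grp <- as.character(gr$group[match(coh$participant_id, gr$participant_id)])
  # protective: shifted only in asymptomatic carriers (large, deterministic)
  coh$QRS_v1 <- coh$QRS_v1 - 40 * (grp == "asymptomatic_carrier")
  # direct variant effect: shifted in all carriers
  coh$PQ_v1 <- coh$PQ_v1 - 40 * (coh$carrier == 1)
  s1 <- run_step1(coh, gr, kin, traits = c("QRS", "PQ"))
  expect_true(all(s1$p < 1e-6))
  verd <- confirm_directions(s1, coh, gr, kin)
  expect_equal(verd$verdict[verd$trait == "QRS"], "confirmed")
  expect_equal(verd$verdict[verd$trait == "PQ"], "not_confirmed")
  # a contrast group with < 2 members is untestable
  gr2 <- gr
  drop_ids <- gr2$participant_id[gr2$group == "symptomatic_carrier"]
  gr2 <- gr2[!gr2$participant_id %in% drop_ids[-1], ]
  coh2 <- coh[coh$participant_id %in% gr2$participant_id, ]
  attr(coh2, "traits") <- cohort_traits(coh)
  expect_equal(
    confirm_directions(s1[1, ], coh2, gr2, kin)$verdict, "untestable")
  expect_error(confirm_directions(s1[0, ], coh, gr, kin), "no step-1 hits")
})

test_that("matched controls honour ratio, sex and nearest age", {
  set.seed(14)
  cases <- data.frame(participant_id = sprintf("c%02d", 1:48),
                      age = round(runif(48, 20, 70)),
                      sex = sample(c("male", "female"), 48, TRUE))
  pool <- data.frame(participant_id = sprintf("p%04d", 1:2000),
                     age = round(runif(2000, 10, 85)),
                     sex = sample(c("male", "female"), 2000, TRUE))
  mm <- match_controls(cases, pool, ratio = 4)
  expect_equal(nrow(mm), 192)
  expect_equal(unname(table(mm$case_id)[cases$participant_id]),
               rep(4L, 48), ignore_attr = TRUE)
  sex_of <- setNames(pool$sex, pool$participant_id)
  expect_true(all(sex_of[mm$control_id] ==
                    cases$sex[match(mm$case_id, cases$participant_id)]))
  expect_false(anyDuplicated(mm$control_id) > 0)
  # matched mean age within a year of the case mean age
  expect_lt(abs(mean(mm$age_diff)), 1)
  # exact-age duplicates beat +/- 1 year candidates
  cases1 <- data.frame(participant_id = "c1", age = 50, sex = "male")
  pool1 <- data.frame(participant_id = c("a", "b", "c", "d", "e"),
                      age = c(50, 50, 51, 49, 50), sex = "male")
  m1 <- match_controls(cases1, pool1, ratio = 3)
  expect_setequal(m1$control_id, c("a", "b", "e"))
  expect_error(match_controls(cases1, pool1[1:2, ], ratio = 3),
               "insufficient pool")
})

test_that("the full screen recovers strongly injected traits end to end", {
  cfg <- sim_config(n_individuals = 2500, founder_allele_freq = 0.012,
                    n_genome_variants = 150, n_region_variants = 12,
                    group_effects = list(
                      QRS = setNames(c(0, 0, -12, 0),
                                     penescreen:::group_levels)),
                    seed = 55)
  sim <- simulate_cohort(cfg)
  gr <- assign_groups(sim$cohort)
  kin <- pedigree_kinship(sim$fam)
  pcs <- genotype_pcs(sim$genome, 4)
  scr <- run_screen(sim$cohort, gr, kin, pcs = pcs, B = 150, seed = 4,
                    sensitivity = TRUE)
  s1 <- scr$step1
  expect_lte(s1$q[s1$trait == "QRS"], 0.05)
  expect_equal(scr$step2$verdict[scr$step2$trait == "QRS"], "confirmed")
  # sensitivity analyses agree in sign on the injected effect
  expect_lt(scr$sensitivity$rank_normal$beta[
    scr$sensitivity$rank_normal$trait == "QRS"], 0)
  expect_lt(scr$sensitivity$matched$beta[
    scr$sensitivity$matched$trait == "QRS"], 0)
})
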