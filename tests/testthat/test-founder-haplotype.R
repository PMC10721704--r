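# Build a phased carrier-haplotype fixture directly: variants at 1 kb
# spacing, a founder haplotype shared by all carriers inside the span,
# random alleles outside, and optional recombinants whose haplotype beyond
# a breakpoint is the complement of the founder haplotype.
make_hap_fixture <- function(n_car = 70, nv_side = 50, span_left = 30,
                             span_right = 25, recomb = NULL, seed = 1,
                             maf = NULL) {
  set.seed(seed)
  nv <- 2 * nv_side + 1
  center <- nv_side + 1
  pos <- 1000 * seq_len(nv)
  if (is.null(maf)) maf <- runif(nv, 0.1, 0.5)
  h0 <- rbinom(nv, 1, 0.5)
  hap <- matrix(rbinom(n_car * nv, 1, 0.5), n_car, nv,
                dimnames = list(sprintf("c%02d", seq_len(n_car)), NULL))
  span <- (center - span_left):(center + span_right)
  hap[, span] <- matrix(h0[span], n_car, length(span), byrow = TRUE)
  if (!is.null(recomb)) {
    for (i in seq_len(nrow(recomb))) {
      cut <- if (recomb$side[i] == "left")
        span[span < center - recomb$offset[i]]
      else span[span > center + recomb$offset[i]]
      hap[recomb$carrier[i], cut] <- 1 - h0[cut]
    }
  }
  hap[, center] <- 1
  mac <- colSums(hap); mac <- pmin(mac, n_car - mac); mac[center] <- n_car
  structure(list(
    variants = data.frame(chrom = "6", pos = pos,
                          id = c(paste0("v", seq_len(nv))), maf = maf,
                          mac = mac),
    hap = hap, index = center), class = "phased_haplotypes")
}

# Independent modal-group counter used as the enumeration oracle.
modal_count <- function(hap, cols) {
  max(table(apply(hap[, cols, drop = FALSE], 1, paste, collapse = "")))
}

test_that("identical carriers give the full region as one group", {
  fx <- make_hap_fixture(n_car = 20, nv_side = 15, span_left = 15,
                         span_right = 15)
  w <- expand_shared_haplotype(fx, maf_min = 0, split_threshold = 3)
  expect_equal(w$left_pos, fx$variants$pos[1])
  expect_equal(w$right_pos, fx$variants$pos[nrow(fx$variants)])
  expect_length(w$groups, 1)
  expect_equal(w$modal_size, 20)
  expect_equal(unname(w$stop_reason), rep("end_of_region", 2))
})

test_that("window boundaries land where the shared span ends", {
  fx <- make_hap_fixture(seed = 3)
  w <- expand_shared_haplotype(fx, maf_min = 0, split_threshold = 3)
  center <- fx$index
  # the modal group (all 70) splits roughly in half one variant past the
  # span on each side, so the window freezes exactly at the span edges
  expect_equal(w$left_index, center - 30)
  expect_equal(w$right_index, center + 25)
  expect_equal(unname(w$stop_reason), rep("split", 2))
  expect_equal(w$modal_size, 70)
  expect_equal(w$span_bp, w$right_pos - w$left_pos + 1)
  # enumeration oracle: inside the window the modal group never dropped by
  # more than the threshold; one variant further it collapses
  expect_equal(modal_count(fx$hap, w$left_index:w$right_index), 70)
  expect_gt(70 - modal_count(fx$hap, (w$left_index - 1):w$right_index), 3)
  expect_gt(70 - modal_count(fx$hap, w$left_index:(w$right_index + 1)), 3)
})

test_that("recombinant carriers leave the modal group at their breakpoints", {
  rec <- data.frame(carrier = c(5, 12, 33, 61),
                    side = c("left", "left", "right", "right"),
                    offset = c(10, 18, 8, 14))
  fx <- make_hap_fixture(recomb = rec, seed = 9)
  w <- expand_shared_haplotype(fx, maf_min = 0, split_threshold = 3)
  # single-carrier splits (drop of 1) never freeze a side at threshold 3,
  # so the window still reaches the span edges and the modal group is 66
  expect_equal(w$left_index, fx$index - 30)
  expect_equal(w$right_index, fx$index + 25)
  expect_equal(w$modal_size, 66)
  expect_equal(sum(lengths(w$groups)), 70)
  expect_equal(length(w$groups[[1]]), 66)
  expect_false(any(sprintf("c%02d", rec$carrier) %in% w$groups[[1]]))
})

test_that("a shared breakpoint larger than the threshold freezes that side", {
  rec <- data.frame(carrier = c(2, 9, 17, 25, 41),
                    side = "left", offset = 12)
  fx <- make_hap_fixture(recomb = rec, seed = 11)
  w3 <- expand_shared_haplotype(fx, maf_min = 0, split_threshold = 3)
  # five carriers leave at once 13 variants to the left: side freezes there
  # and the offending variant is excluded from the window
  expect_equal(w3$left_index, fx$index - 12)
  expect_equal(w3$right_index, fx$index + 25)
  expect_equal(w3$modal_size, 70)
  # threshold 10 tolerates the 5-carrier split: strictly wider window
  w10 <- expand_shared_haplotype(fx, maf_min = 0, split_threshold = 10)
  expect_lt(w10$left_index, w3$left_index)
  expect_gte(w3$right_index, w3$left_index)
  expect_true(w10$left_index <= w3$left_index &&
                w10$right_index >= w3$right_index)
  expect_equal(w10$modal_size, 65)
})

test_that("threshold extremes and row order behave as documented", {
  rec <- data.frame(carrier = c(5, 12), side = c("left", "right"),
                    offset = c(10, 8))
  fx <- make_hap_fixture(recomb = rec, seed = 13)
  # infinite threshold -> the full filtered region
  winf <- expand_shared_haplotype(fx, maf_min = 0, split_threshold = Inf)
  expect_equal(winf$left_index, 1)
  expect_equal(winf$right_index, nrow(fx$variants))
  # zero threshold -> freeze at the first discordant variant on each side
  w0 <- expand_shared_haplotype(fx, maf_min = 0, split_threshold = 0)
  # recombinant tails start 11 variants left / 9 right of the index, so the
  # last concordant additions are at -10 and +8
  expect_equal(w0$left_index, fx$index - 10)
  expect_equal(w0$right_index, fx$index + 8)
  # shuffling carrier rows changes nothing
  set.seed(4)
  fx2 <- fx
  ord <- sample(nrow(fx$hap))
  fx2$hap <- fx$hap[ord, ]
  w1 <- expand_shared_haplotype(fx, maf_min = 0, split_threshold = 3)
  w2 <- expand_shared_haplotype(fx2, maf_min = 0, split_threshold = 3)
  expect_equal(w2$left_index, w1$left_index)
  expect_equal(w2$right_index, w1$right_index)
  expect_equal(sort(lengths(w2$groups)), sort(lengths(w1$groups)))
  expect_setequal(w2$groups[[1]], w1$groups[[1]])
})

test_that("eligibility profiles filter by MAF or carrier MAC", {
  fx <- make_hap_fixture(n_car = 40, nv_side = 10, span_left = 6,
                         span_right = 6, seed = 15)
  fx$variants$maf[c(3, 7)] <- 0.001    # drop under the common profile
  w <- expand_shared_haplotype(fx, profile = "common")
  expect_false(any(c(3, 7) %in% w$eligible))
  expect_equal(w$split_threshold, 3)
  w2 <- expand_shared_haplotype(fx, profile = "rare")
  expect_true(all(fx$variants$mac[setdiff(w2$eligible, fx$index)] >= 4))
  expect_equal(w2$split_threshold, 10)
})

test_that("carrier haplotype extraction picks the deletion-bearing phase", {
  sim <- small_sim()
  ph <- carrier_haplotypes(sim$region)
  expect_setequal(rownames(ph$hap), sim$truth$carriers)
  j <- ph$index
  expect_true(all(ph$hap[, j] == 1))
  expect_error(carrier_haplotypes(sim$region, index_id = "nope"), "not found")
})

test_that("haplotype-group chi-square matches the textbook statistic", {
  lab <- rep(c("H1", "H2"), c(10, 10))
  names(lab) <- sprintf("c%02d", 1:20)
  status <- setNames(c(rep(TRUE, 8), rep(FALSE, 2),
                       rep(TRUE, 3), rep(FALSE, 7)), names(lab))
  res <- haplotype_group_test(lab, status)
  # 2x2 table (8,2 / 3,7): n(ad-bc)^2 / (r1 r2 c1 c2) = 5.0505
  expect_equal(res$statistic, 5.050505, tolerance = 1e-6)
  expect_equal(res$p, 0.0246188, tolerance = 1e-5)
  # perfect alignment of group and status
  status2 <- setNames(rep(c(TRUE, FALSE), c(10, 10)), names(lab))
  expect_lt(haplotype_group_test(lab, status2)$p, 0.01)
  # degenerate expected counts fall back to a Monte-Carlo p
  lab3 <- rep(c("H1", "H2"), c(17, 3))
  names(lab3) <- names(lab)
  status3 <- setNames(rep(c(TRUE, FALSE), c(18, 2)), names(lab))
  expect_warning(r3 <- haplotype_group_test(lab3, status3), "Monte-Carlo")
  expect_true(r3$p > 0 && r3$p <= 1)
  expect_error(haplotype_group_test(rep("H1", 20), status2), "at least two")
})

test_that("haplotype groups independent of status give uniform p-values", {
  set.seed(19)
  ps <- replicate(60, {
    lab <- setNames(rep(c("H1", "H2", "H3"), c(30, 20, 10)),
                    sprintf("c%02d", 1:60))
    status <- setNames(rbinom(60, 1, 0.4) == 1, names(lab))
    haplotype_group_test(lab, status)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
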