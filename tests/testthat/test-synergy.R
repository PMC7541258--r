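# net in which M1/M2 share targets c1..c3 and have private targets
two_mr_net <- function(n_common = 3, n_u1 = 2, n_u2 = 2, mor = 1) {
  cm <- sprintf("c%d", seq_len(n_common))
  u1 <- sprintf("u%d", seq_len(n_u1))
  u2 <- sprintf("w%d", seq_len(n_u2))
  regulatory_network(data.frame(
    regulator = c(rep("M1", n_common + n_u1), rep("M2", n_common + n_u2)),
    target = c(cm, u1, cm, u2),
    mor = mor, likelihood = 0.8, stringsAsFactors = FALSE))
}

test_that("pair eligibility applies strict count and fraction thresholds", {
  expect_false(eligible_pair(100, 50, 10))   # needs strictly more than 10
  expect_true(eligible_pair(100, 50, 11))
  expect_false(eligible_pair(200, 50, 15))   # 7.5% of the larger regulon
  expect_error(eligible_pair(100, 50, 60), "inconsistent")
})

test_that("ECA is the DE x MOR product and is bilinear in DE", {
  expect_equal(eca(3, 0.5), 1.5)
  expect_equal(eca(7, 0), 0)
  expect_equal(eca(-2, -1), 2)
  de <- c(1.5, -2, 0.3)
  mor <- c(0.4, -0.9, 1)
  expect_equal(eca(5 * de, mor), 5 * eca(de, mor))
  expect_error(eca(1, 1.5), "mor")
})

test_that("synergy test matches exact one-sided enumeration", {
  net <- two_mr_net()
  part <- partition_regulons(net, "M1", "M2")
  sig <- de_signature("d", "microarray",
                      c(c1 = 3, c2 = 4, c3 = 5, u1 = 1, u2 = 2,
                        w1 = 1.5, w2 = 2.5))
  ps <- synergy_test(part, sig, +1, +1)
  # common ECA {3,4,5} vs unique1 ECA {1,2}: 1/C(5,3)
  expect_equal(unname(ps["p1"]), 0.1)
  expect_equal(unname(ps["p1"]),
               enumerate_ranksum_p(c(3, 4, 5), c(1, 2), "greater"))
  # suppressed MR flips the alternative: negated scores give the same p
  sig_neg <- de_signature("d", "microarray",
                          -c(c1 = 3, c2 = 4, c3 = 5, u1 = 1, u2 = 2,
                             w1 = 1.5, w2 = 2.5))
  ps_neg <- synergy_test(part, sig_neg, -1, -1)
  expect_equal(unname(ps_neg["p1"]), 0.1)
})

test_that("common regulons weaker than unique ones give p = 1 under the exact test", {
  net <- two_mr_net(n_common = 2, n_u1 = 3)
  part <- partition_regulons(net, "M1", "M2")
  sig <- de_signature("d", "microarray",
                      c(c1 = 1, c2 = 2, u1 = 3, u2 = 4, u3 = 5,
                        w1 = 2.5, w2 = 3.5))
  ps <- synergy_test(part, sig, +1, +1)
  expect_equal(unname(ps["p1"]), 1.0)
  expect_equal(unname(ps["p1"]),
               enumerate_ranksum_p(c(1, 2), c(3, 4, 5), "greater"))
})

test_that("unscored targets are dropped and empty groups yield NA", {
  net <- two_mr_net()
  part <- partition_regulons(net, "M1", "M2")
  # no unique2 target scored -> p2 undefined
  sig <- de_signature("d", "microarray",
                      c(c1 = 3, c2 = 4, c3 = 5, u1 = 1, u2 = 2))
  ps <- synergy_test(part, sig, +1, +1)
  expect_equal(unname(ps["p1"]), 0.1)
  expect_true(is.na(ps["p2"]))
  expect_error(synergy_test(part, sig, 0, 1), "da_sign")
})

test_that("with unit MORs the synergy p is invariant to a constant DE shift", {
  net <- two_mr_net(mor = 1)
  part <- partition_regulons(net, "M1", "M2")
  base <- c(c1 = 3, c2 = 4, c3 = 5, u1 = 1, u2 = 2, w1 = 1.5, w2 = 2.5)
  p0 <- synergy_test(part, de_signature("d", "microarray", base), +1, +1)
  p1 <- synergy_test(part, de_signature("d", "microarray", base + 10), +1, +1)
  expect_equal(p0, p1)
})

test_that("the screen finds exactly the constructed eligible pairs", {
  # 12 candidate MRs; four designated pairs share 12 of 60 targets, the
  # remaining regulators have small disjoint regulons
  gene_id <- local({
    counter <- 0
    function(k) {
      ids <- sprintf("t%04d", counter + seq_len(k))
      counter <<- counter + k
      ids
    }
  })
  rows <- list()
  for (p in 1:4) {
    m1 <- sprintf("M%02d", 2 * p - 1)
    m2 <- sprintf("M%02d", 2 * p)
    cm <- gene_id(12)
    u1 <- gene_id(48)
    u2 <- gene_id(48)
    rows[[length(rows) + 1]] <- data.frame(
      regulator = c(rep(m1, 60), rep(m2, 60)),
      target = c(cm, u1, cm, u2), mor = 1, likelihood = 0.9,
      stringsAsFactors = FALSE)
  }
  for (m in sprintf("M%02d", 9:12)) {
    rows[[length(rows) + 1]] <- data.frame(
      regulator = m, target = gene_id(20), mor = 1, likelihood = 0.9,
      stringsAsFactors = FALSE)
  }
  net <- regulatory_network(do.call(rbind, rows))
  set.seed(61)
  genes <- sort(unique(net$target))
  sig <- de_signature("d1", "microarray",
                      stats::setNames(stats::rnorm(length(genes)), genes))
  das <- list(da_signature(net, sig))
  res <- synergy_screen(net, sprintf("M%02d", 1:12), list(sig), das)
  pairs <- unique(res[c("mr1", "mr2")])
  expect_equal(nrow(pairs), 4)
  expect_equal(pairs$mr1, sprintf("M%02d", c(1, 3, 5, 7)))
  expect_equal(res$common_size, rep(12, 4))
  # a single candidate yields an empty screen
  empty <- synergy_screen(net, "M01", list(sig), das)
  expect_equal(nrow(empty), 0)
  expect_null(top_synergistic_pair(empty))
})

test_that("the top pair minimizes the worst-case p across datasets", {
  res <- data.frame(
    mr1 = c("A", "A", "B", "B"), mr2 = c("B", "B", "C", "C"),
    size1 = 60, size2 = 60, common_size = 12,
    dataset_id = c("d1", "d2", "d1", "d2"),
    da_sign1 = 1, da_sign2 = 1,
    p1 = c(0.01, 0.2, 0.02, 0.03), p2 = c(0.05, 0.1, 0.04, NA),
    stringsAsFactors = FALSE)
  class(res) <- c("synergy_result", "data.frame")
  # A-B worst = 0.2; B-C worst = 1 (NA counts as 1)
  expect_equal(top_synergistic_pair(res), c("A", "B"))
  res$p2[4] <- 0.05
  # now B-C worst = 0.05 < 0.2
  expect_equal(top_synergistic_pair(res), c("B", "C"))
})
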